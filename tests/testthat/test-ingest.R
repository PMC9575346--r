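test_that("delimited genotype tables round-trip with missing cells", {
    path <- writeTinyGenotypeFile()
    g <- readGenotypes(path)
    expect_s4_class(g, "GenotypeExperiment")
    expect_equal(dim(genotypes(g)), c(2L, 3L))   # SNPs x samples
    expect_identical(genotypes(g)["rs2", "s3"], NA_integer_)
    expect_identical(caseLabels(g), c(0L, 1L, 1L))
})

test_that("malformed genotype tables fail with located errors", {
    dir <- withr::local_tempdir()
    bad <- file.path(dir, "bad.csv")
    writeLines(c("sample_id,label,rs1,rs2", "s1,0,0,3"), bad)
    expect_error(readGenotypes(bad), "row 1.*rs2")
    dupSnp <- file.path(dir, "dupsnp.csv")
    writeLines(c("sample_id,label,rs1,rs1", "s1,0,0,1", "s2,1,1,1"), dupSnp)
    expect_error(readGenotypes(dupSnp), "rs1")
    dupSample <- file.path(dir, "dupsample.csv")
    writeLines(c("sample_id,label,rs1", "s1,0,0", "s1,1,1"), dupSample)
    expect_error(readGenotypes(dupSample), "s1")
})

test_that("VCF GT fields map to additive codes with missing half-calls", {
    files <- writeTinyVcf()
    g <- readGenotypes(files$vcf, dialect = "vcf",
                       sampleTable = files$samples, covariates = "BMI")
    m <- genotypes(g)
    expect_identical(m["rs1", ], c(s1 = 1L, s2 = 2L, s3 = NA_integer_))
    expect_identical(m["rs2", ], c(s1 = 1L, s2 = 0L, s3 = NA_integer_))
    expect_identical(caseLabels(g), c(0L, 1L, 1L))
    expect_equal(covariates(g)[, "BMI"], c(s1 = 22.5, s2 = 27.1, s3 = 24))
    expect_error(readGenotypes(files$vcf, dialect = "vcf"),
                 "companion sample table")
})

test_that("gene scores are per-gene means of additive codes", {
    geno <- matrix(c(0L, 1L, 2L,
                     1L, 1L, 1L), nrow = 3,
                   dimnames = list(c("a1", "a2", "a3"), c("s1", "s2")))
    g <- GenotypeExperiment(geno, label = c(0L, 1L))
    map1 <- data.frame(snp = c("a1", "a2", "a3"), gene = "GA")
    expect_equal(unname(geneScores(computeGeneScores(g, map1))["GA", ]),
                 c(1, 1))
    ## single-SNP gene: score equals the genotype code itself
    map2 <- data.frame(snp = "a2", gene = "GB")
    expect_equal(unname(geneScores(computeGeneScores(g, map2))["GB", ]),
                 as.numeric(geno["a2", ]))
})

test_that("missing policies match a hand-evaluated brute-force mean", {
    ## 2 samples x 2 SNPs of one gene, one missing cell
    geno <- matrix(c(2L, NA, 0L, 1L), nrow = 2,
                   dimnames = list(c("r1", "r2"), c("s1", "s2")))
    g <- GenotypeExperiment(geno, label = c(0L, 1L))
    map <- data.frame(snp = c("r1", "r2"), gene = "G")
    ## drop_from_mean: s1 averages its sole observed SNP (r1 = 2)
    drop <- geneScores(computeGeneScores(g, map,
                                         missingPolicy = "drop_from_mean"))
    expect_equal(unname(drop["G", ]), c(mean(2), mean(c(0, 1))))
    ## per_snp_mean_impute: missing r2(s1) <- mean of r2 over samples = 1
    imp <- geneScores(computeGeneScores(g, map))
    expect_equal(unname(imp["G", ]), c(mean(c(2, 1)), mean(c(0, 1))))
    ## brute force over the four cells agrees
    filled <- geno; filled[2, 1] <- mean(geno[2, ], na.rm = TRUE)
    expect_equal(unname(imp["G", ]), unname(colMeans(filled)))
})

test_that("score aggregation is order-invariant and policy-consistent", {
    cfg <- simConfig(nCase = 30, nControl = 30, genes = paste0("G", 1:4),
                     snpsPerGene = 3, plantedEdges = NULL,
                     covariateSpecs = list(), seed = 5)
    cohort <- simulateCohort(cfg)$cohort
    base <- geneScores(computeGeneScores(cohort))
    ## no missing data: the two policies coincide exactly
    dropped <- geneScores(computeGeneScores(cohort,
                                            missingPolicy = "drop_from_mean"))
    expect_identical(base, dropped)
    ## permuting samples permutes columns correspondingly
    perm <- sample(ncol(cohort))
    permuted <- geneScores(computeGeneScores(cohort[, perm]))
    expect_identical(base[, colnames(permuted)], permuted)
    ## SNP order within genes is irrelevant
    shuffled <- computeGeneScores(cohort[sample(nrow(cohort)), ])
    expect_equal(base[rownames(geneScores(shuffled)), ],
                 geneScores(shuffled))
    ## scores bounded in [0, 2]
    expect_true(all(base >= 0 & base <= 2))
})

test_that("genes absent from the genotype data are reported", {
    path <- writeTinyGenotypeFile()
    g <- readGenotypes(path)
    expect_error(computeGeneScores(g, data.frame(snp = "zz", gene = "GZ")),
                 "GZ")
})
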