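## Small cohort builders shared across test files.

twoGeneConfig <- function(rhoCase, rhoControl, nCase = 400, nControl = 400,
                          seed = 1, snpsPerGene = 3) {
    simConfig(nCase = nCase, nControl = nControl, genes = c("G1", "G2"),
              snpsPerGene = snpsPerGene,
              plantedEdges = data.frame(geneA = "G1", geneB = "G2",
                                        rhoCase = rhoCase,
                                        rhoControl = rhoControl),
              covariateSpecs = list(), seed = seed)
}

## cohort where all planted dependence is identical in the two groups
nullStarConfig <- function(genes, seed, nCase = 400, nControl = 400) {
    pe <- defaultPlantedEdges(genes)
    pe$rhoCase <- 0.3
    pe$rhoControl <- 0.3
    simConfig(nCase = nCase, nControl = nControl, genes = genes,
              snpsPerGene = 3, plantedEdges = pe, covariateSpecs = list(),
              seed = seed)
}

## write a tiny delimited genotype file; returns its path
writeTinyGenotypeFile <- function(dir = withr::local_tempdir(.local_envir =
                                      parent.frame())) {
    path <- file.path(dir, "tiny.csv")
    writeLines(c("sample_id,label,rs1,rs2",
                 "s1,0,0,1",
                 "s2,1,2,0",
                 "s3,1,1,NA"), path)
    path
}

writeTinyVcf <- function(dir = withr::local_tempdir(.local_envir =
                             parent.frame())) {
    vcf <- file.path(dir, "tiny.vcf")
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", "s1", "s2", "s3", sep = "\t"),
        paste("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
              "0/1", "1/1", "./.", sep = "\t"),
        paste("1", "200", "rs2", "C", "T", ".", "PASS", ".", "GT",
              "0|1", "0/0", "./1", sep = "\t")), vcf)
    samples <- file.path(dir, "samples.csv")
    writeLines(c("sample_id,label,BMI",
                 "s1,0,22.5", "s2,1,27.1", "s3,1,24.0"), samples)
    list(vcf = vcf, samples = samples)
}

## independent brute-force Pearson chi-square (explicit expected-count loop)
bruteChisq <- function(m) {
    n <- sum(m)
    stat <- 0
    for (i in seq_len(nrow(m)))
        for (j in seq_len(ncol(m))) {
            e <- sum(m[i, ]) * sum(m[, j]) / n
            stat <- stat + (m[i, j] - e)^2 / e
        }
    stat
}
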