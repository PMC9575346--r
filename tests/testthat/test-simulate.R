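test_that("identical config yields bit-identical cohorts", {
    cfg <- simConfig(nCase = 60, nControl = 60, genes = paste0("G", 1:5),
                     snpsPerGene = 2, seed = 11)
    a <- simulateCohort(cfg)
    b <- simulateCohort(cfg)
    expect_identical(genotypes(a$cohort), genotypes(b$cohort))
    expect_identical(covariates(a$cohort), covariates(b$cohort))
    expect_identical(truthEdges(a$truth), truthEdges(b$truth))
})

test_that("genotype frequencies follow Hardy-Weinberg proportions", {
    ## single SNP at maf 0.5: expect (0.25, 0.5, 0.25) within 3 SE
    cfg <- simConfig(nCase = 100000, nControl = 2, genes = "G1",
                     snpsPerGene = 1, maf = 0.5, plantedEdges = NULL,
                     covariateSpecs = list(), seed = 3)
    g <- genotypes(simulateCohort(cfg)$cohort)
    y <- caseLabels(simulateCohort(cfg)$cohort)
    freq <- tabulate(g[1, y == 1] + 1L, 3) / sum(y == 1)
    se <- sqrt(c(.25 * .75, .5 * .5, .25 * .75) / sum(y == 1))
    expect_true(all(abs(freq - c(0.25, 0.5, 0.25)) < 3 * se))

    ## goodness of fit controlled at nominal level across seeds and MAFs
    nRej <- 0; nTests <- 0
    for (s in 1:15) {
        cfg <- simConfig(nCase = 2000, nControl = 2, genes = "G1",
                         snpsPerGene = 3, maf = c(0.1, 0.3, 0.45),
                         plantedEdges = NULL, covariateSpecs = list(),
                         seed = s)
        sim <- simulateCohort(cfg)
        g <- genotypes(sim$cohort)[, caseLabels(sim$cohort) == 1]
        for (k in 1:3) {
            maf <- c(0.1, 0.3, 0.45)[k]
            expe <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
            obs <- tabulate(g[k, ] + 1L, 3)
            p <- suppressWarnings(stats::chisq.test(obs, p = expe)$p.value)
            nRej <- nRej + (p < 0.05); nTests <- nTests + 1
        }
    }
    ## 45 nominal-0.05 tests: binomial 99% upper bound ~ 6 rejections
    expect_lte(nRej, 6)
})

test_that("planted differential edges move the gene-score correlation", {
    cfg <- twoGeneConfig(0.6, 0.0, nCase = 10000, nControl = 10000, seed = 9)
    sim <- simulateCohort(cfg)
    S <- geneScores(computeGeneScores(sim$cohort))
    y <- caseLabels(sim$cohort)
    rCase <- cor(S[1, y == 1], S[2, y == 1])
    rCtrl <- cor(S[1, y == 0], S[2, y == 0])
    expect_gt(rCase, 0.3)
    expect_lt(abs(rCtrl), 0.05)
    ## direction matches sign of rhoCase - rhoControl with margin >> MC noise
    expect_gt(rCase - rCtrl, 0.25)
})

test_that("degenerate designs are rejected with informative errors", {
    expect_error(simConfig(nCase = 1, nControl = 50, genes = c("A", "B")),
                 "nCase")
    expect_error(simConfig(genes = c("A", "B"), maf = 0.7,
                           plantedEdges = NULL), "MAF")
    expect_error(simConfig(genes = c("A", "B"), plantedEdges = data.frame(
        geneA = "A", geneB = "A", rhoCase = .2, rhoControl = 0)), "distinct")
    ## an impossible correlation structure names the offending edges
    pe <- data.frame(geneA = "A", geneB = c("B", "C", "D", "E"),
                     rhoCase = 0.95, rhoControl = 0)
    cfg <- simConfig(nCase = 50, nControl = 50, genes = LETTERS[1:5],
                     snpsPerGene = 2, plantedEdges = pe,
                     covariateSpecs = list(), seed = 1)
    expect_error(simulateCohort(cfg), "positive definite.*A-B",
                 perl = TRUE)
})

test_that("null configs mark every planted edge non-differential", {
    cfg <- nullStarConfig(paste0("G", 1:6), seed = 2)
    truth <- simulateCohort(cfg)$truth
    expect_true(all(!truthEdges(truth)$differential))
})

test_that("covariate defaults produce group-shifted BMI and menopause", {
    cfg <- simConfig(nCase = 5000, nControl = 5000, genes = paste0("G", 1:5),
                     snpsPerGene = 2, plantedEdges = NULL, seed = 21)
    cohort <- simulateCohort(cfg)$cohort
    z <- covariates(cohort)
    y <- caseLabels(cohort)
    expect_setequal(colnames(z), c("BMI", "menopause"))
    expect_gt(mean(z[y == 1, "BMI"]), mean(z[y == 0, "BMI"]))
    expect_gt(mean(z[y == 1, "menopause"]), mean(z[y == 0, "menopause"]))
    expect_true(all(z[, "menopause"] %in% 0:1))
})
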