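test_that("binary-predictor odds ratio equals the cross-product ratio", {
    ## expand the BMI contingency counts (control 849/85, case 799/117)
    ## into per-subject data: the saturated 2x2 logistic OR is ad/bc
    g <- c(rep(0, 849), rep(1, 85), rep(0, 799), rep(1, 117))
    y <- c(rep(0, 934), rep(1, 916))
    res <- snpLogistic(g, y, snpId = "bmiHigh")
    expect_equal(res$OR, (117 * 849) / (85 * 799), tolerance = 1e-8)
    expect_lt(res$ci_low, res$OR); expect_gt(res$ci_high, res$OR)
})

test_that("identical genotype distributions give OR 1", {
    g <- rep(c(0, 1, 2, 0, 1, 2), each = 50)
    y <- rep(c(0, 1), each = 150)
    res <- snpLogistic(g, y)
    expect_equal(res$OR, 1, tolerance = 1e-8)
    expect_gt(res$p, 0.99)
})

test_that("label swap inverts the odds ratio and preserves the p-value", {
    set.seed(2)
    g <- rbinom(500, 2, 0.3)
    y <- rbinom(500, 1, plogis(-0.3 + 0.5 * g))
    a <- snpLogistic(g, y)
    b <- snpLogistic(g, 1 - y)
    expect_equal(a$OR, 1 / b$OR, tolerance = 1e-8)
    expect_equal(a$p, b$p, tolerance = 1e-8)
})

test_that("aliased covariates leave the SNP estimate unchanged", {
    set.seed(3)
    g <- rbinom(300, 2, 0.25)
    y <- rbinom(300, 1, plogis(-0.2 + 0.4 * g))
    plain <- snpLogistic(g, y)
    withConst <- snpLogistic(g, y, z = data.frame(cns = rep(1, 300)))
    expect_equal(withConst$OR, plain$OR, tolerance = 1e-10)
    expect_equal(withConst$p, plain$p, tolerance = 1e-10)
})

test_that("the per-allele log odds ratio is recovered from simulation", {
    set.seed(4)
    g <- rbinom(5000, 2, 0.3)
    y <- rbinom(5000, 1, plogis(-0.8 + 0.5 * g))
    res <- snpLogistic(g, y)
    se <- (log(res$ci_high) - log(res$OR)) / 1.96
    expect_lt(abs(log(res$OR) - 0.5), 3 * se)
})

test_that("degenerate association inputs fail informatively", {
    expect_error(snpLogistic(rep(1, 100), rep(c(0, 1), 50), snpId = "rsX"),
                 "rsX")
    expect_error(snpLogistic(rbinom(50, 2, .3), rep(1, 50)), "classes")
    ## perfect separation is flagged
    g <- c(rep(0, 30), rep(2, 30))
    y <- c(rep(0, 30), rep(1, 30))
    expect_error(suppressWarnings(snpLogistic(g, y, snpId = "rsSep")),
                 "rsSep")
})

test_that("the association table covers the SNPs of requested genes", {
    sim <- simulateCohort(simConfig(nCase = 200, nControl = 200,
                                    genes = paste0("G", 1:5), snpsPerGene = 2,
                                    seed = 14))
    tab <- associationTable(sim$cohort, genes = c("G1", "G2"))
    expect_equal(nrow(tab), 4)
    expect_setequal(unique(tab$gene), c("G1", "G2"))
    expect_true(all(tab$ci_low <= tab$OR & tab$OR <= tab$ci_high))
    expect_identical(unique(tab$covariates_used), "BMI,menopause")
})

test_that("edge validation is deterministic and detects a planted edge", {
    sim <- simulateCohort(twoGeneConfig(0.6, 0.0, nCase = 2000,
                                        nControl = 1750, seed = 17))
    gs <- computeGeneScores(sim$cohort)
    S <- geneScores(gs); y <- caseLabels(gs)
    a <- validateEdge(S[1, ], S[2, ], y, seed = 5)
    b <- validateEdge(S[1, ], S[2, ], y, seed = 5)
    expect_identical(a, b)
    expect_lt(a$p, 0.05)
})

test_that("edge validation p-values are near-uniform on null edges", {
    ps <- vapply(1:40, function(s) {
        sim <- simulateCohort(twoGeneConfig(0.3, 0.3, nCase = 250,
                                            nControl = 250, seed = s + 60))
        gs <- computeGeneScores(sim$cohort)
        S <- geneScores(gs)
        validateEdge(S[1, ], S[2, ], caseLabels(gs), seed = s)$p
    }, numeric(1))
    expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})
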