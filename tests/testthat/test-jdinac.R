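test_that("a planted differential edge is selected in single splits", {
    cfg <- jdinacConfig(seed = 1)
    hits <- 0
    for (s in 1:10) {
        sim <- simulateCohort(twoGeneConfig(0.6, 0.0, seed = s))
        gs <- computeGeneScores(sim$cohort)
        sel <- jdinacSingleSplit(gs, cfg = cfg, splitSeed = s * 31)
        hits <- hits + sel$selected[1]
    }
    expect_gte(hits, 8)
})

test_that("null pairs are rarely selected in single splits", {
    cfg <- jdinacConfig(seed = 1)
    hits <- 0
    for (s in 1:15) {
        sim <- simulateCohort(twoGeneConfig(0.2, 0.2, nCase = 100,
                                            nControl = 100, seed = s))
        gs <- computeGeneScores(sim$cohort)
        sel <- jdinacSingleSplit(gs, cfg = cfg, splitSeed = s * 13)
        hits <- hits + sel$selected[1]
    }
    expect_lte(hits / 15, 0.2)
})

test_that("split selection is deterministic in the split seed", {
    sim <- simulateCohort(twoGeneConfig(0.5, 0.0, nCase = 120,
                                        nControl = 120, seed = 3))
    gs <- computeGeneScores(sim$cohort)
    cfg <- jdinacConfig(seed = 2)
    expect_identical(jdinacSingleSplit(gs, cfg = cfg, splitSeed = 77),
                     jdinacSingleSplit(gs, cfg = cfg, splitSeed = 77))
})

test_that("importance scores are bounded, symmetric-complete and reproducible", {
    sim <- simulateCohort(simConfig(nCase = 80, nControl = 80,
                                    genes = paste0("G", 1:4), snpsPerGene = 2,
                                    plantedEdges = NULL,
                                    covariateSpecs = list(), seed = 6))
    gs <- computeGeneScores(sim$cohort)
    cfg <- jdinacConfig(nSplits = 1L, cvFolds = 3L, seed = 5)
    imp <- jdinacImportance(gs, cfg = cfg)
    o <- importanceScores(imp)
    expect_equal(nrow(o), choose(4, 2))
    expect_true(all(o$omega %in% 0:1))   # T = 1 bound
    ## reproducible from the master seed
    imp2 <- jdinacImportance(gs, cfg = cfg)
    expect_identical(importanceScores(imp2), o)
})

test_that("importance is invariant to the order of samples", {
    sim <- simulateCohort(twoGeneConfig(0.5, 0.0, nCase = 100, nControl = 100,
                                        seed = 12))
    gs <- computeGeneScores(sim$cohort)
    cfg <- jdinacConfig(nSplits = 2L, seed = 9)
    base <- importanceScores(jdinacImportance(gs, cfg = cfg))
    perm <- withr::with_seed(1, sample(ncol(gs)))
    shuffled <- importanceScores(jdinacImportance(gs[, perm], cfg = cfg))
    expect_identical(base, shuffled)
})

test_that("a case-associated covariate independent of scores is adjusted away", {
    ## null gene scores + strongly case-associated binary covariate:
    ## adjusting for it must keep the pair mostly unselected
    cfg <- jdinacConfig(seed = 4)
    hits <- 0
    for (s in 1:10) {
        sim <- simulateCohort(twoGeneConfig(0.2, 0.2, nCase = 150,
                                            nControl = 150, seed = s + 40))
        gs <- computeGeneScores(sim$cohort)
        y <- caseLabels(gs)
        z <- withr::with_seed(s, matrix(rbinom(length(y), 1,
                                               ifelse(y == 1, 0.7, 0.2)),
                                        ncol = 1,
                                        dimnames = list(colnames(gs), "conf")))
        sel <- jdinacSingleSplit(gs, z = z, cfg = cfg, splitSeed = s * 19)
        hits <- hits + sel$selected[1]
    }
    expect_lte(hits / 10, 0.3)
})

test_that("network thresholding ranks edges and finds hubs by hand", {
    pairs <- data.frame(gene1 = c("A", "A", "B"), gene2 = c("B", "C", "C"),
                        omega = c(13L, 11L, 2L))
    imp <- new("ImportanceTable", pairs = pairs, nSplits = 20L)
    net <- buildNetwork(imp, minScore = 10)
    e <- networkEdges(net)
    expect_identical(paste(e$gene1, e$gene2), c("A B", "A C"))
    expect_identical(e$rank, 1:2)
    expect_setequal(net@nodes, c("A", "B", "C"))
    expect_identical(hubGenes(net), character())   # no degree-4 node
    ## boundary thresholds
    expect_equal(nrow(networkEdges(buildNetwork(imp, minScore = 14))), 0)
    expect_equal(nrow(networkEdges(buildNetwork(imp, minScore = 0))), 3)
    ## ties break lexicographically
    tied <- new("ImportanceTable",
                pairs = data.frame(gene1 = c("B", "A", "A"),
                                   gene2 = c("C", "C", "B"),
                                   omega = c(5L, 5L, 5L)), nSplits = 10L)
    te <- networkEdges(buildNetwork(tied, minScore = 1))
    expect_identical(paste(te$gene1, te$gene2), c("A B", "A C", "B C"))
})

test_that("hub calling needs at least min_degree adjacent genes", {
    star <- new("ImportanceTable",
                pairs = data.frame(gene1 = "hub",
                                   gene2 = paste0("L", 1:4),
                                   omega = 5L), nSplits = 10L)
    net <- buildNetwork(star, minScore = 1)
    expect_identical(findHubs(net, 4), "hub")
    tri <- new("ImportanceTable",
               pairs = data.frame(gene1 = c("A", "A", "B"),
                                  gene2 = c("B", "C", "C"), omega = 9L),
               nSplits = 10L)
    expect_identical(findHubs(buildNetwork(tri, minScore = 1), 4), character())
    empty <- buildNetwork(star, minScore = 6)
    expect_identical(findHubs(empty, 4), character())
})
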