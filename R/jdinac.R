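#' Tuning parameters for the differential network fit
#'
#' @param nSplits number of random splits T over which importance scores are
#'   accumulated (default 20).
#' @param splitFraction fraction of samples assigned to the density-fitting
#'   half in each split (default 0.5; the halves then swap roles).
#' @param cvFolds folds for cross-validated selection of the lasso penalty
#'   (default 5).
#' @param lambdaGrid numeric penalty grid; empty (default) lets glmnet build
#'   its own path.
#' @param densityFloor positive floor applied to both densities before the
#'   log ratio (default 1e-10).
#' @param penalizeCovariates if FALSE (default) covariates enter the model
#'   unpenalized, as adjustments rather than selection candidates.
#' @param seed master seed for split and fold randomness.
#' @return a validated \linkS4class{JdinacConfig}.
#' @export
jdinacConfig <- function(nSplits = 20L, splitFraction = 0.5, cvFolds = 5L,
                         lambdaGrid = numeric(), densityFloor = 1e-10,
                         penalizeCovariates = FALSE, seed = 1L) {
    if (identical(lambdaGrid, "auto")) lambdaGrid <- numeric()
    new("JdinacConfig", nSplits = as.integer(nSplits),
        splitFraction = splitFraction, cvFolds = as.integer(cvFolds),
        lambdaGrid = as.numeric(lambdaGrid), densityFloor = densityFloor,
        penalizeCovariates = penalizeCovariates, seed = as.integer(seed))
}

## Normalize inputs: samples x genes score matrix with sample/gene names,
## rows in canonical (sample id) order so results do not depend on the
## incoming sample order.
scoreInputs <- function(S, y, z) {
    if (is(S, "GeneScoreExperiment")) {
        if (is.null(y)) y <- caseLabels(S)
        if (is.null(z)) z <- covariates(S)
        S <- t(geneScores(S))
    } else {
        S <- as.matrix(S)
    }
    if (is.null(rownames(S))) rownames(S) <- sprintf("sample%06d",
                                                     seq_len(nrow(S)))
    if (is.null(colnames(S))) colnames(S) <- sprintf("gene%03d",
                                                     seq_len(ncol(S)))
    if (is.null(z)) z <- matrix(numeric(), nrow(S), 0)
    z <- as.matrix(z)
    stopifnot(length(y) == nrow(S), nrow(z) == nrow(S))
    ord <- order(rownames(S))
    list(S = S[ord, , drop = FALSE], y = as.integer(y[ord]),
         z = z[ord, , drop = FALSE])
}

## Per-gene Gaussian kernel matrices for one group, shared across all pairs:
## K[[gene]] is |eval| x |centers| with entries dnorm((s_eval - s_center)/h)/h.
## The product-kernel bivariate density of pair (i, j) is then
## rowMeans(K[[i]] * K[[j]]).
geneKernels <- function(Sfit, Seval) {
    lapply(colnames(Sfit), function(g) {
        h <- silvermanBandwidth(Sfit[, g])
        stats::dnorm(outer(Seval[, g], Sfit[, g], "-") / h) / h
    })
}

pairFeatureMatrix <- function(Sfit, yfit, Seval, pairs, floor) {
    Kcase <- geneKernels(Sfit[yfit == 1, , drop = FALSE], Seval)
    Kctrl <- geneKernels(Sfit[yfit == 0, , drop = FALSE], Seval)
    names(Kcase) <- names(Kctrl) <- colnames(Sfit)
    feat <- matrix(0, nrow(Seval), nrow(pairs))
    for (k in seq_len(nrow(pairs))) {
        i <- pairs$gene1[k]; j <- pairs$gene2[k]
        f1 <- rowMeans(Kcase[[i]] * Kcase[[j]])
        f0 <- rowMeans(Kctrl[[i]] * Kctrl[[j]])
        feat[, k] <- log(pmax(f1, floor) / pmax(f0, floor))
    }
    feat
}

## Penalty selection: stratified K-fold CV of the binomial deviance, then
## the one-standard-error rule (sparsest model within one SE of the minimum
## CV deviance), which keeps selection on null features rare. Features are
## not standardized: log density-ratio features share the log
## likelihood-ratio scale, on which a larger variance is itself evidence of
## differential dependence; standardizing would inflate near-constant noise
## features to the same footing.
fitPenalized <- function(feat, y, z, cfg, foldSeed) {
    X <- cbind(feat, z)
    pf <- c(rep(1, ncol(feat)),
            rep(if (cfg@penalizeCovariates) 1 else 0, ncol(z)))
    if (ncol(X) < 2L) {   # glmnet needs >= 2 columns; pad with an inert one
        X <- cbind(X, 0)
        pf <- c(pf, 1)
    }
    lambda <- if (length(cfg@lambdaGrid)) sort(cfg@lambdaGrid,
                                               decreasing = TRUE) else NULL
    tryFit <- function(seed) {
        foldid <- stratifiedFolds(y, cfg@cvFolds, seed)
        glmnet::cv.glmnet(X, y, family = "binomial", foldid = foldid,
                          lambda = lambda, penalty.factor = pf,
                          type.measure = "deviance", standardize = FALSE)
    }
    cv <- tryCatch(tryFit(foldSeed), error = function(e)
        tryCatch(tryFit(foldSeed + 1L), error = function(e2)
            stop("cross-validation failed twice: ", conditionMessage(e2),
                 call. = FALSE)))
    beta <- as.numeric(stats::coef(cv, s = "lambda.1se"))[-1]  # drop intercept
    beta[seq_len(ncol(feat))]
}

#' One random split of the differential network fit
#'
#' Performs a single split of the two-stage estimator: (a) stratified random
#' split of the samples into halves D1/D2 preserving class balance; (b) on
#' D1, fit the case and control bivariate kernel densities of every gene
#' pair; (c) compute log density-ratio features for the D2 samples; (d) fit
#' an L1-penalized logistic regression of the D2 labels on all pair features
#' plus unpenalized covariates, with the penalty chosen by cross-validated
#' deviance; (e) swap the roles of D1 and D2 and repeat. A pair is selected
#' for the split if its coefficient is non-zero in either direction.
#'
#' @param S samples x genes score matrix or a
#'   \linkS4class{GeneScoreExperiment}.
#' @param y binary labels (1 = case); taken from \code{S} if it is a
#'   \linkS4class{GeneScoreExperiment}.
#' @param z covariate matrix (or NULL).
#' @param cfg a \linkS4class{JdinacConfig}.
#' @param splitSeed seed for this split's randomness.
#' @return data.frame gene1, gene2, selected (logical).
#' @export
jdinacSingleSplit <- function(S, y = NULL, z = NULL, cfg = jdinacConfig(),
                              splitSeed = cfg@seed) {
    inp <- scoreInputs(S, y, z)
    S <- inp$S; y <- inp$y; z <- inp$z
    if (min(table(factor(y, c(0, 1)))) < 10L)
        stop("both classes need at least 10 samples")
    if (ncol(S) < 2L) stop("at least 2 genes are required")
    pairs <- canonicalPairs(colnames(S))
    seeds <- spawnSeeds(splitSeed, 3L)
    inD1 <- stratifiedSplit(y, cfg@splitFraction, seeds[1])
    selected <- rep(FALSE, nrow(pairs))
    for (d in 1:2) {
        fitHalf <- if (d == 1) inD1 else !inD1
        feat <- pairFeatureMatrix(S[fitHalf, , drop = FALSE], y[fitHalf],
                                  S[!fitHalf, , drop = FALSE], pairs,
                                  cfg@densityFloor)
        beta <- fitPenalized(feat, y[!fitHalf], z[!fitHalf, , drop = FALSE],
                             cfg, seeds[1L + d])
        selected <- selected | beta != 0
    }
    data.frame(pairs, selected = selected)
}

#' Importance scores over repeated random splits
#'
#' Runs \code{\link{jdinacSingleSplit}} for T independent random splits whose
#' seeds are spawned deterministically from \code{cfg@seed}, and counts for
#' each unordered gene pair the number of splits in which it was selected
#' (received a non-zero lasso coefficient). These counts are the importance
#' scores omega, bounded by T; repeated selection across splits marks robust
#' differential dependence.
#'
#' @inheritParams jdinacSingleSplit
#' @param verbose print a progress line per split.
#' @return an \linkS4class{ImportanceTable}.
#' @export
jdinacImportance <- function(S, y = NULL, z = NULL, cfg = jdinacConfig(),
                             verbose = FALSE) {
    splitSeeds <- spawnSeeds(cfg@seed, cfg@nSplits)
    omega <- NULL
    for (t in seq_len(cfg@nSplits)) {
        sel <- jdinacSingleSplit(S, y, z, cfg, splitSeed = splitSeeds[t])
        if (is.null(omega)) {
            omega <- sel
            omega$omega <- as.integer(sel$selected)
            omega$selected <- NULL
        } else omega$omega <- omega$omega + sel$selected
        if (verbose)
            message(sprintf("split %d/%d: %d pair(s) selected", t,
                            cfg@nSplits, sum(sel$selected)))
    }
    new("ImportanceTable", pairs = omega, nSplits = cfg@nSplits)
}

#' Threshold importance scores into a differential network
#'
#' Retains the gene pairs whose importance score reaches \code{minScore} as
#' network edges, ranked by omega descending with ties broken by
#' lexicographic pair order; nodes are the endpoints of retained edges, and
#' hubs are nodes whose degree on the retained edges reaches
#' \code{minDegree}.
#'
#' @param imp an \linkS4class{ImportanceTable}.
#' @param minScore minimum omega for an edge; default ceiling(T / 4).
#' @param minDegree minimum degree for a hub (default 4).
#' @return a \linkS4class{DifferentialNetwork}.
#' @export
buildNetwork <- function(imp, minScore = ceiling(imp@nSplits / 4),
                         minDegree = 4L) {
    stopifnot(minScore >= 0, minScore <= imp@nSplits)
    p <- imp@pairs
    e <- p[p$omega >= minScore, , drop = FALSE]
    e <- e[order(-e$omega, e$gene1, e$gene2), , drop = FALSE]
    e$rank <- seq_len(nrow(e))
    rownames(e) <- NULL
    nodes <- sort(unique(c(e$gene1, e$gene2)))
    net <- new("DifferentialNetwork", nodes = nodes, edges = e,
               hubs = character(), minScore = as.integer(minScore),
               minDegree = as.integer(minDegree),
               nSplits = imp@nSplits)
    net@hubs <- findHubs(net, minDegree)
    net
}

#' Hub genes of a differential network
#'
#' @param net a \linkS4class{DifferentialNetwork}.
#' @param minDegree minimum number of adjacent genes (default 4).
#' @return character vector of hub genes, degree descending (ties
#'   alphabetical).
#' @export
findHubs <- function(net, minDegree = 4L) {
    e <- networkEdges(net)
    if (!nrow(e)) return(character())
    deg <- table(c(e$gene1, e$gene2))
    deg <- deg[deg >= minDegree]
    names(deg)[order(-deg, names(deg))]
}
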