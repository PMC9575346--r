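#' Covariate-adjusted logistic association for one SNP
#'
#' Maximum-likelihood logistic regression of case status on the additive
#' genotype code (0/1/2 minor-allele copies) plus optional covariates. The
#' per-allele odds ratio is the exponentiated SNP coefficient, with a Wald
#' 95\% confidence interval exp(beta +/- 1.96 SE) and Wald p-value.
#'
#' @param geno per-sample additive genotype code for one SNP.
#' @param y binary labels (1 = case).
#' @param z optional covariate matrix / data.frame.
#' @param snpId,gene identifiers recorded in the result.
#' @return data.frame with snp, gene, OR, ci_low, ci_high, p,
#'   covariates_used.
#' @examples
#' set.seed(1)
#' g <- rbinom(400, 2, 0.3)
#' y <- rbinom(400, 1, plogis(-0.5 + 0.4 * g))
#' snpLogistic(g, y, snpId = "rs1", gene = "G1")
#' @export
snpLogistic <- function(geno, y, z = NULL, snpId = "snp", gene = NA_character_) {
    keep <- !is.na(geno) & !is.na(y)
    geno <- geno[keep]; y <- y[keep]
    if (length(unique(y)) < 2L) stop("both classes must be present")
    if (length(unique(geno)) < 2L)
        stop("SNP ", snpId, " is constant; no association model can be fit")
    df <- data.frame(y = y, g = geno)
    covNames <- character()
    if (!is.null(z)) {
        z <- as.data.frame(z)[keep, , drop = FALSE]
        covNames <- colnames(z)
        df <- cbind(df, z)
    }
    fit <- stats::glm(y ~ ., data = df, family = stats::binomial(),
                      control = stats::glm.control(epsilon = 1e-12,
                                                   maxit = 100))
    cf <- summary(fit)$coefficients
    if (!fit$converged || abs(cf["g", "Estimate"]) > 15)
        stop("logistic regression did not converge (possible separation) ",
             "for SNP ", snpId)
    b <- cf["g", "Estimate"]; se <- cf["g", "Std. Error"]
    data.frame(snp = snpId, gene = gene, OR = exp(b),
               ci_low = exp(b - 1.96 * se), ci_high = exp(b + 1.96 * se),
               p = cf["g", "Pr(>|z|)"],
               covariates_used = paste(covNames, collapse = ","),
               stringsAsFactors = FALSE)
}

#' Association table for the SNPs of selected genes
#'
#' Runs \code{\link{snpLogistic}} on every SNP mapped to the given genes
#' (by default, all genes), in the layout of a hub-gene association table.
#'
#' @param g a \linkS4class{GenotypeExperiment} with a \code{gene} column in
#'   its \code{rowData} (or supply \code{map}).
#' @param genes genes whose SNPs to test; NULL = all.
#' @param map optional data.frame (snp, gene) overriding \code{rowData}.
#' @param adjustFor covariate names to adjust for (default: all declared).
#' @param bhAdjust add a Benjamini-Hochberg adjusted p column.
#' @return data.frame, one row per SNP.
#' @export
associationTable <- function(g, genes = NULL, map = NULL, adjustFor = NULL,
                             bhAdjust = FALSE) {
    if (is.null(map))
        map <- data.frame(snp = rownames(g), gene = rowData(g)$gene)
    if (is.null(genes)) genes <- unique(map$gene)
    map <- map[map$gene %in% genes & map$snp %in% rownames(g), , drop = FALSE]
    if (!nrow(map)) stop("no SNPs found for the requested genes")
    y <- caseLabels(g)
    z <- covariates(g, which = adjustFor)
    if (!ncol(z)) z <- NULL
    geno <- genotypes(g)
    res <- do.call(rbind, lapply(seq_len(nrow(map)), function(k)
        snpLogistic(geno[map$snp[k], ], y, z, snpId = map$snp[k],
                    gene = map$gene[k])))
    if (bhAdjust) res$p_adjust <- stats::p.adjust(res$p, "BH")
    rownames(res) <- NULL
    res
}

#' Split-sample validation of a single edge
#'
#' Tests one gene pair for differential dependence without the lasso
#' machinery: the samples are split at random into two stratified halves;
#' the case and control bivariate kernel densities are fitted on the first
#' half; the log density-ratio feature is computed for the second half; and
#' an unpenalized logistic regression of the second-half labels on that
#' single feature yields the Wald p-value of the edge.
#'
#' @param si,sj per-sample scores of the two genes.
#' @param y binary labels (1 = case).
#' @param seed seed for the random half-split.
#' @param floor density floor before the log ratio.
#' @return data.frame with p and split_seed.
#' @export
validateEdge <- function(si, sj, y, seed = 1L, floor = 1e-10) {
    stopifnot(length(si) == length(sj), length(si) == length(y))
    inD1 <- stratifiedSplit(y, 0.5, seed)
    if (min(table(factor(y[inD1], c(0, 1)))) < 10L ||
        min(table(factor(y[!inD1], c(0, 1)))) < 10L)
        stop("both classes need at least 10 samples in each half")
    model <- pairDensityModel(si[inD1], sj[inD1], y[inD1])
    f <- logDensityRatio(model, si[!inD1], sj[!inD1], floor = floor)
    if (stats::sd(f) == 0)
        stop("degenerate density fit: the log density-ratio feature is constant")
    fit <- stats::glm(y[!inD1] ~ f, family = stats::binomial())
    p <- summary(fit)$coefficients["f", "Pr(>|z|)"]
    data.frame(p = p, split_seed = as.integer(seed))
}

#' Validate every edge of a differential network
#'
#' @param net a \linkS4class{DifferentialNetwork}.
#' @param gs a \linkS4class{GeneScoreExperiment} holding the validation
#'   cohort.
#' @param seed master seed; one sub-seed per edge.
#' @return data.frame gene1, gene2, p.
#' @export
validateNetworkEdges <- function(net, gs, seed = 1L) {
    e <- networkEdges(net)
    if (!nrow(e)) return(data.frame(gene1 = character(), gene2 = character(),
                                    p = numeric()))
    S <- geneScores(gs)
    y <- caseLabels(gs)
    seeds <- spawnSeeds(seed, nrow(e))
    p <- vapply(seq_len(nrow(e)), function(k)
        validateEdge(S[e$gene1[k], ], S[e$gene2[k], ], y, seed = seeds[k])$p,
        numeric(1))
    data.frame(gene1 = e$gene1, gene2 = e$gene2, p = p)
}
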