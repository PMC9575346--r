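#' Describe a synthetic case-control SNP cohort
#'
#' Builds the design of a simulated cohort whose gene-level dependence
#' structure differs between cases and controls only on a planted edge set.
#' Genotypes arise from a latent Gaussian copula: one latent normal dimension
#' per SNP, correlated within genes (local LD) and across the two genes of
#' each planted edge (with a group-specific correlation), then discretized at
#' the Hardy-Weinberg thresholds so that P(2) = maf^2, P(1) = 2 maf (1 - maf),
#' P(0) = (1 - maf)^2.
#'
#' Defaults mirror a hospital-based breast-cancer case-control cohort:
#' 953 cases / 963 controls, 20 genes covered by 5 SNPs each, a BMI-like
#' normal covariate (control mean 24.01 sd 3.11; case mean 24.36 sd 3.46) and
#' a menopause-like binary covariate (prevalence 0.281 control, 0.335 case),
#' and one planted differential hub: the first gene coupled to the next four
#' in cases (rho 0.6) but not in controls.
#'
#' @param nCase,nControl cohort sizes (each >= 2).
#' @param genes character vector of gene ids.
#' @param snpsPerGene SNPs per gene (scalar or per-gene vector).
#' @param maf per-SNP minor allele frequency in (0, 0.5]; scalar, per-SNP
#'   vector, or \code{NULL} for frequencies evenly spaced over [0.1, 0.5].
#' @param plantedEdges data.frame with columns geneA, geneB, rhoCase,
#'   rhoControl; may have zero rows.
#' @param withinGeneRho latent correlation between SNPs of one gene.
#' @param covariateSpecs list of covariate specs; each is a list with
#'   \code{name}, \code{type} ("normal" or "binary") and group-conditional
#'   parameters (\code{mean}/\code{sd} or \code{prob}, each length-2
#'   c(control, case)).
#' @param seed master seed; the whole cohort is reproducible from it.
#' @return a validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(nCase = 100, nControl = 100, genes = paste0("G", 1:4),
#'                  snpsPerGene = 2, seed = 7)
#' cfg
#' @export
simConfig <- function(nCase = 953L, nControl = 963L,
                      genes = sprintf("G%02d", 1:20),
                      snpsPerGene = 5L, maf = NULL,
                      plantedEdges = defaultPlantedEdges(genes),
                      withinGeneRho = 0.3,
                      covariateSpecs = defaultCovariateSpecs(),
                      seed = 1L) {
    snpsPerGene <- rep_len(as.integer(snpsPerGene), length(genes))
    nSnps <- sum(snpsPerGene)
    if (is.null(maf)) maf <- seq(0.1, 0.5, length.out = nSnps)
    maf <- rep_len(maf, nSnps)
    if (is.null(plantedEdges) || !nrow(plantedEdges))
        plantedEdges <- data.frame(geneA = character(), geneB = character(),
                                   rhoCase = numeric(), rhoControl = numeric())
    new("SimConfig", nCase = as.integer(nCase), nControl = as.integer(nControl),
        genes = as.character(genes), snpsPerGene = snpsPerGene,
        maf = as.numeric(maf), plantedEdges = plantedEdges,
        withinGeneRho = withinGeneRho, covariateSpecs = covariateSpecs,
        seed = as.integer(seed))
}

#' Default planted edge set: a differential hub
#'
#' A degree-4 star: the first gene is coupled (latent gene-level rho 0.6) to
#' the next four genes in cases only. A star of four leaves that are
#' mutually independent cannot be a valid correlation structure (it needs
#' sum(rho^2) < 1), so the four leaves additionally share a weak background
#' correlation of 0.2 in \emph{both} groups; those leaf-leaf pairs are
#' recorded as non-differential edges and carry no case/control signal.
#'
#' @rdname simConfig
#' @export
defaultPlantedEdges <- function(genes) {
    if (length(genes) < 5L)
        return(data.frame(geneA = character(), geneB = character(),
                          rhoCase = numeric(), rhoControl = numeric()))
    star <- data.frame(geneA = genes[1L], geneB = genes[2:5],
                       rhoCase = 0.6, rhoControl = 0.0)
    leaves <- canonicalPairs(genes[2:5])
    background <- data.frame(geneA = leaves$gene1, geneB = leaves$gene2,
                             rhoCase = 0.2, rhoControl = 0.2)
    rbind(star, background)
}

#' @rdname simConfig
#' @export
defaultCovariateSpecs <- function() {
    list(list(name = "BMI", type = "normal",
              mean = c(24.01, 24.36), sd = c(3.11, 3.46)),
         list(name = "menopause", type = "binary",
              prob = c(0.2811, 0.3348)))
}

## Latent SNP-level correlation matrix for one group. Within a gene all SNP
## pairs share withinGeneRho (local LD). Across the two genes of a planted
## edge the uniform cross-block correlation is calibrated so that the
## correlation of the two latent gene means (the gene-score precursors)
## equals the planted rho: with m_g SNPs per gene the latent gene mean has
## variance (1 + (m_g - 1) w) / m_g, so the cross-SNP value is
## rho * sqrt(v_a * v_b). Planting rho at the SNP level directly would make
## the matrix indefinite for moderate rho, because the gene-mean correlation
## amplifies it by m / (1 + (m - 1) w).
latentSigma <- function(config, rhoColumn) {
    geneOf <- rep(config@genes, config@snpsPerGene)
    w <- config@withinGeneRho
    m <- stats::setNames(config@snpsPerGene, config@genes)
    v <- (1 + (m - 1) * w) / m
    n <- length(geneOf)
    sigma <- diag(n)
    same <- outer(geneOf, geneOf, "==")
    sigma[same] <- w
    pe <- config@plantedEdges
    for (k in seq_len(nrow(pe))) {
        ia <- geneOf == pe$geneA[k]
        ib <- geneOf == pe$geneB[k]
        rhoSnp <- pe[[rhoColumn]][k] *
            sqrt(v[pe$geneA[k]] * v[pe$geneB[k]])
        sigma[ia, ib] <- rhoSnp
        sigma[ib, ia] <- rhoSnp
    }
    diag(sigma) <- 1
    sigma
}

drawGenotypes <- function(n, sigma, maf, seed, config) {
    ch <- tryCatch(chol(sigma), error = function(e) {
        pe <- config@plantedEdges
        stop("latent correlation matrix is not positive definite; ",
             "check planted edges {",
             paste(sprintf("%s-%s", pe$geneA, pe$geneB), collapse = ", "),
             "} and withinGeneRho", call. = FALSE)
    })
    z <- withr::with_seed(seed,
        matrix(stats::rnorm(n * nrow(sigma)), n) %*% ch)
    t0 <- stats::qnorm((1 - maf)^2)   # below: genotype 0
    t2 <- stats::qnorm(1 - maf^2)     # above: genotype 2
    g <- sweep(z, 2, t0, ">") + sweep(z, 2, t2, ">")
    storage.mode(g) <- "integer"
    g
}

drawCovariate <- function(spec, nControl, nCase, seed) {
    withr::with_seed(seed, {
        if (spec$type == "normal")
            c(stats::rnorm(nControl, spec$mean[1], spec$sd[1]),
              stats::rnorm(nCase, spec$mean[2], spec$sd[2]))
        else if (spec$type == "binary")
            c(stats::rbinom(nControl, 1, spec$prob[1]),
              stats::rbinom(nCase, 1, spec$prob[2]))
        else stop("unknown covariate type: ", spec$type)
    })
}

#' Simulate a case-control cohort with planted differential dependence
#'
#' Draws the cohort described by a \linkS4class{SimConfig}: per-group latent
#' multivariate normal vectors (one dimension per SNP) with the configured
#' within-gene and planted cross-gene correlations, discretized to genotypes
#' 0/1/2 at the Hardy-Weinberg thresholds implied by each SNP's minor allele
#' frequency, plus group-conditional covariates. Fully reproducible from
#' \code{config@seed}.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return a list with elements \code{cohort} (a
#'   \linkS4class{GenotypeExperiment}; controls first, then cases) and
#'   \code{truth} (a \linkS4class{TruthNetwork} recording the planted edges).
#' @examples
#' sim <- simulateCohort(simConfig(nCase = 50, nControl = 50,
#'                                 genes = paste0("G", 1:5), seed = 1))
#' sim$cohort
#' truthEdges(sim$truth)
#' @export
simulateCohort <- function(config) {
    validObject(config)
    seeds <- spawnSeeds(config@seed, 2L + length(config@covariateSpecs))
    sigCase <- latentSigma(config, "rhoCase")
    sigCtrl <- latentSigma(config, "rhoControl")
    gCase <- drawGenotypes(config@nCase, sigCase, config@maf, seeds[1], config)
    gCtrl <- drawGenotypes(config@nControl, sigCtrl, config@maf, seeds[2],
                           config)
    geno <- t(rbind(gCtrl, gCase))   # SNPs x samples, controls first
    geneOf <- rep(config@genes, config@snpsPerGene)
    snpIds <- unlist(lapply(seq_along(config@genes), function(i)
        sprintf("%s_snp%d", config@genes[i], seq_len(config@snpsPerGene[i]))))
    rownames(geno) <- snpIds
    colnames(geno) <- c(sprintf("ctrl_%04d", seq_len(config@nControl)),
                        sprintf("case_%04d", seq_len(config@nCase)))
    label <- c(rep(0L, config@nControl), rep(1L, config@nCase))
    covs <- NULL
    if (length(config@covariateSpecs)) {
        covs <- as.data.frame(lapply(seq_along(config@covariateSpecs),
            function(i) drawCovariate(config@covariateSpecs[[i]],
                                      config@nControl, config@nCase,
                                      seeds[2L + i])))
        colnames(covs) <- vapply(config@covariateSpecs, `[[`, "", "name")
    }
    cohort <- GenotypeExperiment(geno, label, covariates = covs,
                                 geneMap = data.frame(snp = snpIds,
                                                      gene = geneOf))
    pe <- config@plantedEdges
    truth <- new("TruthNetwork", edges = data.frame(
        pe[, c("geneA", "geneB", "rhoCase", "rhoControl")],
        differential = if (nrow(pe)) pe$rhoCase != pe$rhoControl else logical()))
    list(cohort = cohort, truth = truth)
}

#' Write a simulated cohort to disk
#'
#' Writes the delimited genotype dialect consumed by
#' \code{\link{readGenotypes}} (columns sample_id, label, covariates, then
#' one column per SNP), the 2-column SNP-gene map, and the truth-network
#' edge list.
#'
#' @param sim result of \code{\link{simulateCohort}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths written.
#' @export
writeCohort <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    cohort <- sim$cohort
    paths <- c(genotypes = file.path(dir, "genotypes.csv"),
               map = file.path(dir, "snp_gene_map.tsv"),
               truth = file.path(dir, "truth_edges.tsv"))
    covs <- covariates(cohort)
    df <- data.frame(sample_id = colnames(cohort),
                     label = caseLabels(cohort), check.names = FALSE)
    for (nm in colnames(covs)) df[[nm]] <- covs[, nm]
    df <- cbind(df, as.data.frame(t(genotypes(cohort)), check.names = FALSE))
    utils::write.csv(df, paths["genotypes"], row.names = FALSE, quote = FALSE)
    map <- data.frame(snp = rownames(cohort),
                      gene = rowData(cohort)$gene)
    utils::write.table(map, paths["map"], sep = "\t", row.names = FALSE,
                       quote = FALSE)
    utils::write.table(truthEdges(sim$truth), paths["truth"], sep = "\t",
                       row.names = FALSE, quote = FALSE)
    invisible(paths)
}
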