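#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData rowData<-
NULL

#' GenotypeExperiment: case-control SNP genotypes with labels and covariates
#'
#' A \linkS4class{SummarizedExperiment} whose single \code{"genotype"} assay
#' holds additive minor-allele counts (0/1/2, \code{NA} for missing) with SNPs
#' as rows and samples as columns. \code{colData} carries the binary
#' case/control \code{label} (1 = case) and any numeric covariates; a
#' \code{"covariates"} entry in \code{metadata} names which \code{colData}
#' columns are covariates.
#'
#' @aliases GenotypeExperiment-class
#' @exportClass GenotypeExperiment
setClass("GenotypeExperiment", contains = "SummarizedExperiment")

setValidity("GenotypeExperiment", function(object) {
    msg <- character()
    if (!"genotype" %in% names(assays(object)))
        msg <- c(msg, "assay 'genotype' is required")
    else {
        g <- assay(object, "genotype")
        bad <- !is.na(g) & !g %in% c(0L, 1L, 2L)
        if (any(bad))
            msg <- c(msg, sprintf("%d genotype value(s) outside {0,1,2}/NA",
                                  sum(bad)))
    }
    if (!"label" %in% colnames(colData(object)))
        msg <- c(msg, "colData column 'label' is required")
    else {
        y <- colData(object)$label
        if (!all(y %in% c(0L, 1L)))
            msg <- c(msg, "labels must be 0 (control) or 1 (case)")
    }
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample ids")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate SNP ids")
    cv <- metadata(object)$covariates
    if (!is.null(cv) && !all(cv %in% colnames(colData(object))))
        msg <- c(msg, "metadata covariates must name colData columns")
    if (length(msg)) msg else TRUE
})

#' GeneScoreExperiment: per-gene SNP mean scores
#'
#' A \linkS4class{SummarizedExperiment} whose \code{"score"} assay holds the
#' per-sample gene risk score (arithmetic mean of the additive codes of the
#' gene's SNPs, hence bounded in [0, 2]), genes as rows, samples as columns.
#' Labels and covariates are carried over from the source
#' \linkS4class{GenotypeExperiment}.
#'
#' @aliases GeneScoreExperiment-class
#' @exportClass GeneScoreExperiment
setClass("GeneScoreExperiment", contains = "SummarizedExperiment")

setValidity("GeneScoreExperiment", function(object) {
    msg <- character()
    if (!"score" %in% names(assays(object)))
        msg <- c(msg, "assay 'score' is required")
    else {
        s <- assay(object, "score")
        if (any(!is.na(s) & (s < 0 | s > 2)))
            msg <- c(msg, "gene scores must lie in [0, 2]")
    }
    if (!"label" %in% colnames(colData(object)))
        msg <- c(msg, "colData column 'label' is required")
    if (length(msg)) msg else TRUE
})

#' SimConfig: design of a synthetic case-control cohort
#'
#' Describes a cohort generated by a latent Gaussian copula with
#' Hardy-Weinberg discretization: cohort sizes, genes and SNPs per gene,
#' per-SNP minor allele frequencies, planted differential edges (gene pairs
#' with group-specific latent correlations), within-gene latent correlation
#' (local LD), and group-conditional covariate distributions.
#'
#' @slot nCase,nControl cohort sizes.
#' @slot genes character vector of gene identifiers.
#' @slot snpsPerGene integer vector (recycled) of SNP counts per gene.
#' @slot maf per-SNP minor allele frequencies in (0, 0.5].
#' @slot plantedEdges data.frame with columns geneA, geneB, rhoCase,
#'   rhoControl.
#' @slot withinGeneRho latent correlation between SNPs of the same gene.
#' @slot covariateSpecs list of per-covariate specs (see \code{simConfig}).
#' @slot seed master seed.
#' @aliases SimConfig-class
#' @exportClass SimConfig
setClass("SimConfig", representation(
    nCase = "integer", nControl = "integer",
    genes = "character", snpsPerGene = "integer",
    maf = "numeric", plantedEdges = "data.frame",
    withinGeneRho = "numeric", covariateSpecs = "list",
    seed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (object@nCase < 2L || object@nControl < 2L)
        msg <- c(msg, "nCase and nControl must each be >= 2")
    if (anyDuplicated(object@genes))
        msg <- c(msg, "gene ids must be unique")
    if (any(object@snpsPerGene < 1L))
        msg <- c(msg, "snpsPerGene must be positive")
    if (any(object@maf <= 0 | object@maf > 0.5))
        msg <- c(msg, "all MAFs must lie in (0, 0.5]")
    pe <- object@plantedEdges
    if (nrow(pe)) {
        if (!all(c("geneA", "geneB", "rhoCase", "rhoControl") %in% names(pe)))
            msg <- c(msg, "plantedEdges needs geneA, geneB, rhoCase, rhoControl")
        else {
            if (any(pe$geneA == pe$geneB))
                msg <- c(msg, "planted edges must join two distinct genes")
            if (!all(c(pe$geneA, pe$geneB) %in% object@genes))
                msg <- c(msg, "planted edges reference unknown genes")
            if (any(abs(pe$rhoCase) >= 1) || any(abs(pe$rhoControl) >= 1))
                msg <- c(msg, "edge correlations must lie in (-1, 1)")
        }
    }
    if (abs(object@withinGeneRho) >= 1)
        msg <- c(msg, "withinGeneRho must lie in (-1, 1)")
    if (length(msg)) msg else TRUE
})

#' TruthNetwork: planted edge set of a simulated cohort
#'
#' @slot edges data.frame with geneA, geneB, rhoCase, rhoControl and a
#'   logical \code{differential} column (rhoCase != rhoControl).
#' @aliases TruthNetwork-class
#' @exportClass TruthNetwork
setClass("TruthNetwork", representation(edges = "data.frame"))

setValidity("TruthNetwork", function(object) {
    e <- object@edges
    need <- c("geneA", "geneB", "rhoCase", "rhoControl", "differential")
    if (!all(need %in% names(e)))
        return(paste("edges must have columns", paste(need, collapse = ", ")))
    TRUE
})

#' ContingencyTable: categorical factor cross-tabulated by case status
#'
#' @slot counts r x 2 integer matrix, columns \code{control} and \code{case}.
#' @slot factorName name of the tabulated factor.
#' @aliases ContingencyTable-class
#' @exportClass ContingencyTable
setClass("ContingencyTable",
         representation(counts = "matrix", factorName = "character"))

setValidity("ContingencyTable", function(object) {
    m <- object@counts
    msg <- character()
    if (ncol(m) != 2L) msg <- c(msg, "counts must have 2 columns")
    if (nrow(m) < 2L) msg <- c(msg, "counts must have at least 2 rows")
    if (any(m < 0) || any(m != round(m)))
        msg <- c(msg, "counts must be non-negative integers")
    if (ncol(m) == 2L && any(colSums(m) == 0))
        msg <- c(msg, "both column sums must be positive")
    if (length(msg)) msg else TRUE
})

#' PairDensityModel: group-conditional bivariate densities of a gene pair
#'
#' Holds the case and control bivariate kernel density estimates of the two
#' gene scores, each a product-Gaussian-kernel KDE with per-dimension
#' Silverman bandwidths.
#'
#' @slot genePair length-2 character, the two gene ids.
#' @slot kdeCase,kdeControl fitted KDEs (see \code{\link{fitPairDensity}}).
#' @aliases PairDensityModel-class
#' @exportClass PairDensityModel
setClass("PairDensityModel", representation(
    genePair = "character", kdeCase = "list", kdeControl = "list"))

setValidity("PairDensityModel", function(object) {
    msg <- character()
    for (k in c("kdeCase", "kdeControl")) {
        kde <- slot(object, k)
        if (!all(c("x", "y", "hx", "hy", "n") %in% names(kde)))
            msg <- c(msg, sprintf("%s is not a fitted bivariate KDE", k))
        else if (kde$hx <= 0 || kde$hy <= 0)
            msg <- c(msg, sprintf("%s has non-positive bandwidth", k))
    }
    if (length(object@genePair) != 2L)
        msg <- c(msg, "genePair must have length 2")
    if (length(msg)) msg else TRUE
})

#' JdinacConfig: tuning parameters of the differential network fit
#'
#' @slot nSplits number of random sample splits T.
#' @slot splitFraction fraction of samples used for density estimation in
#'   each split (the rest fit the penalized model; roles are then swapped).
#' @slot cvFolds folds for cross-validated penalty selection.
#' @slot lambdaGrid numeric penalty grid, or empty for glmnet's automatic
#'   path.
#' @slot densityFloor positive floor applied to densities before the log.
#' @slot penalizeCovariates logical; covariates are unpenalized by default.
#' @slot seed master seed; all split and fold randomness derives from it.
#' @aliases JdinacConfig-class
#' @exportClass JdinacConfig
setClass("JdinacConfig", representation(
    nSplits = "integer", splitFraction = "numeric", cvFolds = "integer",
    lambdaGrid = "numeric", densityFloor = "numeric",
    penalizeCovariates = "logical", seed = "integer"))

setValidity("JdinacConfig", function(object) {
    msg <- character()
    if (object@nSplits < 1L) msg <- c(msg, "nSplits must be positive")
    if (object@splitFraction <= 0 || object@splitFraction >= 1)
        msg <- c(msg, "splitFraction must lie in (0, 1)")
    if (object@cvFolds < 2L) msg <- c(msg, "cvFolds must be >= 2")
    if (object@densityFloor <= 0) msg <- c(msg, "densityFloor must be > 0")
    if (length(object@lambdaGrid) && any(object@lambdaGrid <= 0))
        msg <- c(msg, "lambdaGrid values must be positive")
    if (length(msg)) msg else TRUE
})

#' ImportanceTable: per-pair selection counts over random splits
#'
#' For every unordered gene pair (i, j), the importance score omega_ij counts
#' the random splits in which the pair's log density-ratio feature received a
#' non-zero lasso coefficient; 0 <= omega_ij <= T.
#'
#' @slot pairs data.frame with columns gene1, gene2, omega.
#' @slot nSplits total number of splits T.
#' @aliases ImportanceTable-class
#' @exportClass ImportanceTable
setClass("ImportanceTable",
         representation(pairs = "data.frame", nSplits = "integer"))

setValidity("ImportanceTable", function(object) {
    p <- object@pairs
    msg <- character()
    if (!all(c("gene1", "gene2", "omega") %in% names(p)))
        return("pairs must have columns gene1, gene2, omega")
    if (any(p$omega < 0) || any(p$omega > object@nSplits))
        msg <- c(msg, "omega must lie in [0, nSplits]")
    key <- paste(pmin(p$gene1, p$gene2), pmax(p$gene1, p$gene2))
    if (anyDuplicated(key))
        msg <- c(msg, "duplicate gene pair(s)")
    if (any(p$gene1 == p$gene2))
        msg <- c(msg, "self-pairs are not allowed")
    if (length(msg)) msg else TRUE
})

#' DifferentialNetwork: thresholded differential edge set with hubs
#'
#' @slot nodes gene ids that are endpoints of retained edges.
#' @slot edges data.frame gene1, gene2, omega, rank (omega descending, ties
#'   broken by lexicographic pair order).
#' @slot hubs genes with degree >= \code{minDegree} on the retained edges.
#' @slot minScore,minDegree,nSplits the thresholds used.
#' @aliases DifferentialNetwork-class
#' @exportClass DifferentialNetwork
setClass("DifferentialNetwork", representation(
    nodes = "character", edges = "data.frame", hubs = "character",
    minScore = "integer", minDegree = "integer", nSplits = "integer"))

setValidity("DifferentialNetwork", function(object) {
    e <- object@edges
    msg <- character()
    if (!all(c("gene1", "gene2", "omega", "rank") %in% names(e)))
        return("edges must have columns gene1, gene2, omega, rank")
    if (nrow(e) && !all(c(e$gene1, e$gene2) %in% object@nodes))
        msg <- c(msg, "every edge endpoint must be a node")
    if (!all(object@hubs %in% object@nodes))
        msg <- c(msg, "hubs must be nodes")
    if (length(msg)) msg else TRUE
})
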