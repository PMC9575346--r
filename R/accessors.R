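#' Construct a GenotypeExperiment
#'
#' @param genotypes integer matrix of additive minor-allele counts, SNPs as
#'   rows and samples as columns (values 0/1/2 or \code{NA}); dimnames give
#'   SNP and sample ids.
#' @param label integer vector, 1 = case, 0 = control, one per sample.
#' @param covariates optional data.frame of numeric covariates (one row per
#'   sample).
#' @param geneMap optional data.frame with columns \code{snp}, \code{gene}
#'   stored in \code{rowData}.
#' @return a validated \linkS4class{GenotypeExperiment}.
#' @examples
#' g <- matrix(c(0L, 1L, 2L, 0L), 2, 2,
#'             dimnames = list(c("rs1", "rs2"), c("s1", "s2")))
#' GenotypeExperiment(g, label = c(0L, 1L))
#' @export
GenotypeExperiment <- function(genotypes, label, covariates = NULL,
                               geneMap = NULL) {
    stopifnot(is.matrix(genotypes), length(label) == ncol(genotypes))
    cd <- DataFrame(label = as.integer(label), row.names = colnames(genotypes))
    covNames <- character()
    if (!is.null(covariates)) {
        stopifnot(nrow(covariates) == ncol(genotypes))
        for (nm in colnames(covariates)) cd[[nm]] <- covariates[[nm]]
        covNames <- colnames(covariates)
    }
    rd <- DataFrame(snp = rownames(genotypes), row.names = rownames(genotypes))
    if (!is.null(geneMap)) {
        idx <- match(rownames(genotypes), geneMap$snp)
        rd$gene <- geneMap$gene[idx]
    }
    se <- SummarizedExperiment(assays = SimpleList(genotype = genotypes),
                               colData = cd, rowData = rd)
    metadata(se)$covariates <- covNames
    new("GenotypeExperiment", se)
}

#' Genotype matrix accessor
#'
#' @param x a \linkS4class{GenotypeExperiment}.
#' @param ... unused.
#' @return the SNP x sample additive genotype matrix.
#' @export
#' @rdname genotypes
setMethod("genotypes", "GenotypeExperiment",
          function(x, ...) assay(x, "genotype"))

#' Gene score matrix accessor
#'
#' @param x a \linkS4class{GeneScoreExperiment}.
#' @param ... unused.
#' @return the gene x sample score matrix.
#' @export
#' @rdname geneScores
setMethod("geneScores", "GeneScoreExperiment",
          function(x, ...) assay(x, "score"))

#' Case/control labels
#'
#' @param x a \linkS4class{GenotypeExperiment} or
#'   \linkS4class{GeneScoreExperiment}.
#' @param ... unused.
#' @return integer vector, 1 = case, 0 = control.
#' @export
#' @rdname caseLabels
setMethod("caseLabels", "SummarizedExperiment",
          function(x, ...) as.integer(colData(x)$label))

#' Covariate matrix
#'
#' @param x a \linkS4class{GenotypeExperiment} or
#'   \linkS4class{GeneScoreExperiment}.
#' @param which optional character vector selecting covariates; default all
#'   declared covariates.
#' @param ... unused.
#' @return numeric matrix (samples x covariates), possibly with 0 columns.
#' @export
#' @rdname covariates
setMethod("covariates", "SummarizedExperiment", function(x, which = NULL, ...) {
    declared <- metadata(x)$covariates
    if (is.null(declared)) declared <- character()
    if (is.null(which)) which <- declared
    if (length(which) && !all(which %in% colnames(colData(x))))
        stop("unknown covariate(s): ",
             paste(setdiff(which, colnames(colData(x))), collapse = ", "))
    m <- as.matrix(as.data.frame(colData(x)[, which, drop = FALSE]))
    if (!length(which))
        m <- matrix(numeric(), nrow = ncol(x), ncol = 0)
    rownames(m) <- colnames(x)
    m
})

#' @rdname importanceScores
#' @param x an \linkS4class{ImportanceTable} or
#'   \linkS4class{DifferentialNetwork}.
#' @param ... unused.
#' @return data.frame of gene pairs with their omega scores.
#' @export
setMethod("importanceScores", "ImportanceTable", function(x, ...) x@pairs)

#' @rdname networkEdges
#' @param x a \linkS4class{DifferentialNetwork}.
#' @param ... unused.
#' @return data.frame of retained edges with omega and rank.
#' @export
setMethod("networkEdges", "DifferentialNetwork", function(x, ...) x@edges)

#' @rdname hubGenes
#' @param x a \linkS4class{DifferentialNetwork}.
#' @param ... unused.
#' @return character vector of hub genes, degree descending.
#' @export
setMethod("hubGenes", "DifferentialNetwork", function(x, ...) x@hubs)

#' @rdname truthEdges
#' @param x a \linkS4class{TruthNetwork}.
#' @param ... unused.
#' @return data.frame of planted edges with per-group correlations.
#' @export
setMethod("truthEdges", "TruthNetwork", function(x, ...) x@edges)

#' @rdname crosstab
#' @param x a \linkS4class{ContingencyTable}.
#' @param ... unused.
#' @export
setMethod("factorCounts", "ContingencyTable", function(x, ...) x@counts)

setMethod("show", "GenotypeExperiment", function(object) {
    y <- caseLabels(object)
    cat(sprintf("GenotypeExperiment: %d SNPs x %d samples (%d cases, %d controls)\n",
                nrow(object), ncol(object), sum(y == 1L), sum(y == 0L)))
    cv <- metadata(object)$covariates
    cat("covariates:", if (length(cv)) paste(cv, collapse = ", ") else "none",
        "\n")
    cat(sprintf("missing genotypes: %d\n", sum(is.na(assay(object, "genotype")))))
})

setMethod("show", "GeneScoreExperiment", function(object) {
    y <- caseLabels(object)
    cat(sprintf("GeneScoreExperiment: %d genes x %d samples (%d cases, %d controls)\n",
                nrow(object), ncol(object), sum(y == 1L), sum(y == 0L)))
})

setMethod("show", "SimConfig", function(object) {
    cat(sprintf("SimConfig: %d cases / %d controls, %d genes, %d SNPs\n",
                object@nCase, object@nControl, length(object@genes),
                sum(rep_len(object@snpsPerGene, length(object@genes)))))
    cat(sprintf("planted edges: %d (%d differential), within-gene rho %.2f, seed %d\n",
                nrow(object@plantedEdges),
                sum(object@plantedEdges$rhoCase != object@plantedEdges$rhoControl),
                object@withinGeneRho, object@seed))
})

setMethod("show", "TruthNetwork", function(object) {
    cat(sprintf("TruthNetwork: %d planted edges (%d differential)\n",
                nrow(object@edges), sum(object@edges$differential)))
})

setMethod("show", "ContingencyTable", function(object) {
    cat(sprintf("ContingencyTable '%s' (%d categories x 2 groups)\n",
                object@factorName, nrow(object@counts)))
    print(object@counts)
})

setMethod("show", "PairDensityModel", function(object) {
    cat(sprintf("PairDensityModel for (%s, %s): n_case %d, n_control %d\n",
                object@genePair[1], object@genePair[2],
                object@kdeCase$n, object@kdeControl$n))
    cat(sprintf("bandwidths case (%.3g, %.3g), control (%.3g, %.3g)\n",
                object@kdeCase$hx, object@kdeCase$hy,
                object@kdeControl$hx, object@kdeControl$hy))
})

setMethod("show", "JdinacConfig", function(object) {
    cat(sprintf(
        "JdinacConfig: T = %d splits, split fraction %.2f, %d-fold CV, seed %d\n",
        object@nSplits, object@splitFraction, object@cvFolds, object@seed))
    cat(sprintf("density floor %g, covariates %s\n", object@densityFloor,
                if (object@penalizeCovariates) "penalized" else "unpenalized"))
})

setMethod("show", "ImportanceTable", function(object) {
    cat(sprintf("ImportanceTable: %d gene pairs, T = %d splits\n",
                nrow(object@pairs), object@nSplits))
    top <- utils::head(object@pairs[order(-object@pairs$omega,
                                          object@pairs$gene1,
                                          object@pairs$gene2), ], 5)
    print(top, row.names = FALSE)
})

setMethod("show", "DifferentialNetwork", function(object) {
    cat(sprintf(
        "DifferentialNetwork: %d nodes, %d edges (omega >= %d of T = %d)\n",
        length(object@nodes), nrow(object@edges), object@minScore,
        object@nSplits))
    cat("hubs (degree >=", object@minDegree, "):",
        if (length(object@hubs)) paste(object@hubs, collapse = ", ")
        else "none", "\n")
})
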