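#' @rdname genotypes
#' @export
setGeneric("genotypes", function(x, ...) standardGeneric("genotypes"))

#' @rdname geneScores
#' @export
setGeneric("geneScores", function(x, ...) standardGeneric("geneScores"))

#' @rdname caseLabels
#' @export
setGeneric("caseLabels", function(x, ...) standardGeneric("caseLabels"))

#' @rdname covariates
#' @export
setGeneric("covariates", function(x, ...) standardGeneric("covariates"))

#' @rdname importanceScores
#' @export
setGeneric("importanceScores",
           function(x, ...) standardGeneric("importanceScores"))

#' @rdname networkEdges
#' @export
setGeneric("networkEdges", function(x, ...) standardGeneric("networkEdges"))

#' @rdname hubGenes
#' @export
setGeneric("hubGenes", function(x, ...) standardGeneric("hubGenes"))

#' @rdname truthEdges
#' @export
setGeneric("truthEdges", function(x, ...) standardGeneric("truthEdges"))

#' @rdname crosstab
#' @export
setGeneric("factorCounts", function(x, ...) standardGeneric("factorCounts"))
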