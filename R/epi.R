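#' Cross-tabulate a per-sample factor by case status
#'
#' Builds the r x 2 contingency table of a categorical (or binned numeric)
#' factor against the binary case/control label. Numeric factors are binned
#' by right-closed half-open intervals at the supplied cut points, i.e.
#' categories x <= c1, c1 < x <= c2, ..., x > ck, matching the
#' "<= 28 / > 28" style of epidemiological baseline tables. Samples with a
#' missing factor value are dropped, so each factor is tabulated on its
#' non-missing subset.
#'
#' @param values per-sample factor values (character, factor or numeric).
#' @param labels per-sample binary labels (1 = case).
#' @param bins optional strictly increasing numeric cut points for numeric
#'   \code{values}.
#' @param factorName name recorded on the table.
#' @return a \linkS4class{ContingencyTable} (columns control, case).
#' @examples
#' crosstab(c(27, 29, 30, 25), c(0, 0, 1, 1), bins = 28, factorName = "BMI")
#' @export
crosstab <- function(values, labels, bins = NULL, factorName = "factor") {
    if (length(values) != length(labels))
        stop("values and labels must have the same length")
    keep <- !is.na(values) & !is.na(labels)
    values <- values[keep]; labels <- labels[keep]
    if (!length(values)) stop("no non-missing observations")
    if (!is.null(bins)) {
        if (is.unsorted(bins, strictly = TRUE))
            stop("bins must be strictly increasing")
        labs <- character(length(bins) + 1L)
        labs[1] <- sprintf("<=%g", bins[1])
        if (length(bins) > 1L)
            labs[2:length(bins)] <- sprintf("(%g,%g]", bins[-length(bins)],
                                            bins[-1])
        labs[length(bins) + 1L] <- sprintf(">%g", bins[length(bins)])
        values <- cut(as.numeric(values), c(-Inf, bins, Inf), labels = labs,
                      right = TRUE)
    }
    tab <- table(values, factor(labels, levels = c(0, 1)))
    m <- matrix(as.integer(tab), nrow = nrow(tab),
                dimnames = list(rownames(tab), c("control", "case")))
    empty <- rowSums(m) == 0
    if (any(empty)) {
        warning("dropping zero-count categor",
                if (sum(empty) > 1) "ies: " else "y: ",
                paste(rownames(m)[empty], collapse = ", "))
        m <- m[!empty, , drop = FALSE]
    }
    new("ContingencyTable", counts = m, factorName = factorName)
}

#' Construct a ContingencyTable from counts
#'
#' @param counts r x 2 matrix of counts, columns (control, case).
#' @param factorName name of the factor.
#' @param rowLabels optional category names.
#' @return a \linkS4class{ContingencyTable}.
#' @export
contingencyTable <- function(counts, factorName = "factor",
                             rowLabels = NULL) {
    m <- as.matrix(counts)
    if (!is.null(rowLabels)) rownames(m) <- rowLabels
    if (is.null(colnames(m))) colnames(m) <- c("control", "case")
    storage.mode(m) <- "integer"
    new("ContingencyTable", counts = m, factorName = factorName)
}

#' Pearson chi-square test of independence
#'
#' Classic Pearson chi-square on an r x 2 contingency table, without Yates
#' continuity correction (also for 2 x 2 tables): the statistic is
#' sum((O - E)^2 / E) with E = row total x column total / grand total,
#' df = (r - 1)(c - 1), and the p-value is the upper tail of the chi-square
#' distribution.
#'
#' @param t a \linkS4class{ContingencyTable} or an r x 2 count matrix.
#' @return list with \code{statistic}, \code{df} and \code{p}.
#' @examples
#' bmi <- contingencyTable(cbind(control = c(849, 85), case = c(799, 117)),
#'                         "BMI", c("<=28", ">28"))
#' chisqIndependence(bmi)   # statistic 6.412, p 0.011
#' @export
chisqIndependence <- function(t) {
    m <- if (is(t, "ContingencyTable")) factorCounts(t) else as.matrix(t)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0))
        stop("zero row or column total: expected counts are zero")
    ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    list(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p = unname(ht$p.value))
}

#' Baseline-characteristics chi-square report
#'
#' Tabulates each requested covariate of a cohort against case status and
#' tests independence, producing one row per factor in the style of a
#' clinical Table 1.
#'
#' @param x a \linkS4class{GenotypeExperiment} or
#'   \linkS4class{GeneScoreExperiment}.
#' @param factors named list; each element is either \code{NULL} (tabulate
#'   the covariate's distinct values) or a numeric vector of cut points for
#'   binning.
#' @return data.frame with columns factor, categories, counts (control/case
#'   with percentages), statistic, df, p.
#' @export
epiReport <- function(x, factors) {
    y <- caseLabels(x)
    rows <- lapply(names(factors), function(nm) {
        v <- colData(x)[[nm]]
        if (is.null(v)) stop("no such covariate: ", nm)
        ct <- crosstab(v, y, bins = factors[[nm]], factorName = nm)
        ht <- chisqIndependence(ct)
        m <- factorCounts(ct)
        pct <- sweep(m, 2, colSums(m), "/") * 100
        data.frame(
            factor = nm,
            categories = paste(rownames(m), collapse = "; "),
            control = paste(sprintf("%d (%.2f%%)", m[, 1], pct[, 1]),
                            collapse = "; "),
            case = paste(sprintf("%d (%.2f%%)", m[, 2], pct[, 2]),
                         collapse = "; "),
            statistic = round(ht$statistic, 3),
            df = ht$df,
            p = round(ht$p, 3))
    })
    do.call(rbind, rows)
}
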