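## Per-dimension Silverman rule-of-thumb bandwidth (stats::bw.nrd0), with a
## fallback for degenerate dimensions: a zero-variance dimension gets a small
## fixed fraction of the overall data scale so the KDE stays proper.
silvermanBandwidth <- function(v) {
    if (stats::sd(v) > 0 || stats::IQR(v) > 0)
        return(stats::bw.nrd0(v))
    warning("zero-variance dimension: falling back to a fixed small bandwidth")
    0.01 * max(diff(range(v)), 1)
}

#' Fit a bivariate product-Gaussian kernel density
#'
#' Estimates the joint density of two gene scores with a product Gaussian
#' kernel and independent per-dimension bandwidths chosen by Silverman's
#' rule of thumb. This is the group-conditional density estimator behind the
#' differential-network features: one fit per gene pair and group.
#'
#' @param x,y paired observations (at least 5, finite).
#' @return an object of class \code{"pairKde"}: list with the data
#'   (\code{x}, \code{y}), bandwidths (\code{hx}, \code{hy}) and \code{n}.
#' @examples
#' set.seed(1)
#' kde <- fitPairDensity(rnorm(200), rnorm(200))
#' evaluateDensity(kde, 0, 0)    # near 1/(2*pi)
#' @export
fitPairDensity <- function(x, y) {
    keep <- is.finite(x) & is.finite(y)
    x <- x[keep]; y <- y[keep]
    if (length(x) < 5L)
        stop("at least 5 paired observations are required to fit a density")
    structure(list(x = x, y = y,
                   hx = silvermanBandwidth(x), hy = silvermanBandwidth(y),
                   n = length(x)),
              class = "pairKde")
}

#' Evaluate a fitted bivariate kernel density
#'
#' @param kde a \code{"pairKde"} fit from \code{\link{fitPairDensity}}.
#' @param px,py coordinates of the evaluation points.
#' @return density values (non-negative) at the points.
#' @export
evaluateDensity <- function(kde, px, py) {
    stopifnot(inherits(kde, "pairKde"), length(px) == length(py))
    if (!length(px)) return(numeric())
    ## chunk evaluation points to bound the outer-product memory
    out <- numeric(length(px))
    chunk <- max(1L, floor(4e6 / kde$n))
    for (start in seq(1L, length(px), by = chunk)) {
        idx <- start:min(start + chunk - 1L, length(px))
        kx <- stats::dnorm(outer(px[idx], kde$x, "-") / kde$hx)
        ky <- stats::dnorm(outer(py[idx], kde$y, "-") / kde$hy)
        out[idx] <- rowMeans(kx * ky) / (kde$hx * kde$hy)
    }
    out
}

#' Fit the case/control density pair of one gene pair
#'
#' @param si,sj per-sample scores of genes i and j.
#' @param y binary labels (1 = case).
#' @param genePair length-2 character naming the pair.
#' @return a \linkS4class{PairDensityModel}.
#' @export
pairDensityModel <- function(si, sj, y, genePair = c("gene_i", "gene_j")) {
    new("PairDensityModel", genePair = as.character(genePair),
        kdeCase = unclass(fitPairDensity(si[y == 1], sj[y == 1])),
        kdeControl = unclass(fitPairDensity(si[y == 0], sj[y == 0])))
}

#' Log density-ratio feature
#'
#' The differential-interaction feature of a gene pair: the log ratio of the
#' case to the control conditional joint density, evaluated at each sample's
#' score pair. Both densities are floored before the log so the feature is
#' always finite; far outside both supports the feature is exactly 0.
#'
#' @param model a \linkS4class{PairDensityModel}.
#' @param px,py evaluation points (score pairs).
#' @param floor positive density floor (default 1e-10).
#' @return finite numeric vector ln(max(f1, floor) / max(f0, floor)).
#' @export
logDensityRatio <- function(model, px, py, floor = 1e-10) {
    stopifnot(floor > 0)
    f1 <- evaluateDensity(structure(model@kdeCase, class = "pairKde"), px, py)
    f0 <- evaluateDensity(structure(model@kdeControl, class = "pairKde"),
                          px, py)
    log(pmax(f1, floor) / pmax(f0, floor))
}
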