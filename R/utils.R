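#' Spawn deterministic sub-seeds from a master seed
#'
#' All randomness in the package flows from a single master seed through
#' named streams drawn by this helper, so that an entire analysis is
#' reproducible from one integer.
#'
#' @param master integer master seed.
#' @param n number of sub-seeds.
#' @return integer vector of n distinct seeds in [1, 2^31 - 2].
#' @export
spawnSeeds <- function(master, n) {
    withr::with_seed(as.integer(master),
                     sample.int(.Machine$integer.max - 1L, n))
}

## stratified split of sample indices: returns logical "in part 1" per sample,
## preserving the class balance; deterministic given seed.
stratifiedSplit <- function(y, fraction, seed) {
    withr::with_seed(as.integer(seed), {
        inD1 <- logical(length(y))
        for (cls in sort(unique(y))) {
            idx <- which(y == cls)
            n1 <- round(length(idx) * fraction)
            n1 <- max(1L, min(length(idx) - 1L, n1))
            inD1[sample(idx, n1)] <- TRUE
        }
        inD1
    })
}

## stratified cross-validation fold ids; every fold gets both classes
## whenever each class has >= nfolds members.
stratifiedFolds <- function(y, nfolds, seed) {
    withr::with_seed(as.integer(seed), {
        foldid <- integer(length(y))
        for (cls in unique(y)) {
            idx <- sample(which(y == cls))
            foldid[idx] <- rep_len(seq_len(nfolds), length(idx))
        }
        foldid
    })
}

canonicalPairs <- function(genes) {
    genes <- sort(genes)
    p <- length(genes)
    i <- rep(seq_len(p - 1L), times = (p - 1L):1L)
    j <- unlist(lapply(seq_len(p - 1L), function(k) (k + 1L):p))
    data.frame(gene1 = genes[i], gene2 = genes[j],
               stringsAsFactors = FALSE)
}
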