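#' Read a case-control genotype table
#'
#' Two dialects are supported. \code{"delimited"}: a UTF-8 comma- or
#' tab-separated table (the separator is sniffed from the header) with
#' reserved columns \code{sample_id} and \code{label}, optional covariate
#' columns named in \code{covariates}, and one column per SNP holding
#' additive minor-allele counts 0/1/2 (empty or NA = missing).
#' \code{"vcf"}: a standard VCF whose GT fields are converted to alternate
#' allele counts (half-calls and non-diploid genotypes become missing);
#' labels and covariates must then be supplied through \code{sampleTable}, a
#' delimited file with a \code{sample_id} column matching the VCF sample
#' names plus \code{label} and covariate columns.
#'
#' @param path genotype file.
#' @param dialect \code{"delimited"} or \code{"vcf"}.
#' @param covariates character vector naming covariate columns.
#' @param sampleTable companion sample table path (VCF dialect only).
#' @return a validated \linkS4class{GenotypeExperiment}.
#' @export
readGenotypes <- function(path, dialect = c("delimited", "vcf"),
                          covariates = character(), sampleTable = NULL) {
    dialect <- match.arg(dialect)
    if (dialect == "delimited")
        readGenotypesDelim(path, covariates)
    else
        readGenotypesVcf(path, sampleTable, covariates)
}

sniffSep <- function(path) {
    header <- readLines(path, n = 1L)
    if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
}

readGenotypesDelim <- function(path, covariates) {
    if (!file.exists(path)) stop("file not found: ", path)
    sep <- sniffSep(path)
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            na.strings = c("NA", ""))
    reserved <- c("sample_id", "label")
    if (!all(reserved %in% names(df)))
        stop("genotype table must have columns 'sample_id' and 'label'")
    if (anyDuplicated(names(df)))
        stop("duplicate column id(s): ",
             paste(unique(names(df)[duplicated(names(df))]), collapse = ", "))
    if (anyDuplicated(df$sample_id))
        stop("duplicate sample id(s): ",
             paste(unique(df$sample_id[duplicated(df$sample_id)]),
                   collapse = ", "))
    missingCov <- setdiff(covariates, names(df))
    if (length(missingCov))
        stop("declared covariate(s) not in table: ",
             paste(missingCov, collapse = ", "))
    snpCols <- setdiff(names(df), c(reserved, covariates))
    if (!length(snpCols)) stop("no SNP columns found")
    g <- as.matrix(df[, snpCols, drop = FALSE])
    bad <- which(!is.na(g) & !g %in% c(0, 1, 2), arr.ind = TRUE)
    if (nrow(bad))
        stop(sprintf("genotype value outside {0,1,2} at row %d, column '%s'",
                     bad[1, 1], snpCols[bad[1, 2]]))
    storage.mode(g) <- "integer"
    rownames(g) <- df$sample_id
    covDf <- if (length(covariates)) df[, covariates, drop = FALSE] else NULL
    GenotypeExperiment(t(g), label = df$label, covariates = covDf)
}

## GT string ("0/1", "1|1", "./.", half-calls, haploid) -> ALT allele count
gtToDosage <- function(gt) {
    alleles <- strsplit(gt, "[/|]")
    vapply(alleles, function(a) {
        if (length(a) != 2L || any(a == ".") || any(is.na(a))) NA_integer_
        else sum(a != "0")
    }, integer(1))
}

readGenotypesVcf <- function(path, sampleTable, covariates) {
    if (is.null(sampleTable))
        stop("VCF dialect requires a companion sample table ",
             "with sample_id, label and covariate columns")
    if (!file.exists(path)) stop("file not found: ", path)
    vcf <- suppressMessages(vcfR::read.vcfR(path, verbose = FALSE))
    gt <- vcfR::extract.gt(vcf, element = "GT")
    if (anyDuplicated(rownames(gt)))
        stop("duplicate SNP id(s) in VCF: ",
             paste(unique(rownames(gt)[duplicated(rownames(gt))]),
                   collapse = ", "))
    g <- matrix(gtToDosage(as.vector(gt)), nrow = nrow(gt),
                dimnames = dimnames(gt))
    sep <- sniffSep(sampleTable)
    st <- utils::read.table(sampleTable, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
    if (!all(c("sample_id", "label") %in% names(st)))
        stop("sample table must have columns 'sample_id' and 'label'")
    if (!all(colnames(g) %in% st$sample_id))
        stop("sample table is missing VCF sample(s): ",
             paste(setdiff(colnames(g), st$sample_id), collapse = ", "))
    st <- st[match(colnames(g), st$sample_id), ]
    covDf <- if (length(covariates)) st[, covariates, drop = FALSE] else NULL
    GenotypeExperiment(g, label = st$label, covariates = covDf)
}

#' Read a SNP-to-gene map
#'
#' A two-column delimited file (snp, gene); each SNP must map to exactly one
#' gene.
#'
#' @param path file path.
#' @return data.frame with columns \code{snp}, \code{gene}.
#' @export
readSnpGeneMap <- function(path) {
    sep <- sniffSep(path)
    m <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
    names(m)[1:2] <- c("snp", "gene")
    if (anyDuplicated(m$snp))
        stop("SNP(s) mapped to more than one gene: ",
             paste(unique(m$snp[duplicated(m$snp)]), collapse = ", "))
    m
}

#' Aggregate SNP genotypes into per-gene risk scores
#'
#' The gene risk score of a sample is the arithmetic mean of its additive
#' genotype codes over the gene's SNPs, so scores lie in [0, 2]. Missing
#' genotypes are handled by \code{missingPolicy}:
#' \code{"per_snp_mean_impute"} (default) replaces each missing entry by that
#' SNP's sample mean before averaging, keeping every sample's score defined;
#' \code{"drop_from_mean"} averages each sample over its non-missing SNPs
#' only (a sample with no observed SNP for a gene gets \code{NA}, with a
#' warning).
#'
#' @param g a \linkS4class{GenotypeExperiment}.
#' @param map data.frame with columns \code{snp}, \code{gene}; defaults to
#'   the \code{gene} column of \code{rowData(g)} when present.
#' @param missingPolicy missing-genotype policy (see above).
#' @return a \linkS4class{GeneScoreExperiment} (genes x samples) carrying the
#'   labels and covariates of \code{g}.
#' @examples
#' g <- matrix(c(0L, 1L, 2L, 0L, 1L, 2L), nrow = 3,
#'             dimnames = list(c("rs1", "rs2", "rs3"), c("a", "b")))
#' ge <- GenotypeExperiment(g, label = c(0L, 1L))
#' map <- data.frame(snp = c("rs1", "rs2", "rs3"), gene = "G1")
#' geneScores(computeGeneScores(ge, map))
#' @export
computeGeneScores <- function(g, map = NULL,
                              missingPolicy = c("per_snp_mean_impute",
                                                "drop_from_mean")) {
    missingPolicy <- match.arg(missingPolicy)
    if (is.null(map)) {
        if (!"gene" %in% colnames(rowData(g)))
            stop("no SNP-gene map supplied and rowData(g) has no 'gene'")
        map <- data.frame(snp = rownames(g), gene = rowData(g)$gene)
    }
    if (anyDuplicated(map$snp))
        stop("SNP(s) mapped to more than one gene: ",
             paste(unique(map$snp[duplicated(map$snp)]), collapse = ", "))
    geno <- genotypes(g)
    genes <- unique(map$gene)
    absent <- genes[!vapply(genes, function(gg)
        any(map$snp[map$gene == gg] %in% rownames(geno)), logical(1))]
    if (length(absent))
        stop("gene(s) with no SNP present in the genotype data: ",
             paste(absent, collapse = ", "))
    if (missingPolicy == "per_snp_mean_impute" && anyNA(geno)) {
        mu <- rowMeans(geno, na.rm = TRUE)
        idx <- which(is.na(geno), arr.ind = TRUE)
        geno[idx] <- mu[idx[, 1]]
    }
    scores <- matrix(NA_real_, length(genes), ncol(geno),
                     dimnames = list(genes, colnames(geno)))
    for (gg in genes) {
        snps <- intersect(map$snp[map$gene == gg], rownames(geno))
        sub <- geno[snps, , drop = FALSE]
        scores[gg, ] <- colMeans(sub, na.rm = TRUE)
    }
    if (anyNA(scores) || any(is.nan(scores))) {
        scores[is.nan(scores)] <- NA_real_
        warning("sample(s) with all SNPs of a gene missing: score set to NA")
    }
    se <- SummarizedExperiment(assays = SimpleList(score = scores),
                               colData = colData(g))
    metadata(se)$covariates <- metadata(g)$covariates
    new("GeneScoreExperiment", se)
}

#' Write gene scores as a delimited table
#'
#' @param gs a \linkS4class{GeneScoreExperiment}.
#' @param path output file (CSV; columns sample_id, label, one per gene).
#' @return invisibly, \code{path}.
#' @export
writeGeneScores <- function(gs, path) {
    df <- data.frame(sample_id = colnames(gs), label = caseLabels(gs),
                     t(geneScores(gs)), check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
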