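#' Run the full analysis pipeline from a declarative configuration
#'
#' Orchestrates the whole analysis as one reproducible run: obtain a cohort
#' (either simulate one or read genotype files), aggregate SNPs into gene
#' scores, emit the demographic chi-square report, fit the differential
#' network under one or more covariate-adjustment scenarios, call hubs, test
#' hub-gene SNP associations, validate the retained edges on a fresh split,
#' and write every artifact plus a metadata sidecar to the output directory.
#'
#' The configuration is a named list (or a YAML file with the same
#' structure) with entries:
#' \describe{
#'   \item{simulation}{arguments for \code{\link{simConfig}} (exclusive with
#'     \code{input}).}
#'   \item{input}{list with \code{genotypes}, optional \code{dialect},
#'     \code{map}, \code{sample_table}, \code{covariates} for
#'     \code{\link{readGenotypes}}.}
#'   \item{epi_factors}{named list of factors for \code{\link{epiReport}}
#'     (value = cut points or NULL).}
#'   \item{jdinac}{arguments for \code{\link{jdinacConfig}}, plus optional
#'     \code{min_score} and \code{min_hub_degree}.}
#'   \item{covariate_scenarios}{list of covariate-name vectors; one network
#'     is fitted per scenario (default: one scenario using all declared
#'     covariates).}
#'   \item{out_dir}{output directory.}
#'   \item{seed}{master seed; every stage draws its randomness from named
#'     sub-streams of it.}
#' }
#'
#' @param config named list or path to a YAML file.
#' @return invisibly, a list with the in-memory results (cohort, scores,
#'   epi report, per-scenario networks, association and validation tables,
#'   artifact paths).
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    if (is.null(config$out_dir)) stop("config needs an out_dir")
    if (!is.null(config$input) && !is.null(config$simulation))
        stop("config must have exactly one of 'input' and 'simulation'")
    if (is.null(config$input) && is.null(config$simulation))
        stop("config must have exactly one of 'input' and 'simulation'")
    if (!is.null(config$input)) {
        inp <- config$input
        for (f in c(inp$genotypes, inp$map, inp$sample_table))
            if (!file.exists(f)) stop("input file not found: ", f)
    }
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    masterSeed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
    stageSeeds <- spawnSeeds(masterSeed, 3L)
    paths <- list()

    ## --- cohort -----------------------------------------------------------
    truth <- NULL
    if (!is.null(config$simulation)) {
        simArgs <- config$simulation
        simArgs$seed <- stageSeeds[1]
        sim <- do.call(simConfig, simArgs)
        out <- simulateCohort(sim)
        cohort <- out$cohort
        truth <- out$truth
        paths <- c(paths, as.list(writeCohort(out, config$out_dir)))
    } else {
        inp <- config$input
        cohort <- readGenotypes(inp$genotypes,
                                dialect = if (is.null(inp$dialect)) "delimited"
                                          else inp$dialect,
                                covariates = unlist(inp$covariates),
                                sampleTable = inp$sample_table)
        if (!is.null(inp$map)) {
            map <- readSnpGeneMap(inp$map)
            rowData(cohort)$gene <- map$gene[match(rownames(cohort), map$snp)]
        }
    }

    ## --- gene scores ------------------------------------------------------
    scores <- computeGeneScores(cohort)
    paths$gene_scores <- file.path(config$out_dir, "gene_scores.csv")
    writeGeneScores(scores, paths$gene_scores)

    ## --- demographic report -----------------------------------------------
    epi <- NULL
    epiFactors <- config$epi_factors
    if (is.null(epiFactors)) {
        declared <- metadata(cohort)$covariates
        epiFactors <- stats::setNames(vector("list", length(declared)),
                                      declared)
    }
    if (length(epiFactors)) {
        epi <- epiReport(cohort, epiFactors)
        paths$epi_report <- file.path(config$out_dir, "epi_report.tsv")
        utils::write.table(epi, paths$epi_report, sep = "\t",
                           row.names = FALSE, quote = FALSE)
    }

    ## --- differential network per covariate scenario ----------------------
    jdArgs <- config$jdinac
    minScore <- jdArgs$min_score
    minHubDegree <- if (is.null(jdArgs$min_hub_degree)) 4L
                    else jdArgs$min_hub_degree
    jdArgs$min_score <- NULL; jdArgs$min_hub_degree <- NULL
    if (is.null(jdArgs)) jdArgs <- list()
    jdArgs$seed <- stageSeeds[2]
    cfg <- do.call(jdinacConfig, jdArgs)
    scenarios <- config$covariate_scenarios
    if (is.null(scenarios))
        scenarios <- list(metadata(cohort)$covariates)
    scenarioName <- function(cv)
        if (!length(cv)) "unadjusted" else paste(cv, collapse = "_")
    networks <- list()
    for (cv in scenarios) {
        cv <- as.character(unlist(cv))
        nm <- scenarioName(cv)
        imp <- jdinacImportance(scores, z = covariates(scores, which = cv),
                                cfg = cfg)
        ms <- if (is.null(minScore)) ceiling(cfg@nSplits / 4) else minScore
        net <- buildNetwork(imp, minScore = ms, minDegree = minHubDegree)
        networks[[nm]] <- list(importance = imp, network = net)
        paths[[paste0("importance_", nm)]] <-
            writeImportance(imp, file.path(config$out_dir,
                                           sprintf("importance_%s.tsv", nm)))
        paths[[paste0("network_sif_", nm)]] <-
            writeSif(net, file.path(config$out_dir,
                                    sprintf("network_%s.sif", nm)))
        paths[[paste0("network_graphml_", nm)]] <-
            writeGraphml(net, file.path(config$out_dir,
                                        sprintf("network_%s.graphml", nm)))
        hubPath <- file.path(config$out_dir, sprintf("hubs_%s.tsv", nm))
        writeLines(c("gene", hubGenes(net)), hubPath)
        paths[[paste0("hubs_", nm)]] <- hubPath
    }

    ## --- hub-gene SNP association + edge validation (first scenario) ------
    first <- networks[[1]]
    assoc <- NULL
    hubs <- hubGenes(first$network)
    if (length(hubs) && "gene" %in% colnames(rowData(cohort))) {
        assoc <- associationTable(cohort, genes = hubs)
        paths$association <- file.path(config$out_dir, "association.tsv")
        utils::write.table(assoc, paths$association, sep = "\t",
                           row.names = FALSE, quote = FALSE)
    }
    validation <- validateNetworkEdges(first$network, scores,
                                       seed = stageSeeds[3])
    paths$edge_validation <- file.path(config$out_dir, "edge_validation.tsv")
    utils::write.table(validation, paths$edge_validation, sep = "\t",
                       row.names = FALSE, quote = FALSE)

    ## --- metadata sidecar -------------------------------------------------
    meta <- list(
        package_version = as.character(utils::packageVersion("jdinac")),
        master_seed = masterSeed,
        stage_seeds = list(simulation = stageSeeds[1], network = stageSeeds[2],
                           validation = stageSeeds[3]),
        bandwidth_rule = "Silverman rule of thumb, per dimension",
        jdinac = list(nSplits = cfg@nSplits, splitFraction = cfg@splitFraction,
                      cvFolds = cfg@cvFolds, densityFloor = cfg@densityFloor,
                      penalizeCovariates = cfg@penalizeCovariates,
                      minScore = if (is.null(minScore))
                          ceiling(cfg@nSplits / 4) else minScore,
                      minHubDegree = minHubDegree),
        scenarios = lapply(scenarios, function(cv)
            scenarioName(as.character(unlist(cv)))))
    paths$metadata <- file.path(config$out_dir, "run_metadata.yaml")
    yaml::write_yaml(meta, paths$metadata)

    invisible(list(cohort = cohort, truth = truth, scores = scores,
                   epi = epi, networks = networks, association = assoc,
                   validation = validation, paths = paths))
}
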