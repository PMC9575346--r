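#' Export a differential network
#'
#' \code{writeSif} writes the simple interaction format
#' ("geneA interacts geneB", tab-separated); \code{writeGraphml} writes
#' GraphML with the importance score as edge weight and the hub flag as a
#' node attribute; \code{asIgraph} returns the corresponding igraph object.
#'
#' @param net a \linkS4class{DifferentialNetwork}.
#' @param path output file.
#' @return invisibly, \code{path} (or the igraph object for
#'   \code{asIgraph}).
#' @export
writeSif <- function(net, path) {
    e <- networkEdges(net)
    lines <- sprintf("%s\tinteracts\t%s", e$gene1, e$gene2)
    writeLines(lines, path)
    invisible(path)
}

#' @rdname writeSif
#' @export
asIgraph <- function(net) {
    e <- networkEdges(net)
    g <- igraph::graph_from_data_frame(
        e[, c("gene1", "gene2", "omega", "rank")], directed = FALSE,
        vertices = data.frame(name = net@nodes,
                              hub = net@nodes %in% hubGenes(net)))
    igraph::E(g)$weight <- e$omega
    g
}

#' @rdname writeSif
#' @export
writeGraphml <- function(net, path) {
    igraph::write_graph(asIgraph(net), path, format = "graphml")
    invisible(path)
}

#' Write an importance table as a delimited file
#'
#' @param imp an \linkS4class{ImportanceTable}.
#' @param path output TSV path (columns gene1, gene2, importance, T).
#' @return invisibly, \code{path}.
#' @export
writeImportance <- function(imp, path) {
    df <- importanceScores(imp)
    out <- data.frame(gene1 = df$gene1, gene2 = df$gene2,
                      importance = df$omega, T = imp@nSplits)
    out <- out[order(-out$importance, out$gene1, out$gene2), ]
    utils::write.table(out, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    invisible(path)
}
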