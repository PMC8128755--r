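#' Export a typed graph for external viewers
#'
#' Writes Cytoscape-compatible files. \code{"sif"} uses one interaction
#' token per edge type (\code{targets} for miRNA->mRNA, \code{pp} for
#' mRNA-mRNA, \code{assoc} for lncRNA associations, \code{regulates} for
#' TF->miRNA). \code{"graphml"} (via igraph) carries node type, edge type,
#' directedness and evidence-source count as attributes. \code{"edge_tsv"}
#' is the canonical flat form; \code{\link{readEdgeTsv}} reproduces the
#' same node and edge set from it.
#'
#' @param graph a \code{\link{TypedGraph}} (typically post-pruning).
#' @param path output file path.
#' @param format one of \code{"sif"}, \code{"graphml"}, \code{"edge_tsv"}.
#' @return the path, invisibly.
#' @export
exportGraph <- function(graph, path, format = c("sif", "graphml", "edge_tsv")) {
    stopifnot(is(graph, "TypedGraph"))
    format <- match.arg(format)
    ed <- graphEdges(graph)
    if (format == "sif") {
        token <- c(mrna_mrna = "pp", mirna_target = "targets",
                   lncrna_assoc = "assoc", tf_mirna = "regulates")
        lines <- if (nrow(ed))
            paste(ed$node_a, token[ed$edge_type], ed$node_b, sep = "\t")
        else character()
        writeLines(lines, path)
    } else if (format == "edge_tsv") {
        nodes <- graphNodes(graph)
        tab <- data.frame(node_a = ed$node_a,
                          a_type = unname(nodes[ed$node_a]),
                          node_b = ed$node_b,
                          b_type = unname(nodes[ed$node_b]),
                          edge_type = ed$edge_type,
                          directed = ed$directed,
                          sources = ed$sources,
                          n_sources = ed$n_sources,
                          stringsAsFactors = FALSE)
        write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
        ig <- asIgraph(graph)
        igraph::write_graph(ig, path, format = "graphml")
    }
    invisible(path)
}

#' @rdname exportGraph
#' @export
readEdgeTsv <- function(path) {
    tab <- readTsv(path)
    need <- c("node_a", "a_type", "node_b", "b_type", "edge_type",
              "directed", "sources", "n_sources")
    miss <- setdiff(need, names(tab))
    if (length(miss))
        usageError("edge TSV ", path, " is missing column(s): ",
                   paste(miss, collapse = ", "))
    nodes <- c(setNames(tab$a_type, tab$node_a),
               setNames(tab$b_type, tab$node_b))
    nodes <- nodes[!duplicated(names(nodes))]
    ed <- data.frame(node_a = tab$node_a, node_b = tab$node_b,
                     edge_type = tab$edge_type,
                     directed = as.logical(tab$directed),
                     sources = as.character(tab$sources),
                     n_sources = as.integer(tab$n_sources),
                     stringsAsFactors = FALSE)
    TypedGraph(nodes = nodes, edges = ed,
               provenance = list(imported_from = path))
}

#' Convert a TypedGraph to an igraph object
#'
#' The igraph representation is globally directed; undirected evidence
#' (mRNA-mRNA) is stored as a single arc with edge attribute
#' \code{directed = FALSE}. Node type and evidence-source count are carried
#' as attributes.
#'
#' @param graph a \code{\link{TypedGraph}}.
#' @return an \code{igraph} graph.
#' @export
asIgraph <- function(graph) {
    stopifnot(is(graph, "TypedGraph"))
    nodes <- graphNodes(graph)
    ed <- graphEdges(graph)
    vdf <- data.frame(name = names(nodes), type = unname(nodes),
                      stringsAsFactors = FALSE)
    edf <- data.frame(from = ed$node_a, to = ed$node_b,
                      edge_type = ed$edge_type, directed = ed$directed,
                      sources = ed$sources, n_sources = ed$n_sources,
                      stringsAsFactors = FALSE)
    igraph::graph_from_data_frame(edf, directed = TRUE, vertices = vdf)
}
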