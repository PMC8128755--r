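# Fixture builders and independent oracles shared across test files.
# Oracles are deliberately naive (set comprehension, peeling, enumeration)
# and never call the code paths they check.

tinyCountMatrix <- function(values, assay = "total_rna") {
    RnaCounts(values, assay)
}

tinyAnnotation <- function(ids, symbols = ids, biotype = "mRNA",
                           predicted = FALSE, snorna_class = NULL) {
    n <- length(ids)
    biotype <- rep_len(biotype, n)
    if (is.null(snorna_class))
        snorna_class <- ifelse(biotype == "snoRNA", "unclassified",
                               "not_applicable")
    FeatureAnnotation(data.frame(
        feature_id = ids, symbol = symbols, biotype = biotype,
        predicted = rep_len(predicted, n),
        snorna_class = snorna_class, stringsAsFactors = FALSE))
}

# random typed graph with a detected universe; returns graph + detection
randomRestrictedGraph <- function(seed, nMrna = 30, nMirna = 10,
                                  pEdge = 0.08, pTarget = 0.15) {
    set.seed(seed)
    mrna <- sprintf("m%03d", seq_len(nMrna))
    mirna <- sprintf("mir-%03d", seq_len(nMirna))
    ed <- list()
    for (i in seq_len(nMrna - 1)) for (j in seq(i + 1, nMrna))
        if (runif(1) < pEdge)
            ed[[length(ed) + 1L]] <- data.frame(
                node_a = mrna[i], node_b = mrna[j],
                edge_type = "mrna_mrna", directed = FALSE,
                stringsAsFactors = FALSE)
    for (mi in mirna) for (mj in mrna)
        if (runif(1) < pTarget)
            ed[[length(ed) + 1L]] <- data.frame(
                node_a = mi, node_b = mj,
                edge_type = "mirna_target", directed = TRUE,
                stringsAsFactors = FALSE)
    edges <- do.call(rbind, ed)
    if (is.null(edges)) edges <- synaptoNet:::emptyEdgeTable()
    else {
        edges$sources <- "src"
        edges$n_sources <- 1L
    }
    nodes <- c(setNames(rep("mRNA", nMrna), mrna),
               setNames(rep("miRNA", nMirna), mirna))
    used <- unique(c(edges$node_a, edges$node_b))
    g <- synaptoNet:::TypedGraph(nodes[names(nodes) %in% used], edges)
    det <- DetectionSet("rand", list(mRNA = mrna, miRNA = mirna))
    list(graph = g, detected = det, mrna = mrna, mirna = mirna)
}

# independent 2-core oracle via igraph coreness on the neighbor graph
twoCoreOracle <- function(graph) {
    ed <- graphEdges(graph)
    if (!nrow(ed)) return(character())
    ig <- igraph::graph_from_data_frame(
        unique(data.frame(a = pmin(ed$node_a, ed$node_b),
                          b = pmax(ed$node_a, ed$node_b))),
        directed = FALSE,
        vertices = data.frame(name = names(graphNodes(graph))))
    names(which(igraph::coreness(ig) >= 2))
}

# brute-force coverage: scan every edge row explicitly
bruteCoverage <- function(graph, mrna, mirna) {
    ed <- graphEdges(graph)
    targeted <- character(); with_t <- character()
    for (i in seq_len(nrow(ed))) {
        if (ed$edge_type[i] == "mirna_target" &&
            ed$node_a[i] %in% mirna && ed$node_b[i] %in% mrna) {
            targeted <- union(targeted, ed$node_b[i])
            with_t <- union(with_t, ed$node_a[i])
        }
    }
    list(n_mrna_targeted = length(targeted),
         n_mirna_with_target = length(with_t))
}

# brute-force hub counts per regulator
bruteHubs <- function(graph) {
    ed <- graphEdges(graph)
    nodes <- graphNodes(graph)
    regs <- names(nodes)[nodes == "miRNA"]
    sapply(regs, function(r) {
        length(unique(ed$node_b[ed$edge_type == "mirna_target" &
                                ed$node_a == r &
                                nodes[ed$node_b] == "mRNA"]))
    })
}

# exhaustive hypergeometric upper tail by enumerating all C(N, n) draws
enumHyperP <- function(N, K, n, k) {
    if (n == 0) return(if (k <= 0) 1 else 0)
    draws <- utils::combn(N, n)
    hits <- colSums(draws <= K)   # members are elements 1..K
    mean(hits >= k)
}

expect_same_graph <- function(g1, g2) {
    expect_identical(sort(names(graphNodes(g1))), sort(names(graphNodes(g2))))
    e1 <- graphEdges(g1); e2 <- graphEdges(g2)
    key <- function(e) sort(paste(e$node_a, e$node_b, e$edge_type, e$sources))
    expect_identical(key(e1), key(e2))
}
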