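## Network construction: weak-evidence filtering, expression restriction,
## degree pruning, hub ranking and coverage statistics.

# map heterogeneous node-type labels onto the graph's four node classes
canonicalNodeType <- function(x) {
    x <- tolower(trimws(x))
    out <- rep(NA_character_, length(x))
    out[x %in% c("mrna", "protein", "gene", "coding")] <- "mRNA"
    out[x %in% c("mirna", "microrna", "mir")] <- "miRNA"
    out[x %in% c("lncrna", "lincrna", "ncrna")] <- "lncRNA"
    out[x %in% c("tf", "transcription_factor")] <- "TF"
    out
}

#' Remove weak interaction evidence
#'
#' Drops every record classified as weak in its source. Records from
#' sources that do not label confidence ("unlabeled") are always retained
#' — the exclusion applies only where a classification is available. For
#' sources reporting a numeric score (STRING-style 0-1000 scale), a record
#' is weak when its score is below the per-source threshold (default 400;
#' a score exactly at the threshold is strong).
#'
#' @param records an \code{\link{InteractionTable}}.
#' @param scoreThreshold default numeric cutoff below which a scored record
#'   is weak.
#' @param perSourceThreshold optional named numeric vector of per-source
#'   overrides.
#' @return the filtered \code{\link{InteractionTable}}; per-source removal
#'   counts are attached as attribute \code{"removed"}.
#' @export
filterWeak <- function(records, scoreThreshold = 400,
                       perSourceThreshold = numeric()) {
    stopifnot(is(records, "InteractionTable"))
    rec <- interactionRecords(records)
    if (!nrow(rec)) return(records)
    thr <- rep(scoreThreshold, nrow(rec))
    if (length(perSourceThreshold)) {
        hit <- match(rec$source_db, names(perSourceThreshold))
        thr[!is.na(hit)] <- perSourceThreshold[hit[!is.na(hit)]]
    }
    weak <- rec$confidence == "weak" |
        (rec$confidence == "unlabeled" & !is.na(rec$score) & rec$score < thr)
    if (any(weak)) {
        counts <- table(rec$source_db[weak])
        message("weak records removed: ",
                paste(sprintf("%s=%d", names(counts), counts),
                      collapse = ", "))
    }
    out <- InteractionTable(rec[!weak, , drop = FALSE])
    attr(out, "removed") <- if (any(weak)) table(rec$source_db[weak])
                            else table(character())
    out
}

# classify one record into (edge_type, regulator, target, directed);
# returns NULL rows for unclassifiable type combinations
classifyRecords <- function(rec) {
    ta <- canonicalNodeType(rec$a_type)
    tb <- canonicalNodeType(rec$b_type)
    n <- nrow(rec)
    edge_type <- rep(NA_character_, n)
    from <- rec$node_a; to <- rec$node_b
    tfrom <- ta; tto <- tb

    mm <- ta == "mRNA" & tb == "mRNA"
    edge_type[mm] <- "mrna_mrna"
    # canonical order for undirected pairs
    swap <- mm & from > to
    tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp

    mt_ab <- ta == "miRNA" & tb == "mRNA"
    mt_ba <- ta == "mRNA" & tb == "miRNA"
    edge_type[mt_ab | mt_ba] <- "mirna_target"
    tmp <- from[mt_ba]; from[mt_ba] <- to[mt_ba]; to[mt_ba] <- tmp
    tfrom[mt_ab | mt_ba] <- "miRNA"; tto[mt_ab | mt_ba] <- "mRNA"

    tf_ab <- ta == "TF" & tb == "miRNA"
    tf_ba <- ta == "miRNA" & tb == "TF"
    edge_type[tf_ab | tf_ba] <- "tf_mirna"
    tmp <- from[tf_ba]; from[tf_ba] <- to[tf_ba]; to[tf_ba] <- tmp
    tfrom[tf_ab | tf_ba] <- "TF"; tto[tf_ab | tf_ba] <- "miRNA"

    ln <- is.na(edge_type) & (ta == "lncRNA" | tb == "lncRNA") &
        !is.na(ta) & !is.na(tb)
    edge_type[ln] <- "lncrna_assoc"
    # lncRNA listed first for a canonical orientation
    swapl <- ln & tb == "lncRNA"
    tmp <- from[swapl]; from[swapl] <- to[swapl]; to[swapl] <- tmp
    t2 <- tfrom[swapl]; tfrom[swapl] <- tto[swapl]; tto[swapl] <- t2

    data.frame(node_a = from, node_b = to, a_type = tfrom, b_type = tto,
               edge_type = edge_type,
               directed = edge_type %in% c("mirna_target", "tf_mirna"),
               source_db = rec$source_db, stringsAsFactors = FALSE)
}

#' Build the expression-restricted interaction network
#'
#' The two-step construction: first the mRNA backbone is assembled from
#' mRNA-mRNA evidence in which \emph{both} endpoints are detected mRNAs;
#' then microRNA-target edges are overlaid where the microRNA is detected
#' and the target is a detected mRNA present in the backbone's node set.
#' Optional flags admit lncRNA-association and TF->miRNA edges under the
#' same both-endpoints-detected rule (a TF endpoint counts as detected when
#' its symbol is in the detected mRNA set). Duplicate pairs asserted by
#' several sources are merged into a single edge whose \code{sources}
#' field is the union. Records whose node-type combination fits no edge
#' class are dropped with a message. The result is invariant to record
#' order.
#'
#' @param records a weak-filtered \code{\link{InteractionTable}}.
#' @param detected a \code{\link{DetectionSet}} covering the relevant
#'   biotypes.
#' @param includeLncRna,includeTf admit lncRNA / TF edge overlays
#'   (default off).
#' @return a \code{\link{TypedGraph}}.
#' @export
buildNetwork <- function(records, detected, includeLncRna = FALSE,
                         includeTf = FALSE) {
    stopifnot(is(records, "InteractionTable"), is(detected, "DetectionSet"))
    mrna <- detectedSymbols(detected, "mRNA")
    mirna <- detectedSymbols(detected, "miRNA")
    lncrna <- detectedSymbols(detected, "lncRNA")
    if (!length(mrna))
        warning("no detected mRNAs; the network will be empty")

    rec <- interactionRecords(records)
    prov <- list(dataset = datasetName(detected),
                 n_records_in = nrow(rec),
                 include_lncrna = includeLncRna, include_tf = includeTf)
    if (!nrow(rec))
        return(TypedGraph(provenance = prov))

    cls <- classifyRecords(rec)
    bad <- is.na(cls$edge_type)
    if (any(bad))
        message(sum(bad), " record(s) with unclassifiable node types dropped")
    cls <- cls[!bad, , drop = FALSE]

    # step 1: mRNA backbone, both endpoints detected
    mm <- cls[cls$edge_type == "mrna_mrna" &
              cls$node_a %in% mrna & cls$node_b %in% mrna, , drop = FALSE]
    backbone <- unique(c(mm$node_a, mm$node_b))

    # step 2: miRNA-target overlay onto the backbone
    mt <- cls[cls$edge_type == "mirna_target" &
              cls$node_a %in% mirna & cls$node_b %in% backbone, ,
              drop = FALSE]
    keep <- rbind(mm, mt)

    if (includeLncRna) {
        la <- cls[cls$edge_type == "lncrna_assoc" & cls$node_a %in% lncrna, ,
                  drop = FALSE]
        partnerOk <- (la$b_type == "mRNA" & la$node_b %in% backbone) |
            (la$b_type == "miRNA" & la$node_b %in% mirna) |
            (la$b_type == "lncRNA" & la$node_b %in% lncrna)
        keep <- rbind(keep, la[partnerOk, , drop = FALSE])
    }
    if (includeTf) {
        tf <- cls[cls$edge_type == "tf_mirna" & cls$node_a %in% mrna &
                  cls$node_b %in% mirna, , drop = FALSE]
        keep <- rbind(keep, tf)
    }
    if (!nrow(keep)) return(TypedGraph(provenance = prov))

    # merge duplicate pairs across sources
    key <- paste(keep$node_a, keep$node_b, keep$edge_type, sep = "\r")
    first <- !duplicated(key)
    srcs <- vapply(split(keep$source_db, key), function(s)
        paste(sort(unique(s)), collapse = ";"), character(1))
    ed <- keep[first, , drop = FALSE]
    ed <- ed[order(ed$edge_type, ed$node_a, ed$node_b), , drop = FALSE]
    okey <- paste(ed$node_a, ed$node_b, ed$edge_type, sep = "\r")
    edges <- data.frame(node_a = ed$node_a, node_b = ed$node_b,
                        edge_type = ed$edge_type, directed = ed$directed,
                        sources = unname(srcs[okey]),
                        n_sources = lengths(strsplit(unname(srcs[okey]),
                                                     ";", fixed = TRUE)),
                        stringsAsFactors = FALSE)
    nodes <- c(setNames(ed$a_type, ed$node_a), setNames(ed$b_type, ed$node_b))
    nodes <- nodes[!duplicated(names(nodes))]
    nodes <- nodes[order(names(nodes))]
    TypedGraph(nodes = nodes, edges = edges, provenance = prov)
}

#' Remove weakly connected nodes from the network
#'
#' \code{"one_shot"} (default) removes, in a single pass, every node whose
#' degree on the input graph is at most one, then drops any node left
#' isolated; \code{"iterative"} repeats the removal to a fixed point, which
#' equals the graph's 2-core (every surviving node has degree >= 2 in the
#' output). Degree counts distinct neighbors, ignoring edge direction and
#' type. The pruning mode is recorded in the graph's provenance.
#'
#' @param graph a \code{\link{TypedGraph}}.
#' @param mode \code{"one_shot"} or \code{"iterative"}.
#' @return the pruned \code{\link{TypedGraph}}.
#' @export
pruneLowDegree <- function(graph, mode = c("one_shot", "iterative")) {
    stopifnot(is(graph, "TypedGraph"))
    mode <- match.arg(mode)
    nodes <- graphNodes(graph)
    edges <- graphEdges(graph)
    prov <- graph@provenance
    prov$prune_mode <- mode
    prov$n_nodes_pre_prune <- length(nodes)

    peel <- function(nodes, edges) {
        g <- TypedGraph(nodes, edges)
        deg <- nodeDegrees(g)
        keep <- names(deg)[deg >= 2L]
        edges <- edges[edges$node_a %in% keep & edges$node_b %in% keep, ,
                       drop = FALSE]
        connected <- unique(c(edges$node_a, edges$node_b))
        list(nodes = nodes[names(nodes) %in% connected], edges = edges)
    }

    if (mode == "one_shot") {
        st <- peel(nodes, edges)
    } else {
        st <- list(nodes = nodes, edges = edges)
        repeat {
            nxt <- peel(st$nodes, st$edges)
            if (length(nxt$nodes) == length(st$nodes)) { st <- nxt; break }
            st <- nxt
        }
    }
    TypedGraph(nodes = st$nodes, edges = st$edges, provenance = prov)
}

#' Rank regulators by their distinct mRNA targets
#'
#' For every node of the requested regulator class, counts the distinct
#' mRNA nodes it reaches through its target edges (\code{mirna_target} for
#' microRNAs, \code{lncrna_assoc} edges to mRNA partners for lncRNAs) and
#' returns the ranking, sorted by descending target count with an
#' alphabetical tie-break.
#'
#' @param graph a (typically pruned) \code{\link{TypedGraph}}.
#' @param regulatorType \code{"miRNA"} or \code{"lncRNA"}.
#' @param topK optionally truncate the ranking for display.
#' @return data.frame with columns \code{regulator}, \code{n_targets}.
#' @export
rankHubs <- function(graph, regulatorType = c("miRNA", "lncRNA"),
                     topK = NULL) {
    stopifnot(is(graph, "TypedGraph"))
    regulatorType <- match.arg(regulatorType)
    nodes <- graphNodes(graph)
    regs <- names(nodes)[nodes == regulatorType]
    if (!length(regs))
        return(data.frame(regulator = character(),
                          n_targets = integer(), stringsAsFactors = FALSE))
    ed <- graphEdges(graph)
    etype <- if (regulatorType == "miRNA") "mirna_target" else "lncrna_assoc"
    ed <- ed[ed$edge_type == etype & ed$node_a %in% regs &
             nodes[ed$node_b] == "mRNA", , drop = FALSE]
    cnt <- table(factor(ed$node_a, levels = regs))
    out <- data.frame(regulator = regs, n_targets = as.integer(cnt),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$n_targets, out$regulator), , drop = FALSE]
    rownames(out) <- NULL
    if (!is.null(topK)) out <- head(out, topK)
    out
}

#' Targeting coverage of the detected transcriptome
#'
#' How much of the detected mRNAome receives at least one microRNA-target
#' edge from a detected microRNA, and what fraction of the detected
#' microRNAs have at least one such target. Percentages are stored exactly
#' to one decimal and, for display, rounded half-up to integers; zero
#' denominators give \code{NA} markers. By default this runs on the
#' unpruned expression-restricted network, since the quantity concerns
#' targeting of the detected mRNAome rather than the display network.
#'
#' @param graph a \code{\link{TypedGraph}} (unpruned by convention; pass a
#'   pruned graph to compute coverage on the display network instead).
#' @param detected the \code{\link{DetectionSet}} providing denominators.
#' @return a list of class \code{"coverageReport"}.
#' @export
coverageStats <- function(graph, detected) {
    stopifnot(is(graph, "TypedGraph"), is(detected, "DetectionSet"))
    mrna <- detectedSymbols(detected, "mRNA")
    mirna <- detectedSymbols(detected, "miRNA")
    ed <- graphEdges(graph)
    ed <- ed[ed$edge_type == "mirna_target" & ed$node_a %in% mirna &
             ed$node_b %in% mrna, , drop = FALSE]
    targeted <- unique(ed$node_b)
    withTarget <- unique(ed$node_a)
    structure(list(
        n_mrna_detected = length(mrna),
        n_mrna_targeted = length(targeted),
        pct_mrna_targeted = percentage(length(targeted), length(mrna),
                                       "one_decimal"),
        pct_mrna_targeted_int = percentage(length(targeted), length(mrna),
                                           "integer_half_up"),
        n_mirna_detected = length(mirna),
        n_mirna_with_target = length(withTarget),
        pct_mirna_with_target = percentage(length(withTarget), length(mirna),
                                           "one_decimal"),
        pct_mirna_with_target_int = percentage(length(withTarget),
                                               length(mirna),
                                               "integer_half_up"),
        targeted_mrnas = sort(targeted),
        mirnas_with_target = sort(withTarget)),
        class = "coverageReport")
}

#' @export
print.coverageReport <- function(x, ...) {
    cat(sprintf("coverage: %d/%d mRNAs targeted (%s%%) by %d/%d microRNAs (%s%%)\n",
                x$n_mrna_targeted, x$n_mrna_detected,
                format(x$pct_mrna_targeted),
                x$n_mirna_with_target, x$n_mirna_detected,
                format(x$pct_mirna_with_target)))
    invisible(x)
}
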