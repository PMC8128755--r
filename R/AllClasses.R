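#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#' @importFrom S4Vectors metadata metadata<- SimpleList
NULL

## ---------------------------------------------------------------------------
## Assay matrices
## ---------------------------------------------------------------------------

#' @rdname RnaCounts
#' @export
setClass("RnaCounts", contains = "SummarizedExperiment",
         representation(assayType = "character"))

setValidity("RnaCounts", function(object) {
    msg <- character()
    if (length(object@assayType) != 1L ||
        !object@assayType %in% ASSAY_TYPES)
        msg <- c(msg, sprintf("assayType must be one of %s",
                              paste(ASSAY_TYPES, collapse = ", ")))
    if (!"counts" %in% names(assays(object)))
        msg <- c(msg, "assay 'counts' is required")
    if (nrow(object) < 1L || ncol(object) < 1L)
        msg <- c(msg, "at least one feature and one sample required")
    rn <- rownames(object); cn <- colnames(object)
    if (is.null(rn) || anyDuplicated(rn))
        msg <- c(msg, "feature ids must be present and unique")
    if (is.null(cn) || anyDuplicated(cn))
        msg <- c(msg, "sample ids must be present and unique")
    if ("counts" %in% names(assays(object))) {
        m <- assay(object, "counts")
        bad <- which(!is.finite(m) | m < 0 | m != floor(m))
        if (length(bad)) {
            i <- arrayInd(bad[1L], dim(m))
            msg <- c(msg, sprintf(
                "counts must be non-negative integers; offending cell (%s, %s) = %s",
                rn[i[1L]], cn[i[2L]], format(m[bad[1L]])))
        }
    }
    if (length(msg)) msg else TRUE
})

#' Read-count and TPM matrices
#'
#' \code{RnaCounts} holds validated raw read counts (features x samples) for
#' one assay (\code{"total_rna"} or \code{"small_rna"}); \code{RnaTpm} holds
#' the library-size-scaled values. Both extend
#' \linkS4class{SummarizedExperiment}. Note that "TPM" here is pure
#' library-size scaling (count / column sum x 1e6) with \emph{no}
#' transcript-length term; every non-empty column of an \code{RnaTpm} sums
#' to one million.
#'
#' @param counts,values numeric matrix with rownames (feature ids) and
#'   colnames (sample ids).
#' @param assayType \code{"total_rna"} or \code{"small_rna"}.
#' @return a validated \code{RnaCounts} / \code{RnaTpm} object.
#' @examples
#' m <- matrix(c(10L, 90L, 0L, 5L), 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' rc <- RnaCounts(m, "total_rna")
#' assayType(rc)
#' @aliases RnaTpm RnaCounts-class RnaTpm-class
#' @export
RnaCounts <- function(counts, assayType = c("total_rna", "small_rna")) {
    assayType <- match.arg(assayType)
    counts <- as.matrix(counts)
    storage.mode(counts) <- "double"
    se <- SummarizedExperiment(assays = SimpleList(counts = counts))
    new("RnaCounts", se, assayType = assayType)
}

#' @export
setClass("RnaTpm", contains = "SummarizedExperiment",
         representation(assayType = "character"))

setValidity("RnaTpm", function(object) {
    msg <- character()
    if (length(object@assayType) != 1L ||
        !object@assayType %in% ASSAY_TYPES)
        msg <- c(msg, "invalid assayType")
    if (!"tpm" %in% names(assays(object)))
        msg <- c(msg, "assay 'tpm' is required")
    else {
        m <- assay(object, "tpm")
        if (any(m < 0)) msg <- c(msg, "TPM values must be non-negative")
        cs <- colSums(m)
        bad <- cs > 0 & abs(cs - 1e6) > 1e-9 * 1e6
        if (any(bad))
            msg <- c(msg, sprintf(
                "column '%s' does not sum to 1e6 (got %.6f)",
                colnames(m)[which(bad)[1L]], cs[which(bad)[1L]]))
    }
    if (length(msg)) msg else TRUE
})

#' @rdname RnaCounts
#' @export
RnaTpm <- function(values, assayType = c("total_rna", "small_rna")) {
    assayType <- match.arg(assayType)
    se <- SummarizedExperiment(assays = SimpleList(tpm = as.matrix(values)))
    new("RnaTpm", se, assayType = assayType)
}

#' @rdname RnaCounts
#' @param object an \code{RnaCounts} or \code{RnaTpm} object.
#' @export
setGeneric("assayType", function(object) standardGeneric("assayType"))

#' @rdname RnaCounts
#' @export
setMethod("assayType", "RnaCounts", function(object) object@assayType)

#' @rdname RnaCounts
#' @export
setMethod("assayType", "RnaTpm", function(object) object@assayType)

setMethod("show", "RnaCounts", function(object) {
    cat(sprintf("RnaCounts (%s): %d features x %d samples\n",
                object@assayType, nrow(object), ncol(object)))
    cat("  library sizes:",
        paste(format(colSums(assay(object, "counts"))), collapse = ", "),
        "\n")
})

setMethod("show", "RnaTpm", function(object) {
    cat(sprintf("RnaTpm (%s): %d features x %d samples\n",
                object@assayType, nrow(object), ncol(object)))
})

## ---------------------------------------------------------------------------
## Feature annotation
## ---------------------------------------------------------------------------

#' Feature annotation table
#'
#' Maps feature ids to symbols, biotypes (\code{mRNA}, \code{lncRNA},
#' \code{miRNA}, \code{snoRNA}, \code{other}), a predicted-gene flag, and a
#' snoRNA class (\code{CD_box}, \code{HACA_box}, \code{unclassified};
#' \code{not_applicable} for every non-snoRNA row). This is where the
#' annotation roles usually played by miRBase (microRNAs) and snOPY
#' (snoRNAs) live.
#'
#' @param df data.frame with columns \code{feature_id}, \code{symbol},
#'   \code{biotype}, \code{predicted}, \code{snorna_class}.
#' @return a validated \code{FeatureAnnotation}.
#' @aliases FeatureAnnotation-class annotationTable
#' @export
setClass("FeatureAnnotation", representation(table = "data.frame"))

setValidity("FeatureAnnotation", function(object) {
    tab <- object@table
    need <- c("feature_id", "symbol", "biotype", "predicted", "snorna_class")
    if (!all(need %in% names(tab)))
        return(sprintf("missing columns: %s",
                       paste(setdiff(need, names(tab)), collapse = ", ")))
    msg <- character()
    if (anyDuplicated(tab$feature_id)) {
        d <- tab$feature_id[duplicated(tab$feature_id)][1L]
        msg <- c(msg, sprintf("duplicated feature_id '%s'", d))
    }
    if (!all(tab$biotype %in% BIOTYPES))
        msg <- c(msg, "unknown biotype value")
    if (!all(tab$snorna_class %in% SNORNA_CLASSES))
        msg <- c(msg, "unknown snorna_class value")
    sno <- tab$biotype == "snoRNA"
    if (any(tab$snorna_class[sno] == "not_applicable"))
        msg <- c(msg, "snoRNA rows must carry a snorna_class (use 'unclassified')")
    if (any(tab$snorna_class[!sno] != "not_applicable"))
        msg <- c(msg, "non-snoRNA rows must have snorna_class 'not_applicable'")
    if (!is.logical(tab$predicted))
        msg <- c(msg, "'predicted' must be logical")
    if (length(msg)) msg else TRUE
})

#' @rdname FeatureAnnotation-class
#' @export
FeatureAnnotation <- function(df) {
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    df$norm_symbol <- normalizeSymbols(df$symbol)
    rownames(df) <- NULL
    new("FeatureAnnotation", table = df)
}

#' @rdname FeatureAnnotation-class
#' @param object a \code{FeatureAnnotation}.
#' @export
annotationTable <- function(object) object@table

setMethod("show", "FeatureAnnotation", function(object) {
    cat(sprintf("FeatureAnnotation: %d features\n", nrow(object@table)))
    print(table(object@table$biotype))
})

## ---------------------------------------------------------------------------
## Interaction evidence
## ---------------------------------------------------------------------------

#' Interaction evidence records
#'
#' One row per asserted pairwise interaction from one source database, in
#' the canonical schema: \code{source_db}, \code{node_a}, \code{a_type},
#' \code{node_b}, \code{b_type}, \code{directed}, \code{confidence}
#' (\code{weak} / \code{strong} / \code{unlabeled}) and an optional numeric
#' \code{score} on the source's own scale. Symbols are stored normalized;
#' self-pairs are rejected at construction.
#'
#' @param df data.frame in the canonical schema (\code{score} optional).
#' @return a validated \code{InteractionTable}.
#' @aliases InteractionTable-class interactionRecords
#' @export
setClass("InteractionTable", representation(records = "data.frame"))

setValidity("InteractionTable", function(object) {
    rec <- object@records
    need <- c("source_db", "node_a", "a_type", "node_b", "b_type",
              "directed", "confidence", "score")
    if (!all(need %in% names(rec)))
        return(sprintf("missing columns: %s",
                       paste(setdiff(need, names(rec)), collapse = ", ")))
    msg <- character()
    if (nrow(rec)) {
        if (any(!nzchar(rec$source_db)))
            msg <- c(msg, "source_db must be non-empty")
        if (any(rec$node_a == rec$node_b))
            msg <- c(msg, sprintf("self-pair '%s' is not allowed",
                                  rec$node_a[rec$node_a == rec$node_b][1L]))
        if (!all(rec$confidence %in% c("weak", "strong", "unlabeled")))
            msg <- c(msg, "confidence must be weak/strong/unlabeled")
    }
    if (length(msg)) msg else TRUE
})

emptyInteractionRecords <- function() {
    data.frame(source_db = character(), node_a = character(),
               a_type = character(), node_b = character(),
               b_type = character(), directed = logical(),
               confidence = character(), score = numeric(),
               stringsAsFactors = FALSE)
}

#' @rdname InteractionTable-class
#' @export
InteractionTable <- function(df = emptyInteractionRecords()) {
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    if (is.null(df$score)) df$score <- NA_real_
    rownames(df) <- NULL
    new("InteractionTable", records = df)
}

#' @rdname InteractionTable-class
#' @param object an \code{InteractionTable}.
#' @export
interactionRecords <- function(object) object@records

setMethod("show", "InteractionTable", function(object) {
    rec <- object@records
    cat(sprintf("InteractionTable: %d records from %d source(s)\n",
                nrow(rec), length(unique(rec$source_db))))
    if (nrow(rec)) print(table(rec$source_db, rec$confidence))
})

#' @rdname InteractionTable-class
#' @export
setMethod("length", "InteractionTable", function(x) nrow(x@records))

## ---------------------------------------------------------------------------
## Symbol sets and gene-set collections
## ---------------------------------------------------------------------------

#' Named set of normalized symbols
#'
#' Holds a curated symbol list (e.g. disease-deregulated microRNAs, or an
#' astrocyte-exosome microRNA panel) with normalization applied and the
#' first-seen display form of each symbol retained.
#'
#' @param name label for the set.
#' @param symbols character vector of raw symbols (deduplicated after
#'   normalization).
#' @param stripSpeciesPrefix passed to \code{\link{normalizeSymbols}}.
#' @return a \code{SymbolSet}.
#' @aliases SymbolSet-class symbols displayForms
#' @examples
#' s <- SymbolSet("hubs", c("mmu-miR-22-3p", "miR-124-5p", "MIR-124-5P"))
#' length(s)  # 2
#' @export
setClass("SymbolSet", representation(name = "character",
                                     symbols = "character",
                                     display = "character"))

setValidity("SymbolSet", function(object) {
    msg <- character()
    if (length(object@name) != 1L) msg <- c(msg, "name must be length 1")
    if (anyDuplicated(object@symbols))
        msg <- c(msg, "symbols must be unique after normalization")
    if (!all(object@symbols %in% names(object@display)))
        msg <- c(msg, "every symbol needs a display form")
    if (length(msg)) msg else TRUE
})

#' @rdname SymbolSet-class
#' @export
SymbolSet <- function(name, symbols, stripSpeciesPrefix = TRUE) {
    raw <- trimws(as.character(symbols))
    raw <- raw[nzchar(raw)]
    norm <- normalizeSymbols(raw, stripSpeciesPrefix)
    disp <- displayMap(raw, norm)
    new("SymbolSet", name = as.character(name),
        symbols = unique(norm), display = disp)
}

#' @rdname SymbolSet-class
#' @param object a \code{SymbolSet}.
#' @export
setGeneric("symbols", function(object) standardGeneric("symbols"))

#' @rdname SymbolSet-class
#' @export
setMethod("symbols", "SymbolSet", function(object) object@symbols)

#' @rdname SymbolSet-class
#' @export
displayForms <- function(object) object@display

#' @rdname SymbolSet-class
#' @export
setMethod("length", "SymbolSet", function(x) length(x@symbols))

setMethod("show", "SymbolSet", function(object) {
    cat(sprintf("SymbolSet '%s': %d symbols\n", object@name,
                length(object@symbols)))
    cat(" ", paste(head(object@display, 6), collapse = ", "),
        if (length(object@symbols) > 6) "...", "\n")
})

#' Collection of named gene sets
#'
#' A GMT-style collection: unique set names mapping to non-empty sets of
#' normalized symbols (stand-in for GO/KEGG term membership).
#'
#' @param name collection label.
#' @param sets named list of character vectors.
#' @return a validated \code{GeneSets}.
#' @aliases GeneSets-class geneSets
#' @export
setClass("GeneSets", representation(name = "character", sets = "list"))

setValidity("GeneSets", function(object) {
    msg <- character()
    if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
        msg <- c(msg, "set names must be present and unique")
    if (any(!lengths(object@sets)))
        msg <- c(msg, "every set must be non-empty")
    if (length(msg)) msg else TRUE
})

#' @rdname GeneSets-class
#' @export
GeneSets <- function(name, sets) {
    sets <- lapply(sets, function(s) unique(normalizeSymbols(s)))
    new("GeneSets", name = as.character(name), sets = sets)
}

#' @rdname GeneSets-class
#' @param object a \code{GeneSets} collection.
#' @export
geneSets <- function(object) object@sets

#' @rdname GeneSets-class
#' @export
setMethod("length", "GeneSets", function(x) length(x@sets))

setMethod("show", "GeneSets", function(object) {
    cat(sprintf("GeneSets '%s': %d sets (sizes %s)\n", object@name,
                length(object@sets),
                paste(range(lengths(object@sets)), collapse = "-")))
})

## ---------------------------------------------------------------------------
## Detection sets
## ---------------------------------------------------------------------------

#' Per-biotype detection sets for one dataset
#'
#' The result of applying abundance thresholds to a TPM matrix: for each
#' biotype, the set of (normalized) symbols detected in one dataset
#' (e.g. "synaptosome" or "chamber"). Sets are pairwise disjoint across
#' biotypes. \code{removed} carries symbols dropped by
#' \code{\link{excludePredicted}} as a side report.
#'
#' @aliases DetectionSet-class detectedSymbols datasetName
#' @export
setClass("DetectionSet", representation(dataset = "character",
                                        sets = "list",
                                        display = "character",
                                        thresholds = "list",
                                        nSamples = "integer",
                                        removed = "list"))

setValidity("DetectionSet", function(object) {
    msg <- character()
    if (!all(names(object@sets) %in% DETECTABLE_BIOTYPES))
        msg <- c(msg, "sets must be keyed by detectable biotypes")
    all_syms <- unlist(object@sets, use.names = FALSE)
    if (anyDuplicated(all_syms))
        msg <- c(msg, sprintf("symbol '%s' appears in more than one biotype",
                              all_syms[duplicated(all_syms)][1L]))
    if (length(msg)) msg else TRUE
})

#' @rdname DetectionSet-class
#' @param dataset dataset label.
#' @param sets named list of per-biotype symbol vectors.
#' @param display named character vector of display forms.
#' @param thresholds,nSamples,removed provenance fields.
#' @export
DetectionSet <- function(dataset, sets, display = character(),
                         thresholds = list(), nSamples = NA_integer_,
                         removed = list()) {
    sets <- lapply(sets, function(s) sort(unique(as.character(s))))
    new("DetectionSet", dataset = as.character(dataset), sets = sets,
        display = display, thresholds = thresholds,
        nSamples = as.integer(nSamples), removed = removed)
}

#' @rdname DetectionSet-class
#' @param object a \code{DetectionSet}.
#' @param biotype one of \code{"mRNA"}, \code{"lncRNA"}, \code{"miRNA"},
#'   \code{"snoRNA"}, or \code{NULL} for the full list.
#' @export
detectedSymbols <- function(object, biotype = NULL) {
    if (is.null(biotype)) return(object@sets)
    biotype <- match.arg(biotype, DETECTABLE_BIOTYPES)
    if (is.null(object@sets[[biotype]])) character() else object@sets[[biotype]]
}

#' @rdname DetectionSet-class
#' @export
datasetName <- function(object) object@dataset

setMethod("show", "DetectionSet", function(object) {
    cat(sprintf("DetectionSet '%s' (%s samples)\n", object@dataset,
                ifelse(is.na(object@nSamples), "?", object@nSamples)))
    for (b in names(object@sets))
        cat(sprintf("  %-7s %d detected\n", b, length(object@sets[[b]])))
})

## ---------------------------------------------------------------------------
## Typed interaction graph
## ---------------------------------------------------------------------------

#' Expression-restricted typed interaction graph
#'
#' Nodes are symbols typed as \code{mRNA}, \code{miRNA}, \code{lncRNA} or
#' \code{TF}; edges are deduplicated evidence edges
#' (\code{mrna_mrna} undirected, \code{mirna_target} and \code{tf_mirna}
#' directed, \code{lncrna_assoc}) each carrying the set of source databases
#' asserting the pair. \code{provenance} records thresholds and pruning
#' mode. Degree counts distinct neighbors, ignoring edge direction and type.
#'
#' @aliases TypedGraph-class graphNodes graphEdges nodeDegrees
#' @export
setClass("TypedGraph", representation(nodes = "character",
                                      edges = "data.frame",
                                      provenance = "list"))

emptyEdgeTable <- function() {
    data.frame(node_a = character(), node_b = character(),
               edge_type = character(), directed = logical(),
               sources = character(), n_sources = integer(),
               stringsAsFactors = FALSE)
}

setValidity("TypedGraph", function(object) {
    ed <- object@edges
    msg <- character()
    need <- c("node_a", "node_b", "edge_type", "directed", "sources",
              "n_sources")
    if (!all(need %in% names(ed)))
        return("edge table is missing canonical columns")
    if (nrow(ed)) {
        if (!all(c(ed$node_a, ed$node_b) %in% names(object@nodes)))
            msg <- c(msg, "every edge endpoint must exist in nodes")
        if (any(ed$node_a == ed$node_b))
            msg <- c(msg, "self-loops are not allowed")
        key <- paste(ed$node_a, ed$node_b, ed$edge_type)
        if (anyDuplicated(key))
            msg <- c(msg, "duplicate (node_a, node_b, edge_type) edge")
        if (!all(ed$edge_type %in% EDGE_TYPES))
            msg <- c(msg, "unknown edge_type")
        if (any(!ed$n_sources))
            msg <- c(msg, "edges must carry at least one source")
    }
    if (length(msg)) msg else TRUE
})

TypedGraph <- function(nodes = character(), edges = emptyEdgeTable(),
                       provenance = list()) {
    rownames(edges) <- NULL
    new("TypedGraph", nodes = nodes, edges = edges, provenance = provenance)
}

#' @rdname TypedGraph-class
#' @param object a \code{TypedGraph}.
#' @export
graphNodes <- function(object) object@nodes

#' @rdname TypedGraph-class
#' @export
graphEdges <- function(object) object@edges

#' @rdname TypedGraph-class
#' @export
nodeDegrees <- function(object) {
    deg <- setNames(integer(length(object@nodes)), names(object@nodes))
    ed <- object@edges
    if (nrow(ed)) {
        pair <- unique(data.frame(
            a = pmin(ed$node_a, ed$node_b),
            b = pmax(ed$node_a, ed$node_b)))
        t1 <- table(factor(pair$a, levels = names(deg)))
        t2 <- table(factor(pair$b, levels = names(deg)))
        deg <- as.integer(t1 + t2)
        names(deg) <- names(object@nodes)
    }
    deg
}

setMethod("show", "TypedGraph", function(object) {
    cat(sprintf("TypedGraph: %d nodes, %d edges\n",
                length(object@nodes), nrow(object@edges)))
    if (length(object@nodes)) print(table(object@nodes))
    if (!is.null(object@provenance$prune_mode))
        cat("  pruning:", object@provenance$prune_mode, "\n")
})
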