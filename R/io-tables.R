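## Readers/writers for the tabular formats the pipeline touches. All files
## are TSV, UTF-8, header required; a single bit-exact dialect beats
## guessing. Every reader validates against the domain type's invariants
## and names the offending record in its error.

readTsv <- function(path) {
    if (!file.exists(path)) usageError("file not found: ", path)
    read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
               check.names = FALSE, quote = "", comment.char = "")
}

#' Read and write count matrices
#'
#' The count TSV has a header row of sample ids, the first column holding
#' feature ids, and non-negative integer cells. \code{writeCountMatrix} and
#' \code{readCountMatrix} round-trip exactly.
#'
#' @param path TSV file path.
#' @param assay \code{"total_rna"} or \code{"small_rna"}.
#' @return \code{readCountMatrix}: a validated \code{\link{RnaCounts}}.
#' @export
readCountMatrix <- function(path, assay = c("total_rna", "small_rna")) {
    assay <- match.arg(assay)
    tab <- readTsv(path)
    if (ncol(tab) < 2L)
        usageError("count matrix needs a feature-id column plus >= 1 sample")
    fid <- as.character(tab[[1L]])
    if (anyDuplicated(fid))
        usageError("duplicate feature id '", fid[duplicated(fid)][1L],
                   "' in ", path)
    m <- as.matrix(tab[, -1L, drop = FALSE])
    suppressWarnings(storage.mode(m) <- "double")
    bad <- which(!is.finite(m) | m < 0 | m != floor(m))
    if (length(bad)) {
        i <- arrayInd(bad[1L], dim(m))
        usageError(sprintf(
            "invalid count at feature '%s', sample '%s' in %s",
            fid[i[1L]], colnames(m)[i[2L]], path))
    }
    rownames(m) <- fid
    RnaCounts(m, assay)
}

#' @rdname readCountMatrix
#' @param x an \code{RnaCounts} object.
#' @export
writeCountMatrix <- function(x, path) {
    stopifnot(is(x, "RnaCounts"))
    m <- assay(x, "counts")
    df <- data.frame(feature_id = rownames(m),
                     format(m, scientific = FALSE, trim = TRUE),
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a feature annotation table
#'
#' Expects columns \code{feature_id}, \code{symbol}, \code{biotype},
#' \code{predicted}, \code{snorna_class}. Unknown biotype strings map to
#' \code{"other"} with a warning; a snoRNA row lacking a class defaults to
#' \code{"unclassified"}; non-snoRNA rows get \code{"not_applicable"}
#' regardless of input (the column is meaningless for them).
#'
#' @param path TSV file path.
#' @return a validated \code{\link{FeatureAnnotation}}.
#' @export
readAnnotation <- function(path) {
    tab <- readTsv(path)
    need <- c("feature_id", "symbol", "biotype", "predicted", "snorna_class")
    miss <- setdiff(need, names(tab))
    if (length(miss))
        usageError("annotation ", path, " is missing column(s): ",
                   paste(miss, collapse = ", "))
    if (anyDuplicated(tab$feature_id))
        usageError("duplicated feature_id '",
                   tab$feature_id[duplicated(tab$feature_id)][1L],
                   "' in ", path)
    unknown <- !tab$biotype %in% BIOTYPES
    if (any(unknown)) {
        warning(sprintf("%d feature(s) with unknown biotype mapped to 'other'",
                        sum(unknown)))
        tab$biotype[unknown] <- "other"
    }
    sno <- tab$biotype == "snoRNA"
    cls <- as.character(tab$snorna_class)
    cls[sno & !(cls %in% c("CD_box", "HACA_box"))] <- "unclassified"
    cls[!sno] <- "not_applicable"
    tab$snorna_class <- cls
    tab$predicted <- as.logical(tab$predicted)
    FeatureAnnotation(tab[need])
}

#' @rdname readAnnotation
#' @param x a \code{FeatureAnnotation}.
#' @export
writeAnnotation <- function(x, path) {
    stopifnot(is(x, "FeatureAnnotation"))
    tab <- annotationTable(x)
    cols <- c("feature_id", "symbol", "biotype", "predicted", "snorna_class")
    write.table(tab[cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read interaction evidence tables
#'
#' Each file is one source database in the canonical schema
#' (\code{source_db}, \code{node_a}, \code{a_type}, \code{node_b},
#' \code{b_type}, \code{directed}, \code{confidence}; optional numeric
#' \code{score}). Symbols are normalized on load and self-pairs (after
#' normalization) are dropped with a message. Duplicate pairs across files
#' are retained here; deduplication happens at network build, where source
#' evidence is merged.
#'
#' @param paths character vector of TSV paths (may be empty).
#' @return an \code{\link{InteractionTable}} concatenating all files.
#' @export
readInteractions <- function(paths) {
    if (!length(paths)) return(InteractionTable())
    need <- c("source_db", "node_a", "a_type", "node_b", "b_type",
              "directed", "confidence")
    parts <- lapply(paths, function(p) {
        tab <- readTsv(p)
        miss <- setdiff(need, names(tab))
        if (length(miss))
            usageError("interaction file ", p, " is missing column(s): ",
                       paste(miss, collapse = ", "))
        if (is.null(tab$score)) tab$score <- NA_real_
        tab$score <- suppressWarnings(as.numeric(tab$score))
        tab[c(need, "score")]
    })
    rec <- do.call(rbind, parts)
    rec$node_a <- normalizeSymbols(rec$node_a)
    rec$node_b <- normalizeSymbols(rec$node_b)
    rec$directed <- as.logical(rec$directed)
    conf <- tolower(trimws(as.character(rec$confidence)))
    conf[!conf %in% c("weak", "strong")] <- "unlabeled"
    rec$confidence <- conf
    self <- rec$node_a == rec$node_b
    if (any(self))
        message(sum(self), " self-pair record(s) dropped at load")
    InteractionTable(rec[!self, , drop = FALSE])
}

#' @rdname readInteractions
#' @param x an \code{InteractionTable}.
#' @param path output TSV path.
#' @export
writeInteractions <- function(x, path) {
    stopifnot(is(x, "InteractionTable"))
    write.table(interactionRecords(x), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' Read gene-set collections (GMT) and plain symbol lists
#'
#' GMT is the standard tab-separated format: set name, description, then
#' member symbols. Symbol lists are one symbol per line with \code{'#'}
#' comments. Normalization is applied to all members; a set left empty
#' after normalization is a format error.
#'
#' @param path file path.
#' @param name label for the resulting collection/set.
#' @return \code{readGmt}: a \code{\link{GeneSets}} collection;
#'   \code{readSymbolList}: a \code{\link{SymbolSet}}.
#' @export
readGmt <- function(path, name = basename(path)) {
    if (!file.exists(path)) usageError("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) usageError("empty GMT file: ", path)
    sets <- list()
    for (ln in lines) {
        fields <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
        if (length(fields) < 3L)
            usageError("GMT line with fewer than 3 fields in ", path,
                       ": '", substr(ln, 1, 40), "'")
        members <- unique(normalizeSymbols(fields[-(1:2)]))
        members <- members[nzchar(members)]
        if (!length(members))
            usageError("gene set '", fields[1L], "' is empty after ",
                       "normalization in ", path)
        if (fields[1L] %in% names(sets))
            usageError("duplicated set name '", fields[1L], "' in ", path)
        sets[[fields[1L]]] <- members
    }
    new("GeneSets", name = name, sets = sets)
}

#' @rdname readGmt
#' @param x a \code{GeneSets} collection.
#' @export
writeGmt <- function(x, path) {
    stopifnot(is(x, "GeneSets"))
    lines <- vapply(names(geneSets(x)), function(nm) {
        paste(c(nm, "na", geneSets(x)[[nm]]), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' @rdname readGmt
#' @export
readSymbolList <- function(path, name = basename(path)) {
    if (!file.exists(path)) usageError("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    if (!length(lines))
        usageError("symbol list ", path, " is empty after normalization")
    SymbolSet(name, lines)
}

#' @rdname readGmt
#' @export
writeSymbolList <- function(x, path) {
    stopifnot(is(x, "SymbolSet"))
    writeLines(unname(displayForms(x)[symbols(x)]), path)
    invisible(path)
}
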