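#' @importFrom methods new validObject is slot setValidity show
#' @importFrom stats phyper p.adjust rnbinom runif
#' @importFrom utils read.delim write.table head
NULL

BIOTYPES <- c("mRNA", "lncRNA", "miRNA", "snoRNA", "other")
DETECTABLE_BIOTYPES <- c("mRNA", "lncRNA", "miRNA", "snoRNA")
SNORNA_CLASSES <- c("CD_box", "HACA_box", "unclassified", "not_applicable")
ASSAY_TYPES <- c("total_rna", "small_rna")
EDGE_TYPES <- c("mrna_mrna", "mirna_target", "lncrna_assoc", "tf_mirna")

#' Normalize gene and microRNA symbols for matching
#'
#' Trims whitespace, optionally strips a three-letter species prefix from
#' mature microRNA names (e.g. \code{"mmu-miR-22-3p"} to \code{"miR-22-3p"}),
#' and case-folds. The sources feeding an interaction network use
#' inconsistent capitalization ("Actb" vs "ACTB", "miR-124" vs "Mir124"),
#' so matching always runs on the normalized form while display forms are
#' kept alongside (first-seen wins).
#'
#' @param x character vector of raw symbols.
#' @param stripSpeciesPrefix strip a leading \code{"xxx-"} species code from
#'   microRNA-style names (default \code{TRUE}).
#' @return character vector of normalized (lower-case) symbols.
#' @examples
#' normalizeSymbols(c(" Actb", "mmu-miR-22-3p", "MIR-22-3P"))
#' @export
normalizeSymbols <- function(x, stripSpeciesPrefix = TRUE) {
    x <- trimws(as.character(x))
    if (stripSpeciesPrefix) {
        x <- sub("^[A-Za-z]{3}-(?=(let|mir)-)", "", x,
                 perl = TRUE, ignore.case = TRUE)
    }
    tolower(x)
}

# first-seen display form per normalized key
displayMap <- function(raw, normalized) {
    keep <- !duplicated(normalized)
    m <- raw[keep]
    names(m) <- normalized[keep]
    m
}

#' Percentage with explicit rounding mode
#'
#' Centralizes percentage reporting: \code{"one_decimal"} keeps one decimal
#' place, \code{"integer_half_up"} rounds halves away from zero (so 82.5
#' prints as 83, not the banker's 82). A zero denominator returns \code{NA}
#' (an explicit undefined marker) rather than propagating \code{NaN}.
#'
#' @param numerator,denominator non-negative counts.
#' @param mode \code{"one_decimal"} or \code{"integer_half_up"}.
#' @return numeric scalar, or \code{NA_real_} when the denominator is zero.
#' @examples
#' percentage(45, 54, "integer_half_up")  # 83
#' percentage(1, 3, "one_decimal")        # 33.3
#' @export
percentage <- function(numerator, denominator,
                       mode = c("one_decimal", "integer_half_up")) {
    mode <- match.arg(mode)
    stopifnot(length(numerator) == 1L, length(denominator) == 1L,
              numerator >= 0, denominator >= 0)
    if (denominator == 0) return(NA_real_)
    p <- 100 * numerator / denominator
    if (mode == "integer_half_up") floor(p + 0.5) else round(p, 1)
}

# run expr under a fixed seed without disturbing the caller's RNG stream
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(as.integer(seed %% .Machine$integer.max))
    expr
}

# typed conditions: usage errors are bad arguments/config, runtime errors
# are failures while executing a validated request
usageError <- function(...) {
    stop(errorCondition(paste0(...),
                        class = c("synaptoNet_usage_error", "error")))
}
runtimeError <- function(...) {
    stop(errorCondition(paste0(...),
                        class = c("synaptoNet_runtime_error", "error")))
}
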