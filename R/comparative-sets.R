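## Exact set algebra across datasets and external curated lists.

#' Exact two-set comparison (Venn regions)
#'
#' Region counts, memberships and the Jaccard index for two symbol sets
#' under the same normalization. Swapping the arguments mirrors the
#' exclusive regions and leaves the intersection unchanged.
#'
#' @param a,b \code{\link{SymbolSet}} objects.
#' @return a list of class \code{"vennReport"}: \code{n_a}, \code{n_b},
#'   \code{n_common}, \code{n_a_only}, \code{n_b_only}, \code{jaccard},
#'   plus member vectors \code{common}, \code{a_only}, \code{b_only} and
#'   display forms.
#' @examples
#' v <- venn(SymbolSet("x", c("a", "b", "c")), SymbolSet("y", c("b", "d")))
#' v$n_common  # 1
#' @export
venn <- function(a, b) {
    stopifnot(is(a, "SymbolSet"), is(b, "SymbolSet"))
    sa <- symbols(a); sb <- symbols(b)
    common <- sort(intersect(sa, sb))
    aOnly <- sort(setdiff(sa, sb))
    bOnly <- sort(setdiff(sb, sa))
    uni <- length(sa) + length(sb) - length(common)
    disp <- c(displayForms(a), displayForms(b))
    disp <- disp[!duplicated(names(disp))]
    structure(list(
        name_a = a@name, name_b = b@name,
        n_a = length(sa), n_b = length(sb),
        n_common = length(common),
        n_a_only = length(aOnly), n_b_only = length(bOnly),
        jaccard = if (uni > 0) length(common) / uni else NA_real_,
        common = common, a_only = aOnly, b_only = bOnly,
        display = disp), class = "vennReport")
}

#' @export
print.vennReport <- function(x, ...) {
    cat(sprintf("venn %s (%d) vs %s (%d): %d common, %d | %d exclusive, jaccard %.3f\n",
                x$name_a, x$n_a, x$name_b, x$n_b, x$n_common,
                x$n_a_only, x$n_b_only, x$jaccard))
    invisible(x)
}

#' Overlap of one base set against several comparison lists
#'
#' One row per comparison list: overlap count with the base set and the
#' overlap as a percentage of the base. Member lists are kept alongside
#' counts so overlapping symbols can feed downstream network restriction.
#'
#' @param base a non-empty \code{\link{SymbolSet}}.
#' @param others list of \code{\link{SymbolSet}} objects.
#' @return a list of class \code{"multiOverlapReport"} with fields
#'   \code{base_name}, \code{n_base}, a \code{rows} data.frame
#'   (\code{name}, \code{n_list}, \code{n_overlap}, \code{pct_of_base})
#'   and \code{members} (named list of overlapping symbols).
#' @export
multiOverlap <- function(base, others) {
    stopifnot(is(base, "SymbolSet"))
    if (!length(symbols(base)))
        usageError("empty base set: overlap percentages are undefined")
    if (is(others, "SymbolSet")) others <- list(others)
    stopifnot(all(vapply(others, is, TRUE, "SymbolSet")))
    rows <- lapply(others, function(o) {
        ov <- intersect(symbols(base), symbols(o))
        data.frame(name = o@name, n_list = length(symbols(o)),
                   n_overlap = length(ov),
                   pct_of_base = percentage(length(ov), length(symbols(base)),
                                            "one_decimal"),
                   stringsAsFactors = FALSE)
    })
    members <- lapply(others, function(o)
        sort(intersect(symbols(base), symbols(o))))
    names(members) <- vapply(others, function(o) o@name, character(1))
    structure(list(base_name = base@name, n_base = length(symbols(base)),
                   rows = do.call(rbind, rows), members = members),
              class = "multiOverlapReport")
}

#' @export
print.multiOverlapReport <- function(x, ...) {
    cat(sprintf("overlaps with base '%s' (n=%d):\n", x$base_name, x$n_base))
    print(x$rows, row.names = FALSE)
    invisible(x)
}
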