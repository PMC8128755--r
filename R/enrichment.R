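## Over-representation statistics and pathway-fraction reporting.

#' Benjamini-Hochberg adjustment with input validation
#'
#' Standard step-up adjusted values (via \code{\link[stats]{p.adjust}}),
#' clipped at 1, input order preserved. Values outside [0, 1] are an
#' error rather than silently clamped.
#'
#' @param pvalues numeric vector of raw p-values in [0, 1].
#' @return adjusted values in the input order.
#' @export
bhAdjust <- function(pvalues) {
    pvalues <- as.numeric(pvalues)
    if (any(!is.finite(pvalues) | pvalues < 0 | pvalues > 1))
        usageError("p-values must lie in [0, 1]")
    p.adjust(pvalues, method = "BH")
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of a query set against each gene set in
#' a collection, over a background universe (by convention the detected
#' symbols of the relevant biotype, not the whole annotation). The query
#' and every gene set are first intersected with the background; dropped
#' query symbols are reported via a message. For overlap k, set size K,
#' query size n and background size N, \code{p = P(X >= k)} with
#' \code{X ~ Hypergeometric(N, K, n)}; only enrichment (upper tail) is
#' tested. BH correction is applied per collection across all tested sets;
#' rows come back sorted by p.
#'
#' @param query a \code{\link{SymbolSet}}.
#' @param collection a \code{\link{GeneSets}} collection.
#' @param background a \code{\link{SymbolSet}} universe.
#' @return data.frame with columns \code{collection}, \code{set_name},
#'   \code{k}, \code{K}, \code{n}, \code{N}, \code{p}, \code{fdr}.
#' @export
hypergeomEnrich <- function(query, collection, background) {
    stopifnot(is(query, "SymbolSet"), is(collection, "GeneSets"),
              is(background, "SymbolSet"))
    bg <- symbols(background)
    if (!length(bg)) usageError("empty background universe")
    q <- symbols(query)
    dropped <- setdiff(q, bg)
    if (length(dropped))
        message(length(dropped), " query symbol(s) outside the background dropped")
    q <- intersect(q, bg)
    if (!length(q))
        usageError("query is empty after intersection with the background")
    N <- length(bg); n <- length(q)
    rows <- lapply(names(geneSets(collection)), function(nm) {
        set <- intersect(geneSets(collection)[[nm]], bg)
        K <- length(set)
        k <- length(intersect(set, q))
        p <- if (k == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
        data.frame(collection = collection@name, set_name = nm,
                   k = k, K = K, n = n, N = N, p = p,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$fdr <- bhAdjust(out$p)
    out <- out[order(out$p, out$set_name), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Fraction of a pathway's genes in an increased set
#'
#' For one named gene set, the fraction of its members (within the
#' background) that appear in an externally supplied increased/up-regulated
#' symbol list — the statistic behind "half of this pathway responds"
#' style claims for stimulation experiments. The differential-expression
#' call producing the increased list is an input, not something this
#' package fits.
#'
#' @param setName name of the gene set inside \code{collection}.
#' @param collection a \code{\link{GeneSets}} collection.
#' @param increased a \code{\link{SymbolSet}} of up-regulated symbols.
#' @param background a \code{\link{SymbolSet}} universe.
#' @return list with \code{set_name}, \code{n_members_in_background},
#'   \code{n_increased}, \code{fraction}, \code{pct_display}.
#' @export
pathwayFractionIncreased <- function(setName, collection, increased,
                                     background) {
    stopifnot(is(collection, "GeneSets"), is(increased, "SymbolSet"),
              is(background, "SymbolSet"))
    if (!setName %in% names(geneSets(collection)))
        usageError("gene set '", setName, "' not in collection; available: ",
                   paste(names(geneSets(collection)), collapse = ", "))
    bg <- symbols(background)
    members <- intersect(geneSets(collection)[[setName]], bg)
    up <- intersect(intersect(symbols(increased), bg), members)
    frac <- if (length(members)) length(up) / length(members) else NA_real_
    list(set_name = setName,
         n_members_in_background = length(members),
         n_increased = length(up),
         fraction = frac,
         pct_display = percentage(length(up), length(members),
                                  "integer_half_up"))
}
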