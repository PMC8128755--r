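#' Detection thresholds for abundance filtering
#'
#' TPM thresholds used to call a feature "detected". Defaults follow the
#' usual conditions for this kind of data: 1000 TPM for small RNAs
#' (corresponding to an average raw count of 10 reads in a 10,000-read
#' library) and 50 TPM for mRNA/lncRNA from synaptosome-depth total
#' RNA-seq; chamber-depth libraries use 100. \code{replicateRule} controls
#' how replicate columns are aggregated before comparison: \code{"mean"}
#' (default; thresholds the across-sample mean), \code{"all"} (every
#' replicate must pass) or \code{"any"}.
#'
#' @param smallRnaTpm TPM threshold for miRNA/snoRNA (default 1000).
#' @param mrnaTpm TPM threshold for mRNA/lncRNA (default 50).
#' @param replicateRule \code{"mean"}, \code{"all"} or \code{"any"}.
#' @return a list of class \code{"detectionThresholds"}.
#' @export
detectionThresholds <- function(smallRnaTpm = 1000, mrnaTpm = 50,
                                replicateRule = c("mean", "all", "any")) {
    replicateRule <- match.arg(replicateRule)
    if (smallRnaTpm <= 0 || mrnaTpm <= 0)
        usageError("detection thresholds must be positive")
    structure(list(smallRnaTpm = smallRnaTpm, mrnaTpm = mrnaTpm,
                   replicateRule = replicateRule),
              class = "detectionThresholds")
}

#' Library-size TPM normalization
#'
#' Scales each sample column of a count matrix to transcripts per million:
#' \code{tpm(f, s) = count(f, s) / librarySize(s) * 1e6}, where the library
#' size is the column sum over all features of the matrix. No
#' transcript-length term enters (the acronym often implies one; here it is
#' pure library-size scaling). Columns with zero library size are returned
#' all-zero with a warning and flagged in \code{metadata()}.
#'
#' @param counts a validated \code{\link{RnaCounts}}.
#' @return an \code{\link{RnaTpm}} with the same dimensions.
#' @examples
#' m <- matrix(c(10L, 90L), 2, dimnames = list(c("f1", "f2"), "s1"))
#' assay(tpmNormalize(RnaCounts(m, "small_rna")), "tpm")  # 1e5, 9e5
#' @export
tpmNormalize <- function(counts) {
    stopifnot(is(counts, "RnaCounts"))
    m <- assay(counts, "counts")
    lib <- colSums(m)
    zero <- lib == 0
    if (any(zero)) {
        warning(sprintf("sample(s) %s have zero library size; returned all-zero",
                        paste(colnames(m)[zero], collapse = ", ")))
        lib[zero] <- 1  # avoids 0/0; columns are all-zero anyway
    }
    tpm <- sweep(m, 2L, lib, "/") * 1e6
    out <- RnaTpm(tpm, assayType(counts))
    metadata(out)$zero_library_samples <- colnames(m)[zero]
    metadata(out)$library_sizes <- colSums(m)
    out
}

aggregateReplicates <- function(m, rule) {
    switch(rule,
           mean = rowMeans(m),
           all  = apply(m, 1L, min),
           any  = apply(m, 1L, max))
}

#' Call detected features from a TPM matrix
#'
#' A symbol is detected when its replicate-aggregated TPM (per
#' \code{replicateRule}) is greater than or equal to the
#' biotype-appropriate threshold: \code{smallRnaTpm} for miRNA and snoRNA
#' quantified in the small-RNA assay, \code{mrnaTpm} for mRNA and lncRNA in
#' the total-RNA assay. Comparison is inclusive, so a feature sitting
#' exactly on the cutoff is detected. Multiple feature ids sharing a symbol
#' are collapsed by summing their TPM values (equivalent to summing counts
#' before normalization, since the library size is unchanged). Features
#' absent from the annotation are dropped with a message; detectable
#' biotypes that do not belong to the matrix's assay (e.g. miRNA rows in a
#' total-RNA matrix) are excluded with a warning.
#'
#' @param tpm an \code{\link{RnaTpm}}.
#' @param annotation a \code{\link{FeatureAnnotation}} covering the features.
#' @param thresholds a \code{\link{detectionThresholds}} object.
#' @param dataset label for the resulting set (e.g. \code{"synaptosome"}).
#' @return a \code{\link{DetectionSet}} with per-biotype symbol sets.
#' @export
detectExpressed <- function(tpm, annotation,
                            thresholds = detectionThresholds(),
                            dataset = "dataset") {
    stopifnot(is(tpm, "RnaTpm"), is(annotation, "FeatureAnnotation"),
              inherits(thresholds, "detectionThresholds"))
    ann <- annotationTable(annotation)
    m <- assay(tpm, "tpm")
    known <- rownames(m) %in% ann$feature_id
    if (!all(known))
        message(sum(!known), " unannotated feature(s) dropped")
    m <- m[known, , drop = FALSE]
    ann <- ann[match(rownames(m), ann$feature_id), , drop = FALSE]

    eligible <- if (assayType(tpm) == "total_rna") c("mRNA", "lncRNA")
                else c("miRNA", "snoRNA")
    wrong <- ann$biotype %in% setdiff(DETECTABLE_BIOTYPES, eligible)
    if (any(wrong))
        warning(sprintf("%d feature(s) with biotype outside the %s assay excluded",
                        sum(wrong), assayType(tpm)))
    keep <- ann$biotype %in% eligible
    m <- m[keep, , drop = FALSE]
    ann <- ann[keep, , drop = FALSE]

    sets <- list()
    disp <- character()
    for (b in eligible) {
        rows <- ann$biotype == b
        if (!any(rows)) { sets[[b]] <- character(); next }
        sub <- m[rows, , drop = FALSE]
        # collapse features sharing a symbol (TPM is linear in counts)
        bySym <- rowsum(sub, group = ann$norm_symbol[rows])
        agg <- aggregateReplicates(bySym, thresholds$replicateRule)
        thr <- if (b %in% c("miRNA", "snoRNA")) thresholds$smallRnaTpm
               else thresholds$mrnaTpm
        sets[[b]] <- rownames(bySym)[agg >= thr]
        disp <- c(disp, displayMap(ann$symbol[rows], ann$norm_symbol[rows]))
    }
    disp <- disp[!duplicated(names(disp))]
    DetectionSet(dataset = dataset, sets = sets, display = disp,
                 thresholds = unclass(thresholds), nSamples = ncol(m))
}

#' Merge detection sets from complementary assays
#'
#' Combines (by union, per biotype) detection sets for the same dataset,
#' typically the mRNA/lncRNA calls from the total-RNA assay with the
#' miRNA/snoRNA calls from the small-RNA assay.
#'
#' @param ... two or more \code{\link{DetectionSet}} objects.
#' @param dataset label for the merged set (default: first input's label).
#' @return a merged \code{\link{DetectionSet}}.
#' @export
mergeDetectionSets <- function(..., dataset = NULL) {
    xs <- list(...)
    stopifnot(length(xs) >= 1L, all(vapply(xs, is, TRUE, "DetectionSet")))
    if (is.null(dataset)) dataset <- datasetName(xs[[1L]])
    sets <- list()
    disp <- character()
    removed <- list()
    for (x in xs) {
        for (b in names(x@sets))
            sets[[b]] <- union(sets[[b]], x@sets[[b]])
        disp <- c(disp, x@display)
        removed <- c(removed, x@removed)
    }
    DetectionSet(dataset = dataset, sets = sets,
                 display = disp[!duplicated(names(disp))],
                 thresholds = xs[[1L]]@thresholds,
                 nSamples = xs[[1L]]@nSamples, removed = removed)
}

#' Exclude predicted genes from detection sets
#'
#' Removes symbols whose annotated feature carries the predicted-gene flag
#' from the named biotypes (by default lncRNA only, where provisional gene
#' models are common). Removed symbols are retained in the object's side
#' report (slot \code{removed}) so they stay available for exploratory
#' follow-up rather than vanishing silently.
#'
#' @param set a \code{\link{DetectionSet}}.
#' @param annotation the \code{\link{FeatureAnnotation}} carrying
#'   \code{predicted} flags.
#' @param biotypes biotypes to filter (default \code{"lncRNA"}; empty
#'   vector is the identity).
#' @return the filtered \code{\link{DetectionSet}}.
#' @export
excludePredicted <- function(set, annotation, biotypes = "lncRNA") {
    stopifnot(is(set, "DetectionSet"), is(annotation, "FeatureAnnotation"))
    if (!length(biotypes)) return(set)
    ann <- annotationTable(annotation)
    predSyms <- unique(ann$norm_symbol[ann$predicted])
    sets <- set@sets
    removed <- set@removed
    for (b in intersect(biotypes, names(sets))) {
        drop <- intersect(sets[[b]], predSyms)
        if (length(drop)) {
            sets[[b]] <- setdiff(sets[[b]], drop)
            removed[[paste0(b, "_predicted")]] <-
                union(removed[[paste0(b, "_predicted")]], drop)
        }
    }
    DetectionSet(dataset = set@dataset, sets = sets, display = set@display,
                 thresholds = set@thresholds, nSamples = set@nSamples,
                 removed = removed)
}

#' Class composition of the detected snoRNAs
#'
#' Fractions of C/D-box, H/ACA-box and unclassified snoRNAs over the
#' detected snoRNA set. Fractions sum to 1 (within 1e-12); integer
#' percentages (half-up) are reported alongside. An empty snoRNA set gives
#' an empty report rather than an error.
#'
#' @param set a \code{\link{DetectionSet}} with a snoRNA component.
#' @param annotation the \code{\link{FeatureAnnotation}} carrying
#'   \code{snorna_class}.
#' @return list with \code{n}, \code{counts}, \code{fractions},
#'   \code{percents}.
#' @export
snornaClassFractions <- function(set, annotation) {
    stopifnot(is(set, "DetectionSet"), is(annotation, "FeatureAnnotation"))
    sno <- detectedSymbols(set, "snoRNA")
    classes <- c("CD_box", "HACA_box", "unclassified")
    if (!length(sno))
        return(list(n = 0L, counts = setNames(integer(3), classes),
                    fractions = numeric(), percents = numeric()))
    ann <- annotationTable(annotation)
    ann <- ann[ann$biotype == "snoRNA" & ann$norm_symbol %in% sno, ]
    ann <- ann[!duplicated(ann$norm_symbol), ]
    counts <- table(factor(ann$snorna_class, levels = classes))
    n <- sum(counts)
    fr <- as.numeric(counts) / n
    names(fr) <- classes
    list(n = as.integer(n),
         counts = setNames(as.integer(counts), classes),
         fractions = fr,
         percents = vapply(counts, function(k)
             percentage(k, n, "integer_half_up"), numeric(1)))
}
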