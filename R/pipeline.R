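## End-to-end orchestration: one structured (YAML) config drives
## simulate -> detect -> network -> compare -> enrich, every stage writes a
## machine-readable JSON report, and a manifest records config/input
## checksums and seeds. Bad configuration raises a usage-error condition
## (class "synaptoNet_usage_error"); failures during execution raise
## runtime-error conditions — callers wrapping this in a shell entry point
## can map these to exit codes 2 and 1.

pipelineSchema <- list(
    seed = "integer seed for the synthetic inputs",
    dataset = "label for the detection sets (default 'synaptosome')",
    thresholds = "list: small_rna_tpm, mrna_tpm, replicate_rule",
    prune = "one_shot or iterative (default one_shot)",
    network = "list: include_lncrna, include_tf (defaults false)",
    simulate = "optional overrides for simConfig fields")

#' Validate a pipeline configuration
#'
#' Checks the structured configuration (a named list, or a YAML file path)
#' against the pipeline's schema. Missing or malformed required keys raise
#' a usage error naming them.
#'
#' @param config named list or path to a YAML file.
#' @return the validated config list, with defaults filled in.
#' @export
validatePipelineConfig <- function(config) {
    if (is.character(config) && length(config) == 1L) {
        if (!file.exists(config))
            usageError("config file not found: ", config)
        config <- yaml::read_yaml(config)
    }
    if (!is.list(config))
        usageError("config must be a named list or a YAML file path")
    missing <- setdiff(c("seed", "thresholds"), names(config))
    if (length(missing))
        usageError("config is missing required key(s): ",
                   paste(missing, collapse = ", "))
    thr <- config$thresholds
    tmiss <- setdiff(c("small_rna_tpm", "mrna_tpm"), names(thr))
    if (length(tmiss))
        usageError("config$thresholds is missing key(s): ",
                   paste(tmiss, collapse = ", "))
    unknown <- setdiff(names(config), names(pipelineSchema))
    if (length(unknown))
        usageError("unknown config key(s): ",
                   paste(unknown, collapse = ", "),
                   "; known keys: ",
                   paste(names(pipelineSchema), collapse = ", "))
    config$dataset <- config$dataset %||% "synaptosome"
    config$prune <- config$prune %||% "one_shot"
    if (!config$prune %in% c("one_shot", "iterative"))
        usageError("config$prune must be 'one_shot' or 'iterative'")
    config$network <- config$network %||% list()
    config$simulate <- config$simulate %||% list()
    config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

writeReport <- function(x, path) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    path
}

#' Run the full pipeline from one configuration
#'
#' Generates a complete synthetic fixture directory under
#' \code{outDir/fixtures}, reads every input back through the package's
#' own readers, and executes the analysis stages in dependency order:
#' TPM normalization and detection for both assays, predicted-gene
#' exclusion, weak-evidence filtering, expression-restricted network
#' construction, degree pruning, hub ranking, coverage statistics, the
#' paired-set comparison, and enrichment plus pathway-fraction reporting.
#' All reports are written as JSON with a stable schema; graph exports in
#' SIF, GraphML and edge-TSV form sit alongside. A manifest records the
#' config and input checksums so a rerun with identical config can be
#' verified to reproduce identical stage outputs (manifest timestamps
#' aside).
#'
#' @param config named list or YAML file path
#'   (see \code{\link{validatePipelineConfig}}).
#' @param outDir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config, outDir) {
    config <- validatePipelineConfig(config)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    stage <- function(s) message("[", s, "] ", appendLF = FALSE)

    thr <- detectionThresholds(
        smallRnaTpm = config$thresholds$small_rna_tpm,
        mrnaTpm = config$thresholds$mrna_tpm,
        replicateRule = config$thresholds$replicate_rule %||% "mean")
    simArgs <- c(list(seed = config$seed, thresholds = thr),
                 config$simulate)
    sc <- tryCatch(do.call(simConfig, simArgs),
                   error = function(e) {
                       if (inherits(e, "synaptoNet_usage_error")) stop(e)
                       usageError("invalid 'simulate' overrides: ",
                                  conditionMessage(e))
                   })

    stage("simulate"); message("writing fixture directory")
    fixDir <- file.path(outDir, "fixtures")
    paths <- writeSimulation(sc, fixDir)

    stage("detect"); message("normalizing and thresholding both assays")
    annotation <- readAnnotation(paths$annotation)
    detSets <- lapply(c("total_rna", "small_rna"), function(a) {
        counts <- readCountMatrix(paths[[paste0("counts_", a)]], a)
        detectExpressed(tpmNormalize(counts), annotation, thr,
                        dataset = config$dataset)
    })
    detected <- mergeDetectionSets(detSets[[1L]], detSets[[2L]])
    detected <- excludePredicted(detected, annotation)
    snoFrac <- snornaClassFractions(detected, annotation)
    writeReport(list(
        dataset = datasetName(detected),
        thresholds = detected@thresholds,
        n_detected = lapply(detectedSymbols(detected), length),
        detected = detectedSymbols(detected),
        removed_predicted = detected@removed,
        snorna_class = snoFrac[c("n", "counts", "fractions", "percents")]),
        file.path(outDir, "detection.json"))

    stage("network"); message("building expression-restricted network")
    intPaths <- unlist(paths[startsWith(names(paths), "interactions_")])
    records <- filterWeak(readInteractions(intPaths))
    graph <- buildNetwork(records, detected)
    pruned <- pruneLowDegree(graph, config$prune)
    cov <- coverageStats(graph, detected)
    hubs <- rankHubs(pruned, "miRNA")
    exportGraph(pruned, file.path(outDir, "network.sif"), "sif")
    exportGraph(pruned, file.path(outDir, "network.graphml"), "graphml")
    exportGraph(pruned, file.path(outDir, "network.edges.tsv"), "edge_tsv")
    writeReport(unclass(cov)[c("n_mrna_detected", "n_mrna_targeted",
                               "pct_mrna_targeted",
                               "pct_mrna_targeted_int",
                               "n_mirna_detected", "n_mirna_with_target",
                               "pct_mirna_with_target",
                               "pct_mirna_with_target_int")],
                file.path(outDir, "coverage.json"))
    writeReport(list(regulator_type = "miRNA",
                     prune_mode = config$prune,
                     ranking = hubs),
                file.path(outDir, "hubs.json"))

    stage("compare"); message("paired-set comparison")
    v <- venn(readSymbolList(paths$set_a, "set_a"),
              readSymbolList(paths$set_b, "set_b"))
    writeReport(unclass(v)[c("name_a", "name_b", "n_a", "n_b", "n_common",
                             "n_a_only", "n_b_only", "jaccard", "common",
                             "a_only", "b_only")],
                file.path(outDir, "venn.json"))

    stage("enrich"); message("over-representation and pathway fractions")
    collection <- readGmt(paths$gmt, "sim_pathways")
    increased <- readSymbolList(paths$increased, "increased")
    background <- readSymbolList(paths$background, "background")
    enr <- hypergeomEnrich(increased, collection, background)
    pf <- pathwayFractionIncreased(sc$stimulationSpec$pathwayName,
                                   collection, increased, background)
    writeReport(enr, file.path(outDir, "enrichment.json"))
    writeReport(pf, file.path(outDir, "pathway_fraction.json"))

    stage("manifest"); message("checksums and provenance")
    cfgFile <- file.path(outDir, "config_used.yaml")
    yaml::write_yaml(config, cfgFile)
    inputs <- unlist(paths)
    manifest <- list(
        schema_version = "1.0",
        seed = config$seed,
        config_checksum = unname(tools::md5sum(cfgFile)),
        input_checksums = as.list(tools::md5sum(unname(inputs))),
        reports = c("detection.json", "coverage.json", "hubs.json",
                    "venn.json", "enrichment.json",
                    "pathway_fraction.json"),
        timestamp = format(Sys.time(), tz = "UTC"))
    writeReport(manifest, file.path(outDir, "manifest.json"))
    invisible(manifest)
}
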