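## Deterministic synthetic-data generators with planted ground truth.
## Every generator is a pure function of its config: the same seed yields
## identical objects and files. The generators emit exactly the formats the
## readers consume, so the whole pipeline is testable without sequencing
## archives or live database releases.

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-data generators. The
#' defaults describe the study conditions the generators emulate: three
#' replicate samples, negative-binomial counts with dispersion 0.1,
#' planted detected features sitting at twice their detection threshold
#' and undetected ones at half of it, total-RNA libraries around six
#' million reads and small-RNA libraries around two million, six
#' interaction sources with one planted 50-target hub over background
#' regulators of at most 10 targets, a (65, 54, 17) paired-overlap design,
#' and a 40-gene pathway of which half responds to stimulation. snoRNA
#' classes are assigned in the proportions 0.49 / 0.17 / 0.34
#' (C/D box / H/ACA box / unclassified).
#'
#' @param seed mandatory integer seed; generators never draw silent
#'   entropy.
#' @param nFeatures named integer vector of feature-universe sizes per
#'   biotype.
#' @param nSamples replicate count per assay.
#' @param librarySize list with \code{total_rna} and \code{small_rna}
#'   ranges (min, max) for per-sample library sizes.
#' @param dispersion negative-binomial dispersion (variance
#'   \code{mu + mu^2 * dispersion}).
#' @param detectedFraction named fractions of features planted above
#'   threshold per biotype.
#' @param foldAbove,foldBelow placement of planted means relative to the
#'   detection threshold; must satisfy \code{foldAbove > 1} and
#'   \code{foldBelow < 1} so the classes separate.
#' @param predictedFraction fraction of lncRNA features flagged as
#'   predicted gene models.
#' @param snornaClassProbs class proportions for snoRNA features
#'   (assigned deterministically by largest remainder, so realized counts
#'   match the proportions as closely as integers allow).
#' @param thresholds the \code{\link{detectionThresholds}} the planted
#'   means are placed around.
#' @param nFiller number of high-abundance background features (biotype
#'   \code{"other"}) per assay that absorb the remaining TPM mass, as
#'   rRNA/tRNA-like species do in real libraries.
#' @param weakFraction probability that an evidence edge is weak in its
#'   source's dialect (label or sub-threshold score).
#' @param plantedHubTargets integer vector: target counts for planted hub
#'   microRNAs (one hub per entry).
#' @param backgroundTargetsMax maximum targets for non-hub microRNAs.
#' @param vennSpec integer vector \code{(n_a, n_b, n_common)} for
#'   \code{\link{simulateOverlapSets}}.
#' @param stimulationSpec list with \code{pathwayName},
#'   \code{pathwaySize}, \code{fractionUp}, \code{nBackground},
#'   \code{nNoiseUp}, \code{nDecoySets} for
#'   \code{\link{simulateStimulation}}.
#' @return a validated list of class \code{"simConfig"}.
#' @export
simConfig <- function(seed,
                      nFeatures = c(mRNA = 200L, lncRNA = 30L,
                                    miRNA = 60L, snoRNA = 40L),
                      nSamples = 3L,
                      librarySize = list(total_rna = c(5e6, 7e6),
                                         small_rna = c(1e6, 3e6)),
                      dispersion = 0.1,
                      detectedFraction = c(mRNA = 0.5, lncRNA = 0.5,
                                           miRNA = 0.5, snoRNA = 0.5),
                      foldAbove = 2.0, foldBelow = 0.5,
                      predictedFraction = 0.3,
                      snornaClassProbs = c(CD_box = 0.49, HACA_box = 0.17,
                                           unclassified = 0.34),
                      thresholds = detectionThresholds(),
                      nFiller = 20L,
                      weakFraction = 0.2,
                      plantedHubTargets = 50L,
                      backgroundTargetsMax = 10L,
                      vennSpec = c(n_a = 65L, n_b = 54L, n_common = 17L),
                      stimulationSpec = list(pathwayName = "Ribosome",
                                             pathwaySize = 40L,
                                             fractionUp = 0.5,
                                             nBackground = 400L,
                                             nNoiseUp = 30L,
                                             nDecoySets = 3L)) {
    if (missing(seed) || is.null(seed) || is.na(seed))
        usageError("simConfig: 'seed' is mandatory")
    seed <- as.integer(seed)
    need <- c("mRNA", "lncRNA", "miRNA", "snoRNA")
    if (!all(need %in% names(nFeatures)) || any(nFeatures[need] < 1))
        usageError("nFeatures must name positive counts for ",
                   paste(need, collapse = ", "))
    if (nSamples < 1) usageError("nSamples must be >= 1")
    if (dispersion <= 0) usageError("dispersion must be > 0")
    if (any(detectedFraction < 0 | detectedFraction > 1))
        usageError("detectedFraction values must lie in [0, 1]")
    if (foldAbove <= 1 || foldBelow >= 1)
        usageError("foldAbove must exceed 1 and foldBelow be below 1; ",
                   "otherwise planted classes do not separate")
    if (predictedFraction < 0 || predictedFraction > 1)
        usageError("predictedFraction must lie in [0, 1]")
    if (abs(sum(snornaClassProbs) - 1) > 1e-9)
        usageError("snornaClassProbs must sum to 1")
    if (weakFraction < 0 || weakFraction > 1)
        usageError("weakFraction must lie in [0, 1]")
    if (any(plantedHubTargets < 1))
        usageError("plantedHubTargets must be positive")
    if (vennSpec[["n_common"]] > min(vennSpec[["n_a"]], vennSpec[["n_b"]]))
        usageError("vennSpec: n_common exceeds one of the set sizes")
    ss <- stimulationSpec
    if (ss$fractionUp < 0 || ss$fractionUp > 1)
        usageError("stimulationSpec$fractionUp must lie in [0, 1]")
    if (ss$pathwaySize > ss$nBackground)
        usageError("stimulationSpec: pathway larger than background")
    if (ss$nNoiseUp > ss$nBackground - ss$pathwaySize)
        usageError("stimulationSpec: too many noise genes for the background")
    structure(list(seed = seed, nFeatures = nFeatures, nSamples = nSamples,
                   librarySize = librarySize, dispersion = dispersion,
                   detectedFraction = detectedFraction,
                   foldAbove = foldAbove, foldBelow = foldBelow,
                   predictedFraction = predictedFraction,
                   snornaClassProbs = snornaClassProbs,
                   thresholds = thresholds, nFiller = as.integer(nFiller),
                   weakFraction = weakFraction,
                   plantedHubTargets = as.integer(plantedHubTargets),
                   backgroundTargetsMax = as.integer(backgroundTargetsMax),
                   vennSpec = vennSpec, stimulationSpec = stimulationSpec),
              class = "simConfig")
}

# largest-remainder apportionment of n items into proportions p
apportion <- function(n, p) {
    raw <- n * p
    base <- floor(raw)
    rem <- n - sum(base)
    if (rem > 0) {
        extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1
    }
    as.integer(base)
}

simSymbols <- function(biotype, n) {
    idx <- sprintf("%04d", seq_len(n))
    switch(biotype,
           mRNA   = paste0("Syng", idx),
           lncRNA = paste0("Lincs", idx),
           # species prefix + mixed case exercise miRNA normalization
           miRNA  = paste0("mmu-miR-9", idx, "-3p"),
           snoRNA = paste0("SNORX", idx),
           paste0("bg", idx))
}

#' Simulate replicate count matrices with planted detection truth
#'
#' Draws negative-binomial read counts for a mixed-biotype feature
#' universe, with per-feature expected TPM placed either at
#' \code{foldAbove} times the biotype's detection threshold (planted
#' detected) or at \code{foldBelow} times it (planted undetected), log-
#' uniformly jittered upwards for the detected class. mRNA and lncRNA
#' features form the total-RNA assay; miRNA and snoRNA the small-RNA
#' assay. A set of high-abundance filler features (biotype \code{"other"})
#' absorbs the remaining TPM budget in each assay so that nominal TPM
#' placements are achievable; an infeasible budget is an error before any
#' sampling. Output is deterministic under the config's seed.
#'
#' @param config a \code{\link{simConfig}}.
#' @return list with \code{counts} (list of \code{\link{RnaCounts}} keyed
#'   \code{total_rna} / \code{small_rna}), \code{annotation}
#'   (\code{\link{FeatureAnnotation}}) and \code{truth} (per-biotype
#'   planted detected/undetected normalized symbols plus the per-feature
#'   status table).
#' @export
simulateCounts <- function(config) {
    stopifnot(inherits(config, "simConfig"))
    thr <- config$thresholds
    biotypes <- c("mRNA", "lncRNA", "miRNA", "snoRNA")
    assayOf <- c(mRNA = "total_rna", lncRNA = "total_rna",
                 miRNA = "small_rna", snoRNA = "small_rna")
    thrOf <- c(mRNA = thr$mrnaTpm, lncRNA = thr$mrnaTpm,
               miRNA = thr$smallRnaTpm, snoRNA = thr$smallRnaTpm)

    withSeed(config$seed, {
        feat <- do.call(rbind, lapply(biotypes, function(b) {
            n <- config$nFeatures[[b]]
            syms <- simSymbols(b, n)
            nDet <- round(config$detectedFraction[[b]] * n)
            det <- logical(n)
            det[sample.int(n, nDet)] <- TRUE
            data.frame(feature_id = paste0("feat_", tolower(b), "_",
                                           sprintf("%04d", seq_len(n))),
                       symbol = syms, biotype = b, detected = det,
                       stringsAsFactors = FALSE)
        }))
        feat$predicted <- FALSE
        lnc <- which(feat$biotype == "lncRNA")
        nPred <- round(config$predictedFraction * length(lnc))
        feat$predicted[sample(lnc, nPred)] <- TRUE
        feat$snorna_class <- "not_applicable"
        sno <- which(feat$biotype == "snoRNA")
        cls <- rep(names(config$snornaClassProbs),
                   apportion(length(sno), config$snornaClassProbs))
        feat$snorna_class[sno] <- cls

        # nominal TPM placement around the biotype threshold
        t0 <- thrOf[feat$biotype]
        feat$nominal_tpm <- ifelse(
            feat$detected,
            t0 * config$foldAbove * 10^runif(nrow(feat), 0, 0.8),
            t0 * config$foldBelow * runif(nrow(feat), 0.1, 1))

        counts <- list()
        filler <- list()
        for (a in c("total_rna", "small_rna")) {
            rows <- feat[assayOf[feat$biotype] == a, , drop = FALSE]
            budget <- 1e6 - sum(rows$nominal_tpm)
            fillTpm <- budget / config$nFiller
            minFill <- max(thrOf[assayOf == a]) * config$foldAbove
            if (budget <= 0 || fillTpm < minFill)
                usageError("infeasible simulation config: nominal TPM ",
                           "placements exceed the per-library budget for ",
                           "the ", a, " assay")
            fid <- paste0("feat_bg_", a, "_",
                          sprintf("%02d", seq_len(config$nFiller)))
            filler[[a]] <- data.frame(
                feature_id = fid,
                symbol = paste0("bg-", a, "-",
                                sprintf("%02d", seq_len(config$nFiller))),
                biotype = "other", detected = NA,
                predicted = FALSE, snorna_class = "not_applicable",
                nominal_tpm = fillTpm, stringsAsFactors = FALSE)
            all <- rbind(rows, filler[[a]])
            rng <- config$librarySize[[a]]
            lib <- round(runif(config$nSamples, rng[1], rng[2]))
            m <- vapply(seq_len(config$nSamples), function(s)
                rnbinom(nrow(all), mu = all$nominal_tpm / 1e6 * lib[s],
                        size = 1 / config$dispersion),
                numeric(nrow(all)))
            dimnames(m) <- list(all$feature_id,
                                paste0(a, "_s", seq_len(config$nSamples)))
            counts[[a]] <- RnaCounts(m, a)
        }

        annTab <- rbind(feat, filler$total_rna, filler$small_rna)
        annotation <- FeatureAnnotation(
            annTab[c("feature_id", "symbol", "biotype", "predicted",
                     "snorna_class")])
        feat$norm_symbol <- normalizeSymbols(feat$symbol)
        truth <- list(
            detected = lapply(setNames(biotypes, biotypes), function(b)
                sort(feat$norm_symbol[feat$biotype == b & feat$detected])),
            undetected = lapply(setNames(biotypes, biotypes), function(b)
                sort(feat$norm_symbol[feat$biotype == b & !feat$detected])),
            status = feat[c("feature_id", "symbol", "norm_symbol",
                            "biotype", "detected", "predicted",
                            "snorna_class")])
        list(counts = counts, annotation = annotation, truth = truth)
    })
}

#' Simulate multi-source interaction evidence with planted hubs
#'
#' Emits canonical-schema interaction tables for six source databases over
#' the universe of a \code{\link{simulateCounts}} result. Detected mRNAs
#' are wired into a shuffled ring of protein-protein (mRNA-mRNA) evidence
#' plus random chords, guaranteeing each detected mRNA at least two
#' backbone neighbors; planted hub microRNAs receive their specified
#' number of targets among detected mRNAs; background microRNAs get at
#' most \code{backgroundTargetsMax} targets; additional edges touch
#' undetected features (exercising expression restriction), duplicate
#' pairs are injected across sources (exercising evidence merging), and
#' \code{weakFraction} of edges are weak in each source's dialect (label
#' for target databases, sub-threshold 0-1000 score for the protein
#' network source; purely unlabeled sources carry no weak dialect and are
#' retained by the weak filter). The ground truth records, by
#' construction, which edges should survive weak filtering plus expression
#' restriction, and the expected surviving target count of every hub.
#'
#' @param config a \code{\link{simConfig}}.
#' @param sim result of \code{\link{simulateCounts}} on the same config.
#' @return list with \code{tables} (named list of per-source data.frames
#'   in the canonical schema), \code{records} (all sources concatenated as
#'   an \code{\link{InteractionTable}}) and \code{truth}.
#' @export
simulateInteractionDbs <- function(config, sim) {
    stopifnot(inherits(config, "simConfig"))
    st <- sim$truth$status
    det <- function(b) st[st$biotype == b & st$detected, , drop = FALSE]
    und <- function(b) st[st$biotype == b & !st$detected, , drop = FALSE]
    mrnaDet <- det("mRNA"); mrnaUnd <- und("mRNA")
    mirDet <- det("miRNA"); mirUnd <- und("miRNA")
    lncDet <- det("lncRNA")
    nHubs <- length(config$plantedHubTargets)
    if (any(config$plantedHubTargets > nrow(mrnaDet)))
        usageError("planted hub target counts exceed the available ",
                   "detected mRNAs")
    if (nHubs > nrow(mirDet))
        usageError("more planted hubs than detected microRNAs")

    withSeed(config$seed + 1L, {
        isWeak <- function(n) runif(n) < config$weakFraction
        rowsOf <- function(src, a, atype, b, btype, directed, weak,
                           dialect) {
            n <- length(a)
            if (!n) return(NULL)
            conf <- rep("unlabeled", n)
            score <- rep(NA_real_, n)
            if (dialect == "label") {
                conf <- ifelse(weak, "weak", "strong")
            } else if (dialect == "score") {
                score <- ifelse(weak, runif(n, 0, 399.99),
                                runif(n, 400, 1000))
            } else if (any(weak)) {
                # unlabeled sources have no weak dialect: a low-confidence
                # interaction is simply absent from their release
                a <- a[!weak]; b <- b[!weak]
                conf <- conf[!weak]; score <- score[!weak]
                weak <- weak[!weak]
                if (!length(a)) return(NULL)
            }
            data.frame(source_db = src, node_a = a, a_type = atype,
                       node_b = b, b_type = btype, directed = directed,
                       confidence = conf, score = score, weak = weak,
                       stringsAsFactors = FALSE)
        }

        edges <- list()
        # mRNA backbone: shuffled ring through all detected mRNAs (STRING
        # dialect: numeric scores), plus random chords and decoys to
        # undetected mRNAs
        ring <- sample(mrnaDet$symbol)
        nxt <- c(ring[-1L], ring[1L])
        edges$ring <- rowsOf("STRING", ring, "mRNA", nxt, "mRNA", FALSE,
                             isWeak(length(ring)), "score")
        nCh <- max(1L, nrow(mrnaDet) %/% 2L)
        ca <- sample(mrnaDet$symbol, nCh, replace = TRUE)
        cb <- sample(mrnaDet$symbol, nCh, replace = TRUE)
        ok <- ca != cb
        edges$chord <- rowsOf("STRING", ca[ok], "mRNA", cb[ok], "mRNA",
                              FALSE, isWeak(sum(ok)), "score")
        if (nrow(mrnaUnd)) {
            nd <- min(20L, nrow(mrnaUnd))
            edges$decoy_mm <- rowsOf(
                "RISE", sample(mrnaUnd$symbol, nd, replace = TRUE), "mRNA",
                sample(mrnaDet$symbol, nd, replace = TRUE), "mRNA",
                FALSE, isWeak(nd), "none")
        }

        # planted hub microRNAs (TarBase dialect: weak/strong labels);
        # the first few edges of each hub are duplicated into NPInter to
        # exercise evidence merging
        hubOrder <- sample(nrow(mirDet))
        hubs <- mirDet$symbol[hubOrder[seq_len(nHubs)]]
        hubTruth <- list()
        for (i in seq_len(nHubs)) {
            tg <- sample(mrnaDet$symbol, config$plantedHubTargets[i])
            wk <- isWeak(length(tg))
            edges[[paste0("hub", i)]] <-
                rowsOf("TarBase", rep(hubs[i], length(tg)), "miRNA",
                       tg, "mRNA", TRUE, wk, "label")
            dup <- utils::head(which(!wk), 5L)
            if (length(dup))
                edges[[paste0("hubdup", i)]] <-
                    rowsOf("NPInter", rep(hubs[i], length(dup)), "miRNA",
                           tg[dup], "mRNA", TRUE, logical(length(dup)),
                           "none")
            hubTruth[[hubs[i]]] <- list(targets = tg, weak = wk)
        }

        # background microRNA targeting
        bgMir <- mirDet$symbol[hubOrder[-seq_len(nHubs)]]
        for (m in bgMir) {
            k <- sample.int(config$backgroundTargetsMax + 1L, 1L) - 1L
            if (!k) next
            tg <- sample(mrnaDet$symbol, k)
            edges[[paste0("bg_", m)]] <-
                rowsOf("TarBase", rep(m, k), "miRNA", tg, "mRNA", TRUE,
                       isWeak(k), "label")
        }
        if (nrow(mirUnd)) {
            nu <- min(15L, nrow(mirUnd))
            edges$decoy_mt <- rowsOf(
                "TarBase", sample(mirUnd$symbol, nu, replace = TRUE),
                "miRNA", sample(mrnaDet$symbol, nu, replace = TRUE),
                "mRNA", TRUE, isWeak(nu), "label")
        }

        # lncRNA associations and TF regulation of microRNAs
        if (nrow(lncDet)) {
            nl <- nrow(lncDet) * 2L
            edges$lnc <- rowsOf(
                "NPInter", sample(lncDet$symbol, nl, replace = TRUE),
                "lncRNA", sample(mrnaDet$symbol, nl, replace = TRUE),
                "mRNA", FALSE, isWeak(nl), "none")
        }
        nt <- min(10L, nrow(mrnaDet))
        edges$tf <- rowsOf(
            "TransmiR", sample(mrnaDet$symbol, nt, replace = TRUE), "TF",
            sample(mirDet$symbol, nt, replace = TRUE), "miRNA", TRUE,
            isWeak(nt), "label")
        nr <- min(10L, nrow(mrnaDet))
        edges$reg <- rowsOf(
            "RegNetwork", sample(mrnaDet$symbol, nr, replace = TRUE), "TF",
            sample(mirDet$symbol, nr, replace = TRUE), "miRNA", TRUE,
            isWeak(nr), "none")

        all <- do.call(rbind, edges)
        rownames(all) <- NULL

        # ground truth derived from construction: backbone nodes are the
        # endpoints of surviving detected-mRNA evidence; a hub target
        # survives when its edge is strong and the target is on the
        # backbone
        norm <- normalizeSymbols
        mmSurv <- all[!all$weak & all$a_type == "mRNA" &
                      all$b_type == "mRNA" &
                      norm(all$node_a) %in% sim$truth$detected$mRNA &
                      norm(all$node_b) %in% sim$truth$detected$mRNA, ]
        backbone <- unique(norm(c(mmSurv$node_a, mmSurv$node_b)))
        hubExpected <- vapply(names(hubTruth), function(h) {
            ht <- hubTruth[[h]]
            sum(!ht$weak & norm(ht$targets) %in% backbone)
        }, integer(1))
        truth <- list(hubs = norm(names(hubTruth)),
                      hub_expected_targets = setNames(
                          hubExpected, norm(names(hubTruth))),
                      top_hub = norm(names(hubTruth))[
                          which.max(hubExpected)],
                      backbone_mrnas = sort(backbone),
                      weak_fraction = config$weakFraction)

        tables <- split(all[, setdiff(names(all), "weak")], all$source_db)
        list(tables = tables,
             records = InteractionTable(
                 transformLoaded(all[, setdiff(names(all), "weak")])),
             truth = truth)
    })
}

# apply the loader's normalization to an in-memory canonical table, so
# in-memory and file-round-trip paths agree
transformLoaded <- function(rec) {
    rec$node_a <- normalizeSymbols(rec$node_a)
    rec$node_b <- normalizeSymbols(rec$node_b)
    conf <- tolower(trimws(as.character(rec$confidence)))
    conf[!conf %in% c("weak", "strong")] <- "unlabeled"
    rec$confidence <- conf
    rec[rec$node_a != rec$node_b, , drop = FALSE]
}

#' Construct two symbol sets with exact overlap
#'
#' Deterministic generation of paired symbol sets with the specified Venn
#' region sizes — the scaffold for reproducing paired-dataset comparisons
#' such as a 65-vs-54 microRNA overlap sharing exactly 17 members.
#'
#' @param vennSpec integer vector \code{(n_a, n_b, n_common)}.
#' @param namespace prefix style for the generated symbols.
#' @param names labels for the two sets.
#' @return list with \code{a}, \code{b} (\code{\link{SymbolSet}}s) and
#'   \code{truth} (the intended region memberships).
#' @export
simulateOverlapSets <- function(vennSpec = c(n_a = 65L, n_b = 54L,
                                             n_common = 17L),
                                namespace = "miR",
                                names = c("set_a", "set_b")) {
    nA <- vennSpec[["n_a"]]; nB <- vennSpec[["n_b"]]
    nC <- vennSpec[["n_common"]]
    if (nC > min(nA, nB))
        usageError("infeasible overlap spec: n_common exceeds a set size")
    sym <- function(tag, n) if (n) sprintf("%s-%s-%03d", namespace, tag,
                                           seq_len(n)) else character()
    common <- sym("cmn", nC)
    aOnly <- sym("aex", nA - nC)
    bOnly <- sym("bex", nB - nC)
    list(a = SymbolSet(names[1L], c(common, aOnly)),
         b = SymbolSet(names[2L], c(common, bOnly)),
         truth = list(common = normalizeSymbols(common),
                      a_only = normalizeSymbols(aOnly),
                      b_only = normalizeSymbols(bOnly)))
}

#' Simulate a stimulation experiment for enrichment analysis
#'
#' Emulates the analysis shape of a stimulation response: a background
#' transcriptome, a gene-set collection containing one planted pathway
#' (plus decoy sets), and an increased/up-regulated symbol list that
#' contains \code{fractionUp} of the planted pathway together with
#' background noise genes. The differential-expression call itself is
#' outside this package; only its resulting list is modeled.
#'
#' @param config a \code{\link{simConfig}} (uses \code{stimulationSpec}
#'   and \code{seed}).
#' @return list with \code{increased} and \code{background}
#'   (\code{\link{SymbolSet}}s), \code{collection}
#'   (\code{\link{GeneSets}}) and \code{truth}.
#' @export
simulateStimulation <- function(config) {
    stopifnot(inherits(config, "simConfig"))
    ss <- config$stimulationSpec
    withSeed(config$seed + 2L, {
        bg <- sprintf("Stimg%04d", seq_len(ss$nBackground))
        pathway <- sample(bg, ss$pathwaySize)
        nUp <- round(ss$fractionUp * ss$pathwaySize)
        upPath <- if (nUp) sample(pathway, nUp) else character()
        noisePool <- setdiff(bg, pathway)
        noise <- if (ss$nNoiseUp) sample(noisePool, ss$nNoiseUp)
                 else character()
        sets <- list(pathway)
        names(sets) <- ss$pathwayName
        nDecoy <- if (is.null(ss$nDecoySets)) 3L else ss$nDecoySets
        for (i in seq_len(nDecoy))
            sets[[sprintf("decoy_%02d", i)]] <-
                sample(bg, ss$pathwaySize)
        list(increased = SymbolSet("increased", c(upPath, noise)),
             background = SymbolSet("background", bg),
             collection = GeneSets("sim_pathways", sets),
             truth = list(pathway = normalizeSymbols(pathway),
                          up_in_pathway = normalizeSymbols(upPath),
                          fraction_up = if (ss$pathwaySize)
                              nUp / ss$pathwaySize else NA_real_))
    })
}

#' Write a complete simulated fixture directory
#'
#' Emits every input the pipeline reads — count TSVs, the annotation
#' table, one interaction TSV per source, overlap symbol lists, the
#' stimulation GMT and lists — plus the ground truth as JSON.
#'
#' @param config a \code{\link{simConfig}}.
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of the written paths.
#' @export
writeSimulation <- function(config, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    sim <- simulateCounts(config)
    dbs <- simulateInteractionDbs(config, sim)
    ov <- simulateOverlapSets(config$vennSpec)
    stim <- simulateStimulation(config)
    paths <- list()
    for (a in names(sim$counts)) {
        paths[[paste0("counts_", a)]] <- file.path(dir, paste0(a, "_counts.tsv"))
        writeCountMatrix(sim$counts[[a]], paths[[paste0("counts_", a)]])
    }
    paths$annotation <- file.path(dir, "annotation.tsv")
    writeAnnotation(sim$annotation, paths$annotation)
    for (src in names(dbs$tables)) {
        p <- file.path(dir, paste0("interactions_", src, ".tsv"))
        write.table(dbs$tables[[src]], p, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        paths[[paste0("interactions_", src)]] <- p
    }
    paths$set_a <- file.path(dir, "set_a.txt")
    writeSymbolList(ov$a, paths$set_a)
    paths$set_b <- file.path(dir, "set_b.txt")
    writeSymbolList(ov$b, paths$set_b)
    paths$gmt <- file.path(dir, "stimulation.gmt")
    writeGmt(stim$collection, paths$gmt)
    paths$increased <- file.path(dir, "increased.txt")
    writeSymbolList(stim$increased, paths$increased)
    paths$background <- file.path(dir, "background.txt")
    writeSymbolList(stim$background, paths$background)
    paths$truth <- file.path(dir, "ground_truth.json")
    jsonlite::write_json(list(counts = sim$truth[c("detected", "undetected")],
                              interactions = dbs$truth,
                              overlap = ov$truth,
                              stimulation = stim$truth),
                         paths$truth, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(paths)
}
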