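test_that("config validation rejects degenerate or infeasible settings", {
    expect_error(simConfig(), "seed")
    expect_error(simConfig(seed = 1, foldAbove = 1, foldBelow = 1),
                 "separate")
    expect_error(simConfig(seed = 1, dispersion = 0), "dispersion")
    expect_error(simConfig(seed = 1,
                           vennSpec = c(n_a = 5L, n_b = 5L, n_common = 9L)),
                 "n_common")
    expect_error(simConfig(seed = 1, stimulationSpec = list(
        pathwayName = "p", pathwaySize = 50L, fractionUp = 0.5,
        nBackground = 40L, nNoiseUp = 0L)), "background")
    # hub demand beyond the detected mRNA pool fails before sampling
    sc <- simConfig(seed = 1, nFeatures = c(mRNA = 20, lncRNA = 5,
                                            miRNA = 10, snoRNA = 5),
                    plantedHubTargets = 500L)
    expect_error(simulateInteractionDbs(sc, simulateCounts(sc)),
                 "exceed")
})

test_that("generators are pure functions of their config (byte-identical)", {
    sc <- simConfig(seed = 77, nFeatures = c(mRNA = 50, lncRNA = 8,
                                             miRNA = 20, snoRNA = 10),
                    plantedHubTargets = 15L)
    d1 <- withr::local_tempdir()
    d2 <- withr::local_tempdir()
    writeSimulation(sc, d1)
    writeSimulation(sc, d2)
    for (f in list.files(d1)) {
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)), label = f)
    }
    # a different seed changes the data
    writeSimulation(simConfig(seed = 78,
                              nFeatures = c(mRNA = 50, lncRNA = 8,
                                            miRNA = 20, snoRNA = 10),
                              plantedHubTargets = 15L), d2)
    expect_false(identical(readLines(file.path(d1, "total_rna_counts.tsv")),
                           readLines(file.path(d2, "total_rna_counts.tsv"))))
})

test_that("emitted files pass the package's own readers", {
    sc <- simConfig(seed = 13, nFeatures = c(mRNA = 40, lncRNA = 6,
                                             miRNA = 15, snoRNA = 8),
                    plantedHubTargets = 10L)
    dir <- withr::local_tempdir()
    paths <- writeSimulation(sc, dir)
    expect_s4_class(readCountMatrix(paths$counts_total_rna, "total_rna"),
                    "RnaCounts")
    expect_s4_class(readCountMatrix(paths$counts_small_rna, "small_rna"),
                    "RnaCounts")
    expect_s4_class(readAnnotation(paths$annotation), "FeatureAnnotation")
    intPaths <- unlist(paths[startsWith(names(paths), "interactions_")])
    expect_s4_class(readInteractions(intPaths), "InteractionTable")
    expect_s4_class(readGmt(paths$gmt), "GeneSets")
    expect_s4_class(readSymbolList(paths$set_a, "a"), "SymbolSet")
})

test_that("planted interaction structure is recovered through the pipeline", {
    sc <- simConfig(seed = 2024)
    sim <- simulateCounts(sc)
    dbs <- simulateInteractionDbs(sc, sim)

    # injected duplicates merge with evidence from >= 2 sources
    det <- DetectionSet("sim", sim$truth$detected)
    g <- buildNetwork(suppressMessages(filterWeak(dbs$records)), det)
    expect_true(any(graphEdges(g)$n_sources >= 2))

    # the planted hub tops the ranking after pruning, with its expected
    # surviving target count
    h <- rankHubs(pruneLowDegree(g, "one_shot"), "miRNA")
    expect_equal(h$regulator[1L], dbs$truth$top_hub)
    expect_equal(h$n_targets[1L],
                 unname(dbs$truth$hub_expected_targets[dbs$truth$top_hub]))

    # weakFraction 1 leaves nothing after the weak filter
    scW <- simConfig(seed = 2024, weakFraction = 1)
    dbsW <- simulateInteractionDbs(scW, sim)
    expect_equal(length(suppressMessages(filterWeak(dbsW$records))), 0L)
})

test_that("overlap generator hits exact region sizes in edge cases", {
    eq <- simulateOverlapSets(c(n_a = 6L, n_b = 6L, n_common = 6L))
    expect_setequal(symbols(eq$a), symbols(eq$b))
    dj <- simulateOverlapSets(c(n_a = 5L, n_b = 5L, n_common = 0L))
    v <- venn(dj$a, dj$b)
    expect_equal(v$n_common, 0L)
    expect_equal(v$jaccard, 0)
    expect_error(simulateOverlapSets(c(n_a = 3L, n_b = 3L, n_common = 4L)),
                 "infeasible")
})

test_that("stimulation generator plants the requested pathway response", {
    sc <- simConfig(seed = 55)
    stim <- simulateStimulation(sc)
    pf <- pathwayFractionIncreased("Ribosome", stim$collection,
                                   stim$increased, stim$background)
    expect_equal(pf$fraction, 0.5)

    # a pathway with no planted response is never more significant than
    # the planted one on matched draw sizes
    worse <- 0L
    for (s in 1:40) {
        scUp <- simConfig(seed = 9000 + s)
        scNull <- simConfig(seed = 9000 + s, stimulationSpec = list(
            pathwayName = "Ribosome", pathwaySize = 40L, fractionUp = 0,
            nBackground = 400L, nNoiseUp = 50L, nDecoySets = 0L))
        pUp <- with(simulateStimulation(scUp),
                    hypergeomEnrich(increased, collection, background))
        pNull <- with(simulateStimulation(scNull),
                      hypergeomEnrich(increased, collection, background))
        if (pNull[pNull$set_name == "Ribosome", "p"] <
            pUp[pUp$set_name == "Ribosome", "p"]) worse <- worse + 1L
    }
    expect_equal(worse, 0L)
})
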