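mkRecords <- function(...) {
    rows <- list(...)
    df <- do.call(rbind, lapply(rows, function(r)
        data.frame(source_db = r[[1]], node_a = r[[2]], a_type = r[[3]],
                   node_b = r[[4]], b_type = r[[5]],
                   directed = as.logical(r[[6]]), confidence = r[[7]],
                   score = if (length(r) > 7) as.numeric(r[[8]]) else NA_real_,
                   stringsAsFactors = FALSE)))
    # apply the loader's normalization, as readInteractions would
    InteractionTable(synaptoNet:::transformLoaded(df))
}

test_that("weak-evidence filtering honours labels, scores and 'if available'", {
    allWeak <- mkRecords(list("d", "a", "miRNA", "b", "mRNA", TRUE, "weak"),
                         list("d", "c", "miRNA", "b", "mRNA", TRUE, "weak"))
    expect_equal(length(filterWeak(allWeak)), 0L)

    unlab <- mkRecords(list("d", "a", "miRNA", "b", "mRNA", TRUE, "unlabeled"),
                       list("d", "x", "mRNA", "y", "mRNA", FALSE, "unlabeled"))
    expect_equal(length(filterWeak(unlab)), 2L)

    scored <- mkRecords(
        list("s", "a", "mRNA", "b", "mRNA", FALSE, "unlabeled", 399),
        list("s", "a", "mRNA", "c", "mRNA", FALSE, "unlabeled", 400),
        list("s", "a", "mRNA", "d", "mRNA", FALSE, "unlabeled", 950))
    kept <- interactionRecords(filterWeak(scored))
    expect_equal(nrow(kept), 2L)        # score >= 400 is strong
    expect_setequal(kept$node_b, c("c", "d"))

    # property: records from unlabeled, unscored sources are never touched
    set.seed(8)
    for (i in 1:10) {
        n <- sample(5:30, 1)
        rec <- InteractionTable(data.frame(
            source_db = sample(c("u1", "u2"), n, TRUE),
            node_a = sprintf("a%d", seq_len(n)), a_type = "mRNA",
            node_b = sprintf("b%d", seq_len(n)), b_type = "mRNA",
            directed = FALSE, confidence = "unlabeled", score = NA_real_,
            stringsAsFactors = FALSE))
        expect_identical(interactionRecords(filterWeak(rec)),
                         interactionRecords(rec))
    }
})

test_that("network build intersects evidence with the detected transcriptome", {
    rec <- mkRecords(list("d1", "A", "mRNA", "B", "mRNA", FALSE, "strong"),
                     list("d1", "miR1", "miRNA", "A", "mRNA", TRUE, "strong"),
                     list("d1", "miR1", "miRNA", "C", "mRNA", TRUE, "strong"))
    det <- DetectionSet("x", list(mRNA = c("a", "b"), miRNA = "mir1"))
    g <- buildNetwork(rec, det)
    ed <- graphEdges(g)
    expect_equal(nrow(ed), 2L)
    expect_setequal(ed$edge_type, c("mrna_mrna", "mirna_target"))
    expect_false("c" %in% names(graphNodes(g)))

    # no records -> empty graph; no detected mRNAs -> empty with warning
    expect_equal(nrow(graphEdges(buildNetwork(InteractionTable(), det))), 0L)
    emptyDet <- DetectionSet("x", list(mRNA = character(), miRNA = "mir1"))
    expect_warning(g0 <- buildNetwork(rec, emptyDet), "empty")
    expect_equal(length(graphNodes(g0)), 0L)
})

test_that("build equals a brute-force filter and ignores record order", {
    set.seed(21)
    for (rep in 1:5) {
        mrna <- sprintf("G%02d", 1:15)
        mirna <- sprintf("miR-%d", 1:6)
        detM <- tolower(sample(mrna, 9))
        detR <- tolower(sample(mirna, 4))
        n <- 60
        a <- character(n); at <- character(n)
        b <- character(n); bt <- character(n)
        mm <- runif(n) < 0.5
        a[mm] <- sample(mrna, sum(mm), TRUE); at[mm] <- "mRNA"
        b[mm] <- sample(mrna, sum(mm), TRUE); bt[mm] <- "mRNA"
        a[!mm] <- sample(mirna, sum(!mm), TRUE); at[!mm] <- "miRNA"
        b[!mm] <- sample(mrna, sum(!mm), TRUE); bt[!mm] <- "mRNA"
        keep <- a != b
        rec <- InteractionTable(data.frame(
            source_db = sample(c("s1", "s2", "s3"), sum(keep), TRUE),
            node_a = tolower(a[keep]), a_type = at[keep],
            node_b = tolower(b[keep]), b_type = bt[keep],
            directed = at[keep] == "miRNA", confidence = "unlabeled",
            score = NA_real_, stringsAsFactors = FALSE))
        det <- DetectionSet("x", list(mRNA = detM, miRNA = detR))
        g <- buildNetwork(rec, det)

        # independent set-comprehension oracle over the raw records
        rr <- interactionRecords(rec)
        pairKey <- function(x, y) paste(pmin(x, y), pmax(x, y))
        mmRows <- rr$a_type == "mRNA" & rr$node_a %in% detM &
            rr$node_b %in% detM
        backbone <- unique(c(rr$node_a[mmRows], rr$node_b[mmRows]))
        mtRows <- rr$a_type == "miRNA" & rr$node_a %in% detR &
            rr$node_b %in% backbone
        wantKeys <- unique(c(paste("mm", pairKey(rr$node_a[mmRows],
                                                 rr$node_b[mmRows])),
                             paste("mt", rr$node_a[mtRows],
                                   rr$node_b[mtRows])))
        ed <- graphEdges(g)
        gotKeys <- c(paste("mm", pairKey(ed$node_a[ed$edge_type == "mrna_mrna"],
                                         ed$node_b[ed$edge_type == "mrna_mrna"])),
                     paste("mt", ed$node_a[ed$edge_type == "mirna_target"],
                           ed$node_b[ed$edge_type == "mirna_target"]))
        expect_setequal(gotKeys, wantKeys)

        # evidence merging: per-edge source count equals a group-by oracle
        cnt <- tapply(rr$source_db[mmRows],
                      pairKey(rr$node_a[mmRows], rr$node_b[mmRows]),
                      function(s) length(unique(s)))
        edm <- ed[ed$edge_type == "mrna_mrna", ]
        expect_equal(unname(edm$n_sources),
                     as.integer(cnt[pairKey(edm$node_a, edm$node_b)]))

        # order invariance
        perm <- sample(nrow(rr))
        g2 <- buildNetwork(InteractionTable(rr[perm, ]), det)
        expect_same_graph(g, g2)
    }
})

test_that("duplicate pairs across sources merge into one evidenced edge", {
    rec <- mkRecords(list("s1", "miR1", "miRNA", "A", "mRNA", TRUE, "strong"),
                     list("s2", "miR1", "miRNA", "A", "mRNA", TRUE, "strong"),
                     list("s3", "miR1", "miRNA", "A", "mRNA", TRUE, "strong"),
                     list("s1", "A", "mRNA", "B", "mRNA", FALSE, "strong"))
    det <- DetectionSet("x", list(mRNA = c("a", "b"), miRNA = "mir1"))
    ed <- graphEdges(buildNetwork(rec, det))
    mt <- ed[ed$edge_type == "mirna_target", ]
    expect_equal(nrow(mt), 1L)
    expect_equal(mt$n_sources, 3L)
    expect_equal(mt$sources, "s1;s2;s3")
})

test_that("single-pass pruning removes weak nodes; iterative equals the 2-core", {
    path <- synaptoNet:::TypedGraph(
        setNames(rep("mRNA", 3), c("a", "b", "c")),
        data.frame(node_a = c("a", "b"), node_b = c("b", "c"),
                   edge_type = "mrna_mrna", directed = FALSE,
                   sources = "s", n_sources = 1L, stringsAsFactors = FALSE))
    expect_equal(length(graphNodes(pruneLowDegree(path, "one_shot"))), 0L)

    tri <- synaptoNet:::TypedGraph(
        setNames(rep("mRNA", 3), c("a", "b", "c")),
        data.frame(node_a = c("a", "a", "b"), node_b = c("b", "c", "c"),
                   edge_type = "mrna_mrna", directed = FALSE,
                   sources = "s", n_sources = 1L, stringsAsFactors = FALSE))
    for (mode in c("one_shot", "iterative"))
        expect_setequal(names(graphNodes(pruneLowDegree(tri, mode))),
                        c("a", "b", "c"))

    set.seed(31)
    for (rep in 1:10) {
        rg <- randomRestrictedGraph(rep + 100, nMrna = sample(10:40, 1),
                                    nMirna = sample(3:12, 1),
                                    pEdge = runif(1, 0.02, 0.15),
                                    pTarget = runif(1, 0.02, 0.2))
        it <- pruneLowDegree(rg$graph, "iterative")
        expect_setequal(names(graphNodes(it)), twoCoreOracle(rg$graph))
        expect_true(all(nodeDegrees(it) >= 2))

        os <- pruneLowDegree(rg$graph, "one_shot")
        pre <- nodeDegrees(rg$graph)
        expect_true(all(pre[names(graphNodes(os))] >= 2))
        # iterative fixed point is contained in the one-shot survivor set
        expect_true(all(names(graphNodes(it)) %in%
                        c(names(graphNodes(os)),
                          names(graphNodes(pruneLowDegree(os, "one_shot"))))))
        expect_true(all(names(graphNodes(it)) %in% names(graphNodes(os))))
    }
})

test_that("hub ranking counts distinct mRNA targets with stable ties", {
    g <- synaptoNet:::TypedGraph(
        c(miR1 = "miRNA", miR2 = "miRNA", A = "mRNA", B = "mRNA",
          C = "mRNA"),
        data.frame(node_a = c("miR1", "miR1", "miR1", "miR2", "A", "B"),
                   node_b = c("A", "B", "C", "A", "B", "C"),
                   edge_type = c(rep("mirna_target", 4), "mrna_mrna",
                                 "mrna_mrna"),
                   directed = c(rep(TRUE, 4), FALSE, FALSE),
                   sources = "s", n_sources = 1L, stringsAsFactors = FALSE))
    h <- rankHubs(g, "miRNA")
    expect_equal(h$regulator, c("miR1", "miR2"))
    expect_equal(h$n_targets, c(3L, 1L))
    expect_equal(rankHubs(g, "lncRNA")$regulator, character(0))
    expect_equal(nrow(rankHubs(g, "miRNA", topK = 1)), 1L)

    # random graphs agree with the brute-force recount
    for (seed in 1:5) {
        rg <- randomRestrictedGraph(seed + 300)
        h <- rankHubs(rg$graph, "miRNA")
        brute <- bruteHubs(rg$graph)
        expect_equal(setNames(h$n_targets, h$regulator)[names(brute)],
                     brute)
        expect_true(all(diff(h$n_targets) <= 0))
    }
})

test_that("coverage statistics match a brute-force edge scan", {
    # 45 of 54 detected microRNAs with >= 1 target prints as 83%
    mrna <- sprintf("g%03d", 1:60)
    mirna <- sprintf("mir-%02d", 1:54)
    edges <- data.frame(node_a = mirna[1:45], node_b = mrna[1:45],
                        edge_type = "mirna_target", directed = TRUE,
                        sources = "s", n_sources = 1L,
                        stringsAsFactors = FALSE)
    g <- synaptoNet:::TypedGraph(
        c(setNames(rep("mRNA", 60), mrna),
          setNames(rep("miRNA", 54), mirna)), edges)
    det <- DetectionSet("x", list(mRNA = mrna, miRNA = mirna))
    cov <- coverageStats(g, det)
    expect_equal(cov$n_mirna_with_target, 45L)
    expect_equal(cov$pct_mirna_with_target_int, 83)
    expect_equal(cov$pct_mirna_with_target, 83.3)

    empty <- synaptoNet:::TypedGraph(
        setNames(rep("mRNA", 2), c("g001", "g002")))
    cov0 <- coverageStats(empty, det)
    expect_equal(cov0$pct_mrna_targeted, 0)
    expect_equal(cov0$pct_mirna_with_target, 0)

    noDet <- DetectionSet("x", list(mRNA = character(), miRNA = character()))
    covNA <- coverageStats(g, noDet)
    expect_true(is.na(covNA$pct_mrna_targeted))

    for (seed in 1:5) {
        rg <- randomRestrictedGraph(seed + 400)
        cov <- coverageStats(rg$graph, rg$detected)
        brute <- bruteCoverage(rg$graph, rg$mrna, rg$mirna)
        expect_equal(cov$n_mrna_targeted, brute$n_mrna_targeted)
        expect_equal(cov$n_mirna_with_target, brute$n_mirna_with_target)
    }
})
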