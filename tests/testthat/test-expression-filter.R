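test_that("TPM is library-size scaling with exact column sums", {
    m <- matrix(c(10L, 90L), 2, dimnames = list(c("f1", "f2"), "s1"))
    tpm <- tpmNormalize(tinyCountMatrix(m))
    expect_equal(unname(SummarizedExperiment::assay(tpm, "tpm")[, 1]),
                 c(1e5, 9e5))

    one <- tpmNormalize(tinyCountMatrix(
        matrix(7L, 1, 1, dimnames = list("f1", "s1"))))
    expect_equal(unname(SummarizedExperiment::assay(one, "tpm")[1, 1]), 1e6)

    # a raw count of 10 in a 10,000-read library sits exactly at the
    # small-RNA detection cutoff of 1000 TPM
    lib <- matrix(c(10L, 9990L), 2, dimnames = list(c("mir1", "rest"), "s1"))
    t2 <- tpmNormalize(tinyCountMatrix(lib, "small_rna"))
    expect_equal(unname(SummarizedExperiment::assay(t2, "tpm")["mir1", 1]),
                 1000)

    # column-sum invariant over random synthetic fixtures
    for (seed in 1:5) {
        sim <- simulateCounts(simConfig(
            seed = seed, nFeatures = c(mRNA = 40, lncRNA = 5, miRNA = 15,
                                       snoRNA = 8)))
        for (a in names(sim$counts)) {
            tp <- tpmNormalize(sim$counts[[a]])
            cs <- colSums(SummarizedExperiment::assay(tp, "tpm"))
            expect_true(all(abs(cs - 1e6) <= 1e-9 * 1e6 | cs == 0))
        }
    }

    z <- matrix(c(0L, 0L, 5L, 5L), 2,
                dimnames = list(c("f1", "f2"), c("s0", "s1")))
    expect_warning(tz <- tpmNormalize(tinyCountMatrix(z)), "zero library")
    expect_equal(unname(SummarizedExperiment::assay(tz, "tpm")[, "s0"]),
                 c(0, 0))
})

test_that("biotypes outside the assay are excluded with a warning", {
    ann <- tinyAnnotation(c("f1", "f2", "f3"), c("MirA", "Actb", "bg"),
                          biotype = c("miRNA", "mRNA", "other"))
    m <- matrix(c(5e5, 4e5, 1e5), 3, 1,
                dimnames = list(c("f1", "f2", "f3"), "s1"))
    tpm <- RnaTpm(m, "small_rna")
    expect_warning(
        det <- detectExpressed(tpm, ann, detectionThresholds(), "x"),
        "outside the small_rna assay")
    expect_equal(detectedSymbols(det, "miRNA"), "mira")
    expect_equal(detectedSymbols(det, "mRNA"), character(0))
})

test_that("detection: boundary, empty matrix, replicate rules, monotonicity", {
    mkTpm <- function(rows, assay = "small_rna") {
        m <- do.call(rbind, rows)
        filler <- pmax(1e6 - colSums(m), 0)
        m <- rbind(m, filler = filler)
        rownames(m) <- c(names(rows), "filler")
        RnaTpm(m, assay)
    }
    ann <- tinyAnnotation(c("f1", "f2", "filler"),
                          c("mirA", "mirB", "bg"),
                          biotype = c("miRNA", "miRNA", "other"))

    tpm <- mkTpm(list(f1 = c(999, 1001), f2 = c(10, 20)))
    det <- detectExpressed(tpm, ann, detectionThresholds(), "x")
    expect_equal(detectedSymbols(det, "miRNA"), "mira")  # mean == cutoff

    zero <- RnaTpm(matrix(0, 3, 2, dimnames = list(
        c("f1", "f2", "filler"), c("s1", "s2"))), "small_rna")
    dz <- detectExpressed(zero, ann, detectionThresholds(), "x")
    expect_true(all(lengths(detectedSymbols(dz)) == 0))

    # replicate-rule containment: all and mean are both within any
    set.seed(99)
    for (rep in 1:5) {
        vals <- list(f1 = runif(3, 0, 3000), f2 = runif(3, 0, 3000))
        tpmR <- mkTpm(vals)
        d <- function(rule) detectedSymbols(detectExpressed(
            tpmR, ann, detectionThresholds(replicateRule = rule), "x"),
            "miRNA")
        expect_true(all(d("all") %in% d("any")))
        expect_true(all(d("mean") %in% d("any")))
        # monotone in the threshold: raising it never adds a feature
        hi <- detectedSymbols(detectExpressed(
            tpmR, ann, detectionThresholds(smallRnaTpm = 2000), "x"),
            "miRNA")
        expect_true(all(hi %in% d("mean")))
    }
})

test_that("planted features at 2x / 0.5x the threshold recover exactly", {
    sc <- simConfig(seed = 314)
    sim <- simulateCounts(sc)
    for (a in c("total_rna", "small_rna")) {
        det <- detectExpressed(tpmNormalize(sim$counts[[a]]),
                               sim$annotation, sc$thresholds, "sim")
        bts <- if (a == "total_rna") c("mRNA", "lncRNA")
               else c("miRNA", "snoRNA")
        for (b in bts) {
            expect_setequal(detectedSymbols(det, b),
                            sim$truth$detected[[b]])
        }
    }
})

test_that("predicted-gene exclusion removes lncRNAs and keeps a side report", {
    ann <- tinyAnnotation(c("l1", "l2", "m1"),
                          c("Malat1", "Gm12345", "Actb"),
                          biotype = c("lncRNA", "lncRNA", "mRNA"),
                          predicted = c(FALSE, TRUE, FALSE))
    det <- DetectionSet("x", list(lncRNA = c("malat1", "gm12345"),
                                  mRNA = "actb"))
    out <- excludePredicted(det, ann)
    expect_equal(detectedSymbols(out, "lncRNA"), "malat1")
    expect_equal(out@removed$lncRNA_predicted, "gm12345")
    expect_equal(detectedSymbols(out, "mRNA"), "actb")

    # identity when no flags set, or when no biotypes are filtered
    annClean <- tinyAnnotation(c("l1", "l2"), c("Malat1", "Gm12345"),
                               biotype = "lncRNA")
    expect_setequal(
        detectedSymbols(excludePredicted(det, annClean), "lncRNA"),
        c("malat1", "gm12345"))
    expect_setequal(
        detectedSymbols(excludePredicted(det, ann, character()), "lncRNA"),
        c("malat1", "gm12345"))
})

test_that("snoRNA class fractions sum to one and match direct counting", {
    ann <- tinyAnnotation(sprintf("s%d", 1:10), sprintf("Sno%d", 1:10),
                          biotype = "snoRNA",
                          snorna_class = rep(c("CD_box", "HACA_box",
                                               "unclassified"),
                                             c(5, 2, 3)))
    det <- DetectionSet("x", list(snoRNA = sprintf("sno%d", 1:10)))
    fr <- snornaClassFractions(det, ann)
    expect_equal(unname(fr$fractions), c(0.5, 0.2, 0.3))
    expect_equal(sum(fr$fractions), 1, tolerance = 1e-12)

    allCd <- tinyAnnotation(c("s1", "s2"), c("SnoA", "SnoB"),
                            biotype = "snoRNA", snorna_class = "CD_box")
    fr2 <- snornaClassFractions(
        DetectionSet("x", list(snoRNA = c("snoa", "snob"))), allCd)
    expect_equal(unname(fr2$fractions), c(1, 0, 0))

    empty <- snornaClassFractions(DetectionSet("x", list(snoRNA = character())),
                                  ann)
    expect_equal(empty$n, 0L)

    # random assignment vs brute-force counting
    set.seed(4)
    cls <- sample(c("CD_box", "HACA_box", "unclassified"), 40, replace = TRUE)
    annR <- tinyAnnotation(sprintf("r%d", 1:40), sprintf("SnoR%d", 1:40),
                           biotype = "snoRNA", snorna_class = cls)
    frR <- snornaClassFractions(
        DetectionSet("x", list(snoRNA = sprintf("snor%d", 1:40))), annR)
    expect_equal(unname(frR$counts),
                 unname(vapply(c("CD_box", "HACA_box", "unclassified"),
                               function(cc) sum(cls == cc), integer(1))))
})
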