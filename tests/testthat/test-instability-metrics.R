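test_that("relative threshold keeps peaks at or above the cut, max always survives", {
    ld <- RepeatLadder(c(-1, 0, 1), c(190, 1000, 210))
    thr <- applyThreshold(ld, 0.20)       # threshold = 200
    expect_equal(ladderDeltas(thr), c(0L, 1L))

    # factor 1: only the maximum (and exact ties) survive
    ld2 <- RepeatLadder(c(-1, 0, 1, 2), c(500, 1000, 1000, 100))
    expect_equal(ladderDeltas(applyThreshold(ld2, 1)), c(0L, 1L))

    flat <- RepeatLadder(-2:2, rep(77, 5))
    expect_equal(length(applyThreshold(flat, 0.9)), 5L)

    expect_error(applyThreshold(RepeatLadder(integer(0), numeric(0))),
                 "no entries")
    expect_error(applyThreshold(ld, 0), "thresholdFactor")
    expect_error(applyThreshold(ld, 1.2), "thresholdFactor")
})

test_that("instability index follows the normalized height-weighted sum", {
    # symmetric contraction/expansion cancels exactly
    expect_identical(instabilityIndex(
        RepeatLadder(c(-1, 0, 1), c(300, 1000, 300)), 0.25), 0)
    # worked example: (500*1 + 250*2 - 300) / 2050
    ld <- RepeatLadder(c(-1, 0, 1, 2), c(300, 1000, 500, 250))
    expect_equal(instabilityIndex(ld, 0.20), 700 / 2050, tolerance = 1e-12)
    expect_identical(instabilityIndex(RepeatLadder(0L, 123), 0.20), 0)
})

test_that("expansion + contraction split uses the shared denominator", {
    ld <- RepeatLadder(c(-1, 0, 1, 2), c(300, 1000, 500, 250))
    ec <- expansionContractionIndices(ld, 0.20)
    expect_equal(unname(ec), c(1000 / 2050, -300 / 2050), tolerance = 1e-12)
    expect_equal(sum(ec), instabilityIndex(ld, 0.20))

    sym <- RepeatLadder(c(-2, 0, 2), c(150, 800, 150))
    ecs <- expansionContractionIndices(sym, 0.1)
    expect_equal(unname(ecs["expansion"]), -unname(ecs["contraction"]))

    expect_equal(unname(expansionContractionIndices(RepeatLadder(0L, 5))),
                 c(0, 0))
})

test_that("peak counts and composition summarise the thresholded ladder", {
    ld <- RepeatLadder(c(-1, 0, 1, 2), c(300, 1000, 500, 250))
    expect_equal(peakCounts(ld, 0.20),
                 c(contracted = 1L, expanded = 2L))
    expect_equal(composition(ld, 0.20),
                 100 * c(contracted = 300, unchanged = 1000,
                         expanded = 750) / 2050, tolerance = 1e-12)

    expect_equal(unname(peakCounts(RepeatLadder(0L, 10), 0.2)), c(0L, 0L))
    # unimodal ladder at factor 1: only the main peak remains
    uni <- RepeatLadder(c(-1, 0, 1), c(400, 900, 500))
    expect_equal(unname(peakCounts(uni, 1)), c(0L, 0L))

    expect_equal(composition(RepeatLadder(0L, 10)),
                 c(contracted = 0, unchanged = 100, expanded = 0))
    expect_equal(composition(RepeatLadder(c(-1, 0, 1), c(300, 1000, 300))),
                 c(contracted = 18.75, unchanged = 62.5, expanded = 18.75))
})

test_that("main-allele shift reports the tissue mode, ties to smaller delta", {
    tissue <- RepeatLadder(c(-1, 0, 1, 2), c(100, 800, 900, 300))
    expect_identical(mainAlleleShift(tissue), 1L)
    expect_identical(mainAlleleShift(
        RepeatLadder(c(0, 1), c(900, 500))), 0L)
    expect_identical(mainAlleleShift(
        RepeatLadder(c(0, 1), c(700, 700))), 0L)
    # relative to an explicit tail ladder whose mode sits at 0
    tail <- RepeatLadder(c(-1, 0), c(100, 1000))
    expect_identical(mainAlleleShift(tissue, tail), 1L)
})

test_that("small-pool index measures mean deviation from the modal length", {
    expect_equal(smallPoolIndex(
        RepeatLengthDistribution(100:102, c(50, 30, 20))), 0.7)
    expect_identical(smallPoolIndex(RepeatLengthDistribution(105L, 33)), 0)
    expect_equal(smallPoolIndex(
        RepeatLengthDistribution(98:102, c(10, 20, 40, 20, 10))), 0)
    # cross-check against a direct moment computation
    cnt <- c(5, 12, 40, 25, 11, 7)
    len <- 104:109
    p <- cnt / sum(cnt)
    expect_equal(smallPoolIndex(RepeatLengthDistribution(len, cnt)),
                 sum(p * (len - 106)))
    # data.frame input and CSV reader agree
    df <- data.frame(cag_length = len, count = cnt)
    f <- withr::local_tempfile(fileext = ".csv")
    write.csv(df, f, row.names = FALSE)
    expect_equal(smallPoolIndex(readSmallPool(f)), smallPoolIndex(df))
    expect_error(smallPoolIndex(data.frame(x = 1)), "cag_length|positive")
})

test_that("every metric is invariant under uniform height scaling", {
    set.seed(11)
    for (i in 1:40) {
        ld <- randomLadder()
        f <- runif(1, 0.05, 0.4)
        for (cc in c(0.5, 3, 7.7)) {
            sc <- RepeatLadder(ladderDeltas(ld), cc * ladderHeights(ld))
            expect_equal(instabilityIndex(sc, f), instabilityIndex(ld, f),
                         tolerance = 1e-12)
            expect_equal(expansionContractionIndices(sc, f),
                         expansionContractionIndices(ld, f),
                         tolerance = 1e-12)
            expect_identical(peakCounts(sc, f), peakCounts(ld, f))
            expect_equal(composition(sc, f), composition(ld, f),
                         tolerance = 1e-12)
        }
    }
})

test_that("raising the threshold never increases the off-main peak count", {
    set.seed(12)
    for (i in 1:40) {
        ld <- randomLadder()
        counts <- vapply(c(0.05, 0.1, 0.2, 0.5, 1),
                         function(f) sum(peakCounts(ld, f)), numeric(1))
        expect_true(all(diff(counts) <= 0))
    }
})

test_that("the metric family matches the explicit-loop oracle", {
    set.seed(13)
    for (i in 1:200) {
        ld <- randomLadder()
        f <- runif(1, 0.02, 1)
        o <- bruteProfile(ladderDeltas(ld), ladderHeights(ld), f)
        expect_equal(instabilityIndex(ld, f), o$index, tolerance = 1e-12)
        ec <- expansionContractionIndices(ld, f)
        expect_equal(unname(ec), c(o$expansion, o$contraction),
                     tolerance = 1e-12)
        expect_equal(unname(peakCounts(ld, f)),
                     c(o$nContracted, o$nExpanded))
        expect_equal(composition(ld, f), o$composition, tolerance = 1e-12)
    }
})

test_that("instabilityProfile bundles a self-consistent metric family", {
    ld <- RepeatLadder(c(-1, 0, 1, 2), c(300, 1000, 500, 250))
    p <- instabilityProfile(ld)
    expect_s4_class(p, "InstabilityProfile")
    df <- as.data.frame(p)
    expect_equal(df$instability_index,
                 df$expansion_index + df$contraction_index)
    expect_equal(df$pct_contracted + df$pct_unchanged + df$pct_expanded, 100)
})

test_that("batch quantification pairs tissues with tails and is deterministic", {
    dir <- withr::local_tempdir()
    mf <- writeTraceFixture(dir)
    res <- quantifyInstability(readManifest(mf))
    expect_equal(nrow(res), 2L)
    expect_gt(res$instability_index[res$tissue == "striatum"],
              res$instability_index[res$tissue == "spleen"])
    res2 <- quantifyInstability(readManifest(mf))
    expect_identical(res, res2)

    # missing tail errors with the sample name
    m <- readManifest(mf)
    expect_error(quantifyInstability(m[m$role != "tail", ]), "m1")
})
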