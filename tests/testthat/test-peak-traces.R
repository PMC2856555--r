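test_that("peak tables parse in both dialects and enforce the height invariant", {
    f <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("size,height", "150.1,1000", "153.2,480"), f)
    tr <- readPeakTable(f)
    expect_s4_class(tr, "PeakTrace")
    expect_equal(peakSizes(tr), c(150.1, 153.2))
    expect_equal(peakHeights(tr), c(1000, 480))

    g <- withr::local_tempfile(fileext = ".txt")
    writeLines(c("Dye\tSize\tHeight\tArea", "B\t150.1\t1000\t5",
                 "B\t153.2\t480\t2"), g)
    expect_equal(peakHeights(readPeakTable(g, "genemapper_tsv")),
                 c(1000, 480))

    h <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("size,height", "150.1,1000", "153.2,-5"), h)
    expect_warning(tr2 <- readPeakTable(h), "dropped")
    expect_equal(length(tr2), 1L)

    m <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("size,signal", "150.1,1000"), m)
    expect_error(readPeakTable(m), "height")

    e <- withr::local_tempfile(fileext = ".csv")
    writeLines("size,height", e)
    expect_error(readPeakTable(e), "empty trace")
})

test_that("peak tables round-trip through both writers", {
    tr <- PeakTrace(c(404, 407.1, 410), c(120.5, 990, 310), "m1", "cortex")
    for (d in c("generic_csv", "genemapper_tsv")) {
        f <- withr::local_tempfile()
        writePeakTable(tr, f, d)
        back <- readPeakTable(f, d)
        expect_equal(peakSizes(back), peakSizes(tr))
        expect_equal(peakHeights(back), peakHeights(tr))
    }
})

test_that("main-allele detection takes the highest peak, smaller size on ties", {
    expect_equal(detectMainAllele(PeakTrace(c(150, 153), c(1000, 480))),
                 list(size = 150, height = 1000))
    expect_equal(detectMainAllele(PeakTrace(c(150, 153), c(800, 800)))$size,
                 150)
    expect_equal(detectMainAllele(PeakTrace(151, 42))$size, 151)
    expect_error(detectMainAllele(PeakTrace(numeric(0), numeric(0))),
                 "empty")
    # invariant under uniform height scaling
    tr <- PeakTrace(c(150, 153, 156), c(400, 900, 100))
    sc <- PeakTrace(c(150, 153, 156), 7.3 * c(400, 900, 100))
    expect_equal(detectMainAllele(tr)$size, detectMainAllele(sc)$size)
})

test_that("ladder assignment rounds against nominal spacing with tolerance", {
    tr <- PeakTrace(c(150.0, 153.1, 156.0), c(1000, 500, 200))
    ld <- buildLadder(tr, mainSize = 150, unitSpacing = 3, tolerance = 1)
    expect_equal(ladderDeltas(ld), c(0L, 1L, 2L))
    expect_equal(ladderHeights(ld), c(1000, 500, 200))

    # residual 1.6 bp from both adjacent rungs -> rejected
    tr2 <- PeakTrace(c(150.0, 151.6), c(1000, 300))
    expect_warning(ld2 <- buildLadder(tr2, 150, tolerance = 1), "rejected")
    expect_equal(ladderDeltas(ld2), 0L)

    # split peak: two peaks on the same rung sum
    tr3 <- PeakTrace(c(150.0, 152.9, 153.1), c(1000, 200, 300))
    ld3 <- buildLadder(tr3, 150)
    expect_equal(ladderHeights(ld3)[ladderDeltas(ld3) == 1L], 500)

    expect_error(buildLadder(tr, 150, tolerance = 2), "tolerance")
})

test_that("ladder building is translation-equivariant and round-trips", {
    set.seed(42)
    for (i in 1:25) {
        ld <- randomLadder()
        sizes <- 407 + 3 * ladderDeltas(ld)
        tr <- PeakTrace(sizes, ladderHeights(ld))
        back <- buildLadder(tr, 407)
        expect_identical(ladderDeltas(back), ladderDeltas(ld))
        expect_equal(ladderHeights(back), ladderHeights(ld))
        # shift every coordinate by the same offset
        off <- runif(1, -40, 40)
        shifted <- buildLadder(PeakTrace(sizes + off, ladderHeights(ld)),
                               407 + off)
        expect_identical(ladderDeltas(shifted), ladderDeltas(ld))
    }
})

test_that("spacing recalibration recovers peaks under mobility drift", {
    delta <- 0:12
    sizes <- 407 + 2.92 * delta          # true spacing off nominal
    tr <- PeakTrace(sizes, rep(100, length(sizes)))
    expect_warning(plain <- buildLadder(tr, 407, unitSpacing = 3,
                                        tolerance = 0.5), "rejected")
    recal <- buildLadder(tr, 407, unitSpacing = 3, tolerance = 0.5,
                         recalibrate = TRUE)
    expect_lt(length(plain), length(delta))
    expect_equal(ladderDeltas(recal), delta)
})

test_that("manifests validate columns and roles", {
    f <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("sample_id,tissue,role,path", "m1,tail,tail,a.csv",
                 "m1,striatum,tissue,b.csv"), f)
    m <- readManifest(f)
    expect_equal(nrow(m), 2L)
    expect_true(all(file.path(dirname(f), c("a.csv", "b.csv")) == m$path))

    g <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("sample_id,tissue,role,path", "m1,tail,reference,a.csv"), g)
    expect_error(readManifest(g), "role")
})
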