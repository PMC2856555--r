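test_that("probe ranking orders by |r| with flagged zero-variance probes last", {
    y <- c(1, 2, 3, 4, 5, 6)
    vals <- rbind(pos = y, neg = -y, noise = c(2, 1, 3, 2, 1, 3),
                  flat = rep(5, 6))
    ex <- makeExpr(vals, tissue = paste0("t", 1:6), phenotype = y)
    rk <- rankProbes(ex)
    expect_setequal(rk$probe[1:2], c("pos", "neg"))
    expect_equal(rk$r[rk$probe == "pos"], 1)
    expect_equal(rk$r[rk$probe == "neg"], -1)
    expect_true(rk$flagged[rk$probe == "flat"])
    expect_equal(rk$probe[4], "flat")
})

test_that("ranking is invariant under positive affine transforms of a probe", {
    set.seed(21)
    y <- rnorm(8)
    vals <- matrix(rnorm(80), 10, 8)
    ex1 <- makeExpr(vals, paste0("t", 1:8), y)
    vals2 <- vals
    vals2[4, ] <- 3.7 * vals2[4, ] + 11
    ex2 <- makeExpr(vals2, paste0("t", 1:8), y)
    expect_identical(rankProbes(ex1)$probe, rankProbes(ex2)$probe)
})

test_that("PLS1 with one component on one predictor reproduces OLS", {
    set.seed(22)
    x <- rnorm(10); y <- 2 + 1.5 * x + rnorm(10, sd = 0.1)
    fit <- RepeatInstability:::.pls1(cbind(x), y, 1)
    cf <- RepeatInstability:::.pls1Coef(fit)
    ols <- lm(y ~ x)
    expect_equal(cf$beta, unname(coef(ols)[2]), tolerance = 1e-9)
    expect_equal(cf$intercept, unname(coef(ols)[1]), tolerance = 1e-9)
})

test_that("full-rank PLS equals the multiple least squares fit", {
    set.seed(23)
    X <- matrix(rnorm(48), 12, 4)
    y <- X %*% c(1, -2, 0.5, 3) + rnorm(12, sd = 0.2)
    fit <- RepeatInstability:::.pls1(X, as.vector(y), 4)
    cf <- RepeatInstability:::.pls1Coef(fit)
    ols <- lm(as.vector(y) ~ X)
    expect_equal(cf$beta, unname(coef(ols)[-1]), tolerance = 1e-8)
    expect_equal(cf$intercept, unname(coef(ols)[1]), tolerance = 1e-8)
})

test_that("PLS component requests beyond the data rank are reduced with a warning", {
    set.seed(24)
    x <- rnorm(6)
    X <- cbind(x, 2 * x, -x)          # rank 1
    y <- x + rnorm(6, sd = 0.01)
    expect_warning(fit <- RepeatInstability:::.pls1(X, y, 3), "reduced")
    expect_equal(fit$A, 1L)
})

test_that("refitting on identical data is bit-identical", {
    set.seed(25)
    ex <- simulateExpression(setNames(seq(0, 4, length.out = 6),
                                      paste0("t", 1:6)),
                             nProbes = 200, nSignatureProbes = 20, seed = 9)
    m1 <- fitSignatureModel(ex, nSelected = 20, nComponents = 2)
    m2 <- fitSignatureModel(ex, nSelected = 20, nComponents = 2)
    expect_identical(m1@coefficients, m2@coefficients)
    expect_identical(m1@intercept, m2@intercept)
})

test_that("a noise-free linear phenotype gives near-zero LOO RMSEP", {
    y <- seq(-1, 5, length.out = 8)
    vals <- rbind(driver = 2 * y + 1,
                  matrix(rnorm(7 * 8, sd = 0.5), 7, 8))
    ex <- makeExpr(vals, paste0("t", 1:8), y)
    curve <- looRmsepCurve(ex, nGrid = 1, maxComponents = 2)
    expect_lt(curve$rmsep, 1e-9)
    expect_error(looRmsepCurve(ex, nGrid = integer(0)), "nGrid")
})

test_that("held-out predictions never depend on the held-out phenotype", {
    set.seed(26)
    idx <- setNames(seq(-0.5, 4, length.out = 8), paste0("t", 1:8))
    ex <- simulateExpression(idx, nProbes = 300, nSignatureProbes = 25,
                             seed = 10)
    curve <- looRmsepCurve(ex, nGrid = c(5, 25), maxComponents = 3)
    # corrupt one tissue's phenotype and recompute
    ph <- phenotype(ex)
    ph[tissueOf(ex) == "t3"] <- 50
    ex2 <- InstabilityExperiment(exprValues(ex), tissueOf(ex), ph)
    curve2 <- looRmsepCurve(ex2, nGrid = c(5, 25), maxComponents = 3)
    p1 <- attr(curve, "predictions")
    p2 <- attr(curve2, "predictions")
    held <- tissueOf(ex) == "t3"
    expect_identical(p1[held, ], p2[held, ])
    expect_false(identical(p1[!held, ], p2[!held, ]))
})

test_that("model selection picks the CV minimum and predicts new tissues", {
    set.seed(27)
    idx <- setNames(seq(-1, 6, length.out = 10), paste0("t", 1:10))
    ex <- simulateExpression(idx, nProbes = 500, nSignatureProbes = 30,
                             seed = 12)
    isTest <- tissueOf(ex) %in% c("t2", "t9")
    m <- fitSignatureModel(ex[, !isTest], nGrid = c(10, 30, 60),
                           maxComponents = 4)
    expect_identical(m@nSelected, cvCurve(m)$n[which.min(cvCurve(m)$rmsep)])
    pred <- predictIndex(m, ex[, isTest])
    expect_gt(cor(pred, phenotype(ex)[isTest]), 0.9)
    # averaging replicates returns one value per tissue
    pavg <- predictIndex(m, ex[, isTest], averageReplicates = TRUE)
    expect_setequal(names(pavg), c("t2", "t9"))
    # missing signature probes are a hard error naming them
    keep <- setdiff(rownames(ex), signatureProbes(m)[1])
    expect_error(predictIndex(m, ex[keep, isTest]),
                 signatureProbes(m)[1], fixed = TRUE)
})

test_that("RMSEP evaluation matches hand arithmetic", {
    expect_equal(evaluateRmsep(c(1, 2, 3), c(1, 2, 3))$rmsep, 0)
    expect_equal(evaluateRmsep(c(1, 2, 3), c(1.5, 2.5, 3.5))$rmsep, 0.5)
    ev <- evaluateRmsep(c(0, 1, 3), c(1, 1, 2))
    expect_equal(ev$rmsep, sqrt((1 + 0 + 1) / 3))
    expect_equal(ev$r, cor(c(0, 1, 3), c(1, 1, 2)))
})

test_that("serialised models predict identically after a JSON round-trip", {
    ex <- simulateExpression(setNames(0:5 / 2, paste0("t", 1:6)),
                             nProbes = 100, nSignatureProbes = 10, seed = 13)
    m <- fitSignatureModel(ex, nSelected = 10, nComponents = 2)
    f <- withr::local_tempfile(fileext = ".json")
    writeSignatureModel(m, f)
    m2 <- readSignatureModel(f)
    expect_equal(predictIndex(m2, ex), predictIndex(m, ex),
                 tolerance = 1e-12)
})
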