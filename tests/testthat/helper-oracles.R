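# Independent reference implementations (explicit loops, no shared code with
# the package's vectorized paths) plus small fixture builders.

# metric family by naive per-peak loop
bruteProfile <- function(delta, height, thresholdFactor) {
    thr <- thresholdFactor * max(height)
    kd <- integer(0); kh <- numeric(0)
    for (i in seq_along(delta)) {
        if (height[i] >= thr) {
            kd <- c(kd, delta[i]); kh <- c(kh, height[i])
        }
    }
    S <- 0
    for (h in kh) S <- S + h
    idx <- ei <- ci <- pc <- pu <- pe <- 0
    nc <- ne <- 0L
    for (i in seq_along(kd)) {
        w <- kh[i] / S
        idx <- idx + w * kd[i]
        if (kd[i] > 0) { ei <- ei + w * kd[i]; ne <- ne + 1L; pe <- pe + w }
        else if (kd[i] < 0) { ci <- ci + w * kd[i]; nc <- nc + 1L; pc <- pc + w }
        else pu <- pu + w
    }
    list(index = idx, expansion = ei, contraction = ci,
         nContracted = nc, nExpanded = ne,
         composition = 100 * c(contracted = pc, unchanged = pu,
                               expanded = pe))
}

randomLadder <- function(maxEntries = 6) {
    k <- sample.int(maxEntries, 1)
    delta <- sort(sample(-5:9, k))
    RepeatLadder(delta, round(runif(k, 10, 2000), 1))
}

# running-sum enrichment score by explicit walk over the ranking
loopES <- function(hit, r, weightExponent) {
    N <- length(hit); K <- sum(hit)
    w <- abs(r)^weightExponent
    sw <- sum(w[hit])
    rs <- numeric(N); cur <- 0
    for (i in seq_len(N)) {
        cur <- cur + (if (hit[i]) (if (sw > 0) w[i] / sw else 1 / K)
                      else -1 / (N - K))
        rs[i] <- cur
    }
    hi <- max(c(rs, 0)); lo <- min(c(rs, 0))
    if (hi >= -lo) hi else lo
}

# unweighted ES as a two-sample Kolmogorov-Smirnov statistic: the signed
# extremum of ECDF(hits) - ECDF(misses) along the ranking
ksOracle <- function(hit) {
    N <- length(hit); K <- sum(hit)
    d <- numeric(N)
    for (i in seq_len(N))
        d[i] <- sum(hit[seq_len(i)]) / K - sum(!hit[seq_len(i)]) / (N - K)
    hi <- max(c(d, 0)); lo <- min(c(d, 0))
    if (hi >= -lo) hi else lo
}

# tiny expression object from an explicit matrix
makeExpr <- function(values, tissue, phenotype) {
    if (is.null(rownames(values)))
        rownames(values) <- sprintf("p%03d", seq_len(nrow(values)))
    if (is.null(colnames(values)))
        colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
    InstabilityExperiment(values, tissue = tissue, phenotype = phenotype)
}

# write a minimal tissue+tail fixture and return the manifest path
writeTraceFixture <- function(dir, tissues = c("striatum", "spleen"),
                              noiseSd = 0, seed = 7) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    pr <- tissuePresets()
    pr <- pr[pr$tissue %in% tissues, , drop = FALSE]
    panel <- simulateTissuePanel(pr, noiseSd = noiseSd, seed = seed)
    writePeakTable(panel$tail, file.path(dir, "tail.csv"))
    rows <- data.frame(sample_id = "m1", tissue = "tail", role = "tail",
                       path = "tail.csv")
    for (tis in names(panel$tissues)) {
        writePeakTable(panel$tissues[[tis]], file.path(dir,
                                                       paste0(tis, ".csv")))
        rows <- rbind(rows, data.frame(sample_id = "m1", tissue = tis,
                                       role = "tissue",
                                       path = paste0(tis, ".csv")))
    }
    mf <- file.path(dir, "manifest.csv")
    write.csv(rows, mf, row.names = FALSE, quote = FALSE)
    mf
}
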