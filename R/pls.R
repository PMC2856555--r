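## Univariate-response partial least squares (PLS1, NIPALS).  Predictors and
## response are mean-centered only — no unit-variance scaling — so with a
## full-rank component set the fit coincides with ordinary least squares.

# X: n x p matrix, y: length-n response, ncomp requested components.
# Extraction stops early (with a warning unless quiet) when the centered data
# run out of rank or the response residual vanishes.
.pls1 <- function(X, y, ncomp, quiet = FALSE) {
    X <- as.matrix(X)
    n <- nrow(X); p <- ncol(X)
    stopifnot(length(y) == n, n >= 2)
    ncomp <- min(ncomp, n - 1L, p)
    xMeans <- colMeans(X)
    yMean <- mean(y)
    E <- sweep(X, 2L, xMeans)
    f <- y - yMean
    tolX <- 1e-12 * max(sum(E^2), 1)
    W <- P <- matrix(0, p, ncomp)
    qv <- numeric(ncomp)
    A <- 0L
    for (a in seq_len(ncomp)) {
        w <- crossprod(E, f)[, 1]
        wn <- sqrt(sum(w^2))
        if (!is.finite(wn) || wn^2 <= tolX * 1e-4) break
        w <- w / wn
        tvec <- as.vector(E %*% w)
        tt <- sum(tvec^2)
        if (tt <= tolX) break
        pvec <- crossprod(E, tvec)[, 1] / tt
        qa <- sum(f * tvec) / tt
        E <- E - tcrossprod(tvec, pvec)
        f <- f - qa * tvec
        W[, a] <- w; P[, a] <- pvec; qv[a] <- qa
        A <- a
    }
    if (A < ncomp && !quiet)
        warning("PLS components reduced from ", ncomp, " to ", A,
                " (rank of centered data)")
    if (A == 0L)  # constant response: intercept-only model
        return(list(W = matrix(0, p, 0), P = matrix(0, p, 0), q = numeric(0),
                    xMeans = xMeans, yMean = yMean, A = 0L))
    list(W = W[, seq_len(A), drop = FALSE], P = P[, seq_len(A), drop = FALSE],
         q = qv[seq_len(A)], xMeans = xMeans, yMean = yMean, A = A)
}

# regression coefficients in original predictor space for the first a
# components; intercept absorbs the centering
.pls1Coef <- function(fit, a = fit$A) {
    if (a == 0L)
        return(list(beta = rep(0, length(fit$xMeans)),
                    intercept = fit$yMean))
    W <- fit$W[, seq_len(a), drop = FALSE]
    P <- fit$P[, seq_len(a), drop = FALSE]
    beta <- as.vector(W %*% solve(crossprod(P, W), fit$q[seq_len(a)]))
    list(beta = beta, intercept = fit$yMean - sum(fit$xMeans * beta))
}

# predictions for components 1..A at once: n x A matrix
.pls1PredictAll <- function(fit, Xnew) {
    Xnew <- as.matrix(Xnew)
    if (fit$A == 0L)
        return(matrix(fit$yMean, nrow(Xnew), 1L))
    out <- matrix(NA_real_, nrow(Xnew), fit$A)
    for (a in seq_len(fit$A)) {
        cf <- .pls1Coef(fit, a)
        out[, a] <- Xnew %*% cf$beta + cf$intercept
    }
    out
}
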