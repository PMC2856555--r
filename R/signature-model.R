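## Correlation-ranked forward selection + PLSR modeling of tissue instability
## from gene expression.

# core ranking: X probes x samples, y phenotype
.rankMatrix <- function(X, y) {
    n <- length(y)
    xc <- X - rowMeans(X)
    ssx <- rowSums(xc^2)
    yc <- y - mean(y)
    ssy <- sum(yc^2)
    flagged <- ssx <= 0 | ssy <= 0
    r <- as.vector(xc %*% yc) / sqrt(ssx * ssy)
    r[flagged] <- NA_real_
    p <- ifelse(abs(r) >= 1, 0,
                2 * pt(-abs(r) * sqrt((n - 2) / pmax(1 - r^2, 1e-300)),
                       df = n - 2))
    probe <- rownames(X)
    o <- order(flagged, p, probe)
    data.frame(probe = probe[o], r = r[o], p = p[o], flagged = flagged[o],
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank probes by correlation with the instability phenotype
#'
#' Computes, for every probe, the Pearson correlation with the instability
#' index across training samples (those with a non-missing phenotype) plus a
#' two-sided p-value from the t transform, and sorts ascending by p —
#' equivalently descending |r| — with deterministic probe-id tie-break.
#' Correlation is used purely as a *ranking* metric; the regression itself
#' ([fitSignatureModel()]) works on the raw expression values.  Zero-variance
#' probes have undefined correlation: they are flagged and ranked last.
#'
#' @param expr an [InstabilityExperiment-class] with at least 3 phenotyped
#'   samples.
#' @return data.frame `probe, r, p, flagged` sorted by p.
#' @export
rankProbes <- function(expr) {
    ph <- phenotype(expr)
    use <- !is.na(ph)
    if (sum(use) < 3)
        stop("need at least 3 training samples with measured instability")
    .rankMatrix(exprValues(expr)[, use, drop = FALSE], ph[use])
}

# inner component selection: leave-one-group-out RMSEP over 1..maxA
.chooseComponents <- function(X, y, groups, maxA) {
    maxA <- min(maxA, ncol(X))
    gs <- unique(groups)
    # bounded by the smallest inner training-set size
    maxA <- min(maxA, length(y) - max(table(groups)) - 1L)
    maxA <- max(maxA, 1L)
    err <- matrix(NA_real_, length(y), maxA)
    for (g in gs) {
        te <- groups == g
        fit <- .pls1(X[!te, , drop = FALSE], y[!te], maxA, quiet = TRUE)
        pr <- .pls1PredictAll(fit, X[te, , drop = FALSE])
        err[te, seq_len(ncol(pr))] <- (pr - y[te])^2
    }
    rmsep <- sqrt(colMeans(err, na.rm = TRUE))
    .argmin(rmsep)
}

#' Leave-one-tissue-out RMSEP curve over signature sizes
#'
#' For each candidate signature size `n`, estimates prediction error by
#' cross-validation: one tissue is held out at a time (all its replicates
#' together), probes are re-ranked on the retained samples only — so probe
#' selection never sees the held-out tissue — the top `n` probes enter a PLS
#' regression whose component count is chosen by an inner leave-one-tissue-out
#' RMSEP, and the held-out samples are predicted.  RMSEP(n) is the root mean
#' squared prediction error pooled over all held-out samples.
#'
#' `rerankInFolds = FALSE` switches to a single global ranking (computed on
#' all training samples), which is optimistically biased by selection leakage
#' and provided for comparison only.  `foldBy = "sample"` holds out single
#' samples instead of whole tissues.
#'
#' @param expr an [InstabilityExperiment-class].
#' @param nGrid candidate signature sizes; entries above the probe count are
#'   dropped.
#' @param maxComponents cap on PLS components (default 10).
#' @param foldBy cross-validation unit: `"tissue"` (default) or `"sample"`.
#' @param rerankInFolds re-rank probes inside each fold (default TRUE, the
#'   honest variant).
#' @return data.frame `n, rmsep`; attribute `"predictions"` carries the
#'   held-out predictions (samples x signature sizes).
#' @export
looRmsepCurve <- function(expr,
                          nGrid = c(5, 10, 25, 50, 75, 100, 150, 200, 300, 500),
                          maxComponents = 10, foldBy = c("tissue", "sample"),
                          rerankInFolds = TRUE) {
    foldBy <- match.arg(foldBy)
    ph <- phenotype(expr)
    use <- !is.na(ph)
    X <- t(exprValues(expr)[, use, drop = FALSE])  # samples x probes
    y <- unname(ph[use])
    groups <- if (foldBy == "tissue") tissueOf(expr)[use]
              else colnames(expr)[use]
    nGrid <- sort(unique(as.integer(nGrid)))
    nGrid <- nGrid[nGrid >= 1 & nGrid <= ncol(X)]
    if (!length(nGrid)) stop("nGrid is empty after filtering")
    globalRank <- if (!rerankInFolds) .rankMatrix(t(X), y)
    preds <- matrix(NA_real_, length(y), length(nGrid))
    for (g in unique(groups)) {
        te <- groups == g
        rk <- if (rerankInFolds) .rankMatrix(t(X[!te, , drop = FALSE]),
                                             y[!te])
              else globalRank
        eligible <- rk$probe[!rk$flagged]
        for (j in seq_along(nGrid)) {
            pr <- eligible[seq_len(min(nGrid[j], length(eligible)))]
            A <- .chooseComponents(X[!te, pr, drop = FALSE], y[!te],
                                   groups[!te], maxComponents)
            fit <- .pls1(X[!te, pr, drop = FALSE], y[!te], A, quiet = TRUE)
            cf <- .pls1Coef(fit)
            preds[te, j] <- X[te, pr, drop = FALSE] %*% cf$beta + cf$intercept
        }
    }
    out <- data.frame(n = nGrid, rmsep = sqrt(colMeans((preds - y)^2)))
    dimnames(preds) <- list(names(ph)[use], nGrid)
    # held-out predictions per signature size, for honesty diagnostics
    attr(out, "predictions") <- preds
    out
}

#' Fit the instability signature PLSR model
#'
#' The full training pipeline: rank probes by correlation p-value, pick the
#' signature size minimising the leave-one-tissue-out RMSEP curve (ties
#' resolve to the smaller size), choose the PLS component count by inner
#' cross-validation, and fit the final model on all training samples with
#' mean-centered (never variance-scaled) predictors and response.
#' Coefficients are exported to the original probe space.
#'
#' @inheritParams looRmsepCurve
#' @param nSelected fix the signature size instead of selecting it from the
#'   CV curve.
#' @param nComponents fix the PLS component count instead of choosing it by
#'   inner CV.  Requests beyond the rank of the centered training data are
#'   reduced with a warning.
#' @return a [SignatureModel-class].
#' @export
fitSignatureModel <- function(expr, nSelected = NULL, nComponents = NULL,
                              nGrid = c(5, 10, 25, 50, 75, 100, 150, 200,
                                        300, 500),
                              maxComponents = 10,
                              foldBy = c("tissue", "sample"),
                              rerankInFolds = TRUE) {
    foldBy <- match.arg(foldBy)
    ranking <- rankProbes(expr)
    curve <- data.frame(n = integer(0), rmsep = numeric(0))
    if (is.null(nSelected)) {
        curve <- looRmsepCurve(expr, nGrid, maxComponents, foldBy,
                               rerankInFolds)
        nSelected <- curve$n[.argmin(curve$rmsep)]
    }
    probes <- ranking$probe[!ranking$flagged][seq_len(nSelected)]
    ph <- phenotype(expr)
    use <- !is.na(ph)
    X <- t(exprValues(expr)[probes, use, drop = FALSE])
    y <- unname(ph[use])
    if (is.null(nComponents))
        nComponents <- .chooseComponents(X, y,
                                         tissueOf(expr)[use], maxComponents)
    fit <- .pls1(X, y, nComponents)
    cf <- .pls1Coef(fit)
    new("SignatureModel", ranking = ranking, probes = probes,
        nSelected = as.integer(nSelected), nComponents = as.integer(fit$A),
        coefficients = setNames(cf$beta, probes), intercept = cf$intercept,
        cvCurve = curve)
}

#' Predict instability indices from expression
#'
#' Applies the fitted signature model linearly to new samples.  Every
#' signature probe must be present in the expression matrix; missing probes
#' raise an error naming them.
#'
#' @param model a [SignatureModel-class].
#' @param expr an [InstabilityExperiment-class] (phenotype not required).
#' @param averageReplicates average predictions over replicates of each
#'   tissue (default FALSE: per-sample predictions).
#' @return named numeric vector of predicted indices (per sample, or per
#'   tissue when averaging).
#' @export
predictIndex <- function(model, expr, averageReplicates = FALSE) {
    vals <- exprValues(expr)
    missing <- setdiff(model@probes, rownames(vals))
    if (length(missing))
        stop("expression matrix lacks ", length(missing),
             " signature probe(s): ",
             paste(utils::head(missing, 10), collapse = ", "),
             if (length(missing) > 10) ", ...")
    pred <- as.vector(crossprod(vals[model@probes, , drop = FALSE],
                                model@coefficients)) + model@intercept
    names(pred) <- colnames(vals)
    if (averageReplicates) {
        tis <- tissueOf(expr)
        pred <- tapply(pred, tis, mean)
        pred <- setNames(as.numeric(pred), names(pred))
    }
    pred
}

#' Root mean squared error of prediction
#'
#' @param predicted,measured numeric vectors of equal length.
#' @return list with `rmsep`, and the Pearson correlation `r` between
#'   predicted and measured with its two-sided p-value `p`.
#' @examples
#' evaluateRmsep(c(1, 2, 3), c(1.5, 2.5, 3.5))$rmsep  # 0.5
#' @export
evaluateRmsep <- function(predicted, measured) {
    stopifnot(length(predicted) == length(measured), length(predicted) >= 1)
    rmsep <- sqrt(mean((predicted - measured)^2))
    r <- p <- NA_real_
    if (length(predicted) >= 3 && sd(predicted) > 0 && sd(measured) > 0) {
        ct <- stats::cor.test(predicted, measured)
        r <- unname(ct$estimate); p <- ct$p.value
    }
    list(rmsep = rmsep, r = r, p = p)
}

## ---------------------------------------------------------------------------
## serialisation and file formats
## ---------------------------------------------------------------------------

#' Expression matrix and phenotype file IO
#'
#' The expression TSV carries probe ids in the first column (`probe_id`) and
#' one column per sample; the phenotype CSV has columns
#' `sample_id,tissue,instability_index` (index may be empty for
#' prediction-only samples).
#'
#' @param expr an [InstabilityExperiment-class].
#' @param path output/input file.
#' @param phenotypePath optional phenotype CSV to attach when reading; when
#'   absent, samples are labelled by their own id with `NA` phenotype.
#' @return `readExpressionTsv` returns an [InstabilityExperiment-class]; the
#'   writers return `path` invisibly.
#' @export
writeExpressionTsv <- function(expr, path) {
    vals <- exprValues(expr)
    df <- data.frame(probe_id = rownames(vals), vals, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeExpressionTsv
#' @export
readExpressionTsv <- function(path, phenotypePath = NULL) {
    tab <- read.delim(path, check.names = FALSE)
    if (colnames(tab)[1] != "probe_id")
        stop("expression TSV must have first column 'probe_id'")
    vals <- as.matrix(tab[, -1, drop = FALSE])
    rownames(vals) <- tab$probe_id
    tissue <- colnames(vals)
    pheno <- rep(NA_real_, ncol(vals))
    if (!is.null(phenotypePath)) {
        ph <- read.csv(phenotypePath, stringsAsFactors = FALSE)
        need <- c("sample_id", "tissue", "instability_index")
        if (!all(need %in% colnames(ph)))
            stop("phenotype CSV needs columns ", paste(need, collapse = ","))
        m <- match(colnames(vals), ph$sample_id)
        tissue <- ifelse(is.na(m), colnames(vals), ph$tissue[m])
        pheno <- ph$instability_index[m]
    }
    InstabilityExperiment(vals, tissue = tissue, phenotype = pheno)
}

#' @rdname writeExpressionTsv
#' @export
writePhenotypeCsv <- function(expr, path) {
    write.csv(data.frame(sample_id = colnames(expr),
                         tissue = tissueOf(expr),
                         instability_index = phenotype(expr)),
              path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Serialise a signature model to JSON (and back)
#'
#' @param model a [SignatureModel-class].
#' @param path JSON file.
#' @return `readSignatureModel` returns the model; `writeSignatureModel`
#'   returns `path` invisibly.  The probe ranking table is not serialised;
#'   a round-tripped model predicts identically but carries an empty ranking.
#' @export
writeSignatureModel <- function(model, path) {
    jsonlite::write_json(list(
        probes = model@probes,
        coefficients = unname(model@coefficients),
        intercept = model@intercept,
        n_selected = model@nSelected,
        n_components = model@nComponents,
        cv_curve = model@cvCurve), path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeSignatureModel
#' @export
readSignatureModel <- function(path) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    cv <- as.data.frame(j$cv_curve)
    if (!nrow(cv)) cv <- data.frame(n = integer(0), rmsep = numeric(0))
    new("SignatureModel",
        ranking = data.frame(probe = character(0), r = numeric(0),
                             p = numeric(0), flagged = logical(0)),
        probes = j$probes, nSelected = as.integer(j$n_selected),
        nComponents = as.integer(j$n_components),
        coefficients = setNames(as.numeric(j$coefficients), j$probes),
        intercept = as.numeric(j$intercept), cvCurve = cv)
}

#' Export the ranked signature as CSV
#'
#' Writes the selected signature probes with their correlation statistics,
#' in ranking order.
#'
#' @param model a [SignatureModel-class] whose ranking table is populated.
#' @param path output CSV.
#' @export
writeSignatureCsv <- function(model, path) {
    rk <- model@ranking
    rk <- rk[match(model@probes, rk$probe), c("probe", "r", "p")]
    write.csv(rk, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
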