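## Continuous-phenotype gene set enrichment: probes ranked by signed Pearson
## correlation with the instability index, weighted running-sum enrichment
## scores, and significance by phenotype permutation (tissue replicates
## permuted as a block).

#' Rank probes by signed correlation with the phenotype
#'
#' Orders all probes by their Pearson correlation with the instability index
#' across training samples, descending (most positively correlated first),
#' with a deterministic probe-id tie-break.  Zero-variance probes get a
#' neutral score of 0.
#'
#' @param expr an [InstabilityExperiment-class].
#' @return data.frame `probe, r` in ranking order.
#' @export
correlationRanking <- function(expr) {
    ph <- phenotype(expr)
    use <- !is.na(ph)
    if (sum(use) < 3)
        stop("need at least 3 phenotyped samples")
    X <- exprValues(expr)[, use, drop = FALSE]
    .corRanking(X - rowMeans(X), unname(ph[use]), rownames(X))
}

# xc: row-centered probes x samples; returns ranking for phenotype y
.corRanking <- function(xc, y, probes) {
    ssx <- rowSums(xc^2)
    yc <- y - mean(y)
    ssy <- sum(yc^2)
    r <- as.vector(xc %*% yc) / sqrt(ssx * ssy)
    r[ssx <= 0 | ssy <= 0] <- 0
    o <- order(-r, probes)
    data.frame(probe = probes[o], r = r[o], row.names = NULL,
               stringsAsFactors = FALSE)
}

# ES from sorted hit positions; absr is |r| along the full ranking.
# Candidates for the running-sum extremum are the values just before and
# just after each hit (the sum is linear-decreasing between hits); ties in
# magnitude resolve to the positive extremum.
.esFromPositions <- function(hitPos, absr, N, weightExponent) {
    K <- length(hitPos)
    if (K == 0L || K == N)
        stop("gene set must hit a strict, non-empty subset of the ranking")
    w <- absr[hitPos]^weightExponent
    sw <- sum(w)
    cw <- if (sw > 0) cumsum(w) / sw else seq_len(K) / K
    pen <- (hitPos - seq_len(K)) / (N - K)
    after <- cw - pen
    before <- c(0, cw[-K]) - pen
    hi <- max(after, 0)
    lo <- min(before, 0)
    if (hi >= -lo) hi else lo
}

#' Weighted running-sum enrichment score
#'
#' Walks the correlation ranking: at each member ("hit") of the gene set the
#' running sum increases by \eqn{|r|^{weight}/\sum_{hits}|r|^{weight}}, at
#' each non-member it decreases by \eqn{1/(N - K)}.  The enrichment score is
#' the signed extremum of the running sum (largest magnitude; a tie resolves
#' to the positive side).  At `weightExponent = 0` this reduces to the
#' classic Kolmogorov-Smirnov statistic.
#'
#' @param ranking data.frame `probe, r` from [correlationRanking()].
#' @param members character vector of probe ids (the gene set, after any
#'   gene-to-probe expansion).
#' @param weightExponent hit-weight exponent on |r| (default 1, the standard
#'   weighted statistic).
#' @return list with `es` and the full `runningSum` vector (length N; starts
#'   and ends at 0 up to rounding).
#' @export
enrichmentScore <- function(ranking, members, weightExponent = 1) {
    hit <- ranking$probe %in% members
    K <- sum(hit); N <- length(hit)
    if (K == 0L) stop("no gene-set member present in the ranking universe")
    if (K == N) stop("gene set covers the whole universe; ES degenerate")
    absr <- abs(ranking$r)
    w <- absr^weightExponent
    sw <- sum(w[hit])
    inc <- ifelse(hit,
                  if (sw > 0) w / sw else 1 / K,
                  -1 / (N - K))
    rs <- cumsum(inc)
    es <- .esFromPositions(which(hit), absr, N, weightExponent)
    list(es = es, runningSum = rs)
}

#' Permutation-based enrichment significance
#'
#' Computes the enrichment score of every gene set against the observed
#' phenotype, then builds a per-set null by permuting the phenotype across
#' tissues `nPerm` times — replicates of a tissue carry their tissue's
#' permuted value as a block, preserving the replicate structure.  For each
#' set the normalised enrichment score is
#' \eqn{NES = ES / \mathrm{mean}|ES_{null}|} over same-signed null scores,
#' and the nominal p-value is the fraction of same-signed null scores at
#' least as extreme as the observed one, with a +1 pseudocount in numerator
#' and denominator so finite permutation counts never report p = 0.
#'
#' Sets are first intersected with the expression universe and filtered to
#' `minSize <= size <= maxSize`; dropped sets are reported via `message()`.
#'
#' @param expr an [InstabilityExperiment-class] with phenotyped samples.
#' @param sets named list of character vectors (probe ids), e.g. from
#'   [readGmt()] + [expandGeneSets()].
#' @param nPerm number of phenotype permutations (default 1000; below 50 a
#'   warning is issued, p-values are unstable).
#' @param weightExponent see [enrichmentScore()].
#' @param minSize,maxSize post-intersection set-size filter (defaults 15 and
#'   500).
#' @param seed RNG seed; identical seeds give identical p-values.
#' @return data.frame `name, size, es, nes, p_nominal`, sorted by p then
#'   name.
#' @export
permutationSignificance <- function(expr, sets, nPerm = 1000,
                                    weightExponent = 1, minSize = 15,
                                    maxSize = 500, seed = 1) {
    if (nPerm < 50)
        warning("fewer than 50 permutations: nominal p-values are unstable")
    ph <- phenotype(expr)
    use <- !is.na(ph)
    X <- exprValues(expr)[, use, drop = FALSE]
    xc <- X - rowMeans(X)
    y <- unname(ph[use])
    tis <- tissueOf(expr)[use]
    tissues <- unique(tis)
    tisValue <- vapply(tissues, function(t) y[tis == t][1], numeric(1))
    probes <- rownames(X)
    N <- length(probes)

    members <- lapply(sets, function(s) unique(s[s %in% probes]))
    size <- lengths(members)
    keep <- size >= minSize & size <= maxSize
    if (any(!keep))
        message(sum(!keep), " gene set(s) skipped by size filter [",
                minSize, ", ", maxSize, "] after intersection")
    members <- members[keep]
    size <- size[keep]
    if (!length(members))
        return(data.frame(name = character(0), size = integer(0),
                          es = numeric(0), nes = numeric(0),
                          p_nominal = numeric(0)))

    esForPhenotype <- function(yy) {
        rk <- .corRanking(xc, yy, probes)
        pos <- match(probes, rk$probe)   # probe -> rank position
        absr <- abs(rk$r)
        vapply(members, function(m)
            .esFromPositions(sort(pos[match(m, probes)]), absr, N,
                             weightExponent), numeric(1))
    }

    obs <- esForPhenotype(y)
    nullEs <- .withSeed(seed, {
        out <- matrix(NA_real_, length(members), nPerm)
        for (b in seq_len(nPerm)) {
            permTis <- tisValue[sample.int(length(tissues))]
            names(permTis) <- tissues
            out[, b] <- esForPhenotype(unname(permTis[tis]))
        }
        out
    })

    nes <- p <- numeric(length(obs))
    for (i in seq_along(obs)) {
        same <- if (obs[i] >= 0) nullEs[i, ] >= 0 else nullEs[i, ] < 0
        nSame <- sum(same)
        mAbs <- if (nSame) mean(abs(nullEs[i, same])) else NA_real_
        nes[i] <- if (!is.na(mAbs) && mAbs > 0) obs[i] / mAbs else NA_real_
        p[i] <- (1 + sum(abs(nullEs[i, same]) >= abs(obs[i]))) / (1 + nSame)
    }
    res <- data.frame(name = names(members), size = as.integer(size),
                      es = unname(obs), nes = nes, p_nominal = p,
                      row.names = NULL, stringsAsFactors = FALSE)
    res[order(res$p_nominal, res$name), , drop = FALSE]
}

#' Read a GMT gene-set file
#'
#' Tab-separated, one set per line: name, description, then member ids.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    out <- lapply(lines, function(l) {
        f <- strsplit(l, "\t", fixed = TRUE)[[1]]
        if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 60))
        setNames(list(unique(f[-(1:2)])), f[1])
    })
    do.call(c, out)
}

#' Expand gene-symbol sets to probe ids
#'
#' Gene sets are usually annotated with gene symbols while enrichment runs at
#' probe level; each gene contributes all of its probes.  Symbols without any
#' probe are silently dropped.
#'
#' @param sets named list of gene-symbol vectors (e.g. [readGmt()]).
#' @param annotation data.frame with columns `gene_symbol, probe_id`.
#' @return named list of probe-id vectors.
#' @export
expandGeneSets <- function(sets, annotation) {
    if (!all(c("gene_symbol", "probe_id") %in% colnames(annotation)))
        stop("annotation needs columns gene_symbol,probe_id")
    lapply(sets, function(s)
        unique(annotation$probe_id[annotation$gene_symbol %in% s]))
}

#' Write enrichment results
#'
#' CSV `name,size,es,nes,p_nominal`, already sorted by p (the layout of a
#' significant-pathways table).
#'
#' @param results data.frame from [permutationSignificance()].
#' @param path output CSV.
#' @export
writeEnrichmentResults <- function(results, path) {
    write.csv(results, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
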