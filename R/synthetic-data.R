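## Ground-truthed generators: somatic repeat-length distributions, rendered
## peak traces (stutter + shorter-allele amplification bias + noise), and
## expression matrices with a planted instability-correlated signature.

#' Simulate a somatic repeat-length distribution
#'
#' The per-cell distribution of repeat change \eqn{\Delta} is a three-part
#' mixture emulating expansion-biased somatic instability: a point mass at
#' \eqn{\Delta = 0}, a geometric expansion tail over \eqn{\Delta \ge 1} with
#' decay `tailShape`, scaled so that the tail contributes exactly
#' `expansionRate` to the mean, and a contraction mass split 2:1 over
#' \eqn{\Delta \in \{-1, -2\}}.  The construction is closed-form and
#' deterministic; the exact mean
#' \eqn{\mu = expansionRate - \tfrac{4}{3}\,contractionMass}
#' is recorded as the distribution's ground truth ([trueMeanDelta()]).
#'
#' @param expansionRate expected repeat gain per cell contributed by the
#'   expansion tail (\eqn{\ge 0}).
#' @param contractionMass fraction of cells carrying a contracted repeat, in
#'   `[0, 1)`.  Default 0.15: contraction is modest and similar across
#'   tissues.
#' @param tailShape geometric decay parameter of the expansion tail in
#'   `(0, 1)`; the tail mean is \eqn{1/(1 - tailShape)}.
#' @param mainRepeats constitutive CAG count (default 109).
#' @param seed accepted for interface uniformity; the distribution itself is
#'   closed-form, so the output is identical for any seed.
#' @return a [RepeatLengthDistribution-class] with exact `trueMean`.
#' @examples
#' d <- simulateSomaticDistribution(2.0, contractionMass = 0)
#' trueMeanDelta(d)   # exactly 2
#' @export
simulateSomaticDistribution <- function(expansionRate, contractionMass = 0.15,
                                        tailShape = 0.3, mainRepeats = 109L,
                                        seed = NULL) {
    stopifnot(expansionRate >= 0, tailShape > 0, tailShape < 1,
              contractionMass >= 0, contractionMass < 1)
    q <- tailShape
    e <- expansionRate * (1 - q)          # total expansion mass
    if (e + contractionMass >= 1)
        stop("infeasible parameters: expansion + contraction mass >= 1 ",
             "(raise tailShape or lower the rates)")
    p0 <- 1 - e - contractionMass
    kmax <- if (e > 0) max(1L, ceiling(log(1e-16) / log(q))) else 0L
    delta <- integer(0); prob <- numeric(0)
    if (contractionMass > 0) {
        delta <- c(-2L, -1L)
        prob <- contractionMass * c(1, 2) / 3
    }
    delta <- c(delta, 0L); prob <- c(prob, p0)
    if (e > 0) {
        k <- seq_len(kmax)
        delta <- c(delta, k)
        prob <- c(prob, e * (1 - q) * q^(k - 1))
    }
    keep <- prob > 0 | delta == 0L
    RepeatLengthDistribution(mainRepeats + delta[keep], prob[keep],
                             mainAlleleRepeats = mainRepeats,
                             trueMean = expansionRate - 4 * contractionMass / 3)
}

# geometric minus-one-dominant stutter kernel over offsets -kmax..+1;
# mass sums to 1 (signal conservation before bias/noise)
.stutterKernel <- function(stutterRatio, plusRatio = 0) {
    stopifnot(stutterRatio >= 0, stutterRatio < 1, plusRatio >= 0,
              plusRatio < 1)
    kmax <- if (stutterRatio > 0)
        max(1L, ceiling(log(1e-12) / log(stutterRatio))) else 0L
    offset <- seq(-kmax, 1L)
    w <- ifelse(offset <= 0, stutterRatio^(-offset),
                ifelse(offset == 1L, plusRatio, 0))
    data.frame(offset = offset, weight = w / sum(w))
}

#' Render a repeat-length distribution as a fragment trace
#'
#' Emulates PCR amplification and capillary electrophoresis of a repeat
#' population: the length distribution is convolved with a minus-one-dominant
#' geometric stutter kernel (per-repeat slippage proportion `stutterRatio`,
#' optional `plusRatio` at +1), re-weighted by the relative amplification
#' advantage of shorter alleles \eqn{(1 + ampBias)^{-\Delta}}, scaled by
#' `scale` (models template amount), and perturbed by Gaussian height noise
#' truncated at zero.  Peak positions are placed at exact `unitSpacing`.
#'
#' With stutter, bias and noise all zero the rendered heights are exactly
#' proportional to the distribution, so the measured instability index (at a
#' vanishing threshold) equals the distribution's true mean.
#'
#' @param dist a [RepeatLengthDistribution-class].
#' @param stutterRatio per-repeat minus-one stutter proportion in `[0, 1)`
#'   (default 0.15).
#' @param plusRatio plus-one stutter proportion (default 0).
#' @param ampBias per-repeat relative amplification advantage of shorter
#'   alleles (\eqn{\ge 0}; default 0.01).
#' @param noiseSd height noise SD in RFU.
#' @param scale total signal multiplier (RFU); models ng of template DNA.
#' @param seed RNG seed for the noise draw.
#' @param unitSpacing bp per repeat.
#' @param sizeIntercept bp of flanking sequence (size = intercept +
#'   spacing x CAG).
#' @param sampleId,tissue trace metadata.
#' @return a [PeakTrace-class].
#' @export
renderTrace <- function(dist, stutterRatio = 0.15, plusRatio = 0,
                        ampBias = 0.01, noiseSd = 0, scale = 10000, seed = 1,
                        unitSpacing = 3, sizeIntercept = 80,
                        sampleId = NA_character_, tissue = NA_character_) {
    stopifnot(is(dist, "RepeatLengthDistribution"), ampBias >= 0, scale > 0)
    kern <- .stutterKernel(stutterRatio, plusRatio)
    cagIn <- dist@cagLength
    cagOut <- seq(min(cagIn) + min(kern$offset), max(cagIn) + max(kern$offset))
    sig <- numeric(length(cagOut))
    for (j in seq_len(nrow(kern))) {
        idx <- match(cagIn + kern$offset[j], cagOut)
        sig[idx] <- sig[idx] + dist@prob * kern$weight[j]
    }
    delta <- cagOut - dist@mainAlleleRepeats
    h <- scale * sig * (1 + ampBias)^(-delta)
    if (noiseSd > 0)
        h <- .withSeed(seed, pmax(0, h + rnorm(length(h), sd = noiseSd)))
    keep <- h > 0 & cagOut > 0
    PeakTrace(sizeIntercept + unitSpacing * cagOut[keep], h[keep],
              sampleId = sampleId, tissue = tissue)
}

#' Synthetic tissue panel presets
#'
#' One row per tissue of a 17-tissue panel (tail included) spanning the
#' observed range of tissue instability, from strongly unstable striatum
#' down to stable tissues whose traces read slightly negative.  For each
#' tissue the target index is the literature-scale instability index the
#' tissue should *measure* under the default rendering (stutter 0.15,
#' amplification bias 0.01, 20% threshold); `expansion_rate` and
#' `contraction_mass` were calibrated once, by root finding on the rendering
#' pipeline, so that the measured indices reproduce the targets.  The true
#' distribution means therefore differ from the targets: stutter, bias and
#' thresholding distort the measured value, exactly as they do on real
#' traces.  Stable tissues reach their negative targets through a larger
#' contracted-cell fraction; the two strongly expanding tissues carry a
#' smaller one (0.05), as expansion leaves few unchanged or contracted
#' cells.
#'
#' @return data.frame with columns `tissue, target_index, expansion_rate,
#'   contraction_mass, tail_shape`.
#' @export
tissuePresets <- function() .presetTable

#' Simulate a full tissue panel of fragment traces
#'
#' Generates one synthetic animal: a tail (constitutive) trace plus one trace
#' per preset tissue, all rendered with the same stutter/bias parameters, and
#' returns the traces together with the exact ground truth.
#'
#' @param presets preset table, by default [tissuePresets()].
#' @param noiseSd,scale,stutterRatio,ampBias rendering parameters, see
#'   [renderTrace()].
#' @param mainRepeats constitutive CAG count.
#' @param seed master RNG seed; each tissue derives its own sub-seed.
#' @param sampleId animal identifier.
#' @return list with elements `tail` (a [PeakTrace-class]), `tissues` (named
#'   list of traces) and `truth` (data.frame `tissue, target_index,
#'   true_mean`).
#' @export
simulateTissuePanel <- function(presets = tissuePresets(), noiseSd = 0,
                                scale = 10000, stutterRatio = 0.15,
                                ampBias = 0.01, mainRepeats = 109L, seed = 1,
                                sampleId = "sim1") {
    tailDist <- RepeatLengthDistribution(mainRepeats, 1,
                                         mainAlleleRepeats = mainRepeats,
                                         trueMean = 0)
    tailTrace <- renderTrace(tailDist, stutterRatio, 0, ampBias, noiseSd,
                             scale, seed = seed * 1000L + 999L,
                             sampleId = sampleId, tissue = "tail")
    traces <- vector("list", nrow(presets))
    names(traces) <- presets$tissue
    truth <- presets[, c("tissue", "target_index")]
    truth$true_mean <- NA_real_
    for (i in seq_len(nrow(presets))) {
        d <- simulateSomaticDistribution(presets$expansion_rate[i],
                                         presets$contraction_mass[i],
                                         presets$tail_shape[i], mainRepeats)
        truth$true_mean[i] <- trueMeanDelta(d)
        traces[[i]] <- renderTrace(d, stutterRatio, 0, ampBias, noiseSd,
                                   scale, seed = seed * 1000L + i,
                                   sampleId = sampleId,
                                   tissue = presets$tissue[i])
    }
    list(tail = tailTrace, tissues = traces, truth = truth)
}

#' Simulate an expression matrix with a planted instability signature
#'
#' Emulates a tissue expression atlas at normalised log2 scale: every probe
#' has a baseline drawn from N(8, 1); a planted subset of signature probes
#' additionally responds linearly to the tissue's true instability index with
#' slope `effectSize` (random sign per probe); residual noise of SD
#' `noiseSd` is independent per sample, so replicates of a tissue share the
#' tissue's signal but not its noise.  The phenotype attached to every
#' replicate is the tissue's true index.  Ground truth (planted probe ids,
#' slopes, true indices) is stored in the object's `metadata()` under
#' `"truth"`.
#'
#' @param trueIndex named numeric: true instability index per tissue (names =
#'   tissue labels).  Default: the 16 non-tail preset target indices.
#' @param nProbes total probes (default 20000).
#' @param nSignatureProbes planted signature size (default 150).
#' @param nReplicates expression replicates per tissue (default 2).
#' @param effectSize log2 expression change per index unit (default 0.25).
#' @param noiseSd residual log2 SD (default 0.25).
#' @param seed RNG seed; identical seeds give bit-identical output.
#' @return an [InstabilityExperiment-class].
#' @export
simulateExpression <- function(trueIndex = NULL, nProbes = 20000,
                               nSignatureProbes = 150, nReplicates = 2,
                               effectSize = 0.25, noiseSd = 0.25, seed = 1) {
    if (is.null(trueIndex)) {
        pr <- tissuePresets()
        pr <- pr[pr$tissue != "tail", ]
        trueIndex <- setNames(pr$target_index, pr$tissue)
    }
    stopifnot(nSignatureProbes <= nProbes, length(trueIndex) >= 3,
              !is.null(names(trueIndex)))
    nT <- length(trueIndex)
    probeIds <- sprintf("probe_%05d", seq_len(nProbes))
    sampleIds <- as.vector(t(outer(names(trueIndex),
                                   seq_len(nReplicates),
                                   function(t, r) paste0(t, "_r", r))))
    tissue <- rep(names(trueIndex), each = nReplicates)
    idx <- rep(unname(trueIndex), each = nReplicates)
    .withSeed(seed, {
        sigProbes <- sort(sample.int(nProbes, nSignatureProbes))
        slopes <- effectSize * sample(c(-1, 1), nSignatureProbes,
                                      replace = TRUE)
        baseline <- rnorm(nProbes, mean = 8, sd = 1)
        vals <- matrix(rnorm(nProbes * nT * nReplicates, sd = noiseSd),
                       nrow = nProbes) + baseline
        vals[sigProbes, ] <- vals[sigProbes, ] +
            outer(slopes, idx)
        dimnames(vals) <- list(probeIds, sampleIds)
        ex <- InstabilityExperiment(vals, tissue = tissue, phenotype = idx)
        S4Vectors::metadata(ex)$truth <- list(
            signatureProbes = probeIds[sigProbes],
            slopes = setNames(slopes, probeIds[sigProbes]),
            trueIndex = trueIndex,
            params = list(nProbes = nProbes,
                          nSignatureProbes = nSignatureProbes,
                          nReplicates = nReplicates, effectSize = effectSize,
                          noiseSd = noiseSd, seed = seed))
        ex
    })
}
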