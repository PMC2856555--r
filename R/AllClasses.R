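#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats cor lm coef pt rnorm runif sd setNames
#' @importFrom utils read.csv read.delim write.csv
NULL

## ---------------------------------------------------------------------------
## PeakTrace
## ---------------------------------------------------------------------------

#' Fragment-analysis peak trace
#'
#' A `PeakTrace` holds the peak list exported from fragment-analysis software
#' for one PCR/capillary run: fragment sizes in base pairs and peak heights in
#' relative fluorescence units (RFU).  Peaks are stored sorted by size; sizes
#' are strictly increasing and heights non-negative.
#'
#' @slot sampleId sample identifier (typically one mouse).
#' @slot tissue tissue label; the constitutive reference is conventionally
#'   `"tail"`.
#' @slot size numeric vector of fragment sizes (bp), strictly increasing.
#' @slot height numeric vector of peak heights (RFU), same length as `size`.
#'
#' @seealso [readPeakTable()], [detectMainAllele()], [buildLadder()]
#' @exportClass PeakTrace
setClass("PeakTrace",
    slots = c(sampleId = "character", tissue = "character",
              size = "numeric", height = "numeric"))

setValidity("PeakTrace", function(object) {
    msg <- NULL
    if (length(object@size) != length(object@height))
        msg <- c(msg, "size and height must have equal length")
    if (any(object@height < 0)) msg <- c(msg, "heights must be >= 0")
    if (any(object@size <= 0)) msg <- c(msg, "sizes must be > 0")
    if (length(object@size) > 1 && any(diff(object@size) <= 0))
        msg <- c(msg, "sizes must be strictly increasing")
    if (is.null(msg)) TRUE else msg
})

#' Construct a PeakTrace
#'
#' @param size fragment sizes in bp.
#' @param height peak heights in RFU.
#' @param sampleId,tissue sample metadata.
#' @return a [PeakTrace-class] with peaks sorted by size.
#' @examples
#' PeakTrace(c(150.1, 153.2), c(1000, 480), sampleId = "m1", tissue = "striatum")
#' @export
PeakTrace <- function(size, height, sampleId = NA_character_,
                      tissue = NA_character_) {
    o <- order(size)
    new("PeakTrace", sampleId = as.character(sampleId),
        tissue = as.character(tissue),
        size = as.numeric(size)[o], height = as.numeric(height)[o])
}

#' @describeIn PeakTrace-class number of peaks
#' @param x,object a `PeakTrace`
#' @export
setMethod("length", "PeakTrace", function(x) length(x@size))

#' @export
setMethod("show", "PeakTrace", function(object) {
    cat("PeakTrace:", object@sampleId, "/", object@tissue, "—",
        length(object@size), "peaks")
    if (length(object@size))
        cat(sprintf(" [%.1f–%.1f bp, max height %.0f RFU]",
                    min(object@size), max(object@size), max(object@height)))
    cat("\n")
})

#' Peak sizes and heights
#' @param x a [PeakTrace-class]
#' @return numeric vector.
#' @export
peakSizes <- function(x) x@size

#' @rdname peakSizes
#' @export
peakHeights <- function(x) x@height

## ---------------------------------------------------------------------------
## RepeatLadder
## ---------------------------------------------------------------------------

#' Repeat-unit ladder anchored to the constitutive (main) allele
#'
#' A `RepeatLadder` re-expresses a peak trace on an integer repeat-unit axis:
#' each entry maps a signed repeat change \eqn{\Delta} relative to the tail
#' main allele (expansions positive) to a peak height.  Exactly one entry per
#' \eqn{\Delta}.
#'
#' @slot delta integer vector of repeat-unit changes, sorted, unique.
#' @slot height heights (RFU) per delta.
#' @slot mainAlleleRepeats constitutive CAG count of the animal.
#' @slot unitSpacing nominal bp per repeat unit (3 for a trinucleotide).
#' @seealso [buildLadder()], [instabilityIndex()]
#' @exportClass RepeatLadder
setClass("RepeatLadder",
    slots = c(delta = "integer", height = "numeric",
              mainAlleleRepeats = "integer", unitSpacing = "numeric"))

setValidity("RepeatLadder", function(object) {
    msg <- NULL
    if (length(object@delta) != length(object@height))
        msg <- c(msg, "delta and height must have equal length")
    if (anyDuplicated(object@delta)) msg <- c(msg, "one entry per delta")
    if (length(object@delta) > 1 && is.unsorted(object@delta))
        msg <- c(msg, "delta must be sorted")
    if (any(object@height < 0)) msg <- c(msg, "heights must be >= 0")
    if (length(object@unitSpacing) != 1 || object@unitSpacing <= 0)
        msg <- c(msg, "unitSpacing must be a single positive number")
    if (is.null(msg)) TRUE else msg
})

#' Construct a RepeatLadder
#'
#' @param delta integer repeat changes relative to the main allele.
#' @param height peak heights (RFU).
#' @param mainAlleleRepeats constitutive CAG count (default 109, the knock-in
#'   allele the defaults emulate).
#' @param unitSpacing bp per repeat unit.
#' @return a [RepeatLadder-class].
#' @examples
#' RepeatLadder(c(-1, 0, 1), c(300, 1000, 500))
#' @export
RepeatLadder <- function(delta, height, mainAlleleRepeats = 109L,
                         unitSpacing = 3) {
    o <- order(delta)
    new("RepeatLadder", delta = as.integer(delta)[o],
        height = as.numeric(height)[o],
        mainAlleleRepeats = as.integer(mainAlleleRepeats),
        unitSpacing = as.numeric(unitSpacing))
}

#' @export
setMethod("length", "RepeatLadder", function(x) length(x@delta))

#' @export
setMethod("show", "RepeatLadder", function(object) {
    cat("RepeatLadder:", length(object@delta), "entries, main allele",
        object@mainAlleleRepeats, "repeats\n")
    if (length(object@delta)) {
        d <- object@delta
        cat("  delta range:", min(d), "..", max(d), "\n")
    }
})

#' Ladder accessors
#' @param x a [RepeatLadder-class]
#' @return integer (`ladderDeltas`) or numeric (`ladderHeights`) vector.
#' @export
ladderDeltas <- function(x) x@delta

#' @rdname ladderDeltas
#' @export
ladderHeights <- function(x) x@height

## ---------------------------------------------------------------------------
## InstabilityProfile
## ---------------------------------------------------------------------------

#' Instability metric family for one tissue analysis
#'
#' Bundles every metric of the relative peak-height threshold family computed
#' from one tissue ladder: the instability index (mean repeat-unit change from
#' the main allele per cell), the expansion/contraction split, above-threshold
#' peak counts, the percent composition of contracted/unchanged/expanded
#' signal, and the main-allele shift.
#'
#' By construction `instabilityIndex == expansionIndex + contractionIndex`
#' and the three composition percentages sum to 100.
#'
#' @slot instabilityIndex mean \eqn{\Delta}CAG per cell.
#' @slot expansionIndex non-negative contribution of expanded peaks.
#' @slot contractionIndex non-positive contribution of contracted peaks.
#' @slot nContracted,nExpanded above-threshold peak counts.
#' @slot composition named percentages (contracted, unchanged, expanded).
#' @slot mainAlleleShift signed repeat-unit shift of the tissue's highest peak
#'   relative to the tail main allele.
#' @slot thresholdFactor the relative threshold used.
#' @exportClass InstabilityProfile
setClass("InstabilityProfile",
    slots = c(instabilityIndex = "numeric", expansionIndex = "numeric",
              contractionIndex = "numeric", nContracted = "integer",
              nExpanded = "integer", composition = "numeric",
              mainAlleleShift = "integer", thresholdFactor = "numeric"))

setValidity("InstabilityProfile", function(object) {
    msg <- NULL
    if (!isTRUE(all.equal(unname(object@instabilityIndex),
                          unname(object@expansionIndex + object@contractionIndex),
                          tolerance = 1e-8)))
        msg <- c(msg, "index must equal expansion + contraction")
    if (length(object@composition) != 3 ||
        abs(sum(object@composition) - 100) > 1e-6)
        msg <- c(msg, "composition must be 3 percentages summing to 100")
    if (object@nContracted < 0 || object@nExpanded < 0)
        msg <- c(msg, "peak counts must be >= 0")
    if (is.null(msg)) TRUE else msg
})

#' @export
setMethod("show", "InstabilityProfile", function(object) {
    cat(sprintf("InstabilityProfile (threshold %.0f%% of highest peak)\n",
                100 * object@thresholdFactor))
    cat(sprintf("  instability index : %8.4f\n", object@instabilityIndex))
    cat(sprintf("  expansion index   : %8.4f   contraction index: %8.4f\n",
                object@expansionIndex, object@contractionIndex))
    cat(sprintf("  peaks (contr/exp) : %d / %d    main-allele shift: %+d\n",
                object@nContracted, object@nExpanded, object@mainAlleleShift))
    cat(sprintf("  composition %%     : %.2f contracted / %.2f unchanged / %.2f expanded\n",
                object@composition[["contracted"]],
                object@composition[["unchanged"]],
                object@composition[["expanded"]]))
})

#' @export
#' @describeIn InstabilityProfile-class one-row data.frame, the tidy batch format
#' @param x an `InstabilityProfile`
#' @param row.names,optional,... ignored (base-generic signature)
setMethod("as.data.frame", "InstabilityProfile",
    function(x, row.names = NULL, optional = FALSE, ...) {
        data.frame(instability_index = x@instabilityIndex,
                   expansion_index = x@expansionIndex,
                   contraction_index = x@contractionIndex,
                   n_contracted = x@nContracted, n_expanded = x@nExpanded,
                   pct_contracted = x@composition[["contracted"]],
                   pct_unchanged = x@composition[["unchanged"]],
                   pct_expanded = x@composition[["expanded"]],
                   main_allele_shift = x@mainAlleleShift,
                   threshold_factor = x@thresholdFactor)
    })

## ---------------------------------------------------------------------------
## RepeatLengthDistribution
## ---------------------------------------------------------------------------

#' Single-molecule repeat-length distribution
#'
#' The per-molecule CAG length frequency distribution produced by small-pool
#' PCR, or by the somatic-instability simulator.  Lengths are absolute CAG
#' counts; `prob` holds frequencies (normalised on construction).  Simulated
#' distributions additionally record `trueMean`, the exact mean repeat-unit
#' change from the main allele — the ground truth the rendering identity
#' tests score against.
#'
#' @slot cagLength integer CAG repeat lengths, sorted, unique.
#' @slot prob frequencies summing to 1.
#' @slot mainAlleleRepeats constitutive CAG count.
#' @slot trueMean exact mean of `cagLength - mainAlleleRepeats` under `prob`
#'   (NA for observed data loaded from file).
#' @seealso [simulateSomaticDistribution()], [smallPoolIndex()]
#' @exportClass RepeatLengthDistribution
setClass("RepeatLengthDistribution",
    slots = c(cagLength = "integer", prob = "numeric",
              mainAlleleRepeats = "integer", trueMean = "numeric"))

setValidity("RepeatLengthDistribution", function(object) {
    msg <- NULL
    if (length(object@cagLength) != length(object@prob))
        msg <- c(msg, "cagLength and prob must have equal length")
    if (!length(object@prob) || all(object@prob <= 0))
        msg <- c(msg, "at least one positive entry required")
    if (any(object@prob < 0)) msg <- c(msg, "frequencies must be >= 0")
    if (anyDuplicated(object@cagLength))
        msg <- c(msg, "one entry per CAG length")
    if (is.null(msg)) TRUE else msg
})

#' Construct a RepeatLengthDistribution
#'
#' @param cagLength integer CAG lengths.
#' @param count non-negative counts or frequencies (normalised internally).
#' @param mainAlleleRepeats constitutive CAG count.
#' @param trueMean exact simulated mean delta, if known.
#' @return a [RepeatLengthDistribution-class].
#' @export
RepeatLengthDistribution <- function(cagLength, count,
                                     mainAlleleRepeats = 109L,
                                     trueMean = NA_real_) {
    o <- order(cagLength)
    count <- as.numeric(count)[o]
    if (sum(count) <= 0) stop("distribution has no positive mass")
    new("RepeatLengthDistribution", cagLength = as.integer(cagLength)[o],
        prob = count / sum(count),
        mainAlleleRepeats = as.integer(mainAlleleRepeats),
        trueMean = as.numeric(trueMean))
}

#' @export
setMethod("show", "RepeatLengthDistribution", function(object) {
    cat("RepeatLengthDistribution:", length(object@cagLength),
        "lengths, main allele", object@mainAlleleRepeats, "\n")
    if (!is.na(object@trueMean))
        cat(sprintf("  true mean delta: %.4f repeats\n", object@trueMean))
})

#' @rdname RepeatLengthDistribution
#' @param object a `RepeatLengthDistribution`
#' @return `trueMeanDelta`: the exact simulated mean repeat change (NA for
#'   observed data).
#' @export
trueMeanDelta <- function(object) object@trueMean

## ---------------------------------------------------------------------------
## InstabilityExperiment
## ---------------------------------------------------------------------------

#' Expression matrix with instability phenotype
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass holding log2
#' expression (assay `"log2expr"`, probes x samples) plus per-sample column
#' data: `tissue` (replicates of one tissue share a label) and
#' `instability_index` (the measured phenotype; `NA` for prediction-only
#' samples).  The assay must be complete — no missing values.
#'
#' @seealso [simulateExpression()], [rankProbes()], [fitSignatureModel()]
#' @exportClass InstabilityExperiment
setClass("InstabilityExperiment",
    contains = "SummarizedExperiment")

setValidity("InstabilityExperiment", function(object) {
    msg <- NULL
    if (!"log2expr" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'log2expr' required")
    else if (anyNA(SummarizedExperiment::assay(object, "log2expr")))
        msg <- c(msg, "expression values must not contain NA")
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("tissue", "instability_index") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'tissue' and 'instability_index'")
    if (is.null(msg)) TRUE else msg
})

#' Construct an InstabilityExperiment
#'
#' @param values probes x samples matrix of log2 expression (rownames = probe
#'   ids, colnames = sample ids).
#' @param tissue per-sample tissue labels.
#' @param phenotype per-sample instability index; `NA` marks prediction-only
#'   samples.  Default: all `NA`.
#' @return an [InstabilityExperiment-class].
#' @export
InstabilityExperiment <- function(values, tissue, phenotype = NULL) {
    values <- as.matrix(values)
    if (is.null(phenotype)) phenotype <- rep(NA_real_, ncol(values))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(log2expr = values),
        colData = S4Vectors::DataFrame(tissue = as.character(tissue),
                                       instability_index = as.numeric(phenotype),
                                       row.names = colnames(values)))
    new("InstabilityExperiment", se)
}

#' Accessors for InstabilityExperiment
#'
#' `exprValues` returns the log2 expression matrix, `phenotype` the
#' per-sample instability index (NA where unmeasured) and `tissueOf` the
#' per-sample tissue label.
#'
#' @param x an [InstabilityExperiment-class]
#' @return matrix / numeric / character respectively.
#' @export
exprValues <- function(x) SummarizedExperiment::assay(x, "log2expr")

#' @rdname exprValues
#' @export
phenotype <- function(x) {
    setNames(SummarizedExperiment::colData(x)$instability_index, colnames(x))
}

#' @rdname exprValues
#' @export
tissueOf <- function(x) {
    setNames(as.character(SummarizedExperiment::colData(x)$tissue), colnames(x))
}

#' @export
setMethod("show", "InstabilityExperiment", function(object) {
    ph <- phenotype(object)
    cat("InstabilityExperiment:", nrow(object), "probes x", ncol(object),
        "samples,", length(unique(tissueOf(object))), "tissues;",
        sum(!is.na(ph)), "samples with measured instability\n")
})

## ---------------------------------------------------------------------------
## SignatureModel
## ---------------------------------------------------------------------------

#' Instability-correlated expression signature and PLSR model
#'
#' Holds the full probe ranking (Pearson r against the instability phenotype
#' with two-sided p), the selected signature, the fitted partial least squares
#' regression coefficients mapped back to original probe space, and the
#' leave-one-tissue-out RMSEP curve that selected the signature size.
#'
#' @slot ranking data.frame `probe, r, p, flagged` sorted by p (flagged
#'   zero-variance probes last).
#' @slot probes the selected signature probe ids, in ranking order.
#' @slot nSelected signature size (argmin of the CV curve; ties -> smaller).
#' @slot nComponents PLSR latent components of the final fit.
#' @slot coefficients regression weights in original probe space (named).
#' @slot intercept model intercept.
#' @slot cvCurve data.frame `n, rmsep`.
#' @seealso [fitSignatureModel()], [predictIndex()]
#' @exportClass SignatureModel
setClass("SignatureModel",
    slots = c(ranking = "data.frame", probes = "character",
              nSelected = "integer", nComponents = "integer",
              coefficients = "numeric", intercept = "numeric",
              cvCurve = "data.frame"))

setValidity("SignatureModel", function(object) {
    msg <- NULL
    if (length(object@probes) != object@nSelected)
        msg <- c(msg, "probes must have length nSelected")
    if (length(object@coefficients) != length(object@probes))
        msg <- c(msg, "one coefficient per signature probe")
    if (nrow(object@cvCurve)) {
        best <- object@cvCurve$n[which.min(object@cvCurve$rmsep)]
        if (best != object@nSelected)
            msg <- c(msg, "nSelected must minimise the CV curve")
    }
    if (is.null(msg)) TRUE else msg
})

#' @export
setMethod("show", "SignatureModel", function(object) {
    cat("SignatureModel:", object@nSelected, "probes,",
        object@nComponents, "PLS component(s)\n")
    if (nrow(object@cvCurve))
        cat(sprintf("  LOO RMSEP at selected size: %.4f\n",
                    min(object@cvCurve$rmsep)))
})

#' Signature model accessors
#' @param model a [SignatureModel-class]
#' @return `signatureProbes`: character vector of selected probe ids;
#'   `cvCurve`: data.frame of signature size vs LOO RMSEP; `probeRanking`:
#'   the full ranking table.
#' @export
signatureProbes <- function(model) model@probes

#' @rdname signatureProbes
#' @export
cvCurve <- function(model) model@cvCurve

#' @rdname signatureProbes
#' @export
probeRanking <- function(model) model@ranking
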