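## The relative peak-height threshold metric family.
##
## All metrics share the same background correction: within one analysis the
## threshold is a fixed fraction (default 20%) of that analysis' highest peak,
## and every peak below it is excluded before normalisation.  All metrics are
## therefore invariant to uniform scaling of heights (template-DNA amount).

#' Apply the relative peak-height threshold
#'
#' Removes every ladder entry whose height falls below
#' `thresholdFactor * max(height)` of the same ladder.  The highest entry
#' always survives; entries exactly at the threshold are kept.
#'
#' @param ladder a [RepeatLadder-class]; must be non-empty.
#' @param thresholdFactor fraction of the highest peak in `(0, 1]`.  The
#'   default 0.20 is conservative; 0.10 or 0.05 give more sensitive
#'   quantification when signal is strong.
#' @return the thresholded [RepeatLadder-class].
#' @examples
#' ld <- RepeatLadder(c(-1, 0, 1), c(190, 1000, 210))
#' applyThreshold(ld, 0.20)   # drops the -1 entry (190 < 200)
#' @export
applyThreshold <- function(ladder, thresholdFactor = 0.20) {
    .checkLadder(ladder, thresholdFactor)
    thr <- thresholdFactor * max(ladder@height)
    keep <- ladder@height >= thr
    RepeatLadder(ladder@delta[keep], ladder@height[keep],
                 mainAlleleRepeats = ladder@mainAlleleRepeats,
                 unitSpacing = ladder@unitSpacing)
}

.checkLadder <- function(ladder, thresholdFactor) {
    if (!length(ladder@delta)) stop("ladder has no entries")
    if (thresholdFactor <= 0 || thresholdFactor > 1)
        stop("thresholdFactor must be in (0, 1]")
    invisible(TRUE)
}

# normalized weights over above-threshold entries
.normalizedLadder <- function(ladder, thresholdFactor) {
    ld <- applyThreshold(ladder, thresholdFactor)
    list(delta = ld@delta, w = ld@height / sum(ld@height))
}

#' Instability index
#'
#' The height-normalised mean repeat-unit change from the main allele per
#' cell.  After thresholding, each peak height is divided by the summed
#' height of all signal peaks, multiplied by its repeat change
#' \eqn{\Delta} from the tail main allele, and the products are summed:
#' \deqn{I = \sum_\Delta \frac{h_\Delta}{\sum h}\,\Delta.}
#' A symmetric distribution of contraction and expansion gives exactly 0.
#'
#' @inheritParams applyThreshold
#' @return the index (repeat units per cell); negative values indicate net
#'   contraction and are reported as-is.
#' @examples
#' ld <- RepeatLadder(c(-1, 0, 1, 2), c(300, 1000, 500, 250))
#' instabilityIndex(ld)          # 700/2050
#' @export
instabilityIndex <- function(ladder, thresholdFactor = 0.20) {
    n <- .normalizedLadder(ladder, thresholdFactor)
    sum(n$w * n$delta)
}

#' Expansion and contraction indices
#'
#' Splits the instability index into the contribution of expanded
#' (\eqn{\Delta > 0}) and contracted (\eqn{\Delta < 0}) peaks.  Both use the
#' shared denominator (sum over all above-threshold peaks), so
#' `expansion + contraction == instabilityIndex` exactly.
#'
#' @inheritParams applyThreshold
#' @return named numeric `c(expansion=, contraction=)`.
#' @export
expansionContractionIndices <- function(ladder, thresholdFactor = 0.20) {
    n <- .normalizedLadder(ladder, thresholdFactor)
    c(expansion = sum(n$w[n$delta > 0] * n$delta[n$delta > 0]),
      contraction = sum(n$w[n$delta < 0] * n$delta[n$delta < 0]))
}

#' Above-threshold peak counts
#'
#' @inheritParams applyThreshold
#' @return named integer `c(contracted=, expanded=)`.
#' @export
peakCounts <- function(ladder, thresholdFactor = 0.20) {
    n <- .normalizedLadder(ladder, thresholdFactor)
    c(contracted = sum(n$delta < 0), expanded = sum(n$delta > 0))
}

#' Percent composition of contracted / unchanged / expanded signal
#'
#' Shares of the summed above-threshold height carried by peaks with
#' \eqn{\Delta < 0}, \eqn{\Delta = 0} and \eqn{\Delta > 0}; sums to 100.
#'
#' @inheritParams applyThreshold
#' @return named numeric percentages `c(contracted=, unchanged=, expanded=)`.
#' @export
composition <- function(ladder, thresholdFactor = 0.20) {
    n <- .normalizedLadder(ladder, thresholdFactor)
    100 * c(contracted = sum(n$w[n$delta < 0]),
            unchanged = sum(n$w[n$delta == 0]),
            expanded = sum(n$w[n$delta > 0]))
}

#' Main-allele shift
#'
#' The repeat-unit position of the tissue analysis' highest above-threshold
#' peak relative to the tail main allele (0 = no shift, +1 = one repeat
#' gained).  Exact height ties resolve to the smaller \eqn{\Delta}.
#'
#' @param tissueLadder tissue [RepeatLadder-class] anchored to the tail main
#'   allele.
#' @param tailLadder optional tail ladder; if supplied, the shift is taken
#'   relative to the tail's own highest peak (which is \eqn{\Delta = 0} by
#'   construction when the tail was used as anchor).
#' @inheritParams applyThreshold
#' @return integer shift.
#' @export
mainAlleleShift <- function(tissueLadder, tailLadder = NULL,
                            thresholdFactor = 0.20) {
    modeOf <- function(ladder) {
        ld <- applyThreshold(ladder, thresholdFactor)
        ld@delta[which(ld@height == max(ld@height))[1L]]  # deltas sorted
    }
    ref <- if (is.null(tailLadder)) 0L else modeOf(tailLadder)
    as.integer(modeOf(tissueLadder) - ref)
}

#' Small-pool PCR instability index
#'
#' From a single-molecule CAG repeat-length frequency distribution: the
#' frequency of each length is multiplied by its repeat distance (+ or -)
#' from the modal length and the products are summed.  Frequencies are
#' normalised to sum to 1; a modal tie resolves to the smaller length.
#'
#' @param dist a [RepeatLengthDistribution-class], or a data.frame with
#'   columns `cag_length,count` as read by [readSmallPool()].
#' @return the small-pool instability index (repeat units).
#' @examples
#' smallPoolIndex(RepeatLengthDistribution(100:102, c(50, 30, 20)))  # 0.7
#' @export
smallPoolIndex <- function(dist) {
    if (is.data.frame(dist)) {
        if (!all(c("cag_length", "count") %in% colnames(dist)))
            stop("table input needs columns cag_length,count")
        dist <- RepeatLengthDistribution(dist$cag_length, dist$count)
    }
    if (!is(dist, "RepeatLengthDistribution"))
        stop("dist must be a RepeatLengthDistribution or cag_length/count table")
    len <- dist@cagLength
    p <- dist@prob
    modal <- len[which(p == max(p))[1L]]  # lengths sorted ascending
    sum(p * (len - modal))
}

#' Read a small-pool PCR length table
#'
#' CSV with columns `cag_length,count`.
#'
#' @param path file path.
#' @param mainAlleleRepeats constitutive CAG count, if known.
#' @return a [RepeatLengthDistribution-class].
#' @export
readSmallPool <- function(path, mainAlleleRepeats = 109L) {
    tab <- read.csv(path)
    if (!all(c("cag_length", "count") %in% colnames(tab)))
        stop("small-pool table needs columns cag_length,count")
    RepeatLengthDistribution(tab$cag_length, tab$count,
                             mainAlleleRepeats = mainAlleleRepeats)
}

#' Full instability profile of one tissue analysis
#'
#' Computes the whole metric family for a tissue ladder anchored to the tail
#' main allele.
#'
#' @inheritParams mainAlleleShift
#' @return an [InstabilityProfile-class].
#' @export
instabilityProfile <- function(tissueLadder, tailLadder = NULL,
                               thresholdFactor = 0.20) {
    ec <- expansionContractionIndices(tissueLadder, thresholdFactor)
    cnt <- peakCounts(tissueLadder, thresholdFactor)
    new("InstabilityProfile",
        instabilityIndex = instabilityIndex(tissueLadder, thresholdFactor),
        expansionIndex = unname(ec["expansion"]),
        contractionIndex = unname(ec["contraction"]),
        nContracted = as.integer(cnt["contracted"]),
        nExpanded = as.integer(cnt["expanded"]),
        composition = composition(tissueLadder, thresholdFactor),
        mainAlleleShift = mainAlleleShift(tissueLadder, tailLadder,
                                          thresholdFactor),
        thresholdFactor = thresholdFactor)
}

#' Batch instability quantification
#'
#' Runs the full pipeline for every tissue row of a manifest: read the tail
#' trace, threshold it and locate the main allele, anchor both tail and
#' tissue traces to it, and compute the instability profile.  Tissue rows are
#' paired with the tail row sharing their `sample_id`.
#'
#' @param manifest data.frame from [readManifest()] (columns
#'   `sample_id,tissue,role,path`).
#' @param thresholdFactor relative threshold (default 0.20).
#' @param unitSpacing,tolerance,recalibrate passed to [buildLadder()].
#' @param mainRepeats constitutive CAG count of the line.
#' @param dialect peak-table dialect, see [readPeakTable()].
#' @return tidy data.frame, one row per tissue sample, with columns
#'   `sample_id, tissue, instability_index, expansion_index,
#'   contraction_index, n_contracted, n_expanded, pct_contracted,
#'   pct_unchanged, pct_expanded, main_allele_shift, threshold_factor`.
#' @export
quantifyInstability <- function(manifest, thresholdFactor = 0.20,
                                unitSpacing = 3, tolerance = 1,
                                recalibrate = FALSE, mainRepeats = 109L,
                                dialect = "generic_csv") {
    tails <- manifest[manifest$role == "tail", , drop = FALSE]
    tissues <- manifest[manifest$role == "tissue", , drop = FALSE]
    out <- vector("list", nrow(tissues))
    for (i in seq_len(nrow(tissues))) {
        row <- tissues[i, ]
        tl <- tails[tails$sample_id == row$sample_id, , drop = FALSE]
        if (!nrow(tl))
            stop("no tail analysis in manifest for sample ", row$sample_id)
        tailTrace <- readPeakTable(tl$path[1], dialect, tl$sample_id[1], "tail")
        # tail gets the same background correction before anchoring; harmless
        # for main-allele detection since the highest peak always survives
        keep <- tailTrace@height >= thresholdFactor * max(tailTrace@height)
        tailTrace <- PeakTrace(tailTrace@size[keep], tailTrace@height[keep],
                               tailTrace@sampleId, tailTrace@tissue)
        main <- detectMainAllele(tailTrace)
        tissueTrace <- readPeakTable(row$path, dialect, row$sample_id,
                                     row$tissue)
        tissueLadder <- buildLadder(tissueTrace, main$size, mainRepeats,
                                    unitSpacing, tolerance, recalibrate)
        tailLadder <- buildLadder(tailTrace, main$size, mainRepeats,
                                  unitSpacing, tolerance, recalibrate)
        prof <- instabilityProfile(tissueLadder, tailLadder, thresholdFactor)
        out[[i]] <- cbind(data.frame(sample_id = row$sample_id,
                                     tissue = row$tissue),
                          as.data.frame(prof))
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
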