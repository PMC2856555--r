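## Parsing fragment-analyzer peak exports and anchoring them to an integer
## repeat-unit ladder.

#' Read a fragment-analysis peak table
#'
#' Parses a peak export into a [PeakTrace-class].  Two dialects are
#' supported: `generic_csv` (comma-separated, header `size,height`) and
#' `genemapper_tsv` (tab-separated with columns `Size` and `Height`; any
#' extra columns are ignored).  Rows with missing or negative heights are
#' dropped with a warning giving the count; peaks are returned sorted by
#' size.
#'
#' @param path file path.
#' @param dialect `"generic_csv"` or `"genemapper_tsv"`.
#' @param sampleId,tissue metadata attached to the trace.
#' @return a [PeakTrace-class].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("size,height", "150.1,1000", "153.2,480"), f)
#' readPeakTable(f)
#' @export
readPeakTable <- function(path, dialect = c("generic_csv", "genemapper_tsv"),
                          sampleId = NA_character_, tissue = NA_character_) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop("file not found: ", path)
    tab <- tryCatch(
        if (dialect == "generic_csv") read.csv(path, check.names = FALSE)
        else read.delim(path, check.names = FALSE),
        error = function(e) stop("empty or unreadable peak table: ", path))
    wanted <- if (dialect == "generic_csv") c("size", "height")
              else c("Size", "Height")
    if (!all(wanted %in% colnames(tab)))
        stop("peak table ", path, " lacks required column(s): ",
             paste(setdiff(wanted, colnames(tab)), collapse = ", "))
    size <- as.numeric(tab[[wanted[1]]])
    height <- as.numeric(tab[[wanted[2]]])
    bad <- is.na(size) | is.na(height) | height < 0
    if (any(bad))
        warning(sum(bad), " row(s) with missing/negative values dropped from ",
                basename(path))
    size <- size[!bad]; height <- height[!bad]
    if (!length(size)) stop("empty trace: no usable peaks in ", path)
    PeakTrace(size, height, sampleId = sampleId, tissue = tissue)
}

#' Write a peak table in a readable dialect
#'
#' Inverse of [readPeakTable()]; the emitted file round-trips.
#'
#' @param trace a [PeakTrace-class].
#' @param path output file.
#' @param dialect see [readPeakTable()].
#' @return `path`, invisibly.
#' @export
writePeakTable <- function(trace, path,
                           dialect = c("generic_csv", "genemapper_tsv")) {
    dialect <- match.arg(dialect)
    df <- data.frame(size = trace@size, height = trace@height)
    if (dialect == "generic_csv") {
        write.csv(df, path, row.names = FALSE, quote = FALSE)
    } else {
        colnames(df) <- c("Size", "Height")
        utils::write.table(df, path, sep = "\t", row.names = FALSE,
                           quote = FALSE)
    }
    invisible(path)
}

#' Locate the main (constitutive) allele in a tail trace
#'
#' Returns the highest peak of the trace; on an exact height tie the peak
#' with the smaller fragment size wins, consistent with the constitutive
#' allele preceding its expansion products.
#'
#' @param trace a [PeakTrace-class]; normally the tail analysis of the mouse.
#' @return list with elements `size` (bp) and `height` (RFU).
#' @examples
#' detectMainAllele(PeakTrace(c(150, 153), c(1000, 480)))
#' @export
detectMainAllele <- function(trace) {
    if (!length(trace@size)) stop("cannot detect main allele in empty trace")
    i <- which(trace@height == max(trace@height))[1L]  # sizes sorted ascending
    list(size = trace@size[i], height = trace@height[i])
}

#' Convert a peak trace to a repeat-unit ladder
#'
#' Assigns each peak an integer repeat change
#' \eqn{\Delta = \mathrm{round}((size - mainSize)/unitSpacing)} relative to
#' the main allele.  Peaks whose residual from the ideal rung position
#' exceeds `tolerance` are rejected (with a warning giving the count); two
#' peaks mapping to the same \eqn{\Delta} are treated as a split peak and
#' their heights summed.
#'
#' Electrophoretic mobility can drift slightly from the nominal 3 bp per
#' repeat; with `recalibrate = TRUE` a single refinement pass re-estimates
#' spacing and anchor by least squares (size ~ assigned \eqn{\Delta}) and
#' re-assigns.
#'
#' @param trace a [PeakTrace-class].
#' @param mainSize fragment size (bp) of the tail main allele.
#' @param mainRepeats constitutive CAG count corresponding to `mainSize`.
#' @param unitSpacing nominal bp per repeat (default 3).
#' @param tolerance maximum residual (bp) from the ideal rung; must be below
#'   `unitSpacing / 2`.
#' @param recalibrate run the one-pass spacing refinement.
#' @return a [RepeatLadder-class].
#' @examples
#' tr <- PeakTrace(c(150.0, 153.1, 156.0), c(1000, 500, 200))
#' buildLadder(tr, mainSize = 150, mainRepeats = 109)
#' @export
buildLadder <- function(trace, mainSize, mainRepeats = 109L, unitSpacing = 3,
                        tolerance = 1, recalibrate = FALSE) {
    stopifnot(unitSpacing > 0)
    if (tolerance >= unitSpacing / 2)
        stop("tolerance must be below unitSpacing/2 for unambiguous assignment")
    assign1 <- function(sizes, anchor, spacing) {
        delta <- round((sizes - anchor) / spacing)
        resid <- sizes - anchor - delta * spacing
        list(delta = as.integer(delta), ok = abs(resid) <= tolerance)
    }
    a <- assign1(trace@size, mainSize, unitSpacing)
    if (recalibrate && sum(a$ok) >= 2 &&
        length(unique(a$delta[a$ok])) >= 2) {
        fit <- lm(trace@size[a$ok] ~ a$delta[a$ok])
        a <- assign1(trace@size, unname(coef(fit)[1]), unname(coef(fit)[2]))
    }
    if (any(!a$ok))
        warning(sum(!a$ok), " peak(s) rejected: off-ladder residual beyond ",
                tolerance, " bp")
    delta <- a$delta[a$ok]
    height <- trace@height[a$ok]
    if (!length(delta))
        return(RepeatLadder(integer(0), numeric(0),
                            mainAlleleRepeats = mainRepeats,
                            unitSpacing = unitSpacing))
    h <- tapply(height, delta, sum)
    RepeatLadder(as.integer(names(h)), as.numeric(h),
                 mainAlleleRepeats = mainRepeats, unitSpacing = unitSpacing)
}

#' Read a sample manifest
#'
#' The manifest pairs every tissue peak table with the tail (constitutive
#' reference) analysis of the same animal.  Required columns:
#' `sample_id,tissue,role,path` with `role` one of `tail`/`tissue`; `path`
#' is resolved relative to `dir` unless absolute.
#'
#' @param path manifest CSV.
#' @param dir base directory for relative paths (default: the manifest's).
#' @return data.frame with resolved paths.
#' @export
readManifest <- function(path, dir = dirname(path)) {
    m <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "tissue", "role", "path")
    if (!all(need %in% colnames(m)))
        stop("manifest lacks required column(s): ",
             paste(setdiff(need, colnames(m)), collapse = ", "))
    if (!all(m$role %in% c("tail", "tissue")))
        stop("manifest role must be 'tail' or 'tissue'")
    rel <- !grepl("^(/|[A-Za-z]:)", m$path)
    m$path[rel] <- file.path(dir, m$path[rel])
    m
}
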