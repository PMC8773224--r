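# The four per-well photoconversion metrics and the Pre-Parabola
# baseline subtraction.
#
# Per-well aggregation pools objects across the well's imaged fields
# before computing ratios (ratio of sums, not mean of per-field
# ratios).

#' Conversion rate of an object table
#'
#' Percentage of green fluorescent cells that also display red
#' fluorescence: 100 * merged / (green-only + merged). Red-only objects
#' (typically debris) are excluded from the denominator. With no green
#' cells the value is a flagged missing value (\code{NA}), not zero.
#'
#' @param objects object table (possibly pooled over fields) from
#'   \code{\link{classifyObjects}}.
#' @return conversion rate in percent, or \code{NA} if no green cells.
#' @export
conversionRate <- function(objects) {
    nMerged <- sum(objects$class == "merged")
    nGreen <- nMerged + sum(objects$class == "green-only")
    if (nGreen == 0L) return(NA_real_)
    100 * nMerged / nGreen
}

#' Red-intensity metrics of an object table
#'
#' The three fluorescence-intensity metrics: mean red intensity over
#' all red-detected cells (merged + red-only), mean red intensity of
#' merged cells, and the well's integrated red intensity (sum over
#' detected red objects) divided by the number of merged cells.
#' Metrics with an empty denominator are flagged \code{NA}.
#'
#' @param objects object table, pooled over the well's fields.
#' @return named numeric: \code{redMeanAll}, \code{mergedRedMean},
#'   \code{redIntegratedPerWell}.
#' @export
intensityMetrics <- function(objects) {
    redRows <- objects[objects$class %in% c("merged", "red-only"), ,
                       drop = FALSE]
    mergedRows <- objects[objects$class == "merged", , drop = FALSE]
    nMerged <- nrow(mergedRows)
    c(redMeanAll = if (nrow(redRows)) mean(redRows$meanRed) else NA_real_,
      mergedRedMean = if (nMerged) mean(mergedRows$meanRed) else NA_real_,
      redIntegratedPerWell = if (nMerged)
          sum(redRows$integratedRed) / nMerged else NA_real_)
}

#' Per-well metrics from pooled object tables
#'
#' Pools the object tables of a well's fields and computes counts, the
#' conversion rate and the three red-intensity metrics.
#'
#' @param objects a single object table or a list of per-field tables
#'   to pool.
#' @param well well identifier.
#' @return one-row data.frame: well, nGreen, nMerged, nRedOnly,
#'   conversionRate, redMeanAll, mergedRedMean, redIntegratedPerWell.
#' @export
computeWellMetrics <- function(objects, well = NA_character_) {
    if (is.list(objects) && !is.data.frame(objects))
        objects <- do.call(rbind, objects)
    nMerged <- sum(objects$class == "merged")
    im <- intensityMetrics(objects)
    data.frame(well = well,
               nGreen = nMerged + sum(objects$class == "green-only"),
               nMerged = nMerged,
               nRedOnly = sum(objects$class == "red-only"),
               conversionRate = conversionRate(objects),
               redMeanAll = im[["redMeanAll"]],
               mergedRedMean = im[["mergedRedMean"]],
               redIntegratedPerWell = im[["redIntegratedPerWell"]],
               stringsAsFactors = FALSE)
}

#' Pre-Parabola baseline subtraction
#'
#' Subtracts the basal (Pre-Parabola) conversion rate from the rates of
#' the other phases to remove photoconversion driven by basal Ca2+.
#' Negative results are preserved, not clipped.
#'
#' For the data.frame method, rows are grouped by \code{groupCols}, the
#' reference is the mean rate of the \code{refPhase} rows in each
#' group, and an \code{adjustedRate} column is added. A group without a
#' reference row is an error.
#'
#' @param rates numeric vector of rates, or a data.frame with a rate
#'   column and a phase column.
#' @param pre scalar Pre-Parabola reference rate (vector method).
#' @param rateCol,phaseCol,groupCols,refPhase data.frame method fields.
#' @return adjusted rates (vector), or the data.frame with an
#'   \code{adjustedRate} column.
#' @export
setGeneric("baselineSubtract", function(rates, pre, ...)
    standardGeneric("baselineSubtract"))

#' @rdname baselineSubtract
#' @param ... passed on to methods.
#' @export
setMethod("baselineSubtract", signature(rates = "numeric", pre = "numeric"),
    function(rates, pre, ...) {
        if (length(pre) != 1L || is.na(pre))
            stop("missing Pre-Parabola reference")
        rates - pre
    })

#' @rdname baselineSubtract
#' @export
setMethod("baselineSubtract", signature(rates = "data.frame", pre = "missing"),
    function(rates, pre, rateCol = "conversionRate", phaseCol = "role",
             groupCols = character(), refPhase = "Pre-Parabola", ...) {
        key <- if (length(groupCols))
            interaction(rates[groupCols], drop = TRUE)
        else factor(rep("all", nrow(rates)))
        rates$adjustedRate <- NA_real_
        for (g in levels(key)) {
            sel <- key == g
            ref <- rates[[rateCol]][sel & rates[[phaseCol]] == refPhase]
            if (length(ref) == 0L || all(is.na(ref)))
                stop("group '", g, "' has no Pre-Parabola reference")
            rates$adjustedRate[sel] <-
                rates[[rateCol]][sel] - mean(ref, na.rm = TRUE)
        }
        rates
    })

#' Simulate, render and measure one well
#'
#' Generates \code{fieldsPerWell} independent fields at a ground-truth
#' conversion probability, renders them, runs the segmentation mask and
#' pools the object tables into per-well metrics. This is the unit the
#' plate-level pipeline iterates over; nothing larger than one field is
#' held in memory.
#'
#' @param pConvert ground-truth conversion probability.
#' @param nCellsPerField fluorescent cells per field.
#' @param fieldsPerWell imaged fields per well (default 5).
#' @param sceneParams a \code{\link{SceneParams}}.
#' @param segParams a \code{\link{SegmentationParams}}.
#' @param seed integer seed; field f uses \code{seed + f}.
#' @param well well identifier carried into the output.
#' @return list with \code{metrics} (one-row data.frame, plus
#'   \code{trueRate} and cell counts) and \code{objects} (pooled table).
#' @export
measureWell <- function(pConvert, nCellsPerField = 40, fieldsPerWell = 5,
                        sceneParams = SceneParams(),
                        segParams = SegmentationParams(),
                        seed = 1L, well = NA_character_) {
    tabs <- vector("list", fieldsPerWell)
    nValid <- 0L; nConv <- 0L
    for (f in seq_len(fieldsPerWell)) {
        sc <- generateScene(nCellsPerField, pConvert, sceneParams,
                            seed = (as.integer(seed) + f) %% 2147483647L)
        pair <- renderScene(sc, sceneParams)
        ot <- segmentField(pair, segParams)
        ot$field <- f
        tabs[[f]] <- ot
        v <- sc@cells$valid
        nValid <- nValid + sum(v)
        nConv <- nConv + sum(sc@cells$converted[v])
    }
    pooled <- do.call(rbind, tabs)
    m <- computeWellMetrics(pooled, well = well)
    m$nTrueCells <- nValid
    m$nTrueConverted <- nConv
    m$trueRate <- if (nValid) 100 * nConv / nValid else NA_real_
    list(metrics = m, objects = pooled)
}
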