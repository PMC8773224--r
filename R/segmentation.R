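# Re-implementation of the high-content analysis mask: per-channel
# white top-hat background removal, thresholding with a segmentation
# adjustment and an edge-sensitivity offset, selective nuclear hole
# fill, area filtering, and green/red object classification.
#
# Fixed processing order: top-hat -> sensitivity offset -> threshold ->
# hole fill (<= holeFillMax) -> area filter (areaMin..areaMax).

# micrometre(^2) to pixel conversions; ties round up
.umToPx <- function(x, pixelSize) floor(x / pixelSize + 0.5)
.um2ToPx2 <- function(x, pixelSize) floor(x / pixelSize^2 + 0.5)

#' Connected-component labelling
#'
#' Labels connected sets of foreground pixels with 8- (default) or
#' 4-connectivity, in first-encounter order.
#'
#' @param mask logical or 0/1 matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of labels (0 = background).
#' @export
labelComponents <- function(mask, connectivity = 8) {
    storage.mode(mask) <- "logical"
    cc_label(mask, as.integer(connectivity))
}

#' White top-hat background correction
#'
#' Removes background structure larger than the cell scale with a
#' grayscale white top-hat (image minus its morphological opening)
#' using a disc structuring element of radius \code{cellRadius} (um,
#' converted to pixels). The result is nonnegative and maps flat or
#' slowly varying background to ~0 while preserving cell-sized peaks.
#'
#' @param image numeric matrix.
#' @param params a \code{\link{SegmentationParams}}.
#' @param pixelSize um/px.
#' @return background-corrected matrix.
#' @export
tophatBackground <- function(image, params = SegmentationParams(),
                             pixelSize = 1) {
    r <- .umToPx(params@cellRadius, pixelSize)
    side <- 2L * r + 1L
    if (side > min(dim(image)))
        stop("structuring element (", side,
             " px) larger than the image")
    opened <- disc_morph(disc_morph(image, r, TRUE), r, FALSE)
    pmax(image - opened, 0)
}

# selective hole fill: fill background components that do not touch the
# image border and are at most maxHolePx pixels, into the enclosing label
.fillHoles <- function(lab, maxHolePx) {
    bg <- lab == 0L
    bgLab <- labelComponents(bg, connectivity = 4)
    if (max(bgLab) == 0L) return(lab)
    border <- unique(c(bgLab[1, ], bgLab[nrow(bgLab), ],
                       bgLab[, 1], bgLab[, ncol(bgLab)]))
    border <- border[border > 0L]
    sizes <- tabulate(bgLab, nbins = max(bgLab))
    holeIds <- setdiff(which(sizes <= maxHolePx), border)
    if (length(holeIds) == 0L) return(lab)
    fillable <- c(FALSE, seq_len(max(bgLab)) %in% holeIds)
    idx <- which(fillable[bgLab + 1L])
    groups <- split(idx, bgLab[idx])
    for (g in groups) {
        first <- g[1L]             # column-major first pixel
        i <- (first - 1L) %% nrow(lab) + 1L
        j <- (first - 1L) %/% nrow(lab) + 1L
        # the pixel above the first hole pixel is foreground: a
        # 4-connected background neighbour would share the component
        lab[g] <- lab[i - 1L, j]
    }
    lab
}

# remove labels whose pixel area falls outside [minPx, maxPx]; relabel
.areaFilter <- function(lab, minPx, maxPx) {
    if (max(lab) == 0L) return(lab)
    sizes <- tabulate(lab, nbins = max(lab))
    keep <- which(sizes >= minPx & sizes <= maxPx)
    remap <- integer(max(lab))
    remap[keep] <- seq_along(keep)
    out <- lab
    out[lab > 0L] <- remap[lab[lab > 0L]]
    out
}

#' Segment one corrected channel into labelled objects
#'
#' Applies the edge-sensitivity offset (in per-mille of the corrected
#' image's dynamic range) to a top-hat-corrected channel, thresholds at
#' \code{channelThreshold * segmentationAdjustment}, labels connected
#' components (8-connectivity), fills enclosed holes up to
#' \code{holeFillMax} um2 (non-fluorescent nuclei), then removes objects
#' outside the [\code{areaMin}, \code{areaMax}] um2 range.
#'
#' @param corrected background-corrected matrix (see
#'   \code{\link{tophatBackground}}).
#' @param channelThreshold threshold in channel units (GCU or RCU).
#' @param params a \code{\link{SegmentationParams}}.
#' @param pixelSize um/px.
#' @return integer matrix of object labels.
#' @export
segmentChannel <- function(corrected, channelThreshold,
                           params = SegmentationParams(), pixelSize = 1) {
    offset <- params@tophatEdgeSensitivity / 1000 *
        diff(range(corrected))
    mask <- (corrected + offset) >=
        channelThreshold * params@segmentationAdjustment
    lab <- labelComponents(mask, connectivity = 8)
    lab <- .fillHoles(lab, .um2ToPx2(params@holeFillMax, pixelSize))
    .areaFilter(lab,
                .um2ToPx2(params@areaMin, pixelSize),
                .um2ToPx2(params@areaMax, pixelSize))
}

# per-label area (px), centroid (um) and intensity stats on an image
.labelStats <- function(lab, img, pixelSize) {
    n <- max(lab)
    if (n == 0L)
        return(data.frame(label = integer(), areaPx = integer(),
                          x = numeric(), y = numeric(),
                          mean = numeric(), sum = numeric()))
    idx <- which(lab > 0L)
    l <- lab[idx]
    areaPx <- tabulate(l, nbins = n)
    ri <- (idx - 1L) %% nrow(lab) + 1L
    ci <- (idx - 1L) %/% nrow(lab) + 1L
    sx <- rowsum(ri - 0.5, l); sy <- rowsum(ci - 0.5, l)
    si <- rowsum(img[idx], l)
    data.frame(label = seq_len(n), areaPx = areaPx,
               x = as.numeric(sx) / areaPx * pixelSize,
               y = as.numeric(sy) / areaPx * pixelSize,
               mean = as.numeric(si) / areaPx, sum = as.numeric(si))
}

#' Classify green and red objects into merged / green-only / red-only
#'
#' A green object counts as merged when its pixel overlap with some red
#' object reaches \code{overlapFraction} (default 0.5) of the smaller
#' object's area; red objects matched by no green object are red-only.
#' Mean intensities are computed per object on the corrected images:
#' merged and red-only rows carry the red object's red statistics,
#' green rows carry the green object's green statistics.
#'
#' @param greenMask,redMask labelled masks from
#'   \code{\link{segmentChannel}}; must share geometry.
#' @param greenImg,redImg corrected channel images.
#' @param params a \code{\link{SegmentationParams}}.
#' @param pixelSize um/px.
#' @return an object table (data.frame): objectId, class, area (um2),
#'   x, y (um), meanGreen, meanRed, integratedRed, greenLabel, redLabel.
#' @export
classifyObjects <- function(greenMask, redMask, greenImg, redImg,
                            params = SegmentationParams(), pixelSize = 1) {
    if (!identical(dim(greenMask), dim(redMask)))
        stop("green and red masks must share geometry")
    pxArea <- pixelSize^2
    gs <- .labelStats(greenMask, greenImg, pixelSize)
    gr <- .labelStats(greenMask, redImg, pixelSize)   # red under green mask
    rs <- .labelStats(redMask, redImg, pixelSize)
    rg <- .labelStats(redMask, greenImg, pixelSize)

    # sparse overlap counts between green and red labels
    both <- which(greenMask > 0L & redMask > 0L)
    bestRed <- integer(nrow(gs)); bestOv <- integer(nrow(gs))
    if (length(both)) {
        key <- paste(greenMask[both], redMask[both])
        cnt <- table(key)
        parts <- do.call(rbind, strsplit(names(cnt), " ", fixed = TRUE))
        ov <- data.frame(g = as.integer(parts[, 1]),
                         r = as.integer(parts[, 2]),
                         n = as.integer(cnt))
        ov <- ov[order(ov$g, -ov$n), ]
        top <- ov[!duplicated(ov$g), ]
        bestRed[top$g] <- top$r
        bestOv[top$g] <- top$n
    }
    merged <- bestRed > 0L &
        bestOv >= params@overlapFraction *
            pmin(gs$areaPx, rs$areaPx[pmax(bestRed, 1L)])

    rows <- list()
    if (nrow(gs)) {
        cls <- ifelse(merged, "merged", "green-only")
        rl <- ifelse(merged, bestRed, NA_integer_)
        rows$green <- data.frame(
            objectId = paste0("G", gs$label), class = cls,
            area = gs$areaPx * pxArea, x = gs$x, y = gs$y,
            meanGreen = gs$mean,
            meanRed = ifelse(merged, rs$mean[pmax(bestRed, 1L)], gr$mean),
            integratedRed = ifelse(merged, rs$sum[pmax(bestRed, 1L)],
                                   NA_real_),
            greenLabel = gs$label, redLabel = rl,
            stringsAsFactors = FALSE)
    }
    claimed <- unique(bestRed[merged])
    redOnly <- setdiff(rs$label, claimed)
    if (length(redOnly)) {
        ro <- rs[rs$label %in% redOnly, , drop = FALSE]
        rog <- rg[rg$label %in% redOnly, , drop = FALSE]
        rows$red <- data.frame(
            objectId = paste0("R", ro$label), class = "red-only",
            area = ro$areaPx * pxArea, x = ro$x, y = ro$y,
            meanGreen = rog$mean, meanRed = ro$mean,
            integratedRed = ro$sum,
            greenLabel = NA_integer_, redLabel = ro$label,
            stringsAsFactors = FALSE)
    }
    out <- if (length(rows)) do.call(rbind, rows) else
        data.frame(objectId = character(), class = character(),
                   area = numeric(), x = numeric(), y = numeric(),
                   meanGreen = numeric(), meanRed = numeric(),
                   integratedRed = numeric(),
                   greenLabel = integer(), redLabel = integer(),
                   stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' Segment a two-channel field end to end
#'
#' Convenience wrapper: top-hat correction of both channels, per-channel
#' segmentation at the GCU/RCU thresholds, and object classification.
#'
#' @param pair an \code{\link{ImagePair}}.
#' @param params a \code{\link{SegmentationParams}}.
#' @return an object table (see \code{\link{classifyObjects}}).
#' @export
segmentField <- function(pair, params = SegmentationParams()) {
    px <- pair@pixelSize
    gC <- tophatBackground(pair@green, params, px)
    rC <- tophatBackground(pair@red, params, px)
    gM <- segmentChannel(gC, params@gcuThreshold, params, px)
    rM <- segmentChannel(rC, params@rcuThreshold, params, px)
    classifyObjects(gM, rM, gC, rC, params, px)
}
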