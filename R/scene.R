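# Synthetic two-channel fluorescence fields with known ground truth.
#
# Cells are ellipses with a concentric non-fluorescent nuclear hole,
# placed without overlap by rejection sampling; each cell is converted
# (red above threshold) independently with probability pConvert. Debris
# objects are red-autofluorescent only. Rendering adds a background
# level and Gaussian read noise per channel.

.sampleTruncLnorm <- function(n, meanlog, sdlog, lo, hi) {
    x <- stats::rlnorm(n, meanlog, sdlog)
    for (i in 1:20) {
        bad <- x < lo | x > hi
        if (!any(bad)) break
        x[bad] <- stats::rlnorm(sum(bad), meanlog, sdlog)
    }
    pmin(pmax(x, lo), hi)
}

# rejection placement of ellipses by bounding-circle separation;
# largest objects are placed first so big debris blobs find room
.placeObjects <- function(maxAxis, width, height, minGap, maxTries) {
    n <- length(maxAxis)
    ord <- order(maxAxis, decreasing = TRUE)
    maxAxis <- maxAxis[ord]
    x <- numeric(n); y <- numeric(n)
    for (i in seq_len(n)) {
        a <- maxAxis[i]
        if (2 * a + 2 > min(width, height))
            stop("object of extent ", round(2 * a), " um cannot fit the field")
        ok <- FALSE
        for (try in seq_len(maxTries)) {
            cx <- stats::runif(1, a + 1, width - a - 1)
            cy <- stats::runif(1, a + 1, height - a - 1)
            if (i == 1L) { ok <- TRUE }
            else {
                j <- seq_len(i - 1L)
                d2 <- (x[j] - cx)^2 + (y[j] - cy)^2
                ok <- all(d2 > (maxAxis[j] + a + minGap)^2)
            }
            if (ok) { x[i] <- cx; y[i] <- cy; break }
        }
        if (!ok)
            stop("field too small: placement failed after ", maxTries,
                 " tries for object ", i)
    }
    inv <- integer(n); inv[ord] <- seq_len(n)
    cbind(x = x[inv], y = y[inv])
}

#' Generate a ground-truthed synthetic scene
#'
#' Draws \code{nCells} fluorescent cells (areas log-normal within the
#' valid 150-5500 um2 range unless under/oversized filter-test fractions
#' are requested) plus red-autofluorescent debris, places all objects
#' without overlap, and marks each cell converted independently with
#' probability \code{pConvert}. Identical seeds give identical scenes.
#'
#' @param nCells number of fluorescent cells.
#' @param pConvert per-cell conversion probability in [0, 1].
#' @param params a \code{\link{SceneParams}}.
#' @param seed integer seed.
#' @return a \code{\link{SyntheticScene}}.
#' @examples
#' sc <- generateScene(20, 0.5, seed = 1)
#' trueConvertedFraction(sc)
#' @export
generateScene <- function(nCells, pConvert, params = SceneParams(),
                          seed = 1L) {
    stopifnot(nCells >= 0, pConvert >= 0, pConvert <= 1)
    set.seed(as.integer(seed))
    p <- params

    nUnder <- round(nCells * p@undersizedFrac)
    nOver <- round(nCells * p@oversizedFrac)
    nValid <- nCells - nUnder - nOver
    area <- c(
        .sampleTruncLnorm(nValid, p@cellAreaMeanlog, p@cellAreaSdlog,
                          p@areaMin, p@areaMax),
        if (nUnder) stats::runif(nUnder, 40, p@areaMin - 1),
        if (nOver) stats::runif(nOver, p@areaMax + 100, 1.6 * p@areaMax))
    valid <- rep(c(TRUE, FALSE, FALSE), c(nValid, nUnder, nOver))

    # all cell attributes are drawn before any debris randomness, so a
    # fixed seed yields the same cell population with or without debris
    aspect <- stats::runif(nCells, p@aspectMin, p@aspectMax)
    theta <- stats::runif(nCells, 0, pi)
    holeArea <- pmin(stats::runif(nCells, p@holeAreaMin, p@holeAreaMax),
                     0.4 * area)
    converted <- stats::rbinom(nCells, 1L, pConvert) == 1L
    green <- pmax(stats::rnorm(nCells, p@greenMean, p@greenCellSd),
                  0.3 * p@greenMean)
    green[converted] <- green[converted] * p@greenConvertedFactor
    red <- ifelse(converted,
                  pmax(stats::rnorm(nCells, p@redMeanConverted, p@redCellSd),
                       0.35 * p@redMeanConverted),
                  p@redMeanUnconverted)

    nDebris <- round(nCells * p@debrisFrac)
    dArea <- stats::rlnorm(nDebris, p@debrisAreaMeanlog, p@debrisAreaSdlog)
    dArea <- pmin(pmax(dArea, 40), 2 * p@areaMax)
    dAspect <- stats::runif(nDebris, 0.4, 1)
    dTheta <- stats::runif(nDebris, 0, pi)
    dRed <- pmax(stats::rnorm(nDebris, p@debrisRedMean, p@debrisRedSd),
                 0.3 * p@debrisRedMean)

    allAreas <- c(area, dArea)
    allAspect <- c(aspect, dAspect)
    maxAxis <- sqrt(allAreas / (pi * allAspect))
    xy <- if (length(allAreas))
        .placeObjects(maxAxis, p@fieldWidth, p@fieldHeight, p@minGap,
                      p@maxPlaceTries)
    else cbind(x = numeric(0), y = numeric(0))

    ci <- seq_len(nCells)
    cells <- data.frame(
        x = xy[ci, "x"][seq_len(nCells)], y = xy[ci, "y"][seq_len(nCells)],
        area = area, holeArea = holeArea, aspect = aspect, theta = theta,
        green = green, red = red, converted = converted, valid = valid)
    di <- nCells + seq_len(nDebris)
    debris <- data.frame(
        x = xy[di, "x"][seq_len(nDebris)], y = xy[di, "y"][seq_len(nDebris)],
        area = dArea, aspect = dAspect, theta = dTheta, red = dRed)

    new("SyntheticScene", cells = cells, debris = debris,
        fieldSize = c(p@fieldWidth, p@fieldHeight),
        pixelSize = p@pixelSize, seed = as.integer(seed),
        pConvert = pConvert)
}

# linear pixel indices of an ellipse body and its concentric hole; the
# hole is the same ellipse scaled to holeArea, so its boundary is the
# level set r2 = holeArea / area
.ellipsePixels <- function(cx, cy, area, aspect, theta, holeArea,
                           pixelSize, nx, ny) {
    a <- sqrt(area / (pi * aspect)); b <- aspect * a
    ix <- max(1L, floor((cx - a) / pixelSize)):
          min(nx, ceiling((cx + a) / pixelSize))
    iy <- max(1L, floor((cy - a) / pixelSize)):
          min(ny, ceiling((cy + a) / pixelSize))
    px <- (ix - 0.5) * pixelSize - cx
    py <- (iy - 0.5) * pixelSize - cy
    ct <- cos(theta); st <- sin(theta)
    dx <- rep(px, times = length(py))
    dy <- rep(py, each = length(px))
    u <- (dx * ct + dy * st) / a
    v <- (-dx * st + dy * ct) / b
    r2 <- u * u + v * v
    lin <- rep.int(ix, length(iy)) +
        (rep(iy, each = length(ix)) - 1L) * nx
    inside <- r2 <= 1
    if (holeArea > 0) {
        hole <- r2 <= holeArea / area
        list(body = lin[inside & !hole], hole = lin[inside & hole])
    } else {
        list(body = lin[inside], hole = integer(0))
    }
}

#' Render a scene into a two-channel image pair
#'
#' Rasterises cells as filled ellipses with a zero-intensity nuclear
#' hole in both channels, debris into the red channel only, then adds
#' the background level and Gaussian read noise and clamps at zero.
#'
#' @param scene a \code{\link{SyntheticScene}}.
#' @param params a \code{\link{SceneParams}} (noise/background fields).
#' @param seed optional seed for the noise draw; \code{NULL} uses the
#'   current RNG stream.
#' @return an \code{\link{ImagePair}}.
#' @export
renderScene <- function(scene, params = SceneParams(), seed = NULL) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    px <- scene@pixelSize
    nx <- round(scene@fieldSize[1] / px)
    ny <- round(scene@fieldSize[2] / px)
    g <- matrix(0, nx, ny); r <- matrix(0, nx, ny)
    cl <- scene@cells
    for (i in seq_len(nrow(cl))) {
        ep <- .ellipsePixels(cl$x[i], cl$y[i], cl$area[i], cl$aspect[i],
                             cl$theta[i], cl$holeArea[i], px, nx, ny)
        g[ep$body] <- cl$green[i]
        r[ep$body] <- cl$red[i]
        # hole pixels stay at 0 in both channels (non-fluorescent nucleus)
    }
    db <- scene@debris
    for (i in seq_len(nrow(db))) {
        ep <- .ellipsePixels(db$x[i], db$y[i], db$area[i], db$aspect[i],
                             db$theta[i], 0, px, nx, ny)
        r[ep$body] <- db$red[i]
    }
    g <- pmax(g + params@bgGreen +
              matrix(stats::rnorm(nx * ny, 0, params@noiseGreen), nx, ny), 0)
    r <- pmax(r + params@bgRed +
              matrix(stats::rnorm(nx * ny, 0, params@noiseRed), nx, ny), 0)
    new("ImagePair", green = g, red = r, pixelSize = px)
}
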