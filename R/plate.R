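# Plate-level synthetic imaging: per-well fields, TIFF export and the
# sidecar manifest / ground-truth tables.

# TIFF sample values live in [0, 1]; calibrated GCU/RCU intensities are
# stored divided by this fixed full-scale value and restored on read
.TIFF_FULL_SCALE <- 64

#' Write / read a two-channel image pair as single-channel TIFFs
#'
#' Images are written as 32-bit float TIFFs, one file per channel.
#' Calibrated GCU/RCU intensities are mapped onto the TIFF unit range
#' with a fixed full-scale of 64 intensity units, so values round-trip
#' exactly up to float precision (intensities above 64 are clipped).
#'
#' @param pair an \code{\link{ImagePair}}.
#' @param greenFile,redFile output paths.
#' @return \code{writeImagePair}: the two paths, invisibly.
#' @export
writeImagePair <- function(pair, greenFile, redFile) {
    tiff::writeTIFF(pmin(pair@green / .TIFF_FULL_SCALE, 1), greenFile,
                    bits.per.sample = 32L, reduce = FALSE)
    tiff::writeTIFF(pmin(pair@red / .TIFF_FULL_SCALE, 1), redFile,
                    bits.per.sample = 32L, reduce = FALSE)
    invisible(c(greenFile, redFile))
}

#' @rdname writeImagePair
#' @param pixelSize um/px recorded alongside the rasters.
#' @return \code{readImagePair}: an \code{\link{ImagePair}}.
#' @export
readImagePair <- function(greenFile, redFile, pixelSize = 1) {
    g <- tiff::readTIFF(greenFile) * .TIFF_FULL_SCALE
    r <- tiff::readTIFF(redFile) * .TIFF_FULL_SCALE
    new("ImagePair", green = g, red = r, pixelSize = pixelSize)
}

# resolve a conversion probability for (construct, role) from either a
# named numeric (by role) or a data.frame(construct, role, p)
.resolveP <- function(construct, role, pMap) {
    if (is.data.frame(pMap)) {
        hit <- pMap$p[pMap$construct == construct & pMap$role == role]
        if (length(hit) == 0L)
            hit <- pMap$p[pMap$construct == construct & pMap$role == "Any"]
        if (length(hit) == 0L)
            stop("no conversion probability mapped for construct '",
                 construct, "', role '", role, "'")
        hit[[1]]
    } else {
        if (!role %in% names(pMap))
            stop("no conversion probability mapped for role '", role, "'")
        unname(pMap[[role]])
    }
}

#' Generate a synthetic imaged plate
#'
#' Simulates the imaging of (a subset of) a plate: per well,
#' \code{fieldsPerWell} non-overlapping fields are generated at the
#' well's ground-truth conversion probability and rendered in the green
#' and red channels. A sidecar manifest lists one row per field and
#' channel (green, red, and a phase-contrast bookkeeping placeholder
#' that is not rendered); ground truth is aggregated per well and
#' field. With \code{outDir} set, rasters are written as TIFFs; with
#' \code{manifestOnly = TRUE} only the manifest and ground-truth tables
#' are produced (useful for campaign bookkeeping).
#'
#' @param layout a \code{\link{PlateLayout}}.
#' @param pMap conversion probabilities: a named numeric by role, or a
#'   data.frame with columns construct, role, p (role \code{"Any"}
#'   matches all roles of a construct). Every simulated well must
#'   resolve.
#' @param fieldsPerWell imaged fields per well (default 5).
#' @param nCellsPerField fluorescent cells per field.
#' @param params a \code{\link{SceneParams}}.
#' @param seed integer seed; wells and fields derive their own seeds.
#' @param wells optional character vector restricting the simulated
#'   wells.
#' @param outDir optional directory for TIFF output.
#' @param manifestOnly skip rendering entirely.
#' @param keepImages return rendered \code{\link{ImagePair}}s in memory
#'   (only sensible for small subsets).
#' @return list: \code{manifest} (plate, well, field, channel, file,
#'   pixelSize), \code{groundTruth} (per well and field: role,
#'   condition, construct, parabola, nCells, nValid, nConverted,
#'   trueRate), and \code{images} (named list or NULL).
#' @export
generatePlate <- function(layout, pMap, fieldsPerWell = 5,
                          nCellsPerField = 40, params = SceneParams(),
                          seed = 1L, wells = NULL, outDir = NULL,
                          manifestOnly = FALSE, keepImages = FALSE) {
    w <- layout@wells
    if (!is.null(wells)) w <- w[w$well %in% wells, , drop = FALSE]
    if (!is.null(outDir) && !dir.exists(outDir))
        dir.create(outDir, recursive = TRUE)
    manifest <- list(); truth <- list(); images <- list()
    for (i in seq_len(nrow(w))) {
        p <- .resolveP(w$construct[i], w$role[i], pMap)
        for (f in seq_len(fieldsPerWell)) {
            fseed <- (as.integer(seed) * 1009L + i * 131L + f) %% 2147483647L
            files <- c(green = NA_character_, red = NA_character_,
                       phase = NA_character_)
            if (!manifestOnly) {
                sc <- generateScene(nCellsPerField, p, params, seed = fseed)
                pair <- renderScene(sc, params)
                v <- sc@cells$valid
                truth[[length(truth) + 1L]] <- data.frame(
                    plate = layout@plate, well = w$well[i], field = f,
                    role = w$role[i], condition = w$condition[i],
                    construct = w$construct[i], parabola = w$parabola[i],
                    nCells = nrow(sc@cells), nValid = sum(v),
                    nConverted = sum(sc@cells$converted[v]),
                    trueRate = if (sum(v)) 100 * mean(sc@cells$converted[v])
                               else NA_real_,
                    stringsAsFactors = FALSE)
                if (!is.null(outDir)) {
                    base <- sprintf("%s_%s_f%d", layout@plate, w$well[i], f)
                    files["green"] <- file.path(outDir,
                                                paste0(base, "_green.tif"))
                    files["red"] <- file.path(outDir,
                                              paste0(base, "_red.tif"))
                    writeImagePair(pair, files[["green"]], files[["red"]])
                }
                if (keepImages)
                    images[[sprintf("%s_f%d", w$well[i], f)]] <- pair
            }
            manifest[[length(manifest) + 1L]] <- data.frame(
                plate = layout@plate, well = w$well[i], field = f,
                channel = c("green", "red", "phase"),
                file = unname(files), pixelSize = params@pixelSize,
                stringsAsFactors = FALSE)
        }
    }
    list(manifest = do.call(rbind, manifest),
         groundTruth = if (length(truth)) do.call(rbind, truth) else NULL,
         images = if (keepImages) images else NULL)
}
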