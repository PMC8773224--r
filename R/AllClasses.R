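#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib CaMPARIquant, .registration = TRUE
NULL

#' CaMPARI2 variant specification
#'
#' Binding and photoconversion parameters of one CaMPARI2 variant: the
#' Ca2+ dissociation constant (nM), the Hill cooperativity, and the
#' 405 nm photoconversion hazards of the Ca2+-free and Ca2+-bound states
#' (per second). Hazards or \code{kd} may be \code{NA} when unknown for a
#' variant.
#'
#' @slot name variant name, e.g. \code{"CaMPARI2-F391W"}.
#' @slot kd Ca2+ dissociation constant in nM (positive, or \code{NA}).
#' @slot hillN Hill coefficient (positive).
#' @slot kFree conversion hazard of the Ca2+-free state, per s.
#' @slot kBound conversion hazard of the Ca2+-bound state, per s.
#' @exportClass VariantSpec
setClass("VariantSpec",
    representation(name = "character", kd = "numeric", hillN = "numeric",
                   kFree = "numeric", kBound = "numeric"),
    prototype(name = "CaMPARI2", kd = 199.2, hillN = 1,
              kFree = NA_real_, kBound = NA_real_))

setValidity("VariantSpec", function(object) {
    msg <- character()
    if (length(object@name) != 1L || !nzchar(object@name))
        msg <- c(msg, "'name' must be a single non-empty string")
    if (!is.na(object@kd) && object@kd <= 0)
        msg <- c(msg, "'kd' must be positive")
    if (is.na(object@hillN) || object@hillN <= 0)
        msg <- c(msg, "'hillN' must be positive")
    kf <- object@kFree; kb <- object@kBound
    if (!is.na(kf) && kf < 0)
        msg <- c(msg, "'kFree' must be nonnegative")
    if (!is.na(kf) && !is.na(kb) && kf > kb)
        msg <- c(msg, "'kFree' must not exceed 'kBound'")
    if (length(msg)) msg else TRUE
})

#' @describeIn VariantSpec-class constructor.
#' @param name,kd,hillN,kFree,kBound see slots.
#' @export
VariantSpec <- function(name, kd = NA_real_, hillN = 1,
                        kFree = NA_real_, kBound = NA_real_) {
    new("VariantSpec", name = name, kd = as.numeric(kd),
        hillN = as.numeric(hillN), kFree = as.numeric(kFree),
        kBound = as.numeric(kBound))
}

#' A constant-Ca2+ stimulation condition
#'
#' A labelled cytosolic Ca2+ concentration held constant over the
#' illumination window (e.g. basal ~150 nM, histamine ~1e6 nM).
#'
#' @slot label condition name.
#' @slot concentration cytosolic Ca2+ concentration in nM (nonnegative).
#' @exportClass CalciumCondition
setClass("CalciumCondition",
    representation(label = "character", concentration = "numeric"),
    prototype(label = "basal", concentration = 150))

setValidity("CalciumCondition", function(object) {
    if (is.na(object@concentration) || object@concentration < 0)
        "'concentration' must be nonnegative" else TRUE
})

#' @describeIn CalciumCondition-class constructor.
#' @param label,concentration see slots.
#' @export
CalciumCondition <- function(label, concentration) {
    new("CalciumCondition", label = label,
        concentration = as.numeric(concentration))
}

#' Photoconversion illumination parameters
#'
#' Duration and optical power of one 405 nm illumination event. Defaults
#' follow the flight protocol: 8 s at 1.1 W radiant flux.
#'
#' @slot illuminationS illumination duration in seconds (nonnegative).
#' @slot radiantFluxW LED radiant flux in W.
#' @slot wavelengthNm peak emission wavelength in nm.
#' @exportClass ConversionParams
setClass("ConversionParams",
    representation(illuminationS = "numeric", radiantFluxW = "numeric",
                   wavelengthNm = "numeric"),
    prototype(illuminationS = 8, radiantFluxW = 1.1, wavelengthNm = 405))

setValidity("ConversionParams", function(object) {
    if (is.na(object@illuminationS) || object@illuminationS < 0)
        "'illuminationS' must be nonnegative" else TRUE
})

#' @describeIn ConversionParams-class constructor.
#' @param illuminationS,radiantFluxW,wavelengthNm see slots.
#' @export
ConversionParams <- function(illuminationS = 8, radiantFluxW = 1.1,
                             wavelengthNm = 405) {
    new("ConversionParams", illuminationS = as.numeric(illuminationS),
        radiantFluxW = as.numeric(radiantFluxW),
        wavelengthNm = as.numeric(wavelengthNm))
}

#' Parabolic-flight gravity profile
#'
#' Each parabola cycles through five phases (Pre-Parabola, Pull-Up,
#' Zero-G, Pull-Out, Post-Parabola) with fixed g-levels and durations;
#' the profile repeats for \code{nParabolas} consecutive parabolas.
#'
#' @slot phases data.frame with columns \code{phase}, \code{gLevel} (g),
#'   \code{duration} (s); exactly five rows, one per phase.
#' @slot nParabolas number of consecutive parabolas.
#' @exportClass FlightProfile
setClass("FlightProfile",
    representation(phases = "data.frame", nParabolas = "integer"))

.FLIGHT_PHASES <- c("Pre-Parabola", "Pull-Up", "Zero-G", "Pull-Out",
                    "Post-Parabola")

setValidity("FlightProfile", function(object) {
    ph <- object@phases
    msg <- character()
    if (!identical(ph$phase, .FLIGHT_PHASES))
        msg <- c(msg, "phases must be the five flight phases in order")
    if (any(!is.finite(ph$duration)) || any(ph$duration <= 0))
        msg <- c(msg, "phase durations must be positive")
    if (object@nParabolas < 1L)
        msg <- c(msg, "'nParabolas' must be at least 1")
    if (length(msg)) msg else TRUE
})

#' 96-well plate layout
#'
#' Assignment of constructs, parabola numbers and illumination roles to
#' the wells of one 96-well plate, plus the plate-level drug treatment.
#' CaMPARI2 wells occupy the left half (columns 1-6) and CaMPARI2-F391W
#' the right half (columns 7-12); per condition and parabola there are
#' 11 illuminated wells (1 GFP + 2 wells per flight phase) and one
#' post-flight histamine-control well.
#'
#' @slot plate plate identifier.
#' @slot drug plate-level drug treatment.
#' @slot wells data.frame with columns \code{well}, \code{row},
#'   \code{col}, \code{condition} (plate half construct),
#'   \code{construct}, \code{parabola}, \code{role}.
#' @exportClass PlateLayout
setClass("PlateLayout",
    representation(plate = "character", drug = "character",
                   wells = "data.frame"))

.WELL_ROLES <- c("GFP", .FLIGHT_PHASES, "Histamine")

setValidity("PlateLayout", function(object) {
    w <- object@wells
    msg <- character()
    need <- c("well", "row", "col", "condition", "construct", "parabola",
              "role")
    if (!all(need %in% names(w)))
        return(paste("wells must have columns:", paste(need, collapse = ", ")))
    if (nrow(w) != 96L) msg <- c(msg, "layout must cover 96 wells")
    if (!all(w$role %in% .WELL_ROLES))
        msg <- c(msg, "unknown well role")
    bad <- (w$condition == "CaMPARI2" & w$col > 6) |
           (w$condition == "CaMPARI2-F391W" & w$col <= 6)
    if (any(bad))
        msg <- c(msg, "CaMPARI2 wells must sit in the left plate half, F391W in the right")
    ill <- w[w$role != "Histamine", ]
    cnt <- table(ill$condition, ill$parabola)
    if (length(cnt) && any(cnt != 11L))
        msg <- c(msg, "each condition/parabola must have exactly 11 illuminated wells")
    if (sum(w$role == "Histamine") != 8L)
        msg <- c(msg, "a plate must carry 8 histamine-control wells")
    if (length(msg)) msg else TRUE
})

#' Synthetic scene parameters
#'
#' Tunable distributions for the synthetic two-channel field generator:
#' field geometry, cell area/shape distributions, nuclear-hole sizes,
#' channel intensities in calibrated green/red units (GCU/RCU),
#' red-autofluorescent debris, and background/read noise.
#'
#' Defaults emulate transfected chondrocyte monolayers imaged at 10x:
#' a 600 x 600 um field at 1 um/px, log-normal cell areas (median
#' 800 um2) clipped to the valid 150-5500 um2 range, nuclear holes up to
#' 200 um2, transfected-cell green mean 20 GCU (threshold 4), converted
#' red mean 1.5 RCU (threshold 0.3), and debris drawn in the red channel
#' only.
#'
#' @slot fieldWidth,fieldHeight field size in um.
#' @slot pixelSize pixel pitch in um/px.
#' @slot cellAreaMeanlog,cellAreaSdlog log-normal cell-area parameters
#'   (area in um2).
#' @slot areaMin,areaMax valid cell-area range in um2.
#' @slot undersizedFrac,oversizedFrac fractions of cells deliberately
#'   generated outside the valid area range (filter-test objects).
#' @slot holeAreaMin,holeAreaMax nuclear-hole area range in um2.
#' @slot aspectMin,aspectMax ellipse minor/major axis ratio range.
#' @slot greenMean,greenCellSd transfected-cell green intensity (GCU):
#'   population mean and between-cell SD.
#' @slot greenConvertedFactor multiplicative green loss upon conversion.
#' @slot redMeanConverted,redCellSd converted-cell red intensity (RCU).
#' @slot redMeanUnconverted residual red of unconverted cells (RCU).
#' @slot debrisFrac debris objects as a fraction of the cell count.
#' @slot debrisAreaMeanlog,debrisAreaSdlog log-normal debris areas (um2).
#' @slot debrisRedMean,debrisRedSd debris red intensity (RCU).
#' @slot transfectionEfficiency fraction of plated cells that are
#'   fluorescent at all; bookkeeping only, \code{nCells} counts
#'   fluorescent cells.
#' @slot bgGreen,bgRed additive background levels (GCU/RCU).
#' @slot noiseGreen,noiseRed Gaussian read-noise SDs (GCU/RCU).
#' @slot minGap minimum boundary gap between placed objects, um.
#' @slot maxPlaceTries placement retries per object before failing.
#' @exportClass SceneParams
setClass("SceneParams",
    representation(
        fieldWidth = "numeric", fieldHeight = "numeric",
        pixelSize = "numeric",
        cellAreaMeanlog = "numeric", cellAreaSdlog = "numeric",
        areaMin = "numeric", areaMax = "numeric",
        undersizedFrac = "numeric", oversizedFrac = "numeric",
        holeAreaMin = "numeric", holeAreaMax = "numeric",
        aspectMin = "numeric", aspectMax = "numeric",
        greenMean = "numeric", greenCellSd = "numeric",
        greenConvertedFactor = "numeric",
        redMeanConverted = "numeric", redCellSd = "numeric",
        redMeanUnconverted = "numeric",
        debrisFrac = "numeric",
        debrisAreaMeanlog = "numeric", debrisAreaSdlog = "numeric",
        debrisRedMean = "numeric", debrisRedSd = "numeric",
        transfectionEfficiency = "numeric",
        bgGreen = "numeric", bgRed = "numeric",
        noiseGreen = "numeric", noiseRed = "numeric",
        minGap = "numeric", maxPlaceTries = "numeric"),
    prototype(
        fieldWidth = 600, fieldHeight = 600, pixelSize = 1,
        cellAreaMeanlog = log(800), cellAreaSdlog = 0.45,
        areaMin = 150, areaMax = 5500,
        undersizedFrac = 0, oversizedFrac = 0,
        holeAreaMin = 60, holeAreaMax = 200,
        aspectMin = 0.55, aspectMax = 1,
        greenMean = 20, greenCellSd = 2.5,
        greenConvertedFactor = 0.8,
        redMeanConverted = 1.5, redCellSd = 0.2,
        redMeanUnconverted = 0.05,
        debrisFrac = 0,
        debrisAreaMeanlog = log(400), debrisAreaSdlog = 1,
        debrisRedMean = 2.5, debrisRedSd = 0.5,
        transfectionEfficiency = 0.3,
        bgGreen = 0.2, bgRed = 0.02,
        noiseGreen = 0.4, noiseRed = 0.03,
        minGap = 3, maxPlaceTries = 2000))

setValidity("SceneParams", function(object) {
    msg <- character()
    if (object@areaMin >= object@areaMax)
        msg <- c(msg, "'areaMin' must be below 'areaMax'")
    if (object@pixelSize <= 0) msg <- c(msg, "'pixelSize' must be positive")
    if (object@fieldWidth <= 0 || object@fieldHeight <= 0)
        msg <- c(msg, "field dimensions must be positive")
    if (object@aspectMin <= 0 || object@aspectMax > 1 ||
        object@aspectMin > object@aspectMax)
        msg <- c(msg, "aspect range must satisfy 0 < aspectMin <= aspectMax <= 1")
    if (object@debrisFrac < 0) msg <- c(msg, "'debrisFrac' must be nonnegative")
    if (length(msg)) msg else TRUE
})

#' @describeIn SceneParams-class constructor; any slot can be overridden
#'   by name.
#' @param ... named slot overrides.
#' @export
SceneParams <- function(...) new("SceneParams", ...)

#' Ground-truthed synthetic scene
#'
#' Cells and debris with geometry and channel intensities, prior to
#' rasterisation. Reproducible from its seed; the ground-truth converted
#' fraction of valid cells is recorded.
#'
#' @slot cells data.frame: x, y (um), area, holeArea (um2), aspect,
#'   theta, green, red, converted, valid.
#' @slot debris data.frame: x, y, area, aspect, theta, red.
#' @slot fieldSize numeric(2), field width and height in um.
#' @slot pixelSize um/px.
#' @slot seed integer seed the scene was drawn with.
#' @slot pConvert nominal conversion probability.
#' @exportClass SyntheticScene
setClass("SyntheticScene",
    representation(cells = "data.frame", debris = "data.frame",
                   fieldSize = "numeric", pixelSize = "numeric",
                   seed = "integer", pConvert = "numeric"))

#' Two-channel image pair
#'
#' Green and red channel rasters of one imaged field, in calibrated
#' GCU/RCU intensity units, with a shared pixel pitch.
#'
#' @slot green,red numeric matrices of equal dimension, nonnegative.
#' @slot pixelSize um/px.
#' @exportClass ImagePair
setClass("ImagePair",
    representation(green = "matrix", red = "matrix", pixelSize = "numeric"))

setValidity("ImagePair", function(object) {
    msg <- character()
    if (!identical(dim(object@green), dim(object@red)))
        msg <- c(msg, "green and red channels must share dimensions")
    if (min(object@green) < 0 || min(object@red) < 0)
        msg <- c(msg, "intensities must be nonnegative")
    if (length(msg)) msg else TRUE
})

#' Segmentation mask parameters
#'
#' Settings of the high-content analysis mask: a multiplicative
#' segmentation adjustment on the channel threshold, a top-hat edge
#' sensitivity (additive offset in per-mille of the corrected channel's
#' dynamic range), the top-hat cell radius, the nuclear hole-fill limit,
#' the valid object area range, the per-channel intensity thresholds and
#' the green/red overlap fraction defining merged objects.
#'
#' @slot segmentationAdjustment multiplicative factor on thresholds.
#' @slot tophatEdgeSensitivity additive offset in per-mille of the
#'   corrected image's dynamic range (default -30: subtract 3\% of range
#'   before thresholding).
#' @slot cellRadius top-hat structuring-element radius in um.
#' @slot holeFillMax maximal filled hole area in um2.
#' @slot areaMin,areaMax valid object area range in um2.
#' @slot gcuThreshold green-channel threshold in GCU.
#' @slot rcuThreshold red-channel threshold in RCU.
#' @slot overlapFraction minimal overlap (fraction of the smaller
#'   object's area) for a green/red pair to count as merged.
#' @exportClass SegmentationParams
setClass("SegmentationParams",
    representation(segmentationAdjustment = "numeric",
                   tophatEdgeSensitivity = "numeric",
                   cellRadius = "numeric", holeFillMax = "numeric",
                   areaMin = "numeric", areaMax = "numeric",
                   gcuThreshold = "numeric", rcuThreshold = "numeric",
                   overlapFraction = "numeric"),
    prototype(segmentationAdjustment = 1, tophatEdgeSensitivity = -30,
              cellRadius = 25, holeFillMax = 200,
              areaMin = 150, areaMax = 5500,
              gcuThreshold = 4, rcuThreshold = 0.3,
              overlapFraction = 0.5))

setValidity("SegmentationParams", function(object) {
    msg <- character()
    if (object@areaMin >= object@areaMax)
        msg <- c(msg, "'areaMin' must be below 'areaMax'")
    if (object@cellRadius <= 0) msg <- c(msg, "'cellRadius' must be positive")
    if (object@holeFillMax < 0) msg <- c(msg, "'holeFillMax' must be nonnegative")
    if (object@overlapFraction <= 0 || object@overlapFraction > 1)
        msg <- c(msg, "'overlapFraction' must be in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' @describeIn SegmentationParams-class constructor; any slot can be
#'   overridden by name.
#' @param ... named slot overrides.
#' @export
SegmentationParams <- function(...) new("SegmentationParams", ...)

#' Z'-factor result
#'
#' Assay-quality statistic 1 - 3(sd_pos + sd_neg)/|mean_pos - mean_neg|
#' with the group summaries it was computed from. Values above ~0.5
#' indicate an excellent screen; the statistic is bounded above by 1.
#'
#' @slot meanPos,sdPos,meanNeg,sdNeg group summaries (sample SDs).
#' @slot zprime the Z'-factor.
#' @exportClass ZPrimeResult
setClass("ZPrimeResult",
    representation(meanPos = "numeric", sdPos = "numeric",
                   meanNeg = "numeric", sdNeg = "numeric",
                   zprime = "numeric"))

setValidity("ZPrimeResult", function(object) {
    if (!is.na(object@zprime) && object@zprime > 1)
        "'zprime' cannot exceed 1" else TRUE
})

#' Saturation-curve fit
#'
#' Least-squares fit of R(t) = rMax * (1 - exp(-k t)) to a
#' photoconversion time course, with a bootstrap confidence band.
#'
#' @slot rMax plateau (intensity-ratio units); positive.
#' @slot k rate constant per s; positive.
#' @slot sigma residual SD.
#' @slot level confidence level of the band.
#' @slot band data.frame: time, fit, lower, upper.
#' @slot paramCI 2 x 2 matrix of bootstrap CIs for rMax and k.
#' @exportClass SaturationFit
setClass("SaturationFit",
    representation(rMax = "numeric", k = "numeric", sigma = "numeric",
                   level = "numeric", band = "data.frame",
                   paramCI = "matrix"))

setValidity("SaturationFit", function(object) {
    if (object@rMax <= 0 || object@k <= 0)
        "'rMax' and 'k' must be positive" else TRUE
})
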