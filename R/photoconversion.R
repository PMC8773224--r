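# Forward model of Ca2+-dependent CaMPARI2 green-to-red photoconversion
# under 405 nm illumination.
#
# The indicator's Ca2+-bound fraction follows a Hill curve in the
# cytosolic Ca2+ concentration; photoconversion is a two-state hazard
# process whose effective rate interpolates between the Ca2+-free and
# Ca2+-bound hazards with that occupancy. Over an illumination window of
# length t the conversion probability saturates as 1 - exp(-k_eff t).

.hill <- function(concentration, kd, hillN) {
    ifelse(concentration == 0, 0,
           1 / (1 + (kd / concentration)^hillN))
}

#' Hill occupancy of the Ca2+-binding site
#'
#' Fraction of indicator molecules in the Ca2+-bound state at a given
#' cytosolic Ca2+ concentration: \code{C^n / (C^n + kd^n)}. At
#' \code{C = kd} the occupancy is exactly 0.5 for any Hill coefficient.
#'
#' @param concentration cytosolic Ca2+ concentration in nM
#'   (nonnegative; vectorised).
#' @param variant a \code{\link{VariantSpec}} carrying \code{kd} and
#'   \code{hillN}.
#' @return occupancy fraction in [0, 1].
#' @examples
#' f391w <- VariantSpec("CaMPARI2-F391W", kd = 109.7)
#' hillOccupancy(109.7, f391w)  # 0.5
#' @export
hillOccupancy <- function(concentration, variant) {
    stopifnot(is(variant, "VariantSpec"))
    if (any(is.na(concentration)) || any(concentration < 0))
        stop("'concentration' must be nonnegative")
    if (is.na(variant@kd))
        stop("variant '", variant@name, "' has no known K_D")
    .hill(concentration, variant@kd, variant@hillN)
}

#' Photoconversion probability over an illumination window
#'
#' Probability that an indicator molecule converts green-to-red during
#' an illumination of duration \code{t}:
#' \code{p = 1 - exp(-k_eff t)} with
#' \code{k_eff = k_free (1 - f) + k_bound f}, where \code{f} is the
#' Hill occupancy at the condition's Ca2+ concentration. The probability
#' is 0 at \code{t = 0}, tends to 1 as \code{t} grows, and is monotone
#' in \code{t}, the Ca2+ concentration, and each hazard.
#'
#' @param condition a \code{\link{CalciumCondition}} (or a bare
#'   concentration in nM).
#' @param variant a \code{\link{VariantSpec}} with both hazards set.
#' @param params a \code{\link{ConversionParams}}.
#' @return conversion probability in [0, 1).
#' @export
setGeneric("conversionProbability",
    function(condition, variant, params = ConversionParams())
        standardGeneric("conversionProbability"))

#' @rdname conversionProbability
#' @export
setMethod("conversionProbability",
    signature(condition = "CalciumCondition"),
    function(condition, variant, params) {
        conversionProbability(condition@concentration, variant, params)
    })

#' @rdname conversionProbability
#' @export
setMethod("conversionProbability",
    signature(condition = "numeric"),
    function(condition, variant, params) {
        stopifnot(is(variant, "VariantSpec"), is(params, "ConversionParams"))
        if (is.na(variant@kFree) || is.na(variant@kBound))
            stop("variant '", variant@name,
                 "' has no conversion hazards set")
        f <- hillOccupancy(condition, variant)
        keff <- variant@kFree * (1 - f) + variant@kBound * f
        1 - exp(-keff * params@illuminationS)
    })

#' Calibrate a conversion hazard from an observed probability
#'
#' Inverts the saturation law: a conversion probability \code{p}
#' observed after \code{t} seconds of illumination corresponds to the
#' hazard \code{-log(1 - p) / t}. Round-trips exactly with
#' \code{\link{conversionProbability}} at fixed occupancy.
#'
#' @param pObserved observed conversion probability in [0, 1);
#'   vectorised.
#' @param t illumination duration in s (positive).
#' @return hazard in per s.
#' @examples
#' calibrateEmpirical(0.65, 8)  # hazard reproducing 65% conversion in 8 s
#' @export
calibrateEmpirical <- function(pObserved, t) {
    if (any(t <= 0)) stop("'t' must be positive")
    if (any(pObserved < 0)) stop("'pObserved' must be nonnegative")
    if (any(pObserved >= 1))
        stop("'pObserved' >= 1 is infeasible: the saturation law never reaches 1")
    -log(1 - pObserved) / t
}

#' Two-point hazard calibration from basal and stimulated conversion
#'
#' Solves for the Ca2+-free and Ca2+-bound hazards from conversion
#' probabilities observed at two Ca2+ concentrations, through the 2 x 2
#' linear system \code{h_i = k_free (1 - f_i) + k_bound f_i} with
#' \code{h_i = -log(1 - p_i)/t} and \code{f_i} the Hill occupancy.
#' When the observed hazard contrast exceeds what occupancy alone can
#' produce, the solved \code{k_free} is negative and a structured
#' infeasibility report is returned instead of parameters.
#'
#' @param pBasal,pStim conversion probabilities in [0, 1).
#' @param cBasal,cStim Ca2+ concentrations in nM (distinct).
#' @param kd dissociation constant in nM.
#' @param hillN Hill coefficient.
#' @param t illumination duration in s.
#' @return a list with elements \code{feasible} (logical), \code{kFree},
#'   \code{kBound} (solved rates, possibly negative when infeasible),
#'   \code{occupancy} (the two occupancies) and \code{reason}.
#' @export
calibrateTwoPoint <- function(pBasal, pStim, cBasal, cStim, kd,
                              hillN = 1, t = 8) {
    stopifnot(pBasal >= 0, pBasal < 1, pStim >= 0, pStim < 1,
              cBasal >= 0, cStim >= 0, kd > 0, hillN > 0, t > 0)
    if (cBasal == cStim)
        stop("singular system: basal and stimulated concentrations coincide")
    f <- .hill(c(cBasal, cStim), kd, hillN)
    h <- calibrateEmpirical(c(pBasal, pStim), t)
    A <- cbind(1 - f, f)
    sol <- solve(A, h)
    kFree <- sol[[1]]; kBound <- sol[[2]]
    feasible <- kFree >= 0 && kBound >= 0 && kFree <= kBound
    reason <- if (feasible) NA_character_
        else if (kFree < 0)
            "observed hazard contrast exceeds the occupancy contrast at this K_D (solved k_free < 0)"
        else if (kBound < 0) "solved k_bound < 0"
        else "solved k_free exceeds k_bound"
    list(feasible = feasible, kFree = kFree, kBound = kBound,
         occupancy = f, hazards = h, reason = reason)
}

#' Bundled CaMPARI2 variant table
#'
#' Reads the variant configuration shipped with the package (YAML):
#' name, K_D in nM, Hill coefficient and conversion hazards for the
#' CaMPARI2 variants used in chondrocyte screening. K_D is known for
#' CaMPARI2 (199.2 nM) and CaMPARI2-F391W (109.7 nM); the remaining
#' variants carry \code{NA}.
#'
#' @param file path to a variant YAML; defaults to the bundled table.
#' @return named list of \code{\link{VariantSpec}} objects.
#' @export
campariVariants <- function(file = system.file("extdata",
        "campari_variants.yaml", package = "CaMPARIquant")) {
    raw <- yaml::read_yaml(file)
    out <- lapply(raw$variants, function(v) {
        VariantSpec(v$name,
                    kd = if (is.null(v$kd_nM)) NA_real_ else v$kd_nM,
                    hillN = if (is.null(v$hill_n)) 1 else v$hill_n,
                    kFree = if (is.null(v$k_free)) NA_real_ else v$k_free,
                    kBound = if (is.null(v$k_bound)) NA_real_ else v$k_bound)
    })
    names(out) <- vapply(out, function(v) v@name, character(1))
    out
}
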