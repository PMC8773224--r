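# show() and accessor methods for the core classes

#' @rdname VariantSpec-class
#' @param object a \code{VariantSpec}.
#' @export
setMethod("show", "VariantSpec", function(object) {
    cat("VariantSpec:", object@name, "\n")
    cat("  K_D:", object@kd, "nM  Hill n:", object@hillN, "\n")
    cat("  hazards (per s): free =", object@kFree,
        " bound =", object@kBound, "\n")
})

#' @rdname CalciumCondition-class
#' @param object a \code{CalciumCondition}.
#' @export
setMethod("show", "CalciumCondition", function(object) {
    cat("CalciumCondition:", object@label, "at",
        object@concentration, "nM\n")
})

#' @rdname FlightProfile-class
#' @param object a \code{FlightProfile}.
#' @export
setMethod("show", "FlightProfile", function(object) {
    cat("FlightProfile:", object@nParabolas, "parabolas,",
        sum(object@phases$duration), "s per parabola\n")
    print(object@phases, row.names = FALSE)
})

#' @rdname PlateLayout-class
#' @param object a \code{PlateLayout}.
#' @export
setMethod("show", "PlateLayout", function(object) {
    cat("PlateLayout", object@plate, "- drug:", object@drug, "\n")
    cat("  wells:", nrow(object@wells), " conditions:",
        paste(unique(object@wells$condition), collapse = ", "), "\n")
    cat("  parabolas:",
        paste(sort(unique(object@wells$parabola)), collapse = ", "), "\n")
})

#' @rdname SyntheticScene-class
#' @param object a \code{SyntheticScene}.
#' @export
setMethod("show", "SyntheticScene", function(object) {
    cat("SyntheticScene:", nrow(object@cells), "cells,",
        nrow(object@debris), "debris objects on",
        paste(object@fieldSize, collapse = " x "), "um\n")
    cat("  ground-truth converted fraction (valid cells):",
        signif(trueConvertedFraction(object), 4), "\n")
})

#' @rdname ImagePair-class
#' @param object an \code{ImagePair}.
#' @export
setMethod("show", "ImagePair", function(object) {
    cat("ImagePair:", paste(dim(object@green), collapse = " x "),
        "px at", object@pixelSize, "um/px\n")
})

#' @rdname ZPrimeResult-class
#' @param object a \code{ZPrimeResult}.
#' @export
setMethod("show", "ZPrimeResult", function(object) {
    cat("Z'-factor:", signif(object@zprime, 4), "\n")
    cat("  positive:", signif(object@meanPos, 4), "+/-",
        signif(object@sdPos, 4), "\n")
    cat("  negative:", signif(object@meanNeg, 4), "+/-",
        signif(object@sdNeg, 4), "\n")
})

#' @rdname SaturationFit-class
#' @param object a \code{SaturationFit}.
#' @export
setMethod("show", "SaturationFit", function(object) {
    cat("SaturationFit: rMax =", signif(object@rMax, 5),
        " k =", signif(object@k, 5), "per s\n")
    cat("  half-time:", signif(log(2) / object@k, 4), "s;",
        100 * object@level, "% bootstrap band over",
        nrow(object@band), "time points\n")
})

#' Accessors
#'
#' Small accessor generics for the core classes: well table of a layout,
#' phase table of a profile, scene ground truth, channel rasters and the
#' Z'-factor value.
#'
#' @param x an object of the documented class.
#' @return the accessed component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wells", function(x) standardGeneric("wells"))
#' @rdname accessors
#' @export
setMethod("wells", "PlateLayout", function(x) x@wells)

#' @rdname accessors
#' @export
setGeneric("plateDrug", function(x) standardGeneric("plateDrug"))
#' @rdname accessors
#' @export
setMethod("plateDrug", "PlateLayout", function(x) x@drug)

#' @rdname accessors
#' @export
setGeneric("flightPhases", function(x) standardGeneric("flightPhases"))
#' @rdname accessors
#' @export
setMethod("flightPhases", "FlightProfile", function(x) x@phases)

#' @rdname accessors
#' @export
setGeneric("nParabolas", function(x) standardGeneric("nParabolas"))
#' @rdname accessors
#' @export
setMethod("nParabolas", "FlightProfile", function(x) x@nParabolas)

#' @rdname accessors
#' @export
setGeneric("sceneCells", function(x) standardGeneric("sceneCells"))
#' @rdname accessors
#' @export
setMethod("sceneCells", "SyntheticScene", function(x) x@cells)

#' @rdname accessors
#' @export
setGeneric("sceneDebris", function(x) standardGeneric("sceneDebris"))
#' @rdname accessors
#' @export
setMethod("sceneDebris", "SyntheticScene", function(x) x@debris)

#' @rdname accessors
#' @export
setGeneric("trueConvertedFraction",
           function(x) standardGeneric("trueConvertedFraction"))
#' @rdname accessors
#' @export
setMethod("trueConvertedFraction", "SyntheticScene", function(x) {
    v <- x@cells[x@cells$valid, , drop = FALSE]
    if (nrow(v) == 0L) NA_real_ else mean(v$converted)
})

#' @rdname accessors
#' @export
setGeneric("greenChannel", function(x) standardGeneric("greenChannel"))
#' @rdname accessors
#' @export
setMethod("greenChannel", "ImagePair", function(x) x@green)

#' @rdname accessors
#' @export
setGeneric("redChannel", function(x) standardGeneric("redChannel"))
#' @rdname accessors
#' @export
setMethod("redChannel", "ImagePair", function(x) x@red)

#' @rdname accessors
#' @export
setGeneric("zprimeValue", function(x) standardGeneric("zprimeValue"))
#' @rdname accessors
#' @export
setMethod("zprimeValue", "ZPrimeResult", function(x) x@zprime)
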