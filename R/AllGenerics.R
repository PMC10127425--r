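#' Accessors for spectral and result classes
#'
#' `wavelengths()` and `intensities()` return the grid and values of a
#' [Spectrum-class]; `catches()` the relative quantum catches of a
#' [ChromaticPoint-class]; `achievedChroma()` its achieved chroma;
#' `rptEstimate()` the point estimate of a [RepeatabilityResult-class].
#'
#' @param x an object of the documented class.
#' @return A numeric vector (or scalar) holding the accessed component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))
#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setGeneric("catches", function(x) standardGeneric("catches"))
#' @rdname accessors
#' @export
setGeneric("achievedChroma", function(x) standardGeneric("achievedChroma"))
#' @rdname accessors
#' @export
setGeneric("rptEstimate", function(x) standardGeneric("rptEstimate"))

#' @rdname accessors
setMethod("wavelengths", "Spectrum", function(x) x@wavelength)
#' @rdname accessors
setMethod("intensities", "Spectrum", function(x) x@values)
#' @rdname accessors
setMethod("catches", "ChromaticPoint", function(x) x@q)
#' @rdname accessors
setMethod("achievedChroma", "ChromaticPoint", function(x) x@rA)
#' @rdname accessors
setMethod("rptEstimate", "RepeatabilityResult", function(x) x@R)

#' @describeIn accessors 95% confidence interval of a repeatability estimate.
#' @param object a [RepeatabilityResult-class].
#' @param parm,level ignored (percentile bootstrap interval as stored).
#' @param ... ignored.
#' @export
setMethod("confint", "RepeatabilityResult",
  function(object, parm, level = 0.95, ...) {
    ci <- object@CI
    names(ci) <- c("2.5 %", "97.5 %")
    ci
  })
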