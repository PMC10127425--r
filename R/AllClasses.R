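#' @import methods
NULL

#' Spectrum: a sampled function of wavelength
#'
#' Holds one spectral curve (reflectance, irradiance, transmission or
#' photoreceptor sensitivity) sampled on an ascending wavelength grid in
#' nanometres. Reflectance and transmission are dimensionless ratios;
#' irradiance is in arbitrary (relative photon-flux) units, which is
#' sufficient because all downstream chromatic quantities are invariant to
#' uniform rescaling of the illuminant.
#'
#' @slot wavelength numeric, ascending wavelengths in nm.
#' @slot values numeric, non-negative spectral values, same length.
#'
#' @examples
#' s <- Spectrum(300:700, rep(0.5, 401))
#' range(wavelengths(s))
#' @export
setClass("Spectrum",
  representation(wavelength = "numeric", values = "numeric"))

setValidity("Spectrum", function(object) {
  w <- object@wavelength; v <- object@values
  if (length(w) != length(v))
    return("wavelength and values must have equal length")
  if (length(w) == 0) return("empty spectrum")
  if (anyNA(w) || anyNA(v)) return("NA values are not allowed")
  if (is.unsorted(w, strictly = TRUE))
    return("wavelength grid must be strictly ascending")
  if (any(v < 0)) return("negative spectral values (clamp on construction)")
  TRUE
})

#' Construct a Spectrum
#'
#' Negative values (common in noisy reflectance measurements near zero) are
#' clamped to 0; the number of clamped points is reported via a warning so
#' heavy clamping is visible.
#'
#' @param wavelength ascending numeric grid, nm.
#' @param values numeric spectral values.
#' @return A [Spectrum-class] object.
#' @export
Spectrum <- function(wavelength, values) {
  wavelength <- as.numeric(wavelength)
  values <- as.numeric(values)
  neg <- sum(values < 0, na.rm = TRUE)
  if (neg > 0) {
    warning(sprintf("clamped %d negative spectral value(s) to 0", neg))
    values <- pmax(values, 0)
  }
  new("Spectrum", wavelength = wavelength, values = values)
}

setMethod("show", "Spectrum", function(object) {
  w <- object@wavelength
  cat(sprintf("Spectrum: %d points, %.4g-%.4g nm, values in [%.4g, %.4g]\n",
              length(w), min(w), max(w),
              min(object@values), max(object@values)))
})

#' ReceptorSet: a trichromatic set of photoreceptor sensitivities
#'
#' Three spectral-sensitivity curves, one per cone opsin class. The default
#' set models the three main opsins of *Pelvicachromis taeniatus* (SWS2A,
#' RH2Abeta, LWS with peak absorbance at 455, 518 and 560 nm).
#'
#' @slot labels character(3), opsin class names.
#' @slot lambdaMax numeric(3), peak wavelengths in nm.
#' @slot sensitivities list of three [Spectrum-class] objects on a common grid.
#' @export
setClass("ReceptorSet",
  representation(labels = "character", lambdaMax = "numeric",
                 sensitivities = "list"))

setValidity("ReceptorSet", function(object) {
  if (length(object@labels) != 3 || length(object@lambdaMax) != 3 ||
      length(object@sensitivities) != 3)
    return("a ReceptorSet is trichromatic: exactly three receptors")
  if (!all(vapply(object@sensitivities, is, TRUE, "Spectrum")))
    return("sensitivities must be Spectrum objects")
  g <- object@sensitivities[[1]]@wavelength
  for (s in object@sensitivities[-1])
    if (!identical(s@wavelength, g)) return("sensitivities must share a grid")
  TRUE
})

setMethod("show", "ReceptorSet", function(object) {
  cat("ReceptorSet (trichromatic):\n")
  for (i in 1:3)
    cat(sprintf("  %-8s lambda_max = %g nm\n",
                object@labels[i], object@lambdaMax[i]))
})

#' ChromaticPoint: a color in the Maxwell triangle
#'
#' Relative photoreceptor quantum catches and their barycentric embedding in
#' an equilateral triangle (centroid at the origin, centroid-to-vertex
#' distance 1). `r` is the distance from the achromatic centre, `hueAngle`
#' the direction (radians), and `rA` the achieved chroma: `r` divided by the
#' maximum distance attainable in the same hue direction, so `rA` is 1
#' exactly when one relative catch is zero.
#'
#' @slot q numeric(3), relative catches, non-negative, summing to 1.
#' @slot xy numeric(2), Maxwell-triangle coordinates.
#' @slot r numeric(1), chroma (distance from centre).
#' @slot hueAngle numeric(1), hue direction in radians (NA at the centre).
#' @slot rA numeric(1), achieved chroma in [0, 1].
#' @export
setClass("ChromaticPoint",
  representation(q = "numeric", xy = "numeric", r = "numeric",
                 hueAngle = "numeric", rA = "numeric"))

setValidity("ChromaticPoint", function(object) {
  q <- object@q
  if (length(q) != 3) return("q must have three components")
  if (any(q < -1e-12)) return("relative catches must be non-negative")
  if (abs(sum(q) - 1) > 1e-9) return("relative catches must sum to 1")
  if (object@rA < -1e-12 || object@rA > 1 + 1e-9)
    return("achieved chroma must lie in [0, 1]")
  TRUE
})

setMethod("show", "ChromaticPoint", function(object) {
  cat(sprintf("ChromaticPoint: q = (%.4f, %.4f, %.4f)\n",
              object@q[1], object@q[2], object@q[3]))
  cat(sprintf("  xy = (%.4f, %.4f), r = %.4f, hue = %.1f deg, r_A = %.4f\n",
              object@xy[1], object@xy[2], object@r,
              object@hueAngle * 180 / pi, object@rA))
})

#' FishImageSim: a synthetic standardized fish photograph
#'
#' An 8-bit-quantized sRGB raster emulating the standardized photo setup: a
#' grey background, an elliptical neutral-grey fish body with a colored
#' ventral patch, a white-standard patch and a 1 cm scale bar. Masks are
#' exact, and the ground-truth slot records the rendered patch color, the
#' exact pixel counts and the relative colored area, which serve as oracles
#' for the photo-analysis chain.
#'
#' @slot image numeric array (height x width x 3), sRGB in [0, 1] quantized
#'   to 8-bit levels.
#' @slot bodyMask logical matrix, the lateral projection of the body.
#' @slot bellyMask logical matrix, the ventral sampling region.
#' @slot whitePatch integer(4), white-standard rectangle
#'   (row0, row1, col0, col1).
#' @slot truth list of ground-truth values (patchLab, patchPx, bodyPx, rca,
#'   pxPerCm, bodyAreaCm2, seed, ...).
#' @export
setClass("FishImageSim",
  representation(image = "array", bodyMask = "matrix", bellyMask = "matrix",
                 whitePatch = "integer", truth = "list"))

setValidity("FishImageSim", function(object) {
  d <- dim(object@image)
  if (length(d) != 3 || d[3] != 3) return("image must be height x width x 3")
  if (!identical(dim(object@bodyMask), d[1:2]) ||
      !identical(dim(object@bellyMask), d[1:2]))
    return("masks must match image dimensions")
  wp <- object@whitePatch
  if (length(wp) != 4) return("whitePatch must be (row0, row1, col0, col1)")
  if (any(object@bodyMask[wp[1]:wp[2], wp[3]:wp[4]]))
    return("white patch must not overlap the body")
  tr <- object@truth
  if (!is.null(tr$patchPx) && !is.null(tr$bodyPx) && tr$bodyPx > 0) {
    if (abs(tr$patchPx / tr$bodyPx - tr$patchAreaFraction) >
        1 / tr$bodyPx + 1e-12)
      return("patch pixel count inconsistent with patch_area_fraction")
  }
  TRUE
})

setMethod("show", "FishImageSim", function(object) {
  d <- dim(object@image)
  cat(sprintf("FishImageSim: %d x %d px, body %d px, patch %d px (RCA %.4f)\n",
              d[1], d[2], object@truth$bodyPx, object@truth$patchPx,
              object@truth$rca))
  cat(sprintf("  scale %g px/cm, seed %s\n", object@truth$pxPerCm,
              format(object@truth$seed)))
})

#' RepeatabilityResult: variance-component repeatability of a measurement
#'
#' Result of a Gaussian random-intercept repeatability analysis: the
#' intraclass correlation R = sigma2_between / (sigma2_between +
#' sigma2_within), a parametric-bootstrap standard error and 95% percentile
#' confidence interval, and a p-value for R > 0.
#'
#' @slot R numeric(1), repeatability estimate in [0, 1].
#' @slot SE numeric(1), bootstrap standard error (NA if not bootstrapped).
#' @slot CI numeric(2), lower and upper confidence bounds.
#' @slot p numeric(1), p-value for the test of R = 0.
#' @slot nGroups integer(1), number of individuals (groups).
#' @slot nObs integer(1), total number of observations.
#' @slot sigma2Between,sigma2Within numeric(1), variance components.
#' @slot method character(1), p-value method ("lrt" or "permutation").
#' @export
setClass("RepeatabilityResult",
  representation(R = "numeric", SE = "numeric", CI = "numeric", p = "numeric",
                 nGroups = "integer", nObs = "integer",
                 sigma2Between = "numeric", sigma2Within = "numeric",
                 method = "character"))

setValidity("RepeatabilityResult", function(object) {
  if (object@R < 0 || object@R > 1) return("R must lie in [0, 1]")
  if (!is.na(object@p) && (object@p < 0 || object@p > 1))
    return("p must lie in [0, 1]")
  if (length(object@CI) != 2) return("CI must be (lower, upper)")
  TRUE
})

setMethod("show", "RepeatabilityResult", function(object) {
  ci <- object@CI
  cat(sprintf("Repeatability: n = %d groups (%d obs)\n",
              object@nGroups, object@nObs))
  cat(sprintf("  R = %.3f, SE = %s, CI = [%.3f, %.3f], p %s (%s)\n",
              object@R,
              if (is.na(object@SE)) "NA" else sprintf("%.3f", object@SE),
              ci[1], ci[2],
              if (is.na(object@p)) "= NA"
              else if (object@p < 0.001) "< 0.001"
              else sprintf("= %.3f", object@p),
              object@method))
})
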