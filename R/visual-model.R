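# Spectrometry chain: replicate averaging, spectral-range restriction, lens
# transmission, Govardovskii pigment templates, quantum catches under the
# measured irradiance, the Maxwell-triangle trichromatic space and achieved
# chroma.

.checkGrid <- function(a, b) {
  if (!identical(a@wavelength, b@wavelength))
    stop("spectra are on different wavelength grids; resample explicitly ",
         "with resampleSpectrum()")
}

#' Pointwise mean of replicate spectra
#'
#' @param replicates a list of [Spectrum-class] objects on a common grid.
#' @return A [Spectrum-class], the arithmetic mean at each wavelength.
#' @export
meanSpectrum <- function(replicates) {
  stopifnot(length(replicates) >= 1,
            all(vapply(replicates, is, TRUE, "Spectrum")))
  for (s in replicates[-1]) .checkGrid(replicates[[1]], s)
  vals <- rowMeans(vapply(replicates, slot, numeric(length(replicates[[1]]@values)),
                          "values"))
  new("Spectrum", wavelength = replicates[[1]]@wavelength, values = vals)
}

#' Restrict a spectrum to a wavelength window
#'
#' The analysis considers 300-700 nm, the likely visual range of cichlids;
#' this trims a spectrum to that (or any) window.
#'
#' @param spectrum a [Spectrum-class].
#' @param lower,upper window bounds in nm (inclusive).
#' @return The restricted [Spectrum-class].
#' @export
restrictSpectrum <- function(spectrum, lower = 300, upper = 700) {
  keep <- spectrum@wavelength >= lower & spectrum@wavelength <= upper
  if (!any(keep)) stop("no wavelengths left after restriction")
  new("Spectrum", wavelength = spectrum@wavelength[keep],
      values = spectrum@values[keep])
}

#' Linear resampling of a spectrum onto a new grid
#'
#' Resampling is always explicit in this package (operations on mismatched
#' grids are errors, never silent interpolation).
#'
#' @param spectrum a [Spectrum-class].
#' @param grid target wavelengths, nm; must lie within the source range.
#' @return The resampled [Spectrum-class].
#' @export
resampleSpectrum <- function(spectrum, grid) {
  r <- range(spectrum@wavelength)
  if (min(grid) < r[1] || max(grid) > r[2])
    stop("target grid extends beyond the measured range; no extrapolation")
  v <- stats::approx(spectrum@wavelength, spectrum@values, xout = grid)$y
  new("Spectrum", wavelength = as.numeric(grid), values = v)
}

#' Apply lens transmission to a reflectance spectrum
#'
#' Ocular-media correction: pointwise multiplication of the (mean)
#' reflectance with the lens transmission.
#'
#' @param reflectance,lens [Spectrum-class] objects on a common grid.
#' @return The effective reflectance [Spectrum-class].
#' @export
applyLens <- function(reflectance, lens) {
  .checkGrid(reflectance, lens)
  new("Spectrum", wavelength = reflectance@wavelength,
      values = reflectance@values * lens@values)
}

#' Govardovskii A1 visual-pigment template
#'
#' Absorbance spectrum of a vitamin-A1 visual pigment from its peak
#' wavelength alone, alpha band plus beta band, peak-normalized to 1 on the
#' grid. Alpha band:
#' `S(x) = 1 / (exp(A(a - x)) + exp(B(b - x)) + exp(C(c - x)) + D)` with
#' `x = lambdaMax / lambda`, `A = 69.7`, `B = 28`, `C = -14.9`,
#' `D = 0.674`, `b = 0.922`, `c = 1.104`, and
#' `a = 0.8795 + 0.0459 exp(-(lambdaMax - 300)^2 / 11940)`. Beta band:
#' `0.26 exp(-((lambda - mb) / wb)^2)` with `mb = 189 + 0.315 lambdaMax`
#' and `wb = -40.5 + 0.195 lambdaMax`.
#'
#' @param lambdaMax peak wavelength, nm (330-700).
#' @param grid wavelength grid, nm (default 300-700 at 1 nm).
#' @return A peak-normalized sensitivity [Spectrum-class].
#' @export
pigmentTemplate <- function(lambdaMax, grid = 300:700) {
  stopifnot(lambdaMax >= 330, lambdaMax <= 700)
  grid <- as.numeric(grid)
  x <- lambdaMax / grid
  a <- 0.8795 + 0.0459 * exp(-(lambdaMax - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                exp(-14.9 * (1.104 - x)) + 0.674)
  mb <- 189 + 0.315 * lambdaMax
  wb <- -40.5 + 0.195 * lambdaMax
  beta <- 0.26 * exp(-((grid - mb) / wb)^2)
  v <- alpha + beta
  new("Spectrum", wavelength = grid, values = v / max(v))
}

#' Construct a trichromatic receptor set
#'
#' Builds the three cone sensitivities from Govardovskii templates. The
#' default peaks (455, 518, 560 nm) are the SWS2A, RH2Abeta and LWS opsins
#' of *Pelvicachromis taeniatus*. `normalize = "area"` rescales each curve
#' to unit integral instead of unit peak (useful for achromatic-limit
#' checks, where equal-area sensitivities map a flat stimulus to the
#' achromatic centre under a flat illuminant).
#'
#' @param lambdaMax numeric(3) peak wavelengths, nm.
#' @param labels receptor names.
#' @param grid wavelength grid, nm.
#' @param normalize "peak" (default) or "area".
#' @return A [ReceptorSet-class].
#' @export
receptorSet <- function(lambdaMax = c(455, 518, 560),
                        labels = c("SWS2A", "RH2Ab", "LWS"),
                        grid = 300:700, normalize = c("peak", "area")) {
  normalize <- match.arg(normalize)
  stopifnot(length(lambdaMax) == 3, length(labels) == 3)
  sens <- lapply(lambdaMax, pigmentTemplate, grid = grid)
  if (normalize == "area") {
    sens <- lapply(sens, function(s) {
      new("Spectrum", wavelength = s@wavelength,
          values = s@values / .trapz(s@wavelength, s@values))
    })
  }
  new("ReceptorSet", labels = labels, lambdaMax = as.numeric(lambdaMax),
      sensitivities = sens)
}

# trapezoid rule on an (arbitrary ascending) grid
.trapz <- function(w, v) {
  n <- length(w)
  sum(diff(w) * (v[-1] + v[-n]) / 2)
}

#' Photoreceptor quantum catch
#'
#' Integral over wavelength of reflectance x irradiance x sensitivity,
#' trapezoid rule on the native grid.
#'
#' @param reflectance effective reflectance [Spectrum-class].
#' @param irradiance illuminant [Spectrum-class] (same grid).
#' @param sensitivity receptor sensitivity [Spectrum-class] (same grid).
#' @return The catch (scalar, arbitrary units).
#' @export
quantumCatch <- function(reflectance, irradiance, sensitivity) {
  .checkGrid(reflectance, irradiance)
  .checkGrid(reflectance, sensitivity)
  if (length(reflectance@wavelength) < 2)
    stop("at least two grid points are required")
  if (all(irradiance@values == 0))
    stop("irradiance is identically zero: stimulus undefined")
  .trapz(reflectance@wavelength,
         reflectance@values * irradiance@values * sensitivity@values)
}

# Maxwell-triangle geometry: vertices at 90, 210, 330 degrees, centroid at
# the origin, centroid-to-vertex distance 1 (so the inradius is 1/2).
.triVertices <- function() {
  ang <- c(90, 210, 330) * pi / 180
  cbind(cos(ang), sin(ang))
}

#' Maximum chroma attainable in a hue direction
#'
#' Distance from the achromatic centre of the Maxwell triangle to its
#' boundary along direction `theta`: `0.5 / cos(delta)`, where `delta` is
#' the angle to the nearest edge normal (the inradius of the triangle is
#' 0.5 with centroid-to-vertex distance 1).
#'
#' @param theta hue angle(s), radians.
#' @return Numeric vector of boundary distances in \[0.5, 1\].
#' @export
maxChroma <- function(theta) {
  normals <- c(30, 150, 270) * pi / 180
  d <- vapply(theta, function(t) {
    delta <- abs(((t - normals + pi) %% (2 * pi)) - pi)
    min(delta)
  }, numeric(1))
  0.5 / cos(d)
}

#' Chromatic point from three quantum catches
#'
#' Normalizes the catches to relative excitations `q = Q / sum(Q)`, embeds
#' them barycentrically in the Maxwell triangle (catch 1 at the top vertex,
#' catches 2 and 3 at the lower-left and lower-right), and computes chroma
#' `r`, hue angle, and achieved chroma `rA = r / maxChroma(hue)` -- chroma
#' relative to the most saturated color of the same hue, so `rA = 1`
#' exactly on the triangle boundary (some `q` component equal to 0).
#'
#' @param Q numeric(3) of non-negative catches, not all zero.
#' @param log if TRUE, catches are log-transformed (`log(1 + Q)`) before
#'   normalization, the alternative receptor-response form.
#' @return A [ChromaticPoint-class].
#' @examples
#' chromaticPoint(c(1, 1, 1))@rA   # achromatic centre
#' chromaticPoint(c(1, 0, 0))@rA   # spectral vertex
#' @export
chromaticPoint <- function(Q, log = FALSE) {
  stopifnot(length(Q) == 3)
  if (any(Q < 0)) stop("quantum catches must be non-negative")
  if (log) Q <- base::log(1 + Q)
  s <- sum(Q)
  if (s == 0) stop("all quantum catches are zero: chromaticity undefined")
  q <- Q / s
  xy <- as.vector(q %*% .triVertices())
  r <- sqrt(sum(xy^2))
  if (r < 1e-14) {
    return(new("ChromaticPoint", q = q, xy = c(0, 0), r = 0,
               hueAngle = NA_real_, rA = 0))
  }
  hue <- atan2(xy[2], xy[1])
  new("ChromaticPoint", q = q, xy = xy, r = r, hueAngle = hue,
      rA = min(r / maxChroma(hue), 1))
}

#' The full spectrometry chain for one individual
#'
#' Mean of the replicate reflectance spectra, restriction to 300-700 nm,
#' lens-transmission correction, quantum catches for the three receptors
#' under the given irradiance, and the chromatic point with achieved
#' chroma. Optionally applies von Kries normalization (each catch divided
#' by the catch of a perfect white under the same illuminant).
#'
#' @param replicates list of reflectance [Spectrum-class] replicates.
#' @param lens lens-transmission [Spectrum-class].
#' @param irradiance illuminant [Spectrum-class].
#' @param receptors a [ReceptorSet-class].
#' @param vonKries logical, chromatic adaptation to the illuminant
#'   (default FALSE: the model is applied to raw relative excitations).
#' @param log logical, log-transform catches (default FALSE, linear).
#' @return A list: `point` (the [ChromaticPoint-class]), `Q` (raw catches,
#'   named by receptor), `meanReflectance` (the processed spectrum).
#' @export
spectraPipeline <- function(replicates, lens, irradiance,
                            receptors = receptorSet(), vonKries = FALSE,
                            log = FALSE) {
  m <- meanSpectrum(replicates)
  m <- restrictSpectrum(m, 300, 700)
  grid <- m@wavelength
  lensR <- if (identical(lens@wavelength, grid)) lens
           else resampleSpectrum(lens, grid)
  irrR <- if (identical(irradiance@wavelength, grid)) irradiance
          else resampleSpectrum(irradiance, grid)
  eff <- applyLens(m, lensR)
  sens <- lapply(receptors@sensitivities, function(s) {
    if (identical(s@wavelength, grid)) s else resampleSpectrum(s, grid)
  })
  Q <- vapply(sens, function(s) quantumCatch(eff, irrR, s), numeric(1))
  names(Q) <- receptors@labels
  if (vonKries) {
    white <- new("Spectrum", wavelength = grid,
                 values = rep(1, length(grid)))
    Qw <- vapply(sens, function(s) quantumCatch(white, irrR, s), numeric(1))
    Q <- Q / Qw
  }
  list(point = chromaticPoint(Q, log = log), Q = Q, meanReflectance = eff)
}
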