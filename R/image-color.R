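# The photo-based quantification chain: white-standard calibration, CIELab
# belly sampling and Lab-chromaticity, HSB-threshold segmentation of the
# colored area with a minimum-component rule, lateral projection area,
# relative colored area, and the Fulton-type condition index.

#' HSB selection thresholds
#'
#' Inclusive per-channel ranges on the 8-bit (0-255) HSB scale used to
#' select colored pixels, the convention of 8-bit image-editor sliders
#' (hue 0-255 spans 0-360 degrees, so the male hue range 0-64 covers
#' red through yellow, roughly 0-90 degrees). `maleThresholds()` selects the
#' yellow ventral ornament of males; `femaleThresholds()` the purple nuptial
#' coloration of females. Hue wraparound is expressed as `hueLo > hueHi`.
#'
#' @param hueLo,hueHi,satLo,satHi,brightLo,brightHi integers in \[0, 255\].
#' @return A validated list of class `colorThresholds`.
#' @examples
#' maleThresholds()
#' @export
colorThresholds <- function(hueLo, hueHi, satLo, satHi, brightLo, brightHi) {
  v <- c(hueLo, hueHi, satLo, satHi, brightLo, brightHi)
  stopifnot(all(v >= 0), all(v <= 255), all(v == round(v)),
            satLo <= satHi, brightLo <= brightHi)
  structure(list(hueLo = hueLo, hueHi = hueHi, satLo = satLo, satHi = satHi,
                 brightLo = brightLo, brightHi = brightHi),
            class = "colorThresholds")
}

#' @rdname colorThresholds
#' @export
maleThresholds <- function() colorThresholds(0, 64, 100, 255, 66, 255)

#' @rdname colorThresholds
#' @export
femaleThresholds <- function() colorThresholds(154, 255, 5, 255, 66, 255)

#' White-standard calibration of an image
#'
#' Adjusts image brightness using the white standard included in the
#' photograph: each channel is scaled in linear-RGB space (gamma removed
#' first) by `reference / observed`, where `observed` is the channel mean
#' over the white-patch region. Values driven above the channel maximum are
#' clipped, with a warning reporting the clipped-pixel count.
#'
#' @param image numeric array (h x w x 3), sRGB in \[0, 1\].
#' @param whitePatch integer(4) rectangle (row0, row1, col0, col1), or a
#'   logical mask matrix.
#' @param referenceRgb the known sRGB value of the white standard
#'   (length 3, in \[0, 1\]).
#' @return The calibrated image (same shape, sRGB in \[0, 1\]).
#' @export
calibrateWhite <- function(image, whitePatch, referenceRgb) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3,
            length(referenceRgb) == 3)
  mask <- if (is.matrix(whitePatch) && is.logical(whitePatch)) whitePatch
  else {
    stopifnot(length(whitePatch) == 4)
    m <- matrix(FALSE, dim(image)[1], dim(image)[2])
    m[whitePatch[1]:whitePatch[2], whitePatch[3]:whitePatch[4]] <- TRUE
    m
  }
  if (!any(mask)) stop("white patch region is empty")
  lin <- srgbDecode(image)
  refLin <- srgbDecode(referenceRgb)
  out <- lin
  clipped <- 0L
  for (ch in 1:3) {
    obs <- mean(lin[, , ch][mask])
    if (obs <= 0)
      stop(sprintf("white patch channel %d has zero mean; cannot calibrate", ch))
    scaled <- lin[, , ch] * (refLin[ch] / obs)
    clipped <- clipped + sum(scaled > 1)
    out[, , ch] <- pmin(scaled, 1)
  }
  if (clipped > 0)
    warning(sprintf("calibration clipped %d pixel value(s) at channel maximum",
                    clipped))
  srgbEncode(out)
}

#' Dim an image in linear-light space
#'
#' Multiplies linear RGB by `factor` and re-encodes, emulating a uniformly
#' weaker illumination; 8-bit quantization is applied so the result matches
#' what a darker photograph would contain.
#'
#' @param image sRGB array in \[0, 1\].
#' @param factor positive scalar (< 1 dims, > 1 brightens).
#' @return The dimmed, quantized image.
#' @export
dimImage <- function(image, factor) {
  stopifnot(factor > 0)
  quantize8(srgbEncode(pmin(srgbDecode(image) * factor, 1)))
}

#' Lab-chromaticity
#'
#' `LC = sqrt(a^2 + b^2)`: the distance of a CIELab color from the
#' achromatic axis, independent of lightness L.
#'
#' @param a,b chromatic coordinates (vectorized).
#' @return Non-negative numeric vector.
#' @examples
#' labChromaticity(20, 21)  # 29
#' @export
labChromaticity <- function(a, b) sqrt(a^2 + b^2)

#' Sample belly color in CIELab
#'
#' Places `nSamples` points on a deterministic, evenly spaced grid over the
#' bounding box of the belly mask; points falling outside the mask are
#' snapped to the nearest mask pixel. Each sample averages the pixel values
#' within a small disc (radius `radius`, restricted to the mask) -- the
#' eyedropper-style local mean -- and converts the mean sRGB to CIELab.
#'
#' @param image calibrated sRGB array in \[0, 1\].
#' @param bellyMask logical matrix marking the ventral sampling region.
#' @param nSamples number of sample points (default 16).
#' @param radius sampling radius in px (default 2).
#' @return A list with `samples` (data.frame: row, col, L, a, b, LC),
#'   `meanLab` (length 3) and `meanLC` (mean of per-sample LC values).
#' @export
sampleBelly <- function(image, bellyMask, nSamples = 16L, radius = 2L) {
  stopifnot(length(dim(image)) == 3, is.logical(bellyMask))
  nMask <- sum(bellyMask)
  if (nMask < nSamples)
    stop(sprintf("belly mask has %d px; at least %d required for %d samples",
                 nMask, nSamples, nSamples))
  idx <- which(bellyMask, arr.ind = TRUE)
  r0 <- range(idx[, 1]); c0 <- range(idx[, 2])

  nr <- max(1L, floor(sqrt(nSamples)))
  nc <- ceiling(nSamples / nr)
  gr <- r0[1] + (seq_len(nr) - 0.5) / nr * (r0[2] - r0[1] + 1)
  gc <- c0[1] + (seq_len(nc) - 0.5) / nc * (c0[2] - c0[1] + 1)
  pts <- expand.grid(row = gr, col = gc)[seq_len(nSamples), ]

  snap <- function(p) {
    i <- round(p[1]); j <- round(p[2])
    if (i >= 1 && i <= nrow(bellyMask) && j >= 1 && j <= ncol(bellyMask) &&
        bellyMask[i, j]) return(c(i, j))
    d2 <- (idx[, 1] - p[1])^2 + (idx[, 2] - p[2])^2
    idx[which.min(d2), ]
  }
  pos <- t(apply(as.matrix(pts), 1, snap))

  sampleOne <- function(i, j) {
    ri <- max(1, i - radius):min(nrow(bellyMask), i + radius)
    ci <- max(1, j - radius):min(ncol(bellyMask), j + radius)
    sub <- bellyMask[ri, ci, drop = FALSE] &
      outer((ri - i)^2, (ci - j)^2, "+") <= radius^2
    if (!any(sub)) sub[] <- TRUE  # isolated pixel: fall back to the box
    vapply(1:3, function(ch) mean(image[ri, ci, ch][sub]), numeric(1))
  }
  rgb <- t(vapply(seq_len(nSamples),
                  function(k) sampleOne(pos[k, 1], pos[k, 2]), numeric(3)))
  lab <- rgb2lab(rgb)
  samples <- data.frame(row = pos[, 1], col = pos[, 2],
                        L = lab[, 1], a = lab[, 2], b = lab[, 3],
                        LC = labChromaticity(lab[, 2], lab[, 3]))
  list(samples = samples, meanLab = colMeans(lab), meanLC = mean(samples$LC))
}

#' HSB-threshold pixel selection
#'
#' Selects the pixels whose hue, saturation and brightness (each on the
#' 0-255 scale) all fall inclusively within the threshold ranges. Hue wraps
#' around: with `hueLo > hueHi` the selected hue set is
#' `[hueLo, 255] U [0, hueHi]`.
#'
#' @param image sRGB array in \[0, 1\].
#' @param thresholds a [colorThresholds()] object.
#' @return Logical matrix of selected pixels.
#' @export
hsbMask <- function(image, thresholds) {
  stopifnot(inherits(thresholds, "colorThresholds"))
  hsb <- imageHsb255(image)
  hueIn <- if (thresholds$hueLo <= thresholds$hueHi)
    hsb$h >= thresholds$hueLo & hsb$h <= thresholds$hueHi
  else
    hsb$h >= thresholds$hueLo | hsb$h <= thresholds$hueHi
  hueIn &
    hsb$s >= thresholds$satLo & hsb$s <= thresholds$satHi &
    hsb$b >= thresholds$brightLo & hsb$b <= thresholds$brightHi
}

#' Colored area from a binary mask
#'
#' Labels 8-connected components of the selection mask and sums the areas of
#' the components larger than `minComponentCm2` (strictly greater, the
#' "greater than 0.05 cm^2" rule), converting pixels to cm^2 with the image
#' scale.
#'
#' @param mask logical matrix of selected pixels.
#' @param pxPerCm image scale (pixels per cm).
#' @param minComponentCm2 minimum component area retained (default 0.05).
#' @param largestOnly if TRUE, keep only the largest qualifying component.
#' @return A list: `coloredCm2`, `nComponentsKept`, `componentAreasCm2`,
#'   `keptMask`.
#' @export
coloredArea <- function(mask, pxPerCm, minComponentCm2 = 0.05,
                        largestOnly = FALSE) {
  stopifnot(pxPerCm > 0)
  lab <- labelComponents(mask, connectivity = 8)
  if (max(lab) == 0)
    return(list(coloredCm2 = 0, nComponentsKept = 0L,
                componentAreasCm2 = numeric(0), keptMask = mask & FALSE))
  areasPx <- tabulate(lab[lab > 0])
  areasCm2 <- areasPx / pxPerCm^2
  keep <- which(areasCm2 > minComponentCm2)
  if (largestOnly && length(keep) > 1) keep <- keep[which.max(areasCm2[keep])]
  list(coloredCm2 = sum(areasCm2[keep]),
       nComponentsKept = length(keep),
       componentAreasCm2 = areasCm2[keep],
       keptMask = matrix(lab %in% keep, nrow(mask), ncol(mask)))
}

#' Lateral projection area and relative colored area
#'
#' `LPA` is the body-mask area in cm^2 (the lateral silhouette excluding
#' fins); `RCA = coloredCm2 / LPA`.
#'
#' @param coloredCm2 colored area in cm^2 (from [coloredArea()]).
#' @param bodyMask logical body mask.
#' @param pxPerCm image scale.
#' @return A list with `LPA` and `RCA`.
#' @export
relativeColoredArea <- function(coloredCm2, bodyMask, pxPerCm) {
  stopifnot(pxPerCm > 0)
  lpa <- sum(bodyMask) / pxPerCm^2
  if (lpa == 0) stop("body mask is empty: LPA is zero")
  list(LPA = lpa, RCA = coloredCm2 / lpa)
}

#' Fulton-type body condition index
#'
#' `CI = 100 * mass / SL^3` in g/cm^3 (condition index after Bolger &
#' Connolly; the factor 100 puts typical values near 2-3).
#'
#' @param massG body mass in grams.
#' @param slCm standard length in cm.
#' @return CI in g/cm^3 (vectorized).
#' @examples
#' conditionIndex(5, 6)  # 2.3148
#' @export
conditionIndex <- function(massG, slCm) {
  if (any(massG <= 0) || any(slCm <= 0))
    stop("mass and standard length must be positive")
  100 * massG / slCm^3
}

#' Run the full photo-analysis chain on one image
#'
#' Calibrate against the white standard, sample the belly in CIELab, select
#' colored pixels by HSB thresholds restricted to the body mask, apply the
#' minimum-component rule, and compute LPA and RCA.
#'
#' @param image sRGB array, or a [FishImageSim-class] (whose masks, white
#'   patch and scale are then used as the measurement inputs).
#' @param bodyMask,bellyMask,whitePatch,referenceRgb,pxPerCm measurement
#'   inputs; taken from the `FishImageSim` when omitted.
#' @param thresholds HSB thresholds (default [maleThresholds()]).
#' @param minComponentCm2 minimum component area (default 0.05 cm^2).
#' @param calibrate logical; apply white calibration first (default TRUE).
#' @return A one-row data.frame: L_mean, a_mean, b_mean, LC, LPA_cm2,
#'   colored_cm2, RCA, n_components.
#' @export
measureFishImage <- function(image, bodyMask = NULL, bellyMask = NULL,
                             whitePatch = NULL, referenceRgb = NULL,
                             pxPerCm = NULL, thresholds = maleThresholds(),
                             minComponentCm2 = 0.05, calibrate = TRUE) {
  if (is(image, "FishImageSim")) {
    sim <- image
    image <- sim@image
    if (is.null(bodyMask)) bodyMask <- sim@bodyMask
    if (is.null(bellyMask)) bellyMask <- sim@bellyMask
    if (is.null(whitePatch)) whitePatch <- sim@whitePatch
    if (is.null(referenceRgb)) referenceRgb <- sim@truth$whiteSrgb
    if (is.null(pxPerCm)) pxPerCm <- sim@truth$pxPerCm
  }
  stopifnot(!is.null(bodyMask), !is.null(pxPerCm))
  if (calibrate) {
    stopifnot(!is.null(whitePatch), !is.null(referenceRgb))
    image <- calibrateWhite(image, whitePatch, referenceRgb)
  }
  belly <- sampleBelly(image, bellyMask)
  mask <- hsbMask(image, thresholds) & bodyMask
  ca <- coloredArea(mask, pxPerCm, minComponentCm2)
  rel <- relativeColoredArea(ca$coloredCm2, bodyMask, pxPerCm)
  data.frame(L_mean = belly$meanLab[1], a_mean = belly$meanLab[2],
             b_mean = belly$meanLab[3], LC = belly$meanLC,
             LPA_cm2 = rel$LPA, colored_cm2 = ca$coloredCm2, RCA = rel$RCA,
             n_components = ca$nComponentsKept)
}
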