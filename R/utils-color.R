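# Color-space plumbing shared by the photo-analysis chain.
#
# Images are numeric arrays (height x width x 3) holding nonlinear sRGB in
# [0, 1], as returned by png::readPNG. Calibration operates in linear RGB
# (gamma removed), color sampling in CIE 1976 L*a*b* with D65 reference
# white -- D65 approximates the 6500 K illumination of the photo setup.

#' sRGB transfer functions
#'
#' `srgbDecode()` maps nonlinear sRGB values in \[0, 1\] to linear-light RGB;
#' `srgbEncode()` is its inverse (IEC 61966-2-1 piecewise curve).
#'
#' @param x numeric vector/array in \[0, 1\].
#' @return Numeric object of the same shape.
#' @export
srgbDecode <- function(x) {
  ifelse(x <= 0.04045, x / 12.92, ((x + 0.055) / 1.055)^2.4)
}

#' @rdname srgbDecode
#' @export
srgbEncode <- function(x) {
  ifelse(x <= 0.0031308, 12.92 * x, 1.055 * x^(1 / 2.4) - 0.055)
}

#' Convert between sRGB and CIELab
#'
#' Thin wrappers around [grDevices::convertColor()] fixing the conventions
#' used throughout the package: nonlinear sRGB in \[0, 1\], CIE 1976 L*a*b*
#' with D65 reference white. `lab2rgb()` raises an error for colors outside
#' the sRGB gamut rather than clipping silently.
#'
#' @param rgb numeric matrix (n x 3) of sRGB values in \[0, 1\], or a single
#'   length-3 vector.
#' @param lab numeric matrix (n x 3) of L, a, b values, or a length-3 vector.
#' @return A matrix (n x 3) in the target space.
#' @examples
#' lab <- rgb2lab(c(0.83, 0.64, 0.26))
#' rgb <- lab2rgb(lab)
#' @export
rgb2lab <- function(rgb) {
  if (is.null(dim(rgb))) rgb <- matrix(rgb, ncol = 3)
  grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
}

#' @rdname rgb2lab
#' @export
lab2rgb <- function(lab) {
  if (is.null(dim(lab))) lab <- matrix(lab, ncol = 3)
  out <- grDevices::convertColor(lab, from = "Lab", to = "sRGB", clip = NA)
  if (anyNA(out)) {
    bad <- which(apply(out, 1, anyNA))
    stop(sprintf(
      "Lab color(s) outside the sRGB gamut (row %s): cannot be rendered",
      paste(bad, collapse = ", ")))
  }
  out
}

#' Per-pixel CIELab color difference
#'
#' Euclidean distance in L*a*b* (the CIE 1976 Delta-E).
#'
#' @param lab1,lab2 matrices (n x 3) or length-3 vectors of Lab colors.
#' @return Numeric vector of Delta-E values.
#' @export
deltaE <- function(lab1, lab2) {
  if (is.null(dim(lab1))) lab1 <- matrix(lab1, ncol = 3)
  if (is.null(dim(lab2))) lab2 <- matrix(lab2, ncol = 3)
  sqrt(rowSums((lab1 - lab2)^2))
}

#' Convert an sRGB image to 8-bit HSB channels
#'
#' Returns hue, saturation and brightness each expressed on the 0-255 scale
#' used by 8-bit image-editor sliders (hue 0-255 spans the full 0-360 degree
#' circle).
#'
#' @param image numeric array (h x w x 3), sRGB in \[0, 1\].
#' @return A list with matrices `h`, `s`, `b` on the 0-255 scale.
#' @export
imageHsb255 <- function(image) {
  d <- dim(image)
  rgb <- rbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
               as.vector(image[, , 3]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  list(h = matrix(hsv[1, ] * 255, d[1], d[2]),
       s = matrix(hsv[2, ] * 255, d[1], d[2]),
       b = matrix(hsv[3, ] * 255, d[1], d[2]))
}

# Quantize an sRGB [0,1] array to the 8-bit levels a PNG round-trip yields.
quantize8 <- function(x) round(pmin(pmax(x, 0), 1) * 255) / 255
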