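# Synthetic-data generators. Every downstream stage of the package is
# testable against these because each generator records its ground truth:
# the exact rendered patch color and pixel counts for images, the noiseless
# curve for reflectance sets, the true variance components for repeated
# measures, and the true slopes/log-odds for dyadic-contest data.
# All generators are pure functions of their arguments including the seed.

#' Simulation configuration
#'
#' Bundles the parameters shared by the tabular generators
#' ([genRepeatedMeasures()] and [genDyadData()]). Defaults emulate the study
#' conditions of the motivating experiment: 46 males measured twice, 23
#' dyadic contests drawn from 12 families.
#'
#' @param nIndividuals number of individuals for repeated measures.
#' @param nReplicates replicates per individual.
#' @param sigma2Between,sigma2Within between- and within-individual
#'   variances of the repeated measurement.
#' @param nPairs number of dyadic contests.
#' @param nFamilies number of families males are drawn from.
#' @param betaDisplay log-odds slope of the display difference on dominance.
#' @param slopeDominant,slopeSubordinate display-to-color slopes conditional
#'   on dominance status (color units per second of display).
#' @param familySd SD of the family random effect (on the dominance
#'   log-odds and, scaled, on color).
#' @param seed integer seed fixing the full output.
#' @return A validated list of class `simConfig`.
#' @export
simConfig <- function(nIndividuals = 46L, nReplicates = 2L,
                      sigma2Between = 50, sigma2Within = 50,
                      nPairs = 23L, nFamilies = 12L,
                      betaDisplay = 0.06,
                      slopeDominant = 0.1, slopeSubordinate = -0.1,
                      familySd = 0.5, seed = 1L) {
  stopifnot(nIndividuals >= 1, nReplicates >= 1, nPairs >= 1, nFamilies >= 2,
            sigma2Between >= 0, sigma2Within >= 0, familySd >= 0,
            seed == round(seed))
  structure(list(nIndividuals = as.integer(nIndividuals),
                 nReplicates = as.integer(nReplicates),
                 sigma2Between = sigma2Between, sigma2Within = sigma2Within,
                 nPairs = as.integer(nPairs), nFamilies = as.integer(nFamilies),
                 betaDisplay = betaDisplay, slopeDominant = slopeDominant,
                 slopeSubordinate = slopeSubordinate, familySd = familySd,
                 seed = as.integer(seed)),
            class = "simConfig")
}

#' Ground truth for a synthetic fish photograph
#'
#' @param patchAreaFraction fraction of body pixels covered by the colored
#'   ventral patch, in \[0, 1\].
#' @param patchLab length-3 CIELab color of the patch; the default is a
#'   saturated carotenoid yellow that falls inside the male HSB selection
#'   thresholds.
#' @param bodyAreaCm2 lateral projection area of the body ellipse, cm^2.
#' @param pxPerCm image scale.
#' @param noiseSd SD of Gaussian pixel noise added in (nonlinear) sRGB
#'   units; emulates sensor noise.
#' @param seed integer seed.
#' @return A validated list of class `imageGroundTruth`.
#' @export
imageGroundTruth <- function(patchAreaFraction = 0.1,
                             patchLab = c(70, 8, 55),
                             bodyAreaCm2 = 12, pxPerCm = 40,
                             noiseSd = 0.003, seed = 1L) {
  stopifnot(patchAreaFraction >= 0, patchAreaFraction <= 1,
            length(patchLab) == 3, bodyAreaCm2 > 0, pxPerCm > 0,
            noiseSd >= 0, seed == round(seed))
  structure(list(patchAreaFraction = patchAreaFraction,
                 patchLab = as.numeric(patchLab),
                 bodyAreaCm2 = bodyAreaCm2, pxPerCm = pxPerCm,
                 noiseSd = noiseSd, seed = as.integer(seed)),
            class = "imageGroundTruth")
}

# sRGB values used for the synthetic scene. Background and body are neutral
# greys (zero saturation, so the HSB color selection never picks them up);
# the white standard is rendered at linear reflectance 0.95, leaving
# headroom below channel maximum for calibration gains.
.sceneColors <- function() {
  list(background = rep(0.5, 3),
       body = rep(0.68, 3),
       white = rep(quantize8(srgbEncode(0.95)), 3),  # as rendered in 8-bit
       bar = rep(0.02, 3))
}

#' Generate a synthetic standardized fish photograph
#'
#' Renders the scene the photo-analysis chain expects: grey background, an
#' elliptical neutral-grey body, a coherent ventral patch of exactly
#' `round(patchAreaFraction * bodyPx)` pixels rendered at `patchLab`, a
#' white-standard patch of known reflectance in the top-left corner, and a
#' 1 cm scale bar. The returned masks are exact, and
#' `truth$rca = patchPx / bodyPx` is the oracle for the photo chain.
#'
#' @param truth an [imageGroundTruth()] list.
#' @return A [FishImageSim-class] object.
#' @examples
#' sim <- genFishImage(imageGroundTruth(patchAreaFraction = 0.08, seed = 3))
#' sim@truth$rca
#' @export
genFishImage <- function(truth = imageGroundTruth()) {
  stopifnot(inherits(truth, "imageGroundTruth"))
  patchRgb <- if (truth$patchAreaFraction > 0)
    lab2rgb(truth$patchLab)[1, ] else NULL   # gamut check up front

  bodyPxTarget <- truth$bodyAreaCm2 * truth$pxPerCm^2
  b <- sqrt(bodyPxTarget / (2 * pi))         # semi-minor (vertical)
  a <- 2 * b                                  # semi-major (horizontal)
  H <- as.integer(ceiling(2 * b) + 60)
  W <- as.integer(max(ceiling(2 * a) + 60, ceiling(truth$pxPerCm) + 20))
  cy <- H / 2; cx <- W / 2

  row <- matrix(seq_len(H), H, W)
  col <- matrix(seq_len(W), H, W, byrow = TRUE)
  bodyMask <- ((col - cx) / a)^2 + ((row - cy) / b)^2 <= 1
  bodyPx <- sum(bodyMask)

  # ventral patch: exact pixel count, coherent. Fill whole rows from the
  # bottom of the ellipse upward; complete the count with a centred
  # contiguous span of the first row that does not fit entirely.
  nPatch <- round(truth$patchAreaFraction * bodyPx)
  patchMask <- matrix(FALSE, H, W)
  if (nPatch > 0) {
    rowsWithBody <- which(rowSums(bodyMask) > 0)
    left <- nPatch
    for (i in rev(rowsWithBody)) {
      cols <- which(bodyMask[i, ])
      if (length(cols) <= left) {
        patchMask[i, cols] <- TRUE
        left <- left - length(cols)
      } else {
        off <- (length(cols) - left) %/% 2
        patchMask[i, cols[(off + 1):(off + left)]] <- TRUE
        left <- 0L
      }
      if (left == 0L) break
    }
  }

  sc <- .sceneColors()
  img <- array(rep(sc$background, each = H * W), dim = c(H, W, 3))
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[bodyMask] <- sc$body[ch]
    if (nPatch > 0) plane[patchMask] <- patchRgb[ch]
    img[, , ch] <- plane
  }

  # white standard, top-left, clear of the body
  wp <- c(6L, 17L, 6L, 17L)
  if (any(bodyMask[wp[1]:wp[2], wp[3]:wp[4]]))
    stop("white patch overlaps body; increase image margins")
  for (ch in 1:3) img[wp[1]:wp[2], wp[3]:wp[4], ch] <- sc$white[ch]

  # 1 cm scale bar, bottom-left
  barRows <- (H - 8):(H - 6)
  barCols <- 6:(5 + round(truth$pxPerCm))
  for (ch in 1:3) img[barRows, barCols, ch] <- sc$bar[ch]

  if (truth$noiseSd > 0) {
    set.seed(truth$seed)
    img <- img + array(stats::rnorm(length(img), 0, truth$noiseSd), dim(img))
  }
  img <- quantize8(img)

  belly <- if (nPatch > 0) patchMask else {
    lower <- bodyMask
    lower[seq_len(floor(cy + 0.25 * b)), ] <- FALSE
    lower
  }

  new("FishImageSim", image = img, bodyMask = bodyMask, bellyMask = belly,
      whitePatch = wp,
      truth = list(patchAreaFraction = truth$patchAreaFraction,
                   patchLab = truth$patchLab, patchRgb = patchRgb,
                   patchMask = patchMask,
                   patchPx = as.integer(nPatch), bodyPx = as.integer(bodyPx),
                   rca = nPatch / bodyPx,
                   bodyAreaCm2 = truth$bodyAreaCm2, pxPerCm = truth$pxPerCm,
                   whiteSrgb = sc$white, noiseSd = truth$noiseSd,
                   seed = truth$seed))
}

#' Generate replicate reflectance spectra with a yellow long-pass step
#'
#' Emulates replicate spectrometer readings of a carotenoid-yellow body
#' region: a sigmoidal long-pass reflectance (low below the step wavelength,
#' rising to `maxReflectance` above it) plus i.i.d. Gaussian noise per
#' replicate, on a 1 nm grid from 300 to 700 nm, clamped to \[0, 1\].
#'
#' @param nReplicates number of replicate spectra (the study averaged 10-20
#'   readings per individual).
#' @param stepWavelength wavelength of the reflectance step, nm.
#' @param maxReflectance asymptotic reflectance above the step.
#' @param noiseSd SD of the additive Gaussian noise.
#' @param baseReflectance reflectance floor below the step.
#' @param slopeNm steepness scale of the sigmoid, nm.
#' @param seed integer seed.
#' @return A list of [Spectrum-class] replicates with attributes
#'   `noiseless` (the underlying curve) and `config`.
#' @export
genReflectanceSet <- function(nReplicates = 12L, stepWavelength = 500,
                              maxReflectance = 0.55, noiseSd = 0.02,
                              baseReflectance = 0.03, slopeNm = 18,
                              seed = 1L) {
  stopifnot(nReplicates >= 1, stepWavelength >= 300, stepWavelength <= 700,
            maxReflectance >= 0, baseReflectance >= 0, slopeNm > 0,
            seed == round(seed))
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  wl <- 300:700
  clean <- baseReflectance +
    (maxReflectance - baseReflectance) / (1 + exp(-(wl - stepWavelength) / slopeNm))
  clean <- pmin(pmax(clean, 0), 1)
  set.seed(seed)
  reps <- lapply(seq_len(nReplicates), function(i) {
    v <- clean + stats::rnorm(length(wl), 0, noiseSd)
    new("Spectrum", wavelength = as.numeric(wl),
        values = pmin(pmax(v, 0), 1))
  })
  attr(reps, "noiseless") <- new("Spectrum", wavelength = as.numeric(wl),
                                 values = clean)
  attr(reps, "config") <- list(nReplicates = nReplicates,
                               stepWavelength = stepWavelength,
                               maxReflectance = maxReflectance,
                               noiseSd = noiseSd, seed = seed)
  reps
}

#' Generate the illumination and ocular-media spectra of the setup
#'
#' `kind = "irradiance"` returns a lamp-like downwelling irradiance that is
#' exactly zero below `cutoffNm` (the experimental tanks were covered with
#' UV-blocking material, so only light above 400 nm was present) and a
#' smooth positive cool-white curve above it. `kind = "lens"` returns a
#' logistic long-pass lens transmission rising from ~0 below the cutoff to
#' ~1 above it.
#'
#' @param kind "irradiance" or "lens".
#' @param cutoffNm cutoff wavelength, nm (default 400).
#' @return A [Spectrum-class] on the 1 nm grid 300-700 nm.
#' @export
genIllumination <- function(kind = c("irradiance", "lens"), cutoffNm = 400) {
  kind <- match.arg(kind)
  stopifnot(cutoffNm >= 300, cutoffNm <= 700)
  wl <- as.numeric(300:700)
  if (kind == "irradiance") {
    # cool-white LED shape: narrow blue peak + broad phosphor hump,
    # windowed to zero at and below the cutoff
    shape <- stats::dnorm(wl, 455, 18) + 1.6 * stats::dnorm(wl, 560, 70)
    window <- ifelse(wl > cutoffNm, 1 - exp(-(wl - cutoffNm) / 10), 0)
    v <- 100 * shape * window
  } else {
    v <- 1 / (1 + exp(-(wl - cutoffNm) / 8))
  }
  new("Spectrum", wavelength = wl, values = v)
}

#' Generate grouped repeated measures with known variance components
#'
#' Draws `value = mu + u_i + e_ij` with `u_i ~ N(0, sigma2Between)` and
#' `e_ij ~ N(0, sigma2Within)`: the data-generating model behind
#' variance-component repeatability. The true repeatability
#' `R = sigma2Between / (sigma2Between + sigma2Within)` is recorded in the
#' `trueR` attribute.
#'
#' @param config a [simConfig()]; `nIndividuals`, `nReplicates` and the two
#'   variances are used.
#' @param mu grand mean (default 30, the scale of Lab-chromaticity values).
#' @return A data.frame with columns `id`, `replicate`, `value` and
#'   attributes `trueR` and `config`.
#' @export
genRepeatedMeasures <- function(config = simConfig(), mu = 30) {
  stopifnot(inherits(config, "simConfig"),
            config$nIndividuals >= 2, config$nReplicates >= 2)
  set.seed(config$seed)
  k <- config$nIndividuals; m <- config$nReplicates
  u <- stats::rnorm(k, 0, sqrt(config$sigma2Between))
  e <- stats::rnorm(k * m, 0, sqrt(config$sigma2Within))
  out <- data.frame(
    id = factor(rep(sprintf("ind%03d", seq_len(k)), each = m)),
    replicate = rep(seq_len(m), k),
    value = mu + rep(u, each = m) + e)
  attr(out, "trueR") <- config$sigma2Between /
    (config$sigma2Between + config$sigma2Within)
  attr(out, "config") <- config
  out
}

#' Generate a dyadic-contest dataset with known effect structure
#'
#' Simulates staged male-male contests: per pair, two males from different
#' families with standard length, mass and condition index, a positive
#' display duration (seconds) and an attack count. Dominance within a pair
#' is drawn with log-odds `betaDisplay * (display1 - display2)` plus the
#' difference of family random effects, so display predicts dominance while
#' attacks, size and prior color do not. Conditional on the realized
#' dominance status, color (Lab-chromaticity `LC`, and relative colored
#' area `RCA` on its natural 0-1 scale) follows
#' `intercept + slope(status) * display + family effect + noise`, with
#' `slopeDominant` for dominant and `slopeSubordinate` for subordinate
#' males -- the interaction structure the mixed-model analysis targets.
#'
#' @param config a [simConfig()].
#' @param lcNoiseSd residual SD of LC (default 6).
#' @param rcaScale ratio converting LC-scale color to the RCA scale
#'   (default 1/600).
#' @param rcaIndepSd SD (on the LC scale) of the variation in RCA
#'   independent of LC; the default 3 yields an LC-RCA correlation near
#'   0.9, the collinearity real ornament measures show.
#' @return A long data.frame, two rows per trial, columns `trial`, `male`,
#'   `family`, `SL`, `mass`, `CI`, `display`, `attacks`, `dominant`, `LC`,
#'   `RCA`; ground-truth parameters in the `config` attribute.
#' @export
genDyadData <- function(config = simConfig(), lcNoiseSd = 6,
                        rcaScale = 1 / 600, rcaIndepSd = 3) {
  stopifnot(inherits(config, "simConfig"), config$nPairs >= 2,
            config$nFamilies >= 2)
  set.seed(config$seed)
  n <- config$nPairs
  fams <- t(vapply(seq_len(n),
                   function(i) sample.int(config$nFamilies, 2L),
                   integer(2)))
  uFamDom <- stats::rnorm(config$nFamilies, 0, config$familySd)
  uFamCol <- stats::rnorm(config$nFamilies, 0, 3)

  SL <- pmax(stats::rnorm(2 * n, 6.15, 0.42), 4.5)
  CI <- pmax(stats::rnorm(2 * n, 2.39, 0.21), 1.5)
  mass <- CI * SL^3 / 100
  display <- stats::rlnorm(2 * n, log(40), 0.7)
  attacks <- stats::rnbinom(2 * n, size = 3, mu = 15)

  fam <- as.vector(t(fams))
  d1 <- display[seq(1, 2 * n, 2)]; d2 <- display[seq(2, 2 * n, 2)]
  eta <- config$betaDisplay * (d1 - d2) + uFamDom[fams[, 1]] - uFamDom[fams[, 2]]
  firstWins <- stats::rbinom(n, 1, stats::plogis(eta))
  dominant <- integer(2 * n)
  dominant[seq(1, 2 * n, 2)] <- firstWins
  dominant[seq(2, 2 * n, 2)] <- 1L - firstWins

  # color depends on display conditional on status, with display centred
  # on its mean: eventual winners and losers then share the same marginal
  # color distribution (with symmetric slopes), so pre-trial color does
  # not predict dominance while the status-dependent display-color slopes
  # remain fully expressed. RCA is generated as a strongly collinear
  # companion of LC (the two measures of one ornament correlate ~0.9 in
  # real fish), not as an independent replicate of the signal.
  slope <- ifelse(dominant == 1, config$slopeDominant, config$slopeSubordinate)
  dc <- display - mean(display)
  LC <- 30 + slope * dc + uFamCol[fam] + stats::rnorm(2 * n, 0, lcNoiseSd)
  RCA <- 0.09 + rcaScale * (LC - 30 + stats::rnorm(2 * n, 0, rcaIndepSd))

  out <- data.frame(
    trial = factor(rep(sprintf("trial%03d", seq_len(n)), each = 2)),
    male = sprintf("male%03d", seq_len(2 * n)),
    family = factor(sprintf("fam%02d", fam),
                    levels = sprintf("fam%02d", seq_len(config$nFamilies))),
    SL = SL, mass = mass, CI = CI,
    display = display, attacks = attacks,
    dominant = dominant, LC = LC, RCA = RCA)
  attr(out, "config") <- config
  out
}
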