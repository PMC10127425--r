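# The photo chain: calibration, Lab sampling, HSB segmentation, component
# filtering, areas, and the condition index.

test_that("Lab-chromaticity is the Euclidean norm of (a, b)", {
  expect_identical(labChromaticity(0, 0), 0)
  expect_equal(labChromaticity(20, 21), 29)
  expect_equal(labChromaticity(-3, 4), 5)
  # independence of L is structural: LC takes no L argument; check the
  # formula on random pairs against a direct norm
  set.seed(1)
  a <- rnorm(100, 0, 40); b <- rnorm(100, 0, 40)
  expect_equal(labChromaticity(a, b), sqrt(a^2 + b^2))
})

test_that("RGB <-> Lab conversion round-trips within dE 0.5 in gamut", {
  set.seed(2)
  rgb <- matrix(runif(300, 0.05, 0.95), ncol = 3)
  lab <- rgb2lab(rgb)
  back <- rgb2lab(lab2rgb(lab))
  expect_lt(max(deltaE(lab, back)), 0.5)
  expect_error(lab2rgb(c(70, 150, 55)), "gamut")
})

test_that("white calibration is a linear per-channel gain with fixed point", {
  sim <- genFishImage(imageGroundTruth(seed = 6, noiseSd = 0))
  ref <- sim@truth$whiteSrgb
  # already at reference: unchanged (within float round-trip)
  cal <- calibrateWhite(sim@image, sim@whitePatch, ref)
  expect_equal(cal, sim@image, tolerance = 1e-12)
  # patch at half reference (linear): gains double every linear value
  halved <- srgbEncode(srgbDecode(sim@image) * 0.5)
  cal2 <- calibrateWhite(halved, sim@whitePatch, ref)
  expect_equal(srgbDecode(cal2), srgbDecode(sim@image), tolerance = 1e-9)
  # zero patch is an error
  dark <- sim@image; dark[] <- 0
  expect_error(calibrateWhite(dark, sim@whitePatch, ref), "zero")
})

test_that("dimmed-then-calibrated images recover belly Lab within dE 2", {
  sim <- genFishImage(imageGroundTruth(seed = 11))
  ref <- sampleBelly(sim@image, sim@bellyMask)
  for (f in c(0.5, 0.7, 0.9)) {
    cal <- suppressWarnings(
      calibrateWhite(dimImage(sim@image, f), sim@whitePatch,
                     sim@truth$whiteSrgb))
    got <- sampleBelly(cal, sim@bellyMask)
    expect_lt(deltaE(ref$meanLab, got$meanLab), 2)
  }
})

test_that("belly sampling recovers a uniform patch color", {
  sim <- genFishImage(imageGroundTruth(patchLab = c(70, 8, 55), seed = 3,
                                       noiseSd = 0))
  s16 <- sampleBelly(sim@image, sim@bellyMask, nSamples = 16)
  # all samples identical on a uniform patch
  expect_lt(max(s16$samples$LC) - min(s16$samples$LC), 1e-9)
  expect_lt(abs(s16$meanLC - labChromaticity(8, 55)), 0.5)
  expect_lt(deltaE(s16$meanLab, c(70, 8, 55)), 0.5)
  s1 <- sampleBelly(sim@image, sim@bellyMask, nSamples = 1)
  expect_equal(s1$meanLC, s16$meanLC, tolerance = 1e-9)
  # achromatic belly
  sim0 <- genFishImage(imageGroundTruth(patchAreaFraction = 0, seed = 3,
                                        noiseSd = 0))
  expect_lt(sampleBelly(sim0@image, sim0@bellyMask)$meanLC, 1)
  expect_error(sampleBelly(sim@image, sim@bellyMask & FALSE), "at least")
})

test_that("HSB mask applies inclusive 0-255 thresholds with hue wrap", {
  px <- function(h, s, b) {
    rgb <- grDevices::hsv(h / 255, s / 255, b / 255)
    v <- t(grDevices::col2rgb(rgb)) / 255
    array(rep(v, each = 1), c(1, 1, 3))
  }
  male <- maleThresholds()
  expect_true(hsbMask(px(32, 200, 150), male)[1, 1])
  expect_false(hsbMask(px(100, 200, 150), male)[1, 1])
  expect_false(hsbMask(px(32, 50, 150), male)[1, 1])   # saturation below 100
  expect_false(hsbMask(px(32, 200, 40), male)[1, 1])   # brightness below 66
  # wraparound range selects reds on both sides of 0
  wrap <- colorThresholds(240, 20, 100, 255, 66, 255)
  expect_true(hsbMask(px(250, 200, 150), wrap)[1, 1])
  expect_true(hsbMask(px(10, 200, 150), wrap)[1, 1])
  expect_false(hsbMask(px(128, 200, 150), wrap)[1, 1])
})

test_that("HSB mask equals the patch mask on a synthetic fish", {
  sim <- genFishImage(imageGroundTruth(patchAreaFraction = 0.15, seed = 8))
  mask <- hsbMask(sim@image, maleThresholds()) & sim@bodyMask
  expect_identical(mask, sim@truth$patchMask)
})

test_that("widening any HSB threshold never removes pixels", {
  sim <- genFishImage(imageGroundTruth(seed = 12))
  base <- colorThresholds(10, 60, 120, 240, 80, 240)
  m0 <- hsbMask(sim@image, base)
  wider <- list(colorThresholds(0, 64, 120, 240, 80, 240),
                colorThresholds(10, 60, 100, 255, 80, 240),
                colorThresholds(10, 60, 120, 240, 66, 255))
  for (w in wider) expect_true(all(m0 <= hsbMask(sim@image, w)))
  # idempotence: masking the mask's pixels again selects the same set
  expect_identical(hsbMask(sim@image, base), m0)
})

test_that("component labeling matches a brute-force flood fill", {
  set.seed(33)
  for (i in 1:8) {
    m <- matrix(runif(30 * 40) < 0.35, 30, 40)
    ours <- labelComponents(m, 8)
    bfs <- bfsLabel(m, 8)
    expect_equal(max(ours), max(bfs))
    # identical partitions (label names may differ)
    expect_true(all(tapply(bfs[m], ours[m],
                           function(v) length(unique(v))) == 1))
    ours4 <- labelComponents(m, 4)
    expect_equal(max(ours4), max(bfsLabel(m, 4)))
  }
})

test_that("colored area applies the strict 0.05 cm2 component rule", {
  pxPerCm <- 10  # 1 px = 0.01 cm2
  m <- matrix(FALSE, 40, 60)
  m[2:3, 2:3] <- TRUE                 # 4 px = 0.04 cm2 -> dropped
  expect_equal(coloredArea(m, pxPerCm)$coloredCm2, 0)
  m2 <- matrix(FALSE, 40, 60)
  m2[10:11, 10:14] <- TRUE            # 10 px = 0.10 cm2 -> kept
  expect_equal(coloredArea(m2, pxPerCm)$coloredCm2, 0.10)
  m3 <- m2; m3[30:31, 30:31] <- TRUE  # extra 0.04 blob -> 0.06 + nothing
  m3[10:11, 13:14] <- FALSE           # shrink first blob to 6 px
  res <- coloredArea(m3, pxPerCm)
  expect_equal(res$coloredCm2, 0.06)
  expect_equal(res$nComponentsKept, 1L)
  # exactly 0.05 cm2 is not "greater than 0.05"
  m4 <- matrix(FALSE, 40, 60); m4[5, 5:9] <- TRUE
  expect_equal(coloredArea(m4, pxPerCm)$coloredCm2, 0)
})

test_that("LPA and RCA follow from the body mask and scale", {
  body <- matrix(FALSE, 50, 50); body[11:40, 11:40] <- TRUE  # 900 px
  rel <- relativeColoredArea(1.2, body, pxPerCm = sqrt(900 / 15))
  expect_equal(rel$LPA, 15)
  expect_equal(rel$RCA, 0.08)
  expect_equal(relativeColoredArea(0, body, 10)$RCA, 0)
  expect_error(relativeColoredArea(1, body & FALSE, 10), "empty")
})

test_that("condition index is the Fulton formula in g/cm3", {
  expect_equal(conditionIndex(5, 6), 100 * 5 / 216)
  expect_equal(conditionIndex(10, 6), 2 * conditionIndex(5, 6))
  expect_equal(conditionIndex(5.728, 6.194), 2.41, tolerance = 0.005)
  expect_error(conditionIndex(-1, 6), "positive")
  expect_error(conditionIndex(5, 0), "positive")
})

test_that("the full photo chain recovers ground-truth RCA", {
  for (seed in c(1, 23)) {
    frac <- 0.05 + 0.2 * (seed %% 7) / 7
    sim <- genFishImage(imageGroundTruth(patchAreaFraction = frac,
                                         seed = seed))
    m <- measureFishImage(sim)
    expect_lt(abs(m$RCA - sim@truth$rca), 0.005)
    expect_lte(m$colored_cm2, m$LPA_cm2)
  }
})
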