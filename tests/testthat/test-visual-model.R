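# The spectrometry chain: averaging, lens correction, pigment templates,
# quantum catches, Maxwell-triangle geometry and achieved chroma.

flatSpec <- function(v, grid = 300:700) Spectrum(grid, rep(v, length(grid)))

test_that("mean spectrum is the pointwise mean and guards its grid", {
  s <- genReflectanceSet(nReplicates = 1, noiseSd = 0, seed = 1)[[1]]
  expect_equal(intensities(meanSpectrum(list(s, s))), intensities(s))
  expect_equal(intensities(meanSpectrum(list(flatSpec(0.2), flatSpec(0.4)))),
               rep(0.3, 401))
  reps <- genReflectanceSet(nReplicates = 12, noiseSd = 0.05, seed = 9)
  mat <- sapply(reps, intensities)
  expect_equal(intensities(meanSpectrum(reps)), rowMeans(mat))
  short <- Spectrum(400:700, rep(1, 301))
  expect_error(meanSpectrum(list(s, short)), "grid")
})

test_that("lens transmission multiplies pointwise and commutes with mean", {
  reps <- genReflectanceSet(nReplicates = 5, seed = 2)
  lens <- genIllumination("lens", 400)
  one <- flatSpec(1)
  expect_equal(intensities(applyLens(reps[[1]], one)),
               intensities(reps[[1]]))
  blocked <- Spectrum(300:700, ifelse(300:700 < 400, 0, 1))
  prod <- applyLens(reps[[1]], blocked)
  expect_true(all(intensities(prod)[wavelengths(prod) < 400] == 0))
  a <- applyLens(meanSpectrum(reps), lens)
  b <- meanSpectrum(lapply(reps, applyLens, lens = lens))
  expect_equal(intensities(a), intensities(b))
})

test_that("pigment template matches a direct transcription of the formula", {
  for (lmax in c(455, 518, 560)) {
    tpl <- pigmentTemplate(lmax)
    expect_lt(max(abs(intensities(tpl) - govardovskiiDirect(lmax, 300:700))),
              1e-9)
    expect_equal(max(intensities(tpl)), 1)
    expect_equal(wavelengths(tpl)[which.max(intensities(tpl))], lmax)
  }
  tpl560 <- pigmentTemplate(560)
  v <- intensities(tpl560)
  expect_lt(v[wavelengths(tpl560) == 455], v[wavelengths(tpl560) == 560])
  expect_error(pigmentTemplate(300))
})

test_that("quantum catch is a trapezoid integral, linear in reflectance", {
  irr <- genIllumination("irradiance", 400)
  sens <- pigmentTemplate(560)
  expect_equal(quantumCatch(flatSpec(0), irr, sens), 0)
  r <- genReflectanceSet(nReplicates = 1, seed = 4)[[1]]
  q1 <- quantumCatch(r, irr, sens)
  r3 <- Spectrum(wavelengths(r), 3 * pmin(intensities(r), 1 / 3))
  expect_equal(quantumCatch(Spectrum(wavelengths(r), intensities(r) * 0.5),
                            irr, sens), 0.5 * q1)
  expect_error(quantumCatch(r, flatSpec(0), sens), "zero")
  # step stimulus against the fine-grid oracle
  step <- Spectrum(300:700, ifelse(300:700 < 500, 0, 1))
  qStep <- quantumCatch(step, flatSpec(1), sens)
  expect_equal(qStep, fineGridCatch(step, flatSpec(1), sens),
               tolerance = 1e-9)
})

test_that("Maxwell-triangle geometry matches a ray-intersection oracle", {
  thetas <- seq(0, 2 * pi, length.out = 361)[-361]
  ours <- maxChroma(thetas)
  oracle <- vapply(thetas, triBoundaryDist, numeric(1))
  expect_lt(max(abs(ours - oracle)), 1e-9)
  # centroid-to-vertex distance at vertex hues
  expect_equal(maxChroma(pi / 2), 1)
  expect_equal(maxChroma(210 * pi / 180), 1)
  expect_equal(min(ours), 0.5)  # inradius at edge normals
})

test_that("chromatic points have the documented geometry", {
  centre <- chromaticPoint(c(1, 1, 1))
  expect_equal(centre@xy, c(0, 0))
  expect_equal(centre@r, 0)
  expect_equal(centre@rA, 0)
  vertex <- chromaticPoint(c(1, 0, 0))
  expect_equal(vertex@rA, 1)
  expect_equal(vertex@r, 1)
  edge <- chromaticPoint(c(0.5, 0.5, 0))
  expect_equal(edge@rA, 1, tolerance = 1e-9)
  expect_equal(edge@r, 0.5)  # midpoint of an edge sits at the inradius
  expect_error(chromaticPoint(c(0, 0, 0)), "zero")
  expect_error(chromaticPoint(c(-1, 1, 1)))
  # q sums to one and rA bounded over random catches
  set.seed(5)
  for (i in 1:200) {
    p <- chromaticPoint(rexp(3))
    expect_lt(abs(sum(p@q) - 1), 1e-12)
    expect_gte(p@rA, 0); expect_lte(p@rA, 1)
  }
})

test_that("achieved chroma is invariant to uniform scalings", {
  reps <- genReflectanceSet(nReplicates = 3, seed = 6)
  lens <- genIllumination("lens"); irr <- genIllumination("irradiance")
  base <- spectraPipeline(reps, lens, irr)$point@rA
  scaledRefl <- lapply(reps, function(s)
    Spectrum(wavelengths(s), intensities(s) * 0.37))
  expect_equal(spectraPipeline(scaledRefl, lens, irr)$point@rA, base,
               tolerance = 1e-12)
  irr2 <- Spectrum(wavelengths(irr), intensities(irr) * 2)
  expect_equal(spectraPipeline(reps, lens, irr2)$point@rA, base,
               tolerance = 1e-12)
})

test_that("pipeline limits: achromatic flat stimulus and long-pass hue", {
  lens <- flatSpec(1)
  irr <- flatSpec(1)
  rs <- receptorSet(normalize = "area")
  res <- spectraPipeline(list(flatSpec(0.5)), lens, irr, rs)
  expect_lt(res$point@rA, 1e-6)
  # long-pass yellow: LWS catch dominates
  yellow <- genReflectanceSet(nReplicates = 1, stepWavelength = 550,
                              noiseSd = 0, seed = 1)
  resY <- spectraPipeline(yellow, genIllumination("lens"),
                          genIllumination("irradiance"), receptorSet())
  expect_equal(which.max(resY$point@q), 3L, ignore_attr = TRUE)
  # determinism
  res2 <- spectraPipeline(yellow, genIllumination("lens"),
                          genIllumination("irradiance"), receptorSet())
  expect_identical(resY$point@rA, res2$point@rA)
})

test_that("spectral restriction and resampling are explicit", {
  wide <- Spectrum(seq(250, 750, 1), rep(0.5, 501))
  r <- restrictSpectrum(wide, 300, 700)
  expect_equal(range(wavelengths(r)), c(300, 700))
  expect_error(restrictSpectrum(wide, 800, 900), "no wavelengths")
  rs <- resampleSpectrum(wide, seq(300, 700, 0.5))
  expect_equal(length(wavelengths(rs)), 801)
  expect_error(resampleSpectrum(r, 200:700), "extrapolation")
})
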