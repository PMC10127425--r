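# Variance-component repeatability: the profiled REML/ML fitter, the
# bootstrap machinery and the boundary-corrected LRT.

test_that("REML matches the closed-form ANOVA estimator on balanced data", {
  for (seed in c(3, 14, 15)) {
    d <- genRepeatedMeasures(simConfig(nIndividuals = 40, nReplicates = 2,
                                       sigma2Between = 2, sigma2Within = 3,
                                       seed = seed))
    f <- fitVarianceComponents(d$value, d$id)
    a <- anovaVarComp(d$value, d$id)
    expect_lt(abs(f$sigma2Between - a$sigma2Between), 1e-6)
    expect_lt(abs(f$sigma2Within - a$sigma2Within), 1e-6)
  }
})

test_that("REML agrees with lme4 on unbalanced data", {
  set.seed(42)
  n <- c(2, 5, 3, 7, 2, 4, 6, 3, 2, 5)
  g <- rep(seq_along(n), n)
  y <- 3 + rnorm(length(n), 0, 1.5)[g] + rnorm(length(g), 0, 1)
  f <- fitVarianceComponents(y, g)
  lf <- lme4::lmer(y ~ 1 + (1 | g), REML = TRUE,
                   data = data.frame(y = y, g = factor(g)))
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(f$sigma2Between, vc$vcov[1], tolerance = 1e-6)
  expect_equal(f$sigma2Within, vc$vcov[2], tolerance = 1e-6)
  expect_equal(f$logLik, as.numeric(stats::logLik(lf)), tolerance = 1e-6)
  fm <- fitVarianceComponents(y, g, REML = FALSE)
  lm4 <- lme4::lmer(y ~ 1 + (1 | g), REML = FALSE,
                    data = data.frame(y = y, g = factor(g)))
  expect_equal(fm$logLik, as.numeric(stats::logLik(lm4)), tolerance = 1e-6)
})

test_that("degenerate inputs are handled as documented", {
  # identical replicates within individuals: zero within variance, R = 1
  y <- rep(c(1, 5, 9), each = 3)
  g <- rep(1:3, each = 3)
  f <- fitVarianceComponents(y, g)
  expect_equal(f$sigma2Within, 0)
  expect_equal(repeatability(f$sigma2Between, f$sigma2Within), 1)
  # permuted labels kill the between component
  d <- genRepeatedMeasures(simConfig(nIndividuals = 300, sigma2Between = 4,
                                     sigma2Within = 1, seed = 5))
  set.seed(7)
  f <- fitVarianceComponents(d$value, d$id)
  expect_gt(repeatability(f$sigma2Between, f$sigma2Within), 0.7)
  Rperm <- vapply(1:10, function(i) {
    fp <- fitVarianceComponents(sample(d$value), d$id)
    repeatability(fp$sigma2Between, fp$sigma2Within)
  }, numeric(1))
  expect_lt(mean(Rperm), 0.1)  # boundary estimator: small positive bias
  expect_error(fitVarianceComponents(1:5, 1:5), "singleton")
  expect_error(repeatability(0, 0), "undefined")
  expect_error(repeatability(-1, 1), "non-negative")
  expect_equal(repeatability(1, 1), 0.5)
  expect_equal(repeatability(1, 0), 1)
  expect_equal(repeatability(0, 1), 0)
})

test_that("R is invariant under affine transformation of the data", {
  d <- genRepeatedMeasures(simConfig(nIndividuals = 50, seed = 31))
  f0 <- fitVarianceComponents(d$value, d$id)
  R0 <- repeatability(f0$sigma2Between, f0$sigma2Within)
  f1 <- fitVarianceComponents(3.7 * d$value + 11, d$id)
  expect_equal(repeatability(f1$sigma2Between, f1$sigma2Within), R0,
               tolerance = 1e-6)
})

test_that("parametric bootstrap is reproducible and degenerates sanely", {
  d <- genRepeatedMeasures(simConfig(nIndividuals = 30, seed = 19))
  b1 <- bootstrapRepeatability(d$value, d$id, nBoot = 200, seed = 4)
  b2 <- bootstrapRepeatability(d$value, d$id, nBoot = 200, seed = 4)
  expect_identical(b1$CI, b2$CI)
  expect_true(b1$CI[1] <= b1$CI[2])
  # zero within-variance data: interval collapses at 1
  y <- rep(c(1, 5, 9, 2, 7), each = 2); g <- rep(1:5, each = 2)
  bd <- bootstrapRepeatability(y, g, nBoot = 100, seed = 1)
  expect_gte(bd$CI[1], 0.999)
  expect_equal(bd$CI[2], 1)
})

test_that("boundary LRT behaves under null and strong clustering", {
  # strongly clustered data reject decisively
  d <- genRepeatedMeasures(simConfig(nIndividuals = 40, nReplicates = 2,
                                     sigma2Between = 9, sigma2Within = 1,
                                     seed = 23))
  lr <- lrtPvalue(d$value, d$id)
  expect_gte(lr$statistic, 0)
  expect_lt(lr$p, 0.001)
  # null data: statistic often on the boundary, p large on average
  ps <- vapply(1:40, function(s) {
    dn <- genRepeatedMeasures(simConfig(nIndividuals = 40,
                                        sigma2Between = 0,
                                        sigma2Within = 1, seed = 100 + s))
    lrtPvalue(dn$value, dn$id)$p
  }, numeric(1))
  expect_gt(mean(ps), 0.4)
  expect_lt(mean(ps < 0.05), 0.15)
})

test_that("permutation p-value agrees qualitatively with the LRT", {
  d <- genRepeatedMeasures(simConfig(nIndividuals = 40, sigma2Between = 4,
                                     sigma2Within = 1, seed = 77))
  pp <- permutationPvalue(d$value, d$id, nPerm = 199, seed = 3)
  expect_lt(pp$p, 0.01)
  dn <- genRepeatedMeasures(simConfig(nIndividuals = 40, sigma2Between = 0,
                                      sigma2Within = 1, seed = 78))
  ppn <- permutationPvalue(dn$value, dn$id, nPerm = 199, seed = 3)
  expect_gt(ppn$p, 0.05)
})

test_that("rptGaussian assembles a coherent result object", {
  d <- genRepeatedMeasures(simConfig(nIndividuals = 40, sigma2Between = 1,
                                     sigma2Within = 1, seed = 55))
  r <- rptGaussian(d$value, d$id, nBoot = 200, seed = 2)
  expect_s4_class(r, "RepeatabilityResult")
  expect_equal(r@nGroups, 40L)
  expect_equal(r@nObs, 80L)
  expect_gte(r@R, 0); expect_lte(r@R, 1)
  expect_true(r@CI[1] <= r@R + 0.1 && r@CI[2] >= r@R - 0.1)
  expect_equal(unname(confint(r)[1]), r@CI[1])
  expect_output(show(r), "Repeatability")
})
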