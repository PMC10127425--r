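# Variance-component repeatability for grouped Gaussian measurements:
# one-way random-intercept model y_ij = mu + u_i + e_ij, fitted by REML (or
# ML) via the profiled likelihood, which reduces to a one-dimensional
# optimization over the variance ratio gamma = sigma2_between/sigma2_within.
# The closed-form profile makes each fit cheap enough for parametric
# bootstraps and coverage simulations with hundreds of thousands of refits.

.vcSuffStats <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  if (anyNA(values) || anyNA(groups)) {
    keep <- !(is.na(values) | is.na(groups))
    values <- values[keep]; groups <- groups[keep]
  }
  gi <- if (is.integer(groups) && !is.object(groups) &&
            min(groups) >= 1) groups else as.integer(factor(groups))
  k <- max(gi)
  n <- tabulate(gi, nbins = k)
  if (any(n == 0)) {  # re-index when integer ids have gaps
    gi <- match(gi, which(n > 0)); k <- max(gi); n <- tabulate(gi, k)
  }
  if (k < 2) stop("at least two groups are required")
  if (all(n < 2))
    stop("all groups are singletons: within-group variance is not estimable")
  offset <- mean(values)
  values <- values - offset  # centring stabilizes the sums of squares
  sums <- as.vector(rowsum(values, gi))
  ybar <- sums / n
  ssw <- sum(values^2) - sum(sums^2 / n)
  N <- length(values)
  list(n = n, ybar = ybar, ssw = ssw, N = N, k = k, offset = offset,
       sst = sum(values^2))
}

# -2 * profiled log-likelihood at variance ratio gamma (>= 0).
.vcDeviance <- function(gamma, st, REML = TRUE) {
  w <- st$n / (1 + st$n * gamma)
  sw <- sum(w)
  mu <- sum(w * st$ybar) / sw
  Q <- st$ssw + sum(w * (st$ybar - mu)^2)
  logdet <- sum(log1p(st$n * gamma))
  if (REML) {
    df <- st$N - 1
    df * log(Q / df) + df + logdet + log(sw) + df * log(2 * pi)
  } else {
    st$N * log(Q / st$N) + st$N + logdet + st$N * log(2 * pi)
  }
}

.vcMu <- function(gamma, st) {
  w <- st$n / (1 + st$n * gamma)
  sum(w * st$ybar) / sum(w)
}

#' REML variance components of a grouped measurement
#'
#' Fits the Gaussian random-intercept model `value = mu + u_group + e` and
#' returns the between-group and residual variance estimates. Negative
#' between-group estimates are not possible: the profiled likelihood is
#' maximized over the boundary-constrained ratio `sigma2b/sigma2w >= 0`,
#' and a boundary solution (`sigma2b = 0`) is reported as such.
#'
#' @param values numeric measurements.
#' @param groups group (individual) identifiers, coerced to factor.
#' @param REML logical; REML (default) or maximum likelihood.
#' @return A list: `sigma2Between`, `sigma2Within`, `logLik`, `mu`,
#'   `nGroups`, `nObs`, `boundary` (TRUE when `sigma2Between` was estimated
#'   at 0).
#' @examples
#' d <- genRepeatedMeasures(simConfig(nIndividuals = 30, seed = 2))
#' fitVarianceComponents(d$value, d$id)[c("sigma2Between", "sigma2Within")]
#' @export
fitVarianceComponents <- function(values, groups, REML = TRUE) {
  st <- .vcSuffStats(values, groups)
  if (st$ssw <= 1e-12 * max(st$sst, 1)) {
    # replicates within every group identical: residual variance vanishes
    return(list(sigma2Between = stats::var(st$ybar), sigma2Within = 0,
                logLik = Inf, mu = mean(st$ybar) + st$offset, nGroups = st$k,
                nObs = st$N, boundary = FALSE))
  }
  obj <- function(t) .vcDeviance(exp(t), st, REML)
  opt <- stats::optimize(obj, interval = c(-30, 25), tol = 1e-10)
  # polish: re-run Brent in a narrow bracket around the coarse optimum
  opt2 <- stats::optimize(obj, interval = opt$minimum + c(-0.05, 0.05),
                          tol = .Machine$double.eps^0.6)
  if (opt2$objective <= opt$objective) opt <- opt2
  dev0 <- .vcDeviance(0, st, REML)
  if (dev0 <= opt$objective) {
    gamma <- 0; dev <- dev0; boundary <- TRUE
  } else {
    gamma <- exp(opt$minimum); dev <- opt$objective; boundary <- FALSE
  }
  w <- st$n / (1 + st$n * gamma)
  mu <- sum(w * st$ybar) / sum(w)
  Q <- st$ssw + sum(w * (st$ybar - mu)^2)
  s2w <- Q / if (REML) st$N - 1 else st$N
  list(sigma2Between = gamma * s2w, sigma2Within = s2w,
       logLik = -dev / 2, mu = mu + st$offset, nGroups = st$k, nObs = st$N,
       boundary = boundary)
}

#' Repeatability from variance components
#'
#' `R = sigma2Between / (sigma2Between + sigma2Within)`: the fraction of
#' total variance attributable to differences among individuals.
#'
#' @param sigma2Between,sigma2Within non-negative variances, not both zero.
#' @return R in \[0, 1\].
#' @export
repeatability <- function(sigma2Between, sigma2Within) {
  if (sigma2Between < 0 || sigma2Within < 0)
    stop("variances must be non-negative")
  if (sigma2Between + sigma2Within == 0)
    stop("both variance components are zero: repeatability undefined")
  sigma2Between / (sigma2Between + sigma2Within)
}

#' Parametric bootstrap SE and CI for repeatability
#'
#' Simulates `nBoot` datasets from the fitted random-intercept model
#' (same group sizes), refits each, and summarizes the bootstrap
#' distribution of R: `SE = sd(R*)`, CI from the 2.5% and 97.5%
#' percentiles. Failed refits are counted and reported by warning when they
#' exceed 5% of draws.
#'
#' @param values,groups the data, as in [fitVarianceComponents()].
#' @param nBoot number of bootstrap draws (>= 100).
#' @param seed integer seed (reproducible).
#' @param level confidence level (default 0.95).
#' @return A list: `SE`, `CI` (length 2), `Rboot` (the draws), `nFail`.
#' @export
bootstrapRepeatability <- function(values, groups, nBoot = 1000, seed = 1L,
                                   level = 0.95) {
  stopifnot(nBoot >= 100)
  fit <- fitVarianceComponents(values, groups)
  st <- .vcSuffStats(values, groups)
  set.seed(seed)
  sb <- sqrt(fit$sigma2Between); sw <- sqrt(fit$sigma2Within)
  gidx <- rep(seq_len(st$k), st$n)
  Rb <- rep(NA_real_, nBoot)
  nFail <- 0L
  for (b in seq_len(nBoot)) {
    u <- stats::rnorm(st$k, 0, sb)
    y <- fit$mu + u[gidx] + stats::rnorm(st$N, 0, sw)
    f <- tryCatch(fitVarianceComponents(y, gidx), error = function(e) NULL)
    if (is.null(f) || (f$sigma2Between + f$sigma2Within) == 0) {
      nFail <- nFail + 1L
    } else {
      Rb[b] <- repeatability(f$sigma2Between, f$sigma2Within)
    }
  }
  if (nFail > 0.05 * nBoot)
    warning(sprintf("%d of %d bootstrap refits failed", nFail, nBoot))
  a <- (1 - level) / 2
  list(SE = stats::sd(Rb, na.rm = TRUE),
       CI = unname(stats::quantile(Rb, c(a, 1 - a), na.rm = TRUE)),
       Rboot = Rb, nFail = nFail)
}

#' Likelihood-ratio test for repeatability
#'
#' Tests `sigma2Between = 0` by the likelihood ratio of the
#' random-intercept model against the intercept-only model (both ML). The
#' null value lies on the boundary of the parameter space, so the reference
#' distribution is the equal mixture `0.5 chi2_0 + 0.5 chi2_1`.
#'
#' @param values,groups the data.
#' @return A list: `statistic` (the LR statistic, >= 0), `p`.
#' @export
lrtPvalue <- function(values, groups) {
  st <- .vcSuffStats(values, groups)
  fit1 <- fitVarianceComponents(values, groups, REML = FALSE)
  if (!is.finite(fit1$logLik)) return(list(statistic = Inf, p = 0))
  ll0 <- -(st$N * log(st$sst / st$N) + st$N + st$N * log(2 * pi)) / 2
  stat <- max(0, 2 * (fit1$logLik - ll0))
  p <- if (stat <= 0) 1 else 0.5 * stats::pchisq(stat, df = 1,
                                                 lower.tail = FALSE)
  list(statistic = stat, p = p)
}

#' Permutation test for repeatability
#'
#' Re-estimates R after randomly permuting observations across groups; the
#' p-value is the fraction of permutations with R at least as large as
#' observed (add-one correction).
#'
#' @param values,groups the data.
#' @param nPerm number of permutations (default 1000).
#' @param seed integer seed.
#' @return A list: `statistic` (observed R), `p`.
#' @export
permutationPvalue <- function(values, groups, nPerm = 1000, seed = 1L) {
  fit <- fitVarianceComponents(values, groups)
  Robs <- repeatability(fit$sigma2Between, fit$sigma2Within)
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(nPerm)) {
    f <- fitVarianceComponents(sample(values), groups)
    Rp <- if (f$sigma2Between + f$sigma2Within == 0) 0
          else repeatability(f$sigma2Between, f$sigma2Within)
    if (Rp >= Robs) hits <- hits + 1L
  }
  list(statistic = Robs, p = (hits + 1) / (nPerm + 1))
}

#' Repeatability analysis of a repeated measurement
#'
#' The complete analysis behind a repeatability table row: REML variance
#' components, the point estimate R, a parametric-bootstrap SE and 95%
#' percentile CI, and a p-value from the boundary-corrected LRT (default)
#' or a permutation test.
#'
#' @param values numeric measurements.
#' @param groups individual identifiers.
#' @param nBoot bootstrap draws for SE/CI (default 1000).
#' @param seed integer seed for bootstrap/permutation.
#' @param method "lrt" (default) or "permutation".
#' @param nPerm permutations when `method = "permutation"`.
#' @return A [RepeatabilityResult-class].
#' @examples
#' d <- genRepeatedMeasures(simConfig(nIndividuals = 40, seed = 7))
#' rptGaussian(d$value, d$id, nBoot = 200)
#' @export
rptGaussian <- function(values, groups, nBoot = 1000, seed = 1L,
                        method = c("lrt", "permutation"), nPerm = 1000) {
  method <- match.arg(method)
  fit <- fitVarianceComponents(values, groups)
  R <- repeatability(fit$sigma2Between, fit$sigma2Within)
  bt <- bootstrapRepeatability(values, groups, nBoot = nBoot, seed = seed)
  p <- if (method == "lrt") lrtPvalue(values, groups)$p
       else permutationPvalue(values, groups, nPerm = nPerm, seed = seed)$p
  new("RepeatabilityResult", R = R, SE = bt$SE, CI = bt$CI, p = p,
      nGroups = as.integer(fit$nGroups), nObs = as.integer(fit$nObs),
      sigma2Between = fit$sigma2Between, sigma2Within = fit$sigma2Within,
      method = method)
}
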