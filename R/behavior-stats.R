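# The dominance/display analysis: normality checks and Box-Cox
# transformation, two-sample comparisons, the binomial mixed model for
# dominance with stepwise single-term LRT reduction, linear mixed models
# with the display x dominance interaction and dominance-subset models, and
# the mixed Pearson/Spearman correlation matrix.
#
# Mixed-model numerics are delegated to lme4 (glmer/lmer); the model
# construction, the single-term-deletion LRT chain (df always 1) and the
# subset logic are implemented here.

#' Lilliefors-corrected Kolmogorov-Smirnov normality test
#'
#' KS test against a normal distribution with mean and SD estimated from
#' the sample, with the Lilliefors small-sample p-value approximation.
#'
#' @param x numeric vector, n >= 5, non-constant.
#' @return A list: `statistic`, `p`.
#' @export
lillieforsNormality <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 5) stop("at least 5 observations are required")
  if (stats::sd(x) == 0) stop("constant vector: normality test undefined")
  t <- nortest::lillie.test(x)
  list(statistic = unname(t$statistic), p = unname(t$p.value))
}

#' Box-Cox transformation towards normality
#'
#' Chooses the power `lambda` maximizing the Box-Cox profile log-likelihood
#' (grid search via [MASS::boxcox()] refined to 0.001) and applies
#' `(x^lambda - 1) / lambda` (natural log at `lambda = 0`).
#'
#' @param x positive numeric vector.
#' @param lambdaRange search interval (default -2..2).
#' @return A list: `lambda`, `transformed`.
#' @export
boxCoxTransform <- function(x, lambdaRange = c(-2, 2)) {
  nbad <- sum(x <= 0, na.rm = TRUE)
  if (nbad > 0)
    stop(sprintf("Box-Cox requires positive values; %d value(s) <= 0", nbad))
  bc <- MASS::boxcox(x ~ 1, lambda = seq(lambdaRange[1], lambdaRange[2],
                                         by = 0.001), plotit = FALSE)
  lambda <- bc$x[which.max(bc$y)]
  transformed <- if (abs(lambda) < 1e-8) log(x) else (x^lambda - 1) / lambda
  list(lambda = lambda, transformed = transformed)
}

#' Two-sample comparisons
#'
#' The three standard comparisons used for body and color variables:
#' Welch's t-test, the Wilcoxon rank-sum test (exact when both samples have
#' at most 50 observations and there are no ties, normal approximation with
#' tie correction otherwise), and the paired t-test. All two-sided.
#'
#' @param x,y numeric samples (equal length for `kind = "paired_t"`).
#' @param kind "welch_t", "wilcoxon" or "paired_t".
#' @return A list: `statistic`, `df` (NA for Wilcoxon), `p`, `method`.
#' @export
twoSampleTest <- function(x, y, kind = c("welch_t", "wilcoxon", "paired_t")) {
  kind <- match.arg(kind)
  if (length(x) < 2 || length(y) < 2)
    stop("each sample needs at least 2 observations")
  if (kind == "welch_t") {
    t <- stats::t.test(x, y, var.equal = FALSE)
    list(statistic = unname(t$statistic), df = unname(t$parameter),
         p = t$p.value, method = "Welch two-sample t-test")
  } else if (kind == "paired_t") {
    if (length(x) != length(y))
      stop("paired test requires equal-length samples")
    d <- x - y
    if (stats::sd(d) == 0)  # constant differences: t.test cannot be used
      return(list(statistic = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
                  df = length(d) - 1,
                  p = if (mean(d) == 0) 1 else 0,
                  method = "Paired t-test"))
    t <- stats::t.test(x, y, paired = TRUE)
    list(statistic = unname(t$statistic), df = unname(t$parameter),
         p = t$p.value, method = "Paired t-test")
  } else {
    exact <- max(length(x), length(y)) <= 50 &&
      !any(duplicated(c(x, y)))
    t <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                             correct = !exact))
    list(statistic = unname(t$statistic), df = NA_real_, p = t$p.value,
         method = if (exact) "Wilcoxon rank sum exact test"
                  else "Wilcoxon rank sum test (normal approximation)")
  }
}

# Single-term-deletion LRT chain: fit the full model, drop each fixed term
# in turn, compare by LRT with df = 1. `fitter` maps a formula to a fitted
# model; logLik must be comparable across fits (ML).
.dropTermLRT <- function(fullFormula, terms, data, fitter) {
  full <- fitter(fullFormula)
  llFull <- as.numeric(stats::logLik(full))
  fe <- if (inherits(full, "merMod")) lme4::fixef(full) else stats::coef(full)
  res <- lapply(terms, function(tm) {
    reduced <- stats::update(stats::as.formula(fullFormula),
                             stats::as.formula(paste(". ~ . -", tm)))
    red <- fitter(reduced)
    chisq <- max(0, 2 * (llFull - as.numeric(stats::logLik(red))))
    est <- if (tm %in% names(fe)) unname(fe[tm]) else NA_real_
    data.frame(term = tm, chisq = chisq, df = 1,
               p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
               estimate = est,
               sign = if (is.na(est)) NA_integer_ else as.integer(sign(est)))
  })
  out <- do.call(rbind, res)
  attr(out, "fullFit") <- full
  out
}

#' Binomial mixed model for dominance with stepwise LRT reduction
#'
#' Fits the dominance GLMM of the dyadic-contest analysis: a binomial
#' mixed-effects model of the dominance outcome with random intercepts for
#' family and trial ID, and tests each explanatory variable by a
#' single-term-deletion likelihood-ratio test (df always 1).
#'
#' @param data long dyad data, two rows (males) per trial, e.g. from
#'   [genDyadData()]. Must contain the response and term columns plus
#'   `family` and `trial`.
#' @param response name of the binary response column (default "dominant").
#' @param terms explanatory variables (default display, attacks, SL, LC,
#'   RCA).
#' @return A data.frame with one row per term: `term`, `chisq`, `df`, `p`,
#'   `estimate`, `sign`, plus attributes `fullFit` and `separation`
#'   (TRUE when quasi-complete separation was detected, flagged rather
#'   than an error).
#' @export
fitDominanceGLMM <- function(data, response = "dominant",
                             terms = c("display", "attacks", "SL",
                                       "LC", "RCA")) {
  stopifnot(all(c(response, terms, "family", "trial") %in% names(data)))
  yv <- data[[response]]
  if (!all(yv %in% c(0, 1))) stop("response must be binary (0/1)")
  fullFormula <- stats::as.formula(paste(
    response, "~", paste(terms, collapse = " + "),
    "+ (1 | family) + (1 | trial)"))
  fitter <- function(f) {
    withCallingHandlers(
      lme4::glmer(f, data = data, family = stats::binomial,
                  control = lme4::glmerControl(calc.derivs = FALSE,
                                               check.conv.singular = "ignore")),
      message = function(m) invokeRestart("muffleMessage"),
      warning = function(w) invokeRestart("muffleWarning"))
  }
  out <- .dropTermLRT(fullFormula, terms, data, fitter)
  fe <- lme4::fixef(attr(out, "fullFit"))
  attr(out, "separation") <- any(abs(fe[-1]) > 15)
  out
}

#' Linear mixed models for color with dominance and display
#'
#' The Gaussian companion of the dominance analysis. With
#' `subset = "all"`, fits `response ~ display * dominant` with random
#' intercepts for family and trial ID and tests the interaction (and, from
#' the additive model, each main effect) by LRT. With
#' `subset = "dominant"` or `"subordinate"`, restricts the data to that
#' status and fits `response ~ display` with a family random intercept
#' only, returning the display term with the sign of its coefficient.
#' When a random factor has fewer than 2 levels in the (subset) data the
#' model degrades to a fixed-intercept linear model with a warning.
#'
#' @param data long dyad data (see [fitDominanceGLMM()]).
#' @param response "RCA" or "LC" (any numeric column).
#' @param withInteraction logical; test the display x dominance
#'   interaction (only for `subset = "all"`).
#' @param subset "all", "dominant" or "subordinate".
#' @return A data.frame of term results (`term`, `chisq`, `df`, `p`,
#'   `estimate`, `sign`), with the full fit in the `fullFit` attribute.
#' @export
fitColorLMM <- function(data, response = c("RCA", "LC"),
                        withInteraction = TRUE,
                        subset = c("all", "dominant", "subordinate")) {
  response <- if (is.character(response)) response[1] else response
  subset <- match.arg(subset)
  stopifnot(all(c(response, "display", "dominant", "family") %in% names(data)))
  if (subset == "dominant") data <- data[data$dominant == 1, , drop = FALSE]
  if (subset == "subordinate") data <- data[data$dominant == 0, , drop = FALSE]
  if (nrow(data) == 0) stop("subset is empty")
  data$family <- droplevels(factor(data$family))

  useRE <- nlevels(data$family) >= 2
  if (!useRE)
    warning("fewer than 2 family levels: degrading to a fixed-intercept model")

  mlFitter <- function(f) {
    if (useRE)
      withCallingHandlers(
        lme4::lmer(f, data = data, REML = FALSE,
                   control = lme4::lmerControl(calc.derivs = FALSE,
                                               check.conv.singular = "ignore")),
        message = function(m) invokeRestart("muffleMessage"),
        warning = function(w) invokeRestart("muffleWarning"))
    else
      stats::lm(.stripRE(f), data = data)
  }

  if (subset == "all") {
    stopifnot("trial" %in% names(data))
    useTrial <- nlevels(droplevels(factor(data$trial))) >= 2
    re <- if (useTrial) "(1 | family) + (1 | trial)" else "(1 | family)"
    rows <- list()
    if (withInteraction) {
      fInt <- stats::as.formula(paste(response,
                                      "~ display + dominant + display:dominant +",
                                      re))
      rows$int <- .dropTermLRT(fInt, "display:dominant", data, mlFitter)
    }
    fAdd <- stats::as.formula(paste(response, "~ display + dominant +", re))
    rows$main <- .dropTermLRT(fAdd, c("display", "dominant"), data, mlFitter)
    out <- do.call(rbind, c(rows, make.row.names = FALSE))
    attr(out, "fullFit") <- attr(rows[[1]], "fullFit")
  } else {
    f <- stats::as.formula(paste(response, "~ display +",
                                 if (useRE) "(1 | family)" else "1"))
    out <- if (useRE) .dropTermLRT(f, "display", data, mlFitter)
           else .dropTermLRTlm(f, "display", data)
  }
  out
}

.stripRE <- function(f) {
  stats::as.formula(gsub("\\+ *\\(1 *\\| *[A-Za-z.]+\\)", "", deparse(f)))
}

.dropTermLRTlm <- function(f, tm, data) {
  full <- stats::lm(.stripRE(f), data = data)
  red <- stats::update(full, paste(". ~ . -", tm))
  chisq <- max(0, 2 * (as.numeric(stats::logLik(full)) -
                       as.numeric(stats::logLik(red))))
  est <- stats::coef(full)[tm]
  out <- data.frame(term = tm, chisq = chisq, df = 1,
                    p = stats::pchisq(chisq, 1, lower.tail = FALSE),
                    estimate = unname(est), sign = as.integer(sign(est)))
  attr(out, "fullFit") <- full
  out
}

#' Mixed Pearson/Spearman correlation matrix
#'
#' For every pair of variables: Pearson's product-moment correlation when
#' both variables pass the Lilliefors normality test at `alpha`, Spearman's
#' rank correlation otherwise, with the method recorded per cell. The
#' printed layout mirrors the conventional compact table: coefficients in
#' the upper triangle, p-values in the lower.
#'
#' @param data data.frame of numeric variables.
#' @param alpha normality-test level deciding the method (default 0.05).
#' @return A list of class `corrMatrix`: matrices `r`, `p`, `method`
#'   (entries "pearson", "spearman" or NA for undefined cells).
#' @export
correlationMatrix <- function(data, alpha = 0.05) {
  stopifnot(is.data.frame(data), ncol(data) >= 2)
  vars <- names(data)
  k <- length(vars)
  normal <- vapply(vars, function(v) {
    x <- data[[v]][!is.na(data[[v]])]
    if (length(x) < 5 || stats::sd(x) == 0) return(NA)
    lillieforsNormality(x)$p > alpha
  }, logical(1))
  r <- p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  meth <- matrix(NA_character_, k, k, dimnames = list(vars, vars))
  diag(r) <- 1
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ok <- stats::complete.cases(data[[i]], data[[j]])
    if (sum(ok) < 3) next
    x <- data[[i]][ok]; y <- data[[j]][ok]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next  # undefined cell
    m <- if (isTRUE(normal[i]) && isTRUE(normal[j])) "pearson" else "spearman"
    ct <- suppressWarnings(stats::cor.test(x, y, method = m))
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
    meth[i, j] <- meth[j, i] <- m
  }
  structure(list(r = r, p = p, method = meth), class = "corrMatrix")
}

#' @export
print.corrMatrix <- function(x, digits = 3, ...) {
  k <- nrow(x$r)
  out <- matrix("", k, k, dimnames = dimnames(x$r))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    out[i, j] <- if (i == j) "-"
    else if (i < j) formatC(x$r[i, j], digits = digits, format = "f")
    else formatC(x$p[i, j], digits = digits, format = "f")
  }
  cat("Correlation matrix (r upper triangle, p lower triangle;\n",
      " spearman cells marked *):\n", sep = "")
  star <- ifelse(x$method == "spearman" & upper.tri(x$method), "*", "")
  print(matrix(paste0(out, star), k, k, dimnames = dimnames(x$r)),
        quote = FALSE)
  invisible(x)
}
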