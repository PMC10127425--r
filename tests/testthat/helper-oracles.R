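# Independent oracles used across the suite. Each is a deliberately naive
# second implementation (brute force, enumeration, fine-grid quadrature)
# kept free of any code path it is used to check.

# Flood-fill component labeling via an explicit queue.
bfsLabel <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 8)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  cur <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j] || lab[i, j] > 0) next
    cur <- cur + 1L
    queue <- list(c(i, j)); lab[i, j] <- cur
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nb))) {
        a <- p[1] + nb[k, 1]; b <- p[2] + nb[k, 2]
        if (a >= 1 && a <= nr && b >= 1 && b <= nc &&
            mask[a, b] && lab[a, b] == 0) {
          lab[a, b] <- cur
          queue[[length(queue) + 1]] <- c(a, b)
        }
      }
    }
  }
  lab
}

# Exact two-sided Wilcoxon rank-sum p-value by enumerating every split of
# the pooled sample (no ties assumed).
wilcoxExactEnum <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  ranks <- rank(pooled)
  wObs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- utils::combn(length(pooled), n1)
  ws <- apply(splits, 2, function(idx) sum(ranks[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(y) / 2
  p <- mean(abs(ws - mu) >= abs(wObs - mu) - 1e-9)
  p
}

# Direct transcription of the A1 alpha+beta pigment template (peak
# normalized on the grid), written formula-by-formula.
govardovskiiDirect <- function(lmax, wl) {
  SA <- numeric(length(wl))
  for (i in seq_along(wl)) {
    x <- lmax / wl[i]
    aa <- 0.8795 + 0.0459 * exp(-1 * (lmax - 300)^2 / 11940)
    SA[i] <- 1 / (exp(69.7 * (aa - x)) + exp(28 * (0.922 - x)) +
                  exp(-14.9 * (1.104 - x)) + 0.674)
  }
  lmb <- 189 + 0.315 * lmax
  bwd <- -40.5 + 0.195 * lmax
  SB <- 0.26 * exp(-((wl - lmb) / bwd)^2)
  S <- SA + SB
  S / max(S)
}

# Distance from the origin to the boundary of the Maxwell triangle along
# direction theta, by ray/segment intersection against each edge.
triBoundaryDist <- function(theta) {
  ang <- c(90, 210, 330) * pi / 180
  V <- cbind(cos(ang), sin(ang))
  d <- c(cos(theta), sin(theta))
  edges <- list(c(1, 2), c(2, 3), c(3, 1))
  best <- Inf
  for (e in edges) {
    p <- V[e[1], ]; q <- V[e[2], ]
    # solve t*d = p + s*(q - p)
    A <- cbind(d, p - q)
    if (abs(det(A)) < 1e-14) next
    ts <- solve(A, p)
    if (ts[1] > 0 && ts[2] >= -1e-12 && ts[2] <= 1 + 1e-12)
      best <- min(best, ts[1])
  }
  best
}

# Closed-form one-way ANOVA variance-component estimator for balanced data
# (m replicates per each of k groups), truncated at zero.
anovaVarComp <- function(values, groups) {
  g <- factor(groups)
  k <- nlevels(g); m <- length(values) / k
  stopifnot(all(table(g) == m))
  ybar <- tapply(values, g, mean)
  msb <- m * sum((ybar - mean(values))^2) / (k - 1)
  msw <- sum((values - ybar[as.integer(g)])^2) / (k * (m - 1))
  list(sigma2Between = max(0, (msb - msw) / m), sigma2Within = msw,
       msb = msb, msw = msw)
}

# Integral of the piecewise-linear interpolant of sampled spectra by a
# midpoint Riemann sum on a 0.01 nm grid.
fineGridCatch <- function(refl, irr, sens, step = 0.01) {
  w <- refl@wavelength
  fine <- seq(min(w) + step / 2, max(w) - step / 2, by = step)
  f <- stats::approx(w, refl@values * irr@values * sens@values,
                     xout = fine)$y
  sum(f) * step
}
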