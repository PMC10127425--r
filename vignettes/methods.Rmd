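---
title: "Quantifying dynamic fish coloration: models and design choices"
author: "chromaFish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dynamic fish coloration: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromaFish)
```

# The measurement problem

Male *Pelvicachromis taeniatus*, a West African cichlid, carry a
carotenoid-based yellow ventral ornament whose intensity and extent change
within minutes to hours during social interactions. chromaFish implements
the full quantification and analysis chain for such dynamic coloration:

1. **Photo-based color**: standardized photographs are calibrated against a
   white standard, belly color is sampled in CIELab, and the colored area
   is segmented by HSB thresholds.
2. **Physiological color**: reflectance spectra are pushed through a
   trichromatic photoreceptor model to obtain chromaticity as the fish's
   own visual system would encode it.
3. **Repeatability**: variance-component models ask whether a color
   variable is a stable property of an individual or varies within it.
4. **Behavior**: mixed models relate coloration and restrained aggression
   (displays) to contest outcome in staged dyadic contests.

Because raw photographs and spectra of this kind are rarely deposited, the
package ships a synthetic-data module that generates every input with known
ground truth, and the whole chain is validated against those ground truths.

# Photo chain

## Calibration

"Adjusting brightness to the white standard" is underspecified as a pixel
operation, so the package fixes it as per-channel linear gain in
linear-light RGB: the sRGB gamma is removed, each channel is scaled by
(reference / observed patch mean), values above the channel maximum are
clipped (with a count reported), and the gamma is reapplied. A gain in
linear space is what a change of illumination intensity actually does to a
sensor, which is why a dimmed image recalibrates to the original to within
quantization error (the package checks Delta-E < 2 for dimming factors
0.5-0.9, and typically observes ~0.1-0.2).

Images are interpreted as sRGB and converted to CIE 1976 L\*a\*b\* with D65
reference white; D65 approximates the 6500 K illumination the photographic
setup uses.

## Belly sampling and Lab-chromaticity

Sixteen samples are placed on a deterministic, even grid over the bounding
box of the belly mask; points falling off the mask snap to the nearest mask
pixel. The original protocol placed 16 points by hand — a grid is the
reproducible surrogate. Each point averages pixels within a 2 px radius,
mimicking an averaging eyedropper. Chromaticity is `LC = sqrt(a^2 + b^2)`,
the distance from the achromatic axis, independent of lightness.

## Colored-area segmentation

Pixels are selected by inclusive thresholds on hue, saturation and
brightness, each expressed on a 0-255 scale (the convention of 8-bit
image-editor sliders; hue 0-255 spans the full 360 degrees, so the male
range 0-64 covers red through yellow, about 0-90 degrees). Hue wraps
around when `hueLo > hueHi`. The shipped male thresholds (H 0-64,
S 100-255, B 66-255) select saturated yellows; female thresholds
(H 154-255, S 5-255, B 66-255) select the purple nuptial coloration.

Selected pixels are labeled as 8-connected components and components with
area strictly greater than 0.05 cm^2 are summed (a flag restricts to the
largest component only). The "exact select-color-range fuzziness" of
interactive tools is not reproducible; strict thresholding is used instead.
Relative colored area is `RCA = colored area / LPA`, with LPA the lateral
projection area of the body mask; the body condition index is the
Fulton-type `CI = 100 * mass / SL^3` (g/cm^3), putting typical values near
2.4.

# Visual model

Replicate reflectance spectra are averaged pointwise, restricted to
300-700 nm (the likely visual range of cichlids), and multiplied by the
lens transmission. Photoreceptor sensitivities for the three cone opsins
(SWS2A, RH2A-beta, LWS; peak absorbance 455, 518, 560 nm) are built from
the Govardovskii A1 alpha+beta template — the de facto standard pigment
template — peak-normalized to 1. Quantum catches are trapezoid integrals of
reflectance x irradiance x sensitivity on the native 1 nm grid; resampling
is always explicit (mismatched grids are errors, never silently
interpolated). A sampled spectrum *is* the data, so the catch is defined as
the integral of its piecewise-linear interpolant, which the trapezoid rule
computes exactly; the test suite checks it against a 0.01 nm midpoint
quadrature of the same interpolant.

Relative catches `q = Q / sum(Q)` embed barycentrically in a Maxwell
triangle with the centroid at the origin and centroid-to-vertex distance 1
(vertices at 90, 210, 330 degrees). Chroma `r` is the distance from the
achromatic centre; achieved chroma `r_A = r / r_max(hue)` rescales by the
maximum chroma attainable in that hue direction, so `r_A` is 1 exactly on
the triangle boundary (one catch zero) and 0 at the centre. `r_A` is
invariant to uniform rescaling of reflectance, irradiance or all
sensitivities; the triangle size is therefore purely cosmetic.

Linear relative catches are the default (matching "relative excitations");
a `log` switch applies `log(1 + Q)` first. Von Kries adaptation is off by
default — the experimental irradiance is the stimulus, and no adapting
background is modeled — but available as an option. The 300-400 nm band is
carried in all data structures even though the default synthetic irradiance
is zero there (the experimental tanks blocked UV), so its contribution is
negligible rather than excluded. No outlier handling is applied to
replicate spectra; with 10-20 noisy replicates the pointwise mean is
already stable, and silent outlier rejection would be harder to audit.

# Repeatability

Repeatability is the intraclass correlation
`R = sigma2_between / (sigma2_between + sigma2_within)` of the Gaussian
random-intercept model `y_ij = mu + u_i + e_ij`. The package fits it by
REML on the profiled likelihood: for this one-parameter model the deviance
is an explicit function of the variance ratio, so the fit is a
one-dimensional Brent optimization over the boundary-constrained ratio —
hundreds of microseconds per fit, which makes parametric bootstraps
(500 draws) and coverage studies (hundreds of thousands of refits)
practical. On balanced data the estimator coincides with the closed-form
one-way ANOVA estimator (the suite verifies agreement to 1e-6), and on
unbalanced data it matches `lme4::lmer` to the same precision. Negative
between-variance solutions cannot occur; a boundary fit (`sigma2b = 0`) is
reported as such.

Interval estimation is a parametric bootstrap (simulate from the fitted
model, refit, percentile CI), matching the default of the established
repeatability tooling, not case resampling. The test of `R = 0` is a
likelihood-ratio test whose null distribution is the boundary mixture
`0.5 chi2_0 + 0.5 chi2_1`; a label-permutation test is provided as a
cross-check. Which of the two produced the p-values in comparable published
tables is usually unstated; the LRT is the package default.

# Dominance analysis

The contest analysis mirrors the standard mixed-model chain:

* **Dominance GLMM**: binomial mixed model of the dominance outcome with
  random intercepts for family and trial (both contestants contribute a
  row; the trial intercept carries the pairing). Each explanatory variable
  (display, attacks, SL, LC, RCA) is tested by a single-term-deletion
  likelihood-ratio test from the full model, df = 1 each; dropped terms are
  not re-entered. Quasi-complete separation is flagged on the result, not
  raised as an error.
* **Color LMMs**: Gaussian mixed models of LC or RCA. The display x
  dominance interaction is tested by comparing models with and without the
  product term, both containing the main effects. Subset models (dominant
  or subordinate individuals only) use a family random intercept only and
  report the sign of the display coefficient. With fewer than two levels of
  a random factor the model degrades to a fixed-intercept fit with a
  warning.
* All mixed-model likelihood optimization is delegated to lme4 — the tool
  of record for this model class — while model construction, the LRT
  reduction chain and the subset logic live in this package. LRTs use ML
  fits; all tests are two-sided.

Supporting tools: Lilliefors-corrected Kolmogorov-Smirnov normality test,
Box-Cox transformation with profile-likelihood lambda, Welch/paired t and
Wilcoxon rank-sum tests (exact for <= 50 observations without ties), and a
correlation matrix that uses Pearson when both variables pass the
Lilliefors test at the chosen alpha and Spearman otherwise, recording the
method per cell.

# The synthetic-data generators

Every generator is a pure function of its configuration including the seed.

**Images.** A grey scene with an elliptical neutral-grey body (axis ratio
2:1), a coherent ventral patch rendered at a chosen CIELab color with an
exact pixel count (`round(fraction x body pixels)`, filled row-by-row from
the venter), a white standard rendered at linear reflectance 0.95, a 1 cm
scale bar, and seeded Gaussian pixel noise (SD 0.003 in sRGB units) before
8-bit quantization. Masks are exact, and `patch px / body px` is the RCA
oracle. Defaults (12 cm^2 body, 40 px/cm, patch Lab (70, 8, 55), area
fraction 0.1) give a fish-photo scale comparable to the study setup and a
patch that the male HSB thresholds select. Out-of-gamut patch colors are a
hard error, not a silent clip.

**Spectra.** Reflectance replicates are a sigmoidal long-pass step (default
step 500 nm, maximum 0.55, floor 0.03, slope scale 18 nm) plus i.i.d.
Gaussian noise, clamped to [0, 1] — the shape of measured carotenoid-yellow
reflectance. Irradiance is a cool-white LED-like curve that is exactly zero
below a 400 nm cutoff (the tanks blocked UV); lens transmission is a
logistic long-pass at the same default cutoff, standing in for unpublished
ocular-media data. All structural shapes are invented stand-ins and labeled
as such.

**Repeated measures.** `y = mu + u_i + e_ij` with configurable variance
components; the true `R` travels with the data. Defaults (46 individuals,
2 replicates, equal components, mu = 30) echo the study's sample sizes and
the scale of LC values.

**Dyadic contests.** Pairs of males from different families (default 23
pairs, 12 families) with SL ~ N(6.15, 0.42) cm, condition index
~ N(2.39, 0.21) (mass derived), lognormal display durations in seconds
(median 40 s) and negative-binomial attack counts. Dominance is Bernoulli
with log-odds `betaDisplay x (display_1 - display_2)` plus the difference
of family effects. Color is `intercept + slope_status x (display - mean
display) + family effect + noise`, with `slopeDominant` for winners and
`slopeSubordinate` for losers.

Two structural choices here deserve emphasis. First, display is *centred*
in the color equation: with symmetric slopes this makes the marginal color
distribution of eventual winners and losers identical, so pre-trial color
does not predict dominance — the observed pattern in real contests — while
the status-dependent slopes (and hence the interaction and the
opposite-sign subset slopes) remain fully expressed. Generating color from
uncentred display would make winners systematically more colorful and turn
color into a strong dominance predictor, a structure the motivating
experiment explicitly did not find. Second, RCA is generated as a strongly
collinear companion of LC (correlation ~0.9, as the two measures of one
ornament show in real fish) rather than as an independent second readout of
the display signal; two near-redundant color covariates then contribute
almost no *unique* explanatory power each, which is what single-term
deletion tests measure. "Display" is modeled as a duration in seconds; a
count works identically and nothing downstream depends on the unit.

What the generators do **not** emulate: fins and their occlusion of the
patch, melanophore dynamics (the dark submission bar), photon noise
correlated across channels, spectrometer wavelength jitter, or any
dependence of attack counts on dominance. Passing tests therefore certify
the measurement and inference chain on idealized scenes and clean model
structure — not robustness to segmentation error or model misspecification
in real photographs.

# Numerical choices and degenerate inputs

* Connected components: 8-connectivity, run-based union-find; validated
  against a flood-fill oracle.
* REML optimization: Brent on log variance ratio, interval e^-30..e^25,
  tolerance 1e-12, explicit boundary comparison at ratio 0. Zero
  within-group variance (all replicates identical) is detected and returns
  `sigma2w = 0`, R = 1 without optimization. Affine invariance of R holds
  to ~1e-8 (floating-point, not exact, because the deviance shift perturbs
  Brent's tie-breaking).
* Quantile-based bootstrap CIs can fail to bracket the point estimate in
  principle; bootstrap refit failures are counted and reported when above
  5%.
* Box-Cox lambda is located on a 0.001 grid over [-2, 2]; non-positive
  values are an error naming the offending count.
* The paired t-test of identical vectors (zero-variance differences)
  returns statistic 0, p = 1 rather than erroring.
* Wilcoxon switches from exact enumeration to the tie-corrected normal
  approximation above 50 observations or in the presence of ties.

# Problem sizes in the shipped checks

The validation suite runs the photo chain on 50 generated images (area
fractions 0.02-0.3), the repeatability recovery on 1000 simulations per
true R in {0.1, 0.5, 0.9} at 100 x 2, the bootstrap coverage on 500
simulations x 500 draws at 40 x 2, the null-size checks on 2000 simulated
datasets (30-pair contests with a single-covariate GLMM, chosen to keep
2000 replicates of a multi-fit mixed-model chain tractable), and the
pattern-recovery check on 100 contest datasets of 200 pairs with
`betaDisplay = 0.1` and slopes of +/- 0.08 at residual SD 8 — effect sizes
chosen so the display effect is decisive and the interaction unambiguous
while color stays uninformative for the outcome, the configuration the
contest analysis is designed to detect. The acceptance script
(`scripts/acceptance.R`) re-runs a moderately reduced version of the same
computations from scratch at a user-supplied seed.

# Known limitations

* Trichromatic only; no tetrachromatic space, no receptor-noise (ΔS)
  discriminability, no double-cone luminance channel.
* Masks are inputs; the package does not segment fish from background.
* No RAW demosaicing; images enter as rendered sRGB rasters.
* Non-Gaussian repeatability (binomial/Poisson) and covariate-adjusted
  repeatability are out of scope.
* The correlation-matrix normality gate uses each variable's full column,
  not per-pair complete cases, so borderline variables switch method
  globally rather than per cell.
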