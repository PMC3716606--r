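---
title: "Methods: SOC stock change analysis for paired land-use chronosequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SOC stock change analysis for paired land-use chronosequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socchrono)
```

## The problem

Converting secondary forest to rubber (*Hevea brasiliensis*) plantations —
an important ongoing land-use change in montane mainland southeast Asia —
can release soil organic carbon (SOC), but the change cannot be observed
directly without decades of resampling. `socchrono` implements the standard
space-for-time design for this question: spatial *clusters*, each holding
one reference secondary-forest plot and one to three rubber plots of
different ages on matched terrain, stand in for a time series. The package
covers the full analysis chain: stock accounting from horizon measurements,
cluster-paired change statistics, mixed-model inference, covariate
screening, and exponential decay fitting, plus a synthetic-study generator
that makes every stage testable against known truth.

## Stock accounting

The SOC stock of a depth interval is

$$\mathrm{stock}\;[\mathrm{Mg\,C\,ha^{-1}}] =
  \frac{\%C}{100}\times BD\;[\mathrm{g\,cm^{-3}}]\times D\;[\mathrm{m}]
  \times 10^4,$$

with $D$ the interval thickness; profile totals sum the five canonical
intervals 0–0.15, 0.15–0.3, 0.3–0.6, 0.6–0.9 and 0.9–1.2 m. No gravel
correction is applied (the design assumes stone-free cores), and no
carbonate correction (acid soils).

Land-use change alters bulk density, so comparing stocks computed with each
plot's own BD confounds carbon change with mass change. The
**equal-bulk-density correction** (`compute_stocks(bd_correction = TRUE)`,
the default) evaluates each rubber plot's carbon concentrations at its
cluster's *forest* BD profile, so the same mineral-soil mass is compared on
both sides of the conversion. The uncorrected variant is retained
(`bd_correction = FALSE`) only to quantify the error of ignoring BD change
(`bd_correction_comparison()`); when rubber soil is denser than forest
soil, the uncorrected contrast understates the loss.

Cluster-paired differences follow the mean-then-difference order: within a
cluster, the rubber plots are averaged first, the forest plot subtracted,
and the relative difference divides by the forest stock. Across-cluster
summaries report the mean ± SE with *n* = clusters. A plot-wise relative
difference (each rubber plot against its forest) exists separately for the
correlation screen, where the pairing level is an explicit option because
reporting conventions differ.

Litter stocks scale each 0.04-m² frame sample to the hectare
($\mathrm{g\,C\,m^{-2}} \times 0.01 = \mathrm{Mg\,C\,ha^{-1}}$) and average
over a plot's frames. Basal areas use $\pi (DBH/200)^2$ per stem; bamboo
clumps contribute the measured stem's area times the clump's stem count and
are included in *total* but not *tree* basal area.

## Mixed-model inference

Stocks (or any per-plot, per-depth response) are analysed with

`response ~ land_use * depth, random = ~1 | cluster`

fitted by REML (`nlme::lme`). REML is the conventional default for variance
components; the cluster random intercept absorbs the spatial pairing.
Per-depth rubber-minus-forest contrasts are Wald tests on linear
combinations of the fixed effects (`multcomp::glht`), with Holm's step-down
correction applied across the family of five depth contrasts for one
response. An optional `nlme::varIdent` variance function allows
land-use-specific residual variances; the trigger is manual (a config
switch), matching the residual-inspection workflow this design is usually
analysed with, not an automated pretest.

The covariate screen uses Spearman rank correlations with mid-ranks for
ties; p-values come from the exact permutation distribution for $n \le 9$
without ties and the t approximation otherwise. The covariate set is litter
carbon stock, litter C:N, total basal area, silt+clay content of the
interval, plantation age (rubber stratum only), slope and altitude.
Marginal significance at $p \le 0.1$ is flagged with a dagger alongside the
usual star thresholds.

## Decay models and steady state

Rubber stocks are expressed per interval as the proportion of the paired
forest stock, $y = 100 \times \mathrm{rubber}/\mathrm{forest}$, against
years since conversion. Two nested kinetic models are fitted per depth
interval (topsoil intervals by default, fitted independently):

* one pool: $X_t = X_e + (X_0 - X_e)\,e^{-kt}$,
* two pools: $X_t = X_1 e^{-k_1 t} + (100 - X_1)\,e^{-k_2 t}$,

with $X_0$ fixed at 100% because the response is defined relative to the
paired forest (freeing $X_0$ is available behind an option). Fitting is
Levenberg–Marquardt least squares (`minpack.lm::nls.lm`) with bounds
$X_e \in (0, 120]$, $k, k_1, k_2 \in (0, 5]$, $X_1 \in [0, 100]$ — physical
plausibility plus headroom for observed proportions slightly above 100%.
Start values ($X_e = \min y$, $k = 0.1$; $X_1 = 30$, $k_1 = 0.3$,
$k_2 = 0.01$) are augmented by five seeded, jittered restarts; the
converged fit with the lowest SSE wins. The two-pool fit is relabelled so
$k_1 \ge k_2$ (the labile pool is the faster one), removing label
switching. Goodness of fit is the Pearson correlation between observed and
fitted values; parameter significance is Wald, so a non-significant decay
rate is representable rather than an error, and non-convergence is a
returned flag.

Because the chronosequence has no $t = 0$ observation, $k$ is weakly
identified when the youngest plantations sit at or below the equilibrium:
the estimate can run to its upper bound, where the Gauss–Newton covariance
is singular and standard errors are reported as `NA`. This is a property of
the design at $n \approx 11$, visible in a minority of synthetic
replicates, and is surfaced rather than masked.

**Model selection** mirrors how this model pair behaves in practice: the
one-pool model is preferred when any two-pool rate is non-significant at
0.05 or when the two fitted curves differ by less than 0.5 percentage
points (configurable) over the observed ages; otherwise the two-pool model
is chosen.

**Steady state** is the smallest $t$ at which $X_t - X_e \le 0.01 X_e$
(within 1% *of the equilibrium value*), giving
$t^\* = \ln\!\big((X_0 - X_e)/(0.01 X_e)\big)/k$, clamped at 0. An
alternative reading — 1% of the decaying amplitude $X_0 - X_e$ — exists in
the literature; the equilibrium-relative form is the default here and the
closed form is verified against a brute-force grid scan in the tests.

## The synthetic generator

`generate_study()` draws complete input bundles with the design's
statistical structure; `synthetic_config()` holds the knobs. The defaults
are fixed once, at the field-study conditions the package is anchored to:

* 7 clusters; 2,2,2,2,1,1,1 rubber plots (11 total); ages drawn without
  replacement from {5, 7, 9, 12, 15, 18, 22, 25, 30, 38, 46} yr.
* Forest baselines 43.9, 38.9, 52, 35.2, 26.0 Mg C ha⁻¹ for the five
  intervals (≈196 Mg C ha⁻¹ to 1.2 m), with log-normal cluster intercepts
  of 10% CV — the within-cluster correlation of real paired designs is
  unpublished, so this is an exposed free choice.
* Decay truth $X_e$ = 68, 75, 85, 90, 95% (deep intervals nearly inert,
  mirroring non-significant subsoil losses), $k = 0.2$ yr⁻¹.
* Noise is multiplicative log-normal (stocks are positive; SEs scale with
  means): CV 0.05 on each rubber plot's decay proportion (≈5 percentage
  points near 100%) and CV 0.02 measurement noise on every plot's stocks.
* Bulk density: forest 1.0, 1.2, 1.3, 1.3, 1.3 g cm⁻³; rubber 1.1, 1.1,
  1.3, 1.3, 1.3, plus a `bd_rubber_shift` stress-test mode and a
  `bd_match_forest` switch that copies the forest draws so corrected and
  uncorrected stocks coincide exactly.
* Horizon C% is back-computed by inverting the stock equation at the
  *forest* BD, so recomputing corrected stocks from the bundle reproduces
  the recorded truth exactly (round-trip identity).
* Basal area grows linearly with age (slope 0.96 m² ha⁻¹ yr⁻¹, noise SD
  3.5), reproducing the strong age–basal-area rank correlation of such
  plantations; litter is land-use neutral.

What the generator does **not** emulate: spatial autocorrelation beyond the
cluster intercept, within-plot soil composite replicates, terrace
micro-topography, erosion or input-flux mechanisms, and age-dependent
variance. Passing tests therefore demonstrate that the estimators recover
the assumed data-generating process at the study's size and noise — not
that real soils satisfy that process.

## Numerical choices and degenerate inputs

* Stocks: totals equal interval sums to 1e-9 relative tolerance; zero
  forest stock makes a relative difference `NA` with a warning rather than
  an Inf.
* Fitting: `ftol = ptol = 1e-15`, max 1000 iterations; noiseless
  model-generated data is recovered to ≤1e-6 relative error (tested).
* Validation: depth profiles must match the canonical set without gaps or
  overlaps; texture must close to 100 ± 0.5%; BD outside 0.2–2.2 g cm⁻³ is
  rejected; blank optional chemistry stays missing, never zero. Forest
  trees at or below the 4-cm DBH inventory threshold are dropped with a
  warning.
* All randomness (generator draws, restart jitter) flows from explicit
  seeds through an isolated RNG stream that never disturbs the caller's
  RNG state.

## Problem sizes used in the shipped checks

The test suite and acceptance script run the full pipeline on the default
18-plot study, a 200-replicate topsoil parameter-recovery simulation
(median error and 95% Wald coverage of $X_e$ and $k$), a 1000-draw
closed-form-versus-grid steady-state comparison, and brute-force oracles
for Holm, Spearman and the profile-total arithmetic. These sizes were
chosen to estimate each property stably at interactive runtimes.

## Known limitations

* The space-for-time assumption itself (clusters initially identical) is a
  design assumption; the package tests texture exchangeability on synthetic
  data but cannot validate it for real sites.
* With ~11 points and no $t = 0$ observation, the decay rate is imprecise;
  confidence intervals for $k$ should be read alongside the boundary-fit
  flag.
* The mixed model assumes Gaussian residuals; only a land-use variance
  function is built in (depth-stratified variances would be a small
  extension).
* One composite sample per plot × interval is assumed; within-plot
  sampling error is absorbed into the residual.
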