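---
title: "Methods: environmental predictability and interval-censored location-scale models of parturition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: environmental predictability and interval-censored location-scale models of parturition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenosync)
```

`phenosync` links two pieces of machinery: an information-theoretic
description of how predictable a site's environment is, and a
distributional regression of interval-censored birth dates on that
description. This vignette explains both models, the choices that were
genuinely open when the package was designed, and what the synthetic-data
tests do and do not demonstrate.

## 1. Colwell's predictability metrics

### The decomposition

An environmental variable observed over `n` years is collapsed to a matrix
of years by within-year time classes (`t = 12` monthly means for NDVI,
`t = 52` weekly summaries for temperature and precipitation), then each
cell is assigned to one of `s` discrete states. From the resulting
state-by-time frequency table the package computes the entropies `H(X)` of
the time marginal, `H(Y)` of the state marginal and `H(XY)` of the table,
and

* **constancy** `C = 1 - H(Y)/log s` — 1 when the variable sits in a
  single state all year, every year;
* **contingency** `M = (H(X) + H(Y) - H(XY))/log s` — 1 when the state is
  a deterministic function of the time of year, repeated identically
  across years (the usual reading of "seasonality");
* **predictability** `P = C + M`, in `[0, 1]`.

`0·log 0` is treated as zero, natural logarithms are used internally, and
the normalized metrics are invariant to the log base (a tested property).

### Choices the metric definition leaves open

* **Number of states and binning rule.** Neither is canonical for
  continuous variables. The default is `s = 11` equal-width bins over the
  site's observed range, with an equal-frequency (quantile) alternative
  exposed as `strategy = "equal_frequency"`; both are recorded in the
  output metadata. Equal width is the dominant convention for Colwell's
  metrics on continuous environmental variables, and the sensitivity to
  the choice is directly testable by rerunning with the other strategy.
  Bins are half-open `[lo, hi)` with a closed top bin so the maximum is
  counted exactly once. A numerically constant series (range below a
  1e-10 relative tolerance) is forced into a single state rather than
  spread across micro-width bins.
* **Week definition.** Weeks are fixed 7-day blocks counted from
  1 January, with days 365/366 folded into week 52. This is reproducible
  and calendar-library-free. Because the folded week has 8–9 calendar
  days, weekly precipitation is expressed as a 7-day-equivalent total
  (7 × mean daily value): otherwise a perfectly constant drizzle would
  register spurious state variation in week 52.
* **Missing cells** are excluded from the counts (the grand total
  shrinks) rather than imputed, and a completeness fraction is reported
  per table. Entropies are defined on observed mass; imputing would
  fabricate data.
* **NDVI smoothing.** Composites are smoothed with a Savitzky–Golay
  filter specified by a *physical* window (45 days, order 2). The window
  is converted to the nearest odd number of sample points at the series'
  cadence — 5 points for 8-day composites — and never below
  `polyorder + 2`. An order-2 filter passes constants and quadratic
  trends through unchanged, which the tests assert.

## 2. The interval-censored location-scale model

### Likelihood

Fawn ages are estimated, so back-calculated birth dates carry
age-dependent uncertainty. Each record contributes an interval
`[l_i, u_i]` centred on the estimated birth day-of-year with half-width 2,
3 or 5 days for estimated ages ≤7, 8–14 and ≥15 days. The printed rule
has gaps at exactly 7 and 15 days; the package closes them conservatively
(7 → ±2, 15 → ±5) and both boundaries are configurable
(`censor_interval(age_breaks =, half_widths =)`).

The model is Gaussian in both moments:

* location `mu_i = x_i' beta + b_g(i)`, identity link, with a scalar
  Gaussian random intercept per region × year group,
  `b_g ~ N(0, tau^2)`;
* scale `log sigma_i = z_i' gamma`, log link.

The conditional contribution of an interval observation is
`log[Phi((u_i - mu_i)/sigma_i) - Phi((l_i - mu_i)/sigma_i)]`; exact
observations (`l = u`) contribute the log density. The difference of CDFs
is computed in log space (reflecting the interval so its midpoint is
non-positive and differencing lower-tail log-CDFs), which stays accurate
tens of standard deviations into the tails. If even that saturates — which
only happens transiently while the optimizer explores — the interval mass
is approximated by width × density at the midpoint, keeping the objective
finite and smoothly pulling the parameters back toward the data.

### Marginalization and optimization

Group intercepts are integrated out by a Laplace approximation: a
vectorized inner Newton iteration finds every group's posterior mode
simultaneously (the per-group objective is log-concave, so capped Newton
steps converge), and the marginal log-likelihood adds the usual curvature
correction. A 9-node adaptive Gauss–Hermite quadrature
(`method = "agq"`) is available as a cross-check; on the synthetic test
data the two agree to about five significant digits in the log-likelihood,
which is why the faster Laplace method is the default.

The outer optimization is BFGS with finite-difference gradients
(step 1e-6, relative tolerance 1e-10, max 500 iterations), initialized at
the empirical moments of the interval midpoints (location intercept =
mean midpoint, scale intercept = log midpoint SD, other coefficients 0,
`tau` = 5 days). One seeded restart from a perturbed point is attempted on
non-convergence; the best iterate is returned with `converged = FALSE` if
both fail. Scales are floored at 1e-6 days (with a warning at the
user-facing likelihood) and capped at 1e6 days inside the optimizer.
Standard errors come from the observed information matrix of the marginal
likelihood (numeric Hessian); `tau`'s standard error uses the delta method
from the log scale.

### Choices the analysis design left open

* **Where the random effect enters.** The grouping (region × year) is
  stated by the design, the predictor it enters is not. The package puts
  the Gaussian intercept on the location predictor only: that is standard
  distributional-regression practice, identifiable with modest group
  counts, and the quantity the grouping is meant to absorb (annual
  regional shifts in mean timing) lives in the location part.
* **Scale covariates.** The named presets give the scale predictor the
  same covariates as the location predictor. Covariate-driven synchrony
  is the scientific point of a location-scale model; a custom spec can
  restrict either part.
* **Degrees of freedom for AIC.** `n_params` counts fixed effects plus
  one for `tau`; random-effect modes are not counted (marginal-likelihood
  convention). Published ΔAIC values computed under other conventions are
  therefore not exactly comparable, and the comparison table reports raw
  log-likelihoods, parameter counts and signed deltas so the reader can
  apply either convention.
* **Synchrony.** Reported as the central 80% interval width
  `(z_0.9 - z_0.1) * sigma = 2.5631 * sigma`, a common way to express
  birth-season spread in days.

## 3. Record screening

Opportunistic fawn searches can start earlier over the years (e.g. mowing
moved earlier), which would masquerade as a phenological shift. For each
region the package fits linear quantile regressions of marking day on year
at the 0.1, 0.5 and 0.9 quantiles and excludes the region if any quantile
slope is significantly negative at `alpha = 0.05`. Two implementation
choices were open:

* **Quantile-regression solver.** The two-parameter pinball-loss problem
  is solved exactly up to search tolerance by profiling out the intercept
  (for fixed slope the optimal intercept is a residual quantile) and
  minimizing the resulting convex one-dimensional objective by golden
  section. This is written in the package rather than taken from a
  dedicated quantile-regression library.
* **Inference.** The significance method is not prescribed by the design;
  the package uses a seeded case-resampling bootstrap (default
  `B = 1000`) with a normal approximation on the bootstrap SE, two-sided
  p-values, and a one-sided exclusion rule (only *negative* slopes
  trigger exclusion, matching the sampling-bias concern). This is
  distribution-free and exactly reproducible given the seed.

## 4. Spatial prediction

Grid spacing is a physical distance, so `make_grid()` lays points out
`spacing_km` apart in a spherical azimuthal equidistant projection centred
on the extent and back-projects them to longitude/latitude; the geodesic
distance between planar neighbours is correct to well under 1% at
continental extents (tested against an independent geodesic oracle). An
optional polygon mask (vertex table or GeoJSON) restricts the grid to a
study area. Predictions over the grid are conditional on mean (zero)
random effects, and per-region elevation classes use the 10th percentile,
the mean of records between the 45th and 55th percentiles, and the 90th
percentile, with type-7 (linear interpolation) quantiles — the class
values depend on this convention, so it is fixed and documented.

## 5. What the synthetic data emulate — and what they do not

The generator is the package's study-conditions module, not a test dial.

* `env_scenario()` produces an annual sinusoid plus interannual level
  shifts and observation noise per variable, at daily (climate) and 8-day
  (NDVI) cadence over 2001–2020. Larger amplitude relative to noise
  raises contingency; lower total variability raises constancy, so the
  generator can place a site anywhere in the constancy–contingency
  triangle.
* `pop_scenario()` describes 16 study regions with fixed, strongly
  unbalanced sampling weights (the largest region carries ~30% of
  records, mimicking the dominance of a single large monitoring scheme),
  region mean elevations from 150 to 1600 m, latitudes 43.5–62.5°N, and a
  true model `birth ~ N(x'beta + b_g, exp(z'gamma))` with defaults
  `beta` = (145, +3.5 days/SD elevation, Colwell effects of 0.5–2.5
  days/SD), baseline `sigma = 10.5` days, `tau = 3` days, and an age mix
  of 60/30/10% across the three censoring classes. The `"small"` preset
  (~2,400 records over 10 years) is the test default; `"paper_like"`
  scales to ~17,200 records over 20 years.
* Covariates are given realistic correlation *signs* (temperature
  constancy falls with elevation and eastward longitude; NDVI contingency
  rises with both) by generating them as clamped linear functions of
  elevation and longitude plus Gaussian noise. The noise is sized so the
  correlations are moderate rather than collinear.
* True coefficients are defined in days per standard deviation of the
  realized covariates; the generator standardizes internally and stores
  the constants in the truth ledger, so recovery comparisons are exact
  rather than approximately back-transformed.

Because the forward model is exactly the likelihood's data-generating
process, the recovery tests demonstrate *correct implementation of a
correctly specified model* — consistency, near-nominal interval coverage,
sane model selection. They do not demonstrate robustness to the things
real fawn data add: heterogeneous age-estimation error across sites and
observers, non-Gaussian birth-date distributions, spatially structured
residuals, or NDVI contaminated by clouds. The grid covariate table is
likewise fabricated (`gen_grid_covariates()`): the package consumes
pre-extracted tidy series and grid covariates and deliberately does not
download or process rasters.

## 6. Validation against reported distributions

`validate_predictions()` applies the inclusion rule (sites with reported
`n` ≤ 30 excluded; sites with unknown `n` retained), computes per-site
differences (predicted − reported) and summarizes each metric by its mean
absolute error. One site's reported mean is flagged as not directly
sourced in the packaged table; it is kept in the headline MAE and a
variant excluding flagged sites is attached to the report, since the
published MAE's exact site set is ambiguous. Recomputing from the printed
(whole-day rounded) table cells reproduces the published mean-date MAEs to
within half a day, which is the resolution rounding permits.

## 7. Problem sizes used by the test suite

The suite exercises the statistical claims at sizes chosen to give
informative Monte-Carlo precision at desk scale: parameter recovery uses
the full `"small"` preset (16 regions, ~2,400 records) over 10 seeds;
model-selection sanity uses 25 replicates of an 8-region, ~900-record
reduction with the latitude–elevation model as the generator; coverage
checks use 5 seeds with standard errors on a 1,500-record scenario. These
sizes are the package's own choices and are stated here so that anyone
scaling them up knows what was actually verified.

## 8. Known limitations

* The Gaussian assumption is not relaxed; no transformation-model or
  non-Gaussian response alternative is provided.
* Only scalar random intercepts on the location predictor are supported —
  no random slopes, no scale-side random effects (the spec hook exists in
  `icls_spec()` but presets do not use it).
* Smooth (spline) covariate effects are out of scope; presets are linear
  in standardized covariates.
* Colwell metrics are computed per site over the full series; circular
  variables and multi-year periodicities are not handled.
* The day-of-year axis is continuous with no wrap at the year boundary;
  this is correct for spring-birthing species but wrong for populations
  whose birth season straddles 1 January.
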