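# phenosync

Tools for modelling the timing and synchrony of ungulate parturition as a
function of environmental predictability.

## The problem

Birth dates of income-breeding ungulates such as roe deer must track the
short window of peak forage quality. Latitude and elevation are the usual
proxies for that window, but they are coarse: two regions at the same
latitude can differ sharply in how *predictable* their seasons are.
`phenosync` implements an analysis pipeline that

1. quantifies environmental predictability from climate and NDVI time
   series with **Colwell's metrics** — constancy *C*, contingency *M* and
   predictability *P = C + M*;
2. models fawn birth dates with an **interval-censored Gaussian
   location-scale regression** (a GAMLSS-style distributional model), so
   that both the mean birth date and the within-population spread
   (synchrony) depend on covariates;
3. predicts mean parturition date and synchrony over spatial point grids;
4. validates predictions against independently reported parturition
   distributions.

It is aimed at movement/phenology ecologists and biostatisticians who have
per-site environmental series and per-fawn capture records (or want to
simulate them).

## The model

For a state-by-time frequency table with counts `N_ij` (state *i* of *s*,
time class *j* of *t*, grand total *Z*, column totals `X_j`, row totals
`Y_i`), Colwell's metrics are

    H(X)  = -sum_j (X_j/Z) log(X_j/Z)
    H(Y)  = -sum_i (Y_i/Z) log(Y_i/Z)
    H(XY) = -sum_ij (N_ij/Z) log(N_ij/Z)

    C = 1 - H(Y)/log(s),   M = (H(X) + H(Y) - H(XY))/log(s),   P = C + M

Birth dates are observed only up to an age-dependent interval
`[l_i, u_i]` (half-widths ±2 / ±3 / ±5 days for fawns aged ≤7 / 8–14 / ≥15
days). The model is

    birth_i ~ Normal(mu_i, sigma_i^2)
    mu_i        = x_i' beta + b_{g(i)},   b_g ~ N(0, tau^2)   (identity link)
    log sigma_i = z_i' gamma                                   (log link)

with `g(i)` the region × year group. The marginal likelihood sums
`log[ Phi((u_i - mu_i)/sigma_i) - Phi((l_i - mu_i)/sigma_i) ]` over
observations and integrates the group intercepts by a Laplace
approximation (adaptive Gauss–Hermite quadrature is available as a
cross-check). Synchrony is reported as the width of the central 80%
interval, `(z_0.9 - z_0.1) * sigma = 2.5631 * sigma` days.

## Worked example

```r
library(phenosync)

# 1. environmental predictability for one site (synthetic series)
env <- gen_environment(env_scenario(sites = "site_1", years = 2001:2020), seed = 1)
site_predictability(env)
#>   constancy_ndvi contingency_ndvi constancy_precipitation
#> 1          0.025            0.627                   0.187
#>   contingency_precipitation constancy_temperature contingency_temperature
#> 1                     0.119                  0.03                   0.593
```

A temperate seasonal cycle shows high *contingency* (the within-year
pattern repeats across years) and low *constancy* (values are far from
uniform across the year) — exactly the decomposition the metrics are for.

```r
# 2. fit the location-scale model on a simulated population with known truth
scenario <- pop_scenario("small", model = "latitude_elevation",
                         n_regions = 8, total_n = 1200, years = 2012:2017)
pop <- gen_population(scenario, seed = 1)            # truth: beta_lat = 4, beta_elev = 3.5,
tbl <- attach_covariates(censor_interval(pop$records)) #        sigma0 = 10.5, tau = 3
fit <- icls_fit(tbl, icls_spec("latitude_elevation"))
fit
#> <icls_fit> preset 'latitude_elevation', n = 1200, groups = 48
#>   logLik = -2648.4206, AIC = 5310.8411, params = 7, converged = TRUE
#>   random-intercept SD tau = 2.521 days
#>   location: (Intercept)=144.876, latitude=3.016, elevation=4.017
#>   scale:    (Intercept)=2.354, latitude=-0.022, elevation=0.063
```

The location coefficients are in days per standard deviation of each
covariate: here later births at higher latitude and elevation, a baseline
scale of `exp(2.354) ≈ 10.5` days, and region-by-year fluctuations of
about 2.5 days — all close to the generating values.

```r
# 3. predict mean date and synchrony at two covariate points
predict(fit, tibble::tibble(latitude = c(46, 60), elevation = 400))
#>   latitude elevation    mu sigma synchrony80
#> 1       46       400  137.  10.8        27.7
#> 2       60       400  147.  10.0        25.7

# 4. compare against independently reported parturition distributions
validate_predictions(read_literature(), model = "colwell_elevation")
#> <validation_report> 9 sites kept, 0 excluded (n <= 30)
#>   MAE mean date: 4.111 days (9 sites)
#>   MAE synchrony: 3.571 days (7 sites)
```

`mu` is the predicted mean birth day-of-year (DoY 137 ≈ 17 May) and
`synchrony80` the span of the central 80% of births. The validation report
recomputes the mean absolute error of the packaged literature table's
predictions against its reported values.

The full pipeline (metrics → QC → fit → grid prediction → validation) runs
from one config via `run_pipeline()`; see `inst/scripts/phenosync.R` for a
shell entry point and the vignette in `vignettes/` for methods details.

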