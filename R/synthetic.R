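# Synthetic data generation: environmental series with controllable
# predictability, birth-record populations drawn from known location-scale
# parameters (the forward model is exactly the likelihood's data-generating
# process), grid covariate tables, and a parameter-recovery harness.

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Define an environmental-series scenario
#'
#' Each variable follows an annual sinusoid with additive interannual level
#' shifts and observation noise:
#' `value(day) = base + A * sin(2 * pi * (doy - phase) / 365) + shift(year) + noise`,
#' with `shift(year) ~ N(0, year_sd)` and `noise ~ N(0, noise_sd)`. NDVI is
#' clipped to \[-1, 1\] and precipitation truncated at 0. Larger amplitude
#' relative to noise raises contingency; smaller total variability raises
#' constancy. Defaults emulate a temperate European site: daily temperature
#' and precipitation plus 8-day NDVI composites, 2001-2020.
#'
#' @param sites Character vector of site ids.
#' @param years Integer years covered (default 2001:2020).
#' @param params Optional tibble overriding the per-variable defaults
#'   (columns `variable`, `cadence_days`, `base`, `amplitude`, `phase_doy`,
#'   `year_sd`, `noise_sd`); rows replace defaults by variable name.
#' @return A list of class `env_scenario`.
#' @export
env_scenario <- function(sites = "S1", years = 2001:2020, params = NULL) {
  defaults <- tibble(
    variable = c("temperature", "precipitation", "ndvi"),
    cadence_days = c(1, 1, 8),
    base = c(8, 2.2, 0.45),
    amplitude = c(9, 0.8, 0.30),
    phase_doy = c(110, 20, 110),
    year_sd = c(0.8, 0.3, 0.03),
    noise_sd = c(2.5, 3, 0.05)
  )
  if (!is.null(params)) {
    params <- tibble::as_tibble(params)
    keep <- defaults[defaults$variable %not_in% params$variable, ]
    defaults <- dplyr::bind_rows(keep, params) |>
      dplyr::arrange(match(.data$variable, c("temperature", "precipitation", "ndvi")))
  }
  structure(list(sites = sites, years = years, params = defaults),
            class = "env_scenario")
}

#' Generate environmental time series from a scenario
#'
#' @param scenario An [env_scenario()].
#' @param seed Integer seed; the output is fully deterministic given
#'   (scenario, seed).
#' @return A long-format tibble (`site_id`, `date`, `variable`, `value`)
#'   consumable by [site_predictability()].
#' @export
gen_environment <- function(scenario, seed = 1) {
  stopifnot(inherits(scenario, "env_scenario"))
  set.seed(seed)
  years <- scenario$years
  combos <- tidyr::expand_grid(site_id = scenario$sites,
                               variable = scenario$params$variable)
  purrr::pmap_dfr(combos, function(site_id, variable) {
    p <- scenario$params[scenario$params$variable == variable, ]
    dates <- seq(as.Date(paste0(min(years), "-01-01")),
                 as.Date(paste0(max(years), "-12-31")),
                 by = p$cadence_days)
    doy <- lubridate::yday(dates)
    yr <- lubridate::year(dates)
    shift <- setNames(rnorm(length(years), 0, p$year_sd), years)
    value <- p$base +
      p$amplitude * sin(2 * pi * (doy - p$phase_doy) / 365) +
      unname(shift[as.character(yr)]) +
      rnorm(length(dates), 0, p$noise_sd)
    if (variable == "ndvi") value <- pmin(pmax(value, -1), 1)
    if (variable == "precipitation") value <- pmax(value, 0)
    tibble(site_id = site_id, date = dates, variable = variable, value = value)
  })
}

#' Define a birth-record population scenario
#'
#' Describes the forward model for synthetic fawn records: 16 study regions
#' with fixed, strongly unbalanced sampling weights; per-record covariates
#' (elevation, latitude and the six Colwell covariates, generated with
#' realistic correlation signs — temperature constancy falls with elevation
#' and with eastward longitude, NDVI contingency rises with both); true
#' birth dates drawn from `Normal(x'beta + b_g, exp(z'gamma))` with
#' region-by-year intercepts `b_g ~ N(0, tau^2)`; and an observation age
#' per record (60% at 0-7 days, 30% at 8-14, 10% at 15-25 by default) that
#' sets the marking day. `beta` and `gamma` are expressed in days per
#' standard deviation of each covariate (the generator standardizes the
#' realized covariates internally and records the constants in the truth
#' ledger).
#'
#' @param preset `"small"` (~2,400 records over 10 years; the test default)
#'   or `"paper_like"` (~17,200 records over 20 years).
#' @param model Preset whose covariates carry the true effects:
#'   `"colwell_elevation"` (default) or `"latitude_elevation"`.
#' @param n_regions,total_n,years Optional overrides of the preset sizes.
#' @param beta,gamma Optional named replacement coefficient vectors (must
#'   include `"(Intercept)"`).
#' @param tau Random-intercept SD in days (default 3).
#' @param age_probs Probabilities of the three age classes (sum to 1).
#' @return A list of class `pop_scenario`.
#' @export
pop_scenario <- function(preset = c("small", "paper_like"),
                         model = c("colwell_elevation", "latitude_elevation"),
                         n_regions = NULL, total_n = NULL, years = NULL,
                         beta = NULL, gamma = NULL, tau = 3,
                         age_probs = c(young = 0.6, mid = 0.3, old = 0.1)) {
  preset <- match.arg(preset)
  model <- match.arg(model)
  stopifnot(abs(sum(age_probs) - 1) < 1e-8, tau >= 0)
  total_n <- total_n %||% switch(preset, small = 2400, paper_like = 17200)
  years <- years %||% switch(preset, small = 2008:2017, paper_like = 2001:2020)
  n_regions <- n_regions %||% 16L

  lat_perm <- c(9, 3, 14, 1, 12, 6, 16, 8, 2, 11, 5, 15, 4, 10, 7, 13)
  regions <- tibble(
    region_id = sprintf("R%02d", 1:16),
    latitude = seq(43.5, 62.5, length.out = 16)[lat_perm],
    longitude = seq(-1.5, 24.5, length.out = 16),
    elev_mean = c(250, 1200, 450, 150, 900, 300, 1600, 550,
                  200, 700, 350, 1100, 500, 250, 800, 400),
    weight = c(30, 2, 6, 1, 10, 3, 8, 4, 2, 7, 3, 9, 5, 2, 4, 4)
  )[seq_len(n_regions), ]
  regions$weight <- regions$weight / sum(regions$weight)
  regions$elev_sd <- pmax(regions$elev_mean * 0.3, 60)

  if (is.null(beta)) {
    beta <- switch(model,
      colwell_elevation = c(
        "(Intercept)" = 145, elevation = 3.5,
        constancy_temperature = -2.5, contingency_temperature = 1.0,
        constancy_ndvi = -1.5, contingency_ndvi = 2.0,
        constancy_precipitation = -0.5, contingency_precipitation = 0.5
      ),
      latitude_elevation = c("(Intercept)" = 145, latitude = 4, elevation = 3.5)
    )
  }
  if (is.null(gamma)) {
    gamma <- switch(model,
      colwell_elevation = c("(Intercept)" = log(10.5),
                            contingency_ndvi = -0.08, elevation = 0.05),
      latitude_elevation = c("(Intercept)" = log(10.5), elevation = 0.05)
    )
  }
  stopifnot("(Intercept)" %in% names(beta), "(Intercept)" %in% names(gamma))
  structure(
    list(preset = preset, model = model, regions = regions, years = years,
         total_n = total_n, beta = beta, gamma = gamma, tau = tau,
         age_probs = age_probs),
    class = "pop_scenario"
  )
}

#' Generate birth records and a truth ledger from a population scenario
#'
#' Draws covariates, region-by-year random intercepts, true birth dates and
#' observation ages, then emits the records table the real pipeline
#' consumes plus a truth ledger for parameter-recovery tests.
#'
#' @param scenario A [pop_scenario()].
#' @param seed Integer seed; output is fully deterministic given
#'   (scenario, seed).
#' @return A list with `records` (tibble: `record_id`, `region_id`, `year`,
#'   `marking_doy`, `estimated_age_days`, `estimated_birth_doy`,
#'   `longitude`, `latitude`, `elevation` and the six Colwell covariates on
#'   their raw scales) and `truth` (list: `beta`, `gamma`, `tau` on the
#'   standardized scale, `group_effects`, `true_doy`, `mu_fixed`,
#'   `standardization`, `model`).
#' @export
gen_population <- function(scenario, seed = 1) {
  stopifnot(inherits(scenario, "pop_scenario"))
  set.seed(seed)
  regions <- scenario$regions
  n_r <- round(scenario$total_n * regions$weight)
  n_r[1] <- n_r[1] + (scenario$total_n - sum(n_r))
  idx <- rep(seq_len(nrow(regions)), n_r)
  n <- length(idx)
  years <- sample(scenario$years, n, replace = TRUE)

  elev <- pmax(rnorm(n, regions$elev_mean[idx], regions$elev_sd[idx]), 1)
  lat <- regions$latitude[idx] + rnorm(n, 0, 0.15)
  lon <- regions$longitude[idx] + rnorm(n, 0, 0.2)
  covs <- tibble(
    elevation = elev,
    latitude = lat,
    constancy_temperature = clamp01(0.72 - 1.5e-4 * elev - 0.006 * lon + rnorm(n, 0, 0.08)),
    contingency_temperature = clamp01(0.30 + 0.8e-4 * elev + 0.007 * lon + rnorm(n, 0, 0.07)),
    constancy_ndvi = clamp01(0.60 - 1.2e-4 * elev - 0.004 * lon + rnorm(n, 0, 0.07)),
    contingency_ndvi = clamp01(0.32 + 1.4e-4 * elev + 0.006 * lon + rnorm(n, 0, 0.07)),
    constancy_precipitation = clamp01(0.55 - 0.4e-4 * elev + 0.002 * lon + rnorm(n, 0, 0.06)),
    contingency_precipitation = clamp01(0.12 + 0.2e-4 * elev + 0.001 * lon + rnorm(n, 0, 0.04))
  )
  std <- tibble(
    covariate = names(covs),
    mean = vapply(covs, mean, 0),
    sd = vapply(covs, sd, 0)
  )
  zmat <- as.matrix(purrr::map2_dfc(covs, seq_along(covs), function(v, i) {
    (v - std$mean[i]) / std$sd[i]
  }))

  lin_pred <- function(coefs) {
    eta <- rep(unname(coefs["(Intercept)"]), n)
    for (nm in setdiff(names(coefs), "(Intercept)")) {
      eta <- eta + coefs[[nm]] * zmat[, nm]
    }
    eta
  }
  mu_fixed <- lin_pred(scenario$beta)
  sigma <- exp(lin_pred(scenario$gamma))

  groups <- tidyr::expand_grid(region_id = regions$region_id,
                               year = scenario$years) |>
    dplyr::mutate(effect = rnorm(dplyr::n(), 0, scenario$tau))
  key <- paste(regions$region_id[idx], years, sep = ":")
  b <- setNames(groups$effect, paste(groups$region_id, groups$year, sep = ":"))[key]

  true_doy <- rnorm(n, mu_fixed + unname(b), sigma)
  age_class <- sample(c("young", "mid", "old"), n, replace = TRUE,
                      prob = scenario$age_probs)
  age <- dplyr::case_when(
    age_class == "young" ~ sample(0:7, n, replace = TRUE),
    age_class == "mid" ~ sample(8:14, n, replace = TRUE),
    TRUE ~ sample(15:25, n, replace = TRUE)
  )
  est_birth <- round(true_doy)

  records <- dplyr::bind_cols(
    tibble(
      record_id = sprintf("F%05d", seq_len(n)),
      region_id = regions$region_id[idx],
      year = years,
      marking_doy = est_birth + age,
      estimated_age_days = age,
      estimated_birth_doy = est_birth,
      longitude = lon
    ),
    covs
  )
  list(
    records = records,
    truth = list(
      beta = scenario$beta, gamma = scenario$gamma, tau = scenario$tau,
      group_effects = groups, true_doy = true_doy, mu_fixed = mu_fixed,
      standardization = std, model = scenario$model
    )
  )
}

#' Fabricate a grid covariate table
#'
#' Builds a point grid over an extent and attaches synthetic covariates
#' with smooth spatial structure (a west-east predictability gradient and
#' an undulating elevation field), for exercising [predict_surface()]
#' without real rasters.
#'
#' @param extent,spacing_km Passed to [make_grid()].
#' @param seed Integer seed for the small covariate noise.
#' @return A grid tibble with elevation, latitude and the six Colwell
#'   covariates.
#' @export
gen_grid_covariates <- function(extent = c(-5, 25, 42, 62), spacing_km = 100,
                                seed = 1) {
  set.seed(seed)
  grid <- make_grid(extent, spacing_km = spacing_km)
  n <- nrow(grid)
  elev <- pmax(150 + 900 * abs(sin(grid$lat / 4) * cos(grid$lon / 5)) +
                 rnorm(n, 0, 50), 1)
  grid |>
    dplyr::mutate(
      elevation = elev,
      latitude = .data$lat,
      constancy_temperature = clamp01(0.72 - 1.5e-4 * elev - 0.006 * .data$lon + rnorm(n, 0, 0.02)),
      contingency_temperature = clamp01(0.30 + 0.8e-4 * elev + 0.007 * .data$lon + rnorm(n, 0, 0.02)),
      constancy_ndvi = clamp01(0.60 - 1.2e-4 * elev - 0.004 * .data$lon + rnorm(n, 0, 0.03)),
      contingency_ndvi = clamp01(0.32 + 1.4e-4 * elev + 0.006 * .data$lon + rnorm(n, 0, 0.03)),
      constancy_precipitation = clamp01(0.55 - 0.4e-4 * elev + 0.002 * .data$lon + rnorm(n, 0, 0.03)),
      contingency_precipitation = clamp01(0.12 + 0.2e-4 * elev + 0.001 * .data$lon + rnorm(n, 0, 0.02))
    )
}

#' Parameter-recovery harness
#'
#' For each seed: generate a population, censor the records, assemble the
#' model table, fit the requested preset and compare estimates to the truth
#' ledger. Non-convergence is counted, not fatal.
#'
#' @param scenario A [pop_scenario()].
#' @param model Model preset to fit (defaults to the scenario's generating
#'   preset, i.e. a well-specified fit).
#' @param seeds Integer vector of seeds (default 1:10).
#' @param se Compute per-fit standard errors so the summary can report
#'   coverage of nominal 95% intervals (default `FALSE`).
#' @return A list with `summary` (per parameter: truth, mean estimate,
#'   bias, RMSE, coverage), `per_seed` (per-seed estimates, convergence and
#'   the RMSE of the fixed-effect location predictor against the true one)
#'   and `n_failed`.
#' @export
recovery_harness <- function(scenario, model = scenario$model,
                             seeds = 1:10, se = FALSE) {
  runs <- purrr::map(seeds, function(s) {
    pop <- gen_population(scenario, seed = s)
    tbl <- attach_covariates(censor_interval(pop$records))
    fit <- tryCatch(
      icls_fit(tbl, icls_spec(model), se = se),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      return(list(ok = FALSE, seed = s))
    }
    pred <- predict(fit, pop$records, conditional = TRUE)
    list(
      ok = TRUE, seed = s, fit = fit, truth = pop$truth,
      mu_rmse = sqrt(mean((pred$mu - pop$truth$mu_fixed)^2)),
      converged = fit$converged
    )
  })
  ok <- purrr::keep(runs, "ok")
  if (length(ok) == 0) {
    abort("all recovery fits failed")
  }
  truth_for <- function(truth_vec, terms) {
    out <- setNames(numeric(length(terms)), terms)
    shared <- intersect(names(truth_vec), terms)
    out[shared] <- truth_vec[shared]
    out
  }
  per_param <- purrr::map_dfr(ok, function(r) {
    td <- tidy(r$fit)
    truth <- c(
      truth_for(r$truth$beta, names(r$fit$beta)),
      truth_for(r$truth$gamma, names(r$fit$gamma)),
      if (!is.na(r$fit$tau)) r$truth$tau
    )
    td |>
      dplyr::mutate(seed = r$seed, truth = unname(truth)) |>
      dplyr::mutate(covered = abs(.data$estimate - .data$truth) <=
                      1.96 * .data$std.error)
  })
  summary <- per_param |>
    dplyr::group_by(.data$parameter, .data$term) |>
    dplyr::summarise(
      truth = .data$truth[1],
      mean_estimate = mean(.data$estimate),
      bias = mean(.data$estimate - .data$truth),
      rmse = sqrt(mean((.data$estimate - .data$truth)^2)),
      coverage = if (se) mean(.data$covered) else NA_real_,
      .groups = "drop"
    )
  per_seed <- tibble(
    seed = vapply(ok, function(r) r$seed, 0),
    converged = vapply(ok, function(r) r$converged, TRUE),
    mu_rmse = vapply(ok, function(r) r$mu_rmse, 0),
    sigma0 = vapply(ok, function(r) exp(unname(r$fit$gamma["(Intercept)"])), 0),
    tau = vapply(ok, function(r) r$fit$tau, 0)
  )
  list(summary = summary, per_seed = per_seed,
       n_failed = length(runs) - length(ok))
}
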