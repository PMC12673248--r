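# Shared fixture builders. Everything is generated in code; no stored data.

# Long-format series with one constant value per variable.
constant_env_series <- function(site = "A", years = 2001:2020,
                                base = c(temperature = 10, precipitation = 1,
                                         ndvi = 0.5)) {
  sc <- env_scenario(
    sites = site, years = years,
    params = tibble::tibble(
      variable = c("temperature", "precipitation", "ndvi"),
      cadence_days = c(1, 1, 8),
      base = unname(base[c("temperature", "precipitation", "ndvi")]),
      amplitude = 0, phase_doy = 110, year_sd = 0, noise_sd = 0
    )
  )
  gen_environment(sc, seed = 1)
}

# Aggregated-matrix tibble (one site/variable) from a year x class value matrix.
matrix_tbl <- function(values, site = "A", variable = "ndvi") {
  n_years <- nrow(values)
  t_classes <- ncol(values)
  tidyr::expand_grid(year = seq_len(n_years) + 2000,
                     time_class = seq_len(t_classes)) |>
    dplyr::mutate(
      site_id = site, variable = variable,
      value = as.vector(t(values)), n_classes = t_classes,
      .before = 1
    )
}

# Frequency table of a strictly annual-periodic pattern: s states, each
# occupying t/s time classes, identical across years.
periodic_counts <- function(s = 4, t = 12, n_years = 20) {
  counts <- matrix(0, s, t)
  per <- t / s
  for (j in seq_len(t)) counts[ceiling(j / per), j] <- n_years
  counts
}

# Brute-force Colwell oracle: entropies from first principles with explicit
# loops, independent of the package implementation.
colwell_oracle <- function(counts, log_base = exp(1)) {
  z <- sum(counts)
  lg <- function(x) log(x, base = log_base)
  hx <- 0
  for (j in seq_len(ncol(counts))) {
    p <- sum(counts[, j]) / z
    if (p > 0) hx <- hx - p * lg(p)
  }
  hy <- 0
  for (i in seq_len(nrow(counts))) {
    p <- sum(counts[i, ]) / z
    if (p > 0) hy <- hy - p * lg(p)
  }
  hxy <- 0
  for (i in seq_len(nrow(counts))) {
    for (j in seq_len(ncol(counts))) {
      p <- counts[i, j] / z
      if (p > 0) hxy <- hxy - p * lg(p)
    }
  }
  s <- nrow(counts)
  c(constancy = 1 - hy / lg(s),
    contingency = (hx + hy - hxy) / lg(s))
}

# Intercept-only interval-censored data around a known normal.
simple_intervals <- function(n, mu = 145, sigma = 10, half_width = 2,
                             seed = 1) {
  set.seed(seed)
  y <- rnorm(n, mu, sigma)
  tibble::tibble(
    lower_doy = round(y) - half_width,
    upper_doy = round(y) + half_width
  )
}
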