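test_that("Savitzky-Golay smoothing preserves low-order polynomials and damps noise", {
  dates <- seq(as.Date("2001-01-01"), as.Date("2020-12-31"), by = 8)
  base <- tibble::tibble(site_id = "A", date = dates, variable = "ndvi")

  # constants pass through
  const <- dplyr::mutate(base, value = 0.5)
  expect_equal(smooth_ndvi(const)$value, const$value, tolerance = 1e-12)

  # a quadratic in time is reproduced by an order-2 filter
  tt <- as.numeric(dates - dates[1])
  quad <- dplyr::mutate(base, value = 0.3 + 1e-3 * tt - 5e-7 * tt^2)
  expect_lt(max(abs(smooth_ndvi(quad)$value - quad$value)), 1e-9)

  # smoothing brings a noisy sinusoid closer to the noiseless signal
  doy <- lubridate::yday(dates)
  signal_true <- 0.5 + 0.3 * sin(2 * pi * doy / 365)
  set.seed(7)
  noisy <- dplyr::mutate(base, value = signal_true + rnorm(length(doy), 0, 0.05))
  sm <- smooth_ndvi(noisy)
  rmsd <- function(v) sqrt(mean((v - signal_true)^2))
  expect_lt(rmsd(sm$value), rmsd(noisy$value))

  # too short to fit one window
  expect_error(smooth_ndvi(const[1:3, ]), "too short")
})

test_that("aggregation produces weekly/monthly cells with the right statistics", {
  series <- constant_env_series()
  agg <- aggregate_series(series)

  tw <- agg[agg$variable == "temperature", ]
  expect_equal(unique(tw$time_class), 1:52)
  expect_true(all(tw$value == 10))

  # constant 1 mm/day gives a 7-day-equivalent weekly total of 7 everywhere
  pw <- agg[agg$variable == "precipitation", ]
  expect_true(all(abs(pw$value - 7) < 1e-12))

  # NDVI linear in day of year: January mean < December mean, and each
  # monthly cell equals the mean of its in-month composite values
  dates <- seq(as.Date("2001-01-01"), as.Date("2002-12-31"), by = 8)
  lin <- tibble::tibble(site_id = "A", date = dates, variable = "ndvi",
                        value = lubridate::yday(dates) / 1000)
  ma <- aggregate_series(lin)
  jan <- ma$value[ma$year == 2001 & ma$time_class == 1]
  dec <- ma$value[ma$year == 2001 & ma$time_class == 12]
  expect_lt(jan, dec)
  manual <- mean(lin$value[lubridate::year(lin$date) == 2001 &
                             lubridate::month(lin$date) == 3])
  expect_equal(ma$value[ma$year == 2001 & ma$time_class == 3], manual)

  expect_error(
    aggregate_series(dplyr::mutate(lin, variable = "humidity")),
    "unknown environmental variable"
  )
  expect_error(aggregate_series(lin[lubridate::year(lin$date) == 2001, ]),
               "two years")
})

test_that("discretization bins values as specified", {
  # constant matrix: all mass in one state row, Z = n_years * t
  cm <- matrix_tbl(matrix(3.7, nrow = 20, ncol = 12))
  ft <- discretize(cm, n_states = 4)
  expect_equal(sum(ft$counts), 20 * 12)
  expect_equal(sum(rowSums(ft$counts) > 0), 1)

  # values at the range extremes land in the outer states
  vt <- matrix_tbl(matrix(c(1, 9, 1, 9), nrow = 2, byrow = TRUE))
  ft2 <- discretize(vt, n_states = 2)
  expect_equal(unname(ft2$counts), matrix(c(2, 0, 0, 2), 2, 2, byrow = TRUE))

  # equal-frequency bins on uniform values give near-uniform row totals
  set.seed(11)
  un <- matrix_tbl(matrix(runif(20 * 52), nrow = 20), variable = "temperature")
  ft3 <- discretize(un, n_states = 5, strategy = "equal_frequency")
  expect_true(all(abs(rowSums(ft3$counts) - 1040 / 5) <= 0.2 * 1040 / 5))

  # constant matrix under equal_frequency falls back, no error
  ft4 <- discretize(cm, n_states = 4, strategy = "equal_frequency")
  expect_equal(ft4$strategy, "equal_width")
  expect_equal(sum(rowSums(ft4$counts) > 0), 1)

  expect_error(discretize(cm, n_states = 1), "at least 2")
})

test_that("constancy/contingency match hand-derived tables", {
  # constant series: HY = 0, HXY = HX
  const <- colwell(discretize(matrix_tbl(matrix(5, 20, 12)), n_states = 4))
  expect_equal(const$constancy, 1)
  expect_equal(const$contingency, 0)
  expect_equal(const$predictability, 1)

  # perfectly periodic 2x2: HX = HY = HXY = log 2
  two <- colwell(matrix(c(2, 0, 0, 2), 2, 2))
  expect_equal(two$constancy, 0, tolerance = 1e-12)
  expect_equal(two$contingency, 1, tolerance = 1e-12)

  # maximally uninformative 2x2: HXY = log 4
  flat <- colwell(matrix(1, 2, 2))
  expect_equal(flat$constancy, 0, tolerance = 1e-12)
  expect_equal(flat$contingency, 0, tolerance = 1e-12)

  # annual-periodic, 4 states x 3 months each, 20 years:
  # HX = log 12, HY = log 4, HXY = log 12
  per <- colwell(periodic_counts())
  expect_equal(per$HX, log(12), tolerance = 1e-12)
  expect_equal(per$HY, log(4), tolerance = 1e-12)
  expect_equal(per$HXY, log(12), tolerance = 1e-12)
  expect_equal(per$constancy, 0, tolerance = 1e-12)
  expect_equal(per$contingency, 1, tolerance = 1e-12)

  expect_error(colwell(matrix(0, 3, 4)), "empty frequency table")
})

test_that("metrics match a brute-force entropy oracle and stay in bounds", {
  set.seed(42)
  for (i in 1:200) {
    counts <- matrix(sample(0:5, 12, replace = TRUE), 3, 4)
    if (sum(counts) == 0) next
    got <- colwell(counts)
    oracle <- colwell_oracle(counts)
    expect_equal(got$constancy, unname(oracle["constancy"]), tolerance = 1e-12)
    expect_equal(got$contingency, unname(oracle["contingency"]), tolerance = 1e-12)
    expect_true(got$constancy >= -1e-12 && got$constancy <= 1 + 1e-12)
    expect_true(got$contingency >= -1e-12 && got$contingency <= 1 + 1e-12)
    expect_true(got$predictability >= -1e-12 && got$predictability <= 1 + 1e-12)
    expect_equal(got$predictability, got$constancy + got$contingency,
                 tolerance = 1e-12)
    # normalized metrics are invariant to the logarithm base
    oracle2 <- colwell_oracle(counts, log_base = 2)
    expect_equal(unname(oracle["constancy"]), unname(oracle2["constancy"]),
                 tolerance = 1e-12)
    expect_equal(unname(oracle["contingency"]), unname(oracle2["contingency"]),
                 tolerance = 1e-12)
  }
})

test_that("metrics are invariant to permuting year rows", {
  set.seed(5)
  vals <- matrix(rnorm(20 * 12), nrow = 20)
  m1 <- colwell(discretize(matrix_tbl(vals)))
  m2 <- colwell(discretize(matrix_tbl(vals[sample(20), ])))
  expect_equal(m1, m2)
})

test_that("iid noise yields near-zero constancy and contingency at large n", {
  set.seed(99)
  vals <- matrix(runif(500 * 12), nrow = 500)
  m <- colwell(discretize(matrix_tbl(vals), n_states = 4))
  expect_lt(m$constancy, 0.05)
  expect_lt(m$contingency, 0.05)
})

test_that("site_predictability chains the stages and validates inputs", {
  series <- constant_env_series()
  sp <- site_predictability(series)
  expect_equal(nrow(sp), 1)
  expect_true(all(sp[paste0("constancy_", c("ndvi", "precipitation", "temperature"))] == 1))
  expect_true(all(sp[paste0("contingency_", c("ndvi", "precipitation", "temperature"))] == 0))

  # missing variable is named in the error
  expect_error(site_predictability(series[series$variable != "ndvi", ]),
               "missing variable.*ndvi")

  # pipeline output equals manual stage chaining on non-trivial data
  env <- gen_environment(env_scenario(sites = "B", years = 2001:2006), seed = 3)
  sp2 <- site_predictability(env, n_states = 7)
  sm <- smooth_ndvi(env[env$variable == "ndvi", ])
  agg <- aggregate_series(dplyr::bind_rows(env[env$variable != "ndvi", ], sm))
  manual <- colwell(discretize(agg[agg$variable == "temperature", ], n_states = 7))
  expect_equal(sp2$constancy_temperature, manual$constancy)
  expect_equal(sp2$contingency_temperature, manual$contingency)

  # year order in the input is immaterial
  shuffled <- env[order(lubridate::month(env$date), lubridate::year(env$date)), ]
  sp3 <- site_predictability(shuffled, n_states = 7)
  expect_equal(as.data.frame(sp2), as.data.frame(sp3))
})
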