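test_that("interval likelihood matches numerical integration of the normal density", {
  # worked case against the CDF oracle
  expect_equal(loglik_interval_normal(138, 142, 140, 10),
               log(pnorm(0.2) - pnorm(-0.2)), tolerance = 1e-12)

  # unbounded interval carries no information
  expect_equal(loglik_interval_normal(-Inf, Inf, 150, 8), 0)

  # exact observation uses the density
  expect_equal(loglik_interval_normal(140, 140, 145, 10),
               dnorm(140, 145, 10, log = TRUE))

  # 100 random cases against numeric integration, including far tails
  set.seed(8)
  for (i in 1:100) {
    mu <- runif(1, 100, 200)
    sigma <- runif(1, 2, 25)
    l <- runif(1, 80, 220)
    u <- l + runif(1, 0.5, 15)
    oracle <- log(integrate(dnorm, l, u, mean = mu, sd = sigma,
                            rel.tol = 1e-12)$value)
    expect_equal(loglik_interval_normal(l, u, mu, sigma), oracle,
                 tolerance = 1e-8)
  }

  # symmetric interval: contribution is maximized at the midpoint
  mus <- seq(130, 150, by = 0.25)
  ll <- loglik_interval_normal(138, 142, mus, 10)
  expect_equal(mus[which.max(ll)], 140)

  expect_error(loglik_interval_normal(142, 138, 140, 10), "lower")
  expect_error(loglik_interval_normal(138, 142, NaN, 10), "non-finite")
  expect_warning(loglik_interval_normal(138, 142, 140, 1e-9), "underflow")
})

test_that("likelihood stays finite and accurate deep in the tails", {
  # 12 sigma out: still matches log-space oracle
  got <- loglik_interval_normal(200, 204, 140, 5)
  z <- c((200 - 140) / 5, (204 - 140) / 5)
  oracle <- pnorm(z[1], lower.tail = FALSE, log.p = TRUE) +
    log1p(-exp(pnorm(z[2], lower.tail = FALSE, log.p = TRUE) -
                 pnorm(z[1], lower.tail = FALSE, log.p = TRUE)))
  expect_equal(got, oracle, tolerance = 1e-10)
  expect_true(is.finite(loglik_interval_normal(400, 404, 140, 5)))
})

test_that("intercept-only fit recovers mean and scale, matching survreg", {
  skip_if_not_installed("survival")
  d <- simple_intervals(5000, mu = 145, sigma = 10, seed = 42)
  d$x <- rnorm(5000)
  fit <- icls_fit(d, icls_spec("custom", location = "x", random = "none"),
                  se = FALSE)
  expect_true(fit$converged)
  expect_lt(abs(fit$beta[["(Intercept)"]] - 145), 0.3)
  expect_lt(abs(exp(fit$gamma[["(Intercept)"]]) - 10), 0.4)

  sv <- survival::survreg(
    survival::Surv(d$lower_doy, d$upper_doy, type = "interval2") ~ d$x,
    dist = "gaussian"
  )
  expect_equal(fit$beta[["(Intercept)"]], unname(coef(sv)[1]), tolerance = 1e-3)
  expect_lt(abs(fit$beta[["x"]] - unname(coef(sv)[2])), 2e-3)
  expect_equal(exp(fit$gamma[["(Intercept)"]]), sv$scale, tolerance = 1e-3)
})

test_that("random-intercept SD is recovered, including tau = 0", {
  base <- pop_scenario("small", model = "latitude_elevation",
                       n_regions = 8, total_n = 1200, years = 2012:2017)

  zero <- pop_scenario("small", model = "latitude_elevation",
                       n_regions = 8, total_n = 1200, years = 2012:2017,
                       tau = 0)
  pop0 <- gen_population(zero, seed = 4)
  tbl0 <- attach_covariates(censor_interval(pop0$records))
  fit0 <- icls_fit(tbl0, icls_spec("latitude_elevation"), se = FALSE)
  expect_lt(fit0$tau, 0.5)

  pop <- gen_population(base, seed = 4)
  tbl <- attach_covariates(censor_interval(pop$records))
  fit <- icls_fit(tbl, icls_spec("latitude_elevation"), se = FALSE)
  expect_gt(fit$tau, 1)
  expect_lt(abs(fit$tau - base$tau), 2)
  # posterior modes of the group effects centre near zero
  expect_lt(abs(mean(fit$group_modes)), 0.75)

  # Laplace and adaptive Gauss-Hermite agree closely
  fit_agq <- icls_fit(tbl, icls_spec("latitude_elevation"), method = "agq",
                      se = FALSE)
  expect_equal(fit$loglik, fit_agq$loglik, tolerance = 1e-4)
  expect_equal(fit$tau, fit_agq$tau, tolerance = 0.01)
})

test_that("an irrelevant covariate cannot reduce the log-likelihood and usually costs AIC", {
  aic_up <- logical(20)
  for (r in 1:20) {
    d <- simple_intervals(400, seed = 300 + r)
    set.seed(600 + r)
    d$x <- rnorm(400)
    d$junk <- rnorm(400)
    small <- icls_fit(d, icls_spec("custom", location = "x", scale = "x",
                                   random = "none"), se = FALSE)
    big <- icls_fit(d, icls_spec("custom", location = c("x", "junk"),
                                 scale = "x", random = "none"), se = FALSE)
    expect_gte(big$loglik, small$loglik - 1e-4)
    aic_up[r] <- big$AIC > small$AIC
  }
  expect_gte(mean(aic_up), 0.75)
})

test_that("the fit is shift-equivariant and scale-consistent", {
  d <- simple_intervals(1500, mu = 140, sigma = 8, seed = 77)
  spec <- icls_spec("custom", location = character(0), random = "none")
  f1 <- icls_fit(d, spec, se = FALSE)

  shifted <- dplyr::mutate(d, lower_doy = lower_doy + 30,
                           upper_doy = upper_doy + 30)
  f2 <- icls_fit(shifted, spec, se = FALSE)
  expect_equal(f2$beta[["(Intercept)"]], f1$beta[["(Intercept)"]] + 30,
               tolerance = 1e-3)
  expect_equal(f2$gamma[["(Intercept)"]], f1$gamma[["(Intercept)"]],
               tolerance = 1e-4)

  doubled <- dplyr::mutate(d, lower_doy = lower_doy * 2,
                           upper_doy = upper_doy * 2)
  f3 <- icls_fit(doubled, spec, se = FALSE)
  expect_equal(exp(f3$gamma[["(Intercept)"]]),
               2 * exp(f1$gamma[["(Intercept)"]]), tolerance = 0.02)
  expect_equal(f3$beta[["(Intercept)"]], 2 * f1$beta[["(Intercept)"]],
               tolerance = 1e-3)
})

test_that("widening the censoring intervals is not ignored by the fit", {
  set.seed(55)
  y <- rnorm(2500, 145, 10)
  narrow <- tibble::tibble(lower_doy = round(y) - 2, upper_doy = round(y) + 2)
  wide <- tibble::tibble(lower_doy = round(y) - 5, upper_doy = round(y) + 5)
  spec <- icls_spec("custom", location = character(0), random = "none")
  fn <- icls_fit(narrow, spec, se = FALSE)
  fw <- icls_fit(wide, spec, se = FALSE)
  # both recover the true scale through the censoring
  expect_lt(abs(exp(fn$gamma[[1]]) - 10), 0.75)
  expect_lt(abs(exp(fw$gamma[[1]]) - 10), 0.75)
  # but the likelihoods differ: interval width enters the model
  expect_gt(abs(fn$loglik - fw$loglik), 100)
})

test_that("predictions apply links, stored standardization and the synchrony constant", {
  sc <- pop_scenario("small", model = "latitude_elevation",
                     n_regions = 6, total_n = 800, years = 2013:2016)
  pop <- gen_population(sc, seed = 9)
  tbl <- attach_covariates(censor_interval(pop$records))
  fit <- icls_fit(tbl, icls_spec("latitude_elevation"), se = FALSE)

  # covariates at their training means: mu = beta0, sigma = exp(gamma0)
  std <- covariate_scale(tbl)
  at_mean <- tibble::tibble(
    latitude = std$mean[std$covariate == "latitude"],
    elevation = std$mean[std$covariate == "elevation"]
  )
  pr <- predict(fit, at_mean)
  expect_equal(pr$mu, fit$beta[["(Intercept)"]], tolerance = 1e-9)
  expect_equal(pr$sigma, exp(fit$gamma[["(Intercept)"]]), tolerance = 1e-9)
  expect_equal(pr$synchrony80 / pr$sigma, qnorm(0.9) - qnorm(0.1),
               tolerance = 1e-9)

  # increasing a covariate with positive coefficient increases mu
  b_lat <- fit$beta[["latitude"]]
  two <- tibble::tibble(latitude = c(45, 55), elevation = 500)
  mu2 <- predict(fit, two)$mu
  expect_equal(sign(diff(mu2)), sign(b_lat))

  expect_error(predict(fit, tibble::tibble(latitude = 45)), "elevation")
})

test_that("model comparison reports deltas and respects nesting", {
  d <- simple_intervals(800, seed = 101)
  set.seed(102)
  d$x <- rnorm(800)
  d$w <- rnorm(800)
  f_small <- icls_fit(d, icls_spec("custom", location = "x", scale = "x",
                                   random = "none"), se = FALSE)
  f_big <- icls_fit(d, icls_spec("custom", location = c("x", "w"),
                                 scale = c("x", "w"), random = "none"),
                    se = FALSE)
  cmp <- icls_compare(small = f_small, big = f_big, reference = "small")
  expect_equal(cmp$delta_loglik[cmp$name == "small"], 0)
  expect_equal(cmp$delta_AIC[cmp$name == "small"], 0)
  expect_gte(cmp$loglik[cmp$name == "big"],
             cmp$loglik[cmp$name == "small"] - 1e-6)

  # comparing a fit with itself: zero deltas
  self <- icls_compare(a = f_small, b = f_small, reference = "a")
  expect_equal(self$delta_loglik, c(0, 0))

  f_other <- icls_fit(d[1:700, ], icls_spec("custom", location = "x",
                                            random = "none"), se = FALSE)
  expect_error(icls_compare(f_small, f_other), "different observation sets")
})

test_that("tidy and glance expose coefficients and fit summaries", {
  d <- simple_intervals(600, seed = 3)
  set.seed(301)
  d$x <- rnorm(600)
  fit <- icls_fit(d, icls_spec("custom", location = "x", random = "none"))
  td <- tidy(fit)
  expect_setequal(unique(td$parameter), c("location", "scale"))
  expect_true(all(is.finite(td$std.error)))
  gl <- glance(fit)
  expect_equal(gl$AIC, -2 * gl$logLik + 2 * gl$n_params)
  expect_equal(gl$nobs, 600)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
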