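# Birth-record preparation: interval censoring from estimated fawn age,
# quantile-regression screening for sampling-onset bias, and assembly of the
# standardized model table.

#' Build interval-censored birth-date observations
#'
#' Back-calculated parturition dates carry age-dependent uncertainty, so
#' each estimated birth day-of-year is replaced by a symmetric interval
#' whose half-width grows with the fawn's estimated age at marking:
#' +/-2 days up to 7 days of age, +/-3 days at 8-14 days, +/-5 days at 15
#' days or older. The printed rule leaves ages 7 and 15 unassigned; the
#' boundaries close those gaps conservatively (7 -> +/-2, 15 -> +/-5) and
#' are configurable.
#'
#' @param records A data frame with `estimated_birth_doy` (or `marking_doy`
#'   plus `estimated_age_days`, from which it is derived) and
#'   `estimated_age_days`.
#' @param age_breaks Upper age bounds of the first two classes
#'   (default `c(7, 14)`).
#' @param half_widths Interval half-widths in days per age class
#'   (default `c(2, 3, 5)`).
#' @return The input as a tibble with added columns `age_class`
#'   (`young`/`mid`/`old`), `lower_doy` and `upper_doy`. Intervals are kept
#'   on a continuous day-of-year axis (no wrap at the year end).
#' @export
censor_interval <- function(records, age_breaks = c(7, 14),
                            half_widths = c(2, 3, 5)) {
  stopifnot(length(age_breaks) + 1 == length(half_widths))
  records <- tibble::as_tibble(records)
  if (!"estimated_age_days" %in% names(records)) {
    abort("records need an 'estimated_age_days' column")
  }
  age <- records$estimated_age_days
  if (any(is.na(age)) || any(age < 0)) {
    abort("estimated_age_days must be non-negative and non-missing")
  }
  if (!"estimated_birth_doy" %in% names(records)) {
    if (!"marking_doy" %in% names(records)) {
      abort("records need 'estimated_birth_doy' or 'marking_doy'")
    }
    records$estimated_birth_doy <- records$marking_doy - age
  }
  cls <- cut(age, breaks = c(-Inf, age_breaks, Inf),
             labels = c("young", "mid", "old"), right = TRUE)
  delta <- half_widths[as.integer(cls)]
  records |>
    dplyr::mutate(
      age_class = cls,
      lower_doy = .data$estimated_birth_doy - delta,
      upper_doy = .data$estimated_birth_doy + delta
    )
}

# Linear quantile regression of y on x by pinball-loss minimization.
# The intercept is profiled out (for fixed slope the optimal intercept is a
# tau-quantile of the residuals), leaving a convex one-dimensional problem
# solved by golden-section search.
quantile_slope <- function(x, y, tau) {
  xc <- x - mean(x)
  pinball <- function(r) sum(r * (tau - (r < 0)))
  profile_obj <- function(b) {
    r <- y - b * xc
    pinball(r - quantile(r, tau, type = 1, names = FALSE))
  }
  sx <- sd(xc)
  if (sx == 0) {
    return(list(slope = 0, intercept = quantile(y, tau, type = 1, names = FALSE)))
  }
  ols <- sum(xc * (y - mean(y))) / sum(xc^2)
  width <- 10 * (sd(y) / sx + abs(ols)) + 1
  opt <- optimize(profile_obj, interval = c(ols - width, ols + width),
                  tol = 1e-7 * max(1, width))
  b <- opt$minimum
  a <- quantile(y - b * xc, tau, type = 1, names = FALSE)
  list(slope = b, intercept = a - b * mean(x))
}

#' Screen regions for temporal trends in marking dates
#'
#' Opportunistic fawn searches may start progressively earlier over the
#' years (e.g. in response to earlier mowing), which would masquerade as a
#' phenological shift. For each region this fits linear quantile
#' regressions of the day of marking on year at the requested quantiles and
#' flags the region for exclusion if any quantile shows a significantly
#' negative slope. Slope p-values come from a seeded case-resampling
#' bootstrap (normal approximation on the bootstrap standard error,
#' two-sided); only negative slopes trigger exclusion.
#'
#' @param records A data frame with `region_id`, `year` and `marking_doy`.
#' @param taus Quantile levels to screen (default 0.1, 0.5, 0.9).
#' @param alpha Significance level for exclusion (default 0.05).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed controlling the bootstrap resampling.
#' @param min_records Minimum records per region; smaller regions are
#'   skipped with a warning (default 20).
#' @return A tibble with one row per region and quantile: `region_id`,
#'   `tau`, `slope` (days/year), `se`, `p_value`, `n`, `n_years`,
#'   `excluded` (region-level flag) and `alpha`. Skipped regions carry `NA`
#'   estimates and `excluded = NA`.
#' @export
quantile_trend_screen <- function(records, taus = c(0.1, 0.5, 0.9),
                                  alpha = 0.05, n_boot = 1000, seed = 1,
                                  min_records = 20) {
  records <- tibble::as_tibble(records)
  needed <- c("region_id", "year", "marking_doy")
  if (!all(needed %in% names(records))) {
    abort("records need columns region_id, year and marking_doy")
  }
  regions <- sort(unique(records$region_id))
  purrr::imap_dfr(setNames(regions, regions), function(region, key) {
    df <- records[records$region_id == region, ]
    n <- nrow(df)
    n_years <- dplyr::n_distinct(df$year)
    base <- tidyr::expand_grid(region_id = region, tau = taus) |>
      dplyr::mutate(n = n, n_years = n_years, alpha = alpha)
    if (n_years < 2 || n < min_records) {
      warn(paste0("region '", region, "' skipped: needs >= 2 distinct years and >= ",
                  min_records, " records"))
      return(dplyr::mutate(base,
        slope = NA_real_, se = NA_real_, p_value = NA_real_, excluded = NA
      ))
    }
    set.seed(seed + match(region, regions))
    boot_idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    res <- purrr::map_dfr(taus, function(tau) {
      slope <- quantile_slope(df$year, df$marking_doy, tau)$slope
      boot <- vapply(seq_len(n_boot), function(b) {
        i <- boot_idx[, b]
        if (dplyr::n_distinct(df$year[i]) < 2) {
          return(NA_real_)
        }
        quantile_slope(df$year[i], df$marking_doy[i], tau)$slope
      }, numeric(1))
      se <- sd(boot, na.rm = TRUE)
      p <- if (is.na(se) || se == 0) {
        if (slope == 0) 1 else 0
      } else {
        2 * pnorm(-abs(slope / se))
      }
      tibble(tau = tau, slope = slope, se = se, p_value = p)
    })
    base |>
      dplyr::select(-"tau") |>
      dplyr::bind_cols(res) |>
      dplyr::mutate(excluded = any(res$slope < 0 & res$p_value < alpha)) |>
      dplyr::select("region_id", "tau", "slope", "se", "p_value",
                    "n", "n_years", "excluded", "alpha")
  })
}

#' Assemble the standardized model table
#'
#' Joins site/region covariates onto censored observations (if not already
#' present) and z-scores the numeric model covariates, storing the
#' standardization constants for exact back-transformation. Model fits and
#' predictions both rely on these stored constants.
#'
#' @param observations Censored observations from [censor_interval()].
#' @param covariates Optional covariate table joined by the shared key
#'   column(s) (e.g. `region_id` or `site_id`).
#' @param covariate_names Columns to standardize; defaults to whichever of
#'   elevation, latitude and the six Colwell covariates are present.
#' @return A tibble with standardized covariate columns and a
#'   `"standardization"` attribute (tibble of covariate, mean, sd).
#' @seealso [covariate_scale()], [unstandardize()]
#' @export
attach_covariates <- function(observations, covariates = NULL,
                              covariate_names = NULL) {
  observations <- tibble::as_tibble(observations)
  if (!is.null(covariates)) {
    keys <- intersect(names(observations), names(covariates))
    if (length(keys) == 0) {
      abort("no shared key column between observations and covariates")
    }
    observations <- dplyr::left_join(observations, covariates, by = keys)
  }
  default_covs <- c(
    "elevation", "latitude",
    "constancy_ndvi", "contingency_ndvi",
    "constancy_precipitation", "contingency_precipitation",
    "constancy_temperature", "contingency_temperature"
  )
  covariate_names <- covariate_names %||% intersect(default_covs, names(observations))
  missing_cols <- setdiff(covariate_names, names(observations))
  if (length(missing_cols) > 0) {
    abort(paste0("missing covariate column(s): ", paste(missing_cols, collapse = ", ")))
  }
  for (cv in covariate_names) {
    bad <- which(!is.finite(observations[[cv]]))
    if (length(bad) > 0) {
      id <- if ("record_id" %in% names(observations)) {
        observations$record_id[bad[1]]
      } else {
        bad[1]
      }
      abort(paste0("missing covariate '", cv, "' for record ", id))
    }
  }
  const <- tibble(
    covariate = covariate_names,
    mean = vapply(covariate_names, function(cv) mean(observations[[cv]]), 0),
    sd = vapply(covariate_names, function(cv) sd(observations[[cv]]), 0)
  )
  if (any(const$sd == 0)) {
    abort(paste0(
      "covariate(s) constant, cannot standardize: ",
      paste(const$covariate[const$sd == 0], collapse = ", ")
    ))
  }
  for (i in seq_len(nrow(const))) {
    cv <- const$covariate[i]
    observations[[cv]] <- (observations[[cv]] - const$mean[i]) / const$sd[i]
  }
  attr(observations, "standardization") <- const
  observations
}

#' Standardization constants of a model table
#' @param tbl A table produced by [attach_covariates()].
#' @return A tibble with columns `covariate`, `mean`, `sd`.
#' @export
covariate_scale <- function(tbl) {
  attr(tbl, "standardization")
}

#' Undo covariate standardization
#' @param tbl A table produced by [attach_covariates()].
#' @return The table with covariates back on their raw scale.
#' @export
unstandardize <- function(tbl) {
  const <- covariate_scale(tbl)
  if (is.null(const)) {
    abort("table carries no standardization attribute")
  }
  for (i in seq_len(nrow(const))) {
    cv <- const$covariate[i]
    tbl[[cv]] <- tbl[[cv]] * const$sd[i] + const$mean[i]
  }
  attr(tbl, "standardization") <- NULL
  tbl
}
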