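# Colwell's predictability metrics from raw environmental time series:
# smoothing (NDVI), within-year aggregation, state discretization, and the
# entropy-based constancy / contingency / predictability decomposition.

env_variables <- c("temperature", "precipitation", "ndvi")

check_series <- function(series) {
  needed <- c("site_id", "date", "variable", "value")
  missing <- setdiff(needed, names(series))
  if (length(missing) > 0) {
    abort(paste0(
      "series is missing column(s): ", paste(missing, collapse = ", ")
    ))
  }
  bad <- setdiff(unique(series$variable), env_variables)
  if (length(bad) > 0) {
    abort(paste0(
      "unknown environmental variable(s): ", paste(bad, collapse = ", "),
      " (expected one of ", paste(env_variables, collapse = ", "), ")"
    ))
  }
  if (anyDuplicated(series[c("site_id", "variable", "date")]) > 0) {
    abort("duplicate (site_id, variable, date) rows in series")
  }
  dplyr::arrange(tibble::as_tibble(series), .data$site_id, .data$variable, .data$date)
}

#' Smooth an NDVI time series with a Savitzky-Golay filter
#'
#' Applies a Savitzky-Golay polynomial filter to NDVI composites, per site.
#' The physical window length is given in days and converted to the nearest
#' odd number of sample points at the series' cadence (never fewer than
#' `polyorder + 2` points). With the defaults (45-day window, order 2) an
#' 8-day composite series is smoothed with a 5-point quadratic filter.
#'
#' @param series A data frame of NDVI observations with columns `site_id`,
#'   `date` (Date), `variable` (must be `"ndvi"`), `value`.
#' @param window_days Filter window length in days (default 45).
#' @param polyorder Polynomial order of the filter (default 2). The filter
#'   reproduces polynomials up to this degree exactly, so constants and
#'   (with the default) quadratic trends pass through unchanged.
#' @return A tibble with the same rows and columns, `value` replaced by the
#'   smoothed series.
#' @export
smooth_ndvi <- function(series, window_days = 45, polyorder = 2) {
  series <- check_series(series)
  if (!all(series$variable == "ndvi")) {
    abort("smooth_ndvi expects a series with variable 'ndvi' only")
  }
  if (window_days <= polyorder) {
    abort("window_days must exceed polyorder")
  }
  floor_odd <- polyorder + 2 + (polyorder %% 2) # smallest odd >= polyorder + 2
  series |>
    dplyr::group_by(.data$site_id) |>
    dplyr::group_modify(function(df, key) {
      cadence <- median(as.numeric(diff(df$date)))
      n_pts <- nearest_odd(window_days / cadence, floor_odd = floor_odd)
      if (nrow(df) < n_pts) {
        abort("series too short to smooth")
      }
      df$value <- as.numeric(signal::sgolayfilt(df$value, p = polyorder, n = n_pts))
      df
    }) |>
    dplyr::ungroup()
}

#' Aggregate a daily/composite series into year-by-time-class cells
#'
#' Collapses raw observations into the year-by-within-year matrix Colwell's
#' metrics are computed from: monthly means for NDVI (12 classes), weekly
#' means for temperature and weekly totals for precipitation (52 classes).
#' Weeks are fixed 7-day blocks counted from 1 January; day 365/366 folds
#' into week 52. Cells with no data are kept as `NA`.
#'
#' @param series A data frame with columns `site_id`, `date`, `variable`
#'   (one of `"temperature"`, `"precipitation"`, `"ndvi"`), `value`.
#' @return A tibble with columns `site_id`, `variable`, `year`,
#'   `time_class`, `n_classes` and the aggregated `value`, completed so
#'   every (year, time class) combination is present.
#' @export
aggregate_series <- function(series) {
  series <- check_series(series)
  series |>
    dplyr::group_by(.data$site_id, .data$variable) |>
    dplyr::group_modify(function(df, key) {
      year <- lubridate::year(df$date)
      if (dplyr::n_distinct(year) < 2) {
        abort("aggregate_series needs at least two years of data per site/variable")
      }
      if (key$variable == "ndvi") {
        t_classes <- 12L
        cls <- lubridate::month(df$date)
        agg <- function(v) mean(v, na.rm = TRUE)
      } else {
        t_classes <- 52L
        cls <- pmin(ceiling(lubridate::yday(df$date) / 7), 52L)
        # Weekly totals are expressed as 7-day equivalents (7 x mean daily
        # value) so the folded final week (8-9 calendar days) and weeks with
        # missing days stay comparable to full weeks.
        agg <- if (key$variable == "precipitation") {
          function(v) 7 * mean(v, na.rm = TRUE)
        } else {
          function(v) mean(v, na.rm = TRUE)
        }
      }
      yrs <- sort(unique(year))
      classes <- seq_len(t_classes)
      tibble(year = year, time_class = as.integer(cls), value = df$value) |>
        dplyr::filter(!is.na(.data$value)) |>
        dplyr::group_by(.data$year, .data$time_class) |>
        dplyr::summarise(value = agg(.data$value), .groups = "drop") |>
        tidyr::complete(year = yrs, time_class = classes) |>
        dplyr::mutate(n_classes = t_classes)
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$site_id, .data$variable, .data$year, .data$time_class)
}

#' Discretize a year-by-time-class matrix into a state frequency table
#'
#' Bins the aggregated values of one site/variable into `n_states` states
#' and cross-tabulates state against within-year time class. Bin edges span
#' the observed range; all bins are half-open `[lo, hi)` except the top bin,
#' which is closed so the maximum is counted exactly once. Missing cells
#' contribute nothing (the grand total shrinks and the completeness
#' fraction is reported).
#'
#' @param matrix_tbl Output of [aggregate_series()] restricted to a single
#'   site and variable.
#' @param n_states Number of states (default 11, must be >= 2).
#' @param strategy `"equal_width"` (default) or `"equal_frequency"`
#'   (quantile bins). A constant series cannot support quantile bins and
#'   falls back to a single occupied state on an equal-width grid.
#' @return An object of class `colwell_table`: the s-by-t count matrix with
#'   bin edges and bookkeeping metadata.
#' @export
discretize <- function(matrix_tbl, n_states = 11,
                       strategy = c("equal_width", "equal_frequency")) {
  strategy <- match.arg(strategy)
  if (n_states < 2) {
    abort("n_states must be at least 2")
  }
  if (dplyr::n_distinct(matrix_tbl$site_id) > 1 ||
      dplyr::n_distinct(matrix_tbl$variable) > 1) {
    abort("discretize expects a single site and variable; split first")
  }
  vals <- matrix_tbl$value
  obs <- vals[!is.na(vals)]
  if (length(obs) == 0) {
    abort("empty frequency table")
  }
  rng <- range(obs)
  # collapse floating-point dust: a numerically constant series must land
  # in a single state, not spread over micro-width bins
  if (diff(rng) <= 1e-10 * max(1, abs(rng[2]))) {
    rng <- c(mean(rng), mean(rng))
  }
  used_strategy <- strategy
  if (strategy == "equal_frequency" && rng[1] == rng[2]) {
    used_strategy <- "equal_width" # constant series: quantile bins degenerate
  }
  edges <- NULL
  if (strategy == "equal_frequency" && rng[1] < rng[2]) {
    edges <- unname(quantile(obs, probs = seq(0, 1, length.out = n_states + 1),
                             type = 7))
    if (any(diff(edges) <= 0)) {
      edges <- NULL # degenerate quantiles: fall back to equal width
      used_strategy <- "equal_width"
    }
  }
  if (is.null(edges)) {
    if (rng[1] == rng[2]) {
      edges <- seq(rng[1] - 0.5, rng[1] + 0.5, length.out = n_states + 1)
    } else {
      edges <- seq(rng[1], rng[2], length.out = n_states + 1)
    }
  }
  state <- findInterval(obs, edges, rightmost.closed = TRUE)
  state <- pmin(pmax(state, 1L), n_states)
  t_classes <- unique(matrix_tbl$n_classes)
  t_classes <- t_classes[!is.na(t_classes)][1]
  if (is.na(t_classes)) t_classes <- max(matrix_tbl$time_class)
  cls <- matrix_tbl$time_class[!is.na(vals)]
  counts <- matrix(0L, nrow = n_states, ncol = t_classes)
  tab <- table(factor(state, levels = seq_len(n_states)),
               factor(cls, levels = seq_len(t_classes)))
  counts[] <- as.integer(tab)
  n_years <- dplyr::n_distinct(matrix_tbl$year)
  structure(
    list(
      counts = counts,
      bin_edges = edges,
      s = n_states,
      t = as.integer(t_classes),
      n_years = n_years,
      completeness = length(obs) / length(vals),
      site_id = matrix_tbl$site_id[1],
      variable = matrix_tbl$variable[1],
      strategy = used_strategy
    ),
    class = "colwell_table"
  )
}

#' @export
print.colwell_table <- function(x, ...) {
  cat("<colwell_table> ", x$site_id, "/", x$variable,
      ": s = ", x$s, ", t = ", x$t, ", years = ", x$n_years,
      ", completeness = ", round(x$completeness, 3), "\n", sep = "")
  invisible(x)
}

#' Colwell's constancy, contingency and predictability
#'
#' Computes the entropy decomposition of a state-by-time-class frequency
#' table: with column totals \eqn{X_j}, row totals \eqn{Y_i} and grand
#' total \eqn{Z}, the entropies are
#' \eqn{H(X) = -\sum_j (X_j/Z)\log(X_j/Z)},
#' \eqn{H(Y) = -\sum_i (Y_i/Z)\log(Y_i/Z)} and
#' \eqn{H(XY) = -\sum_{ij} (N_{ij}/Z)\log(N_{ij}/Z)}; then constancy
#' \eqn{C = 1 - H(Y)/\log s}, contingency
#' \eqn{M = (H(X) + H(Y) - H(XY))/\log s} and predictability
#' \eqn{P = C + M}. All metrics lie in \[0, 1\]; natural logarithms are
#' used internally but the normalized metrics are log-base invariant.
#' \eqn{0 \log 0} is treated as 0.
#'
#' @param table A `colwell_table` from [discretize()], or a plain
#'   non-negative count matrix (states in rows, time classes in columns).
#' @return A one-row tibble with `constancy`, `contingency`,
#'   `predictability`, the three entropies (nats), `s`, `t`, `n_years` and
#'   `completeness` (the latter two `NA` for a bare matrix).
#' @export
colwell <- function(table) {
  if (inherits(table, "colwell_table")) {
    counts <- table$counts
    meta <- table
  } else {
    counts <- as.matrix(table)
    meta <- NULL
  }
  if (any(counts < 0)) {
    abort("counts must be non-negative")
  }
  z <- sum(counts)
  if (z == 0) {
    abort("empty frequency table")
  }
  s <- nrow(counts)
  if (s < 2) {
    abort("need at least 2 states")
  }
  ent <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  }
  hx <- ent(colSums(counts) / z)
  hy <- ent(rowSums(counts) / z)
  hxy <- ent(counts / z)
  constancy <- 1 - hy / log(s)
  contingency <- (hx + hy - hxy) / log(s)
  tibble(
    constancy = constancy,
    contingency = contingency,
    predictability = constancy + contingency,
    HX = hx, HY = hy, HXY = hxy,
    s = s, t = ncol(counts),
    n_years = if (is.null(meta)) NA_integer_ else meta$n_years,
    completeness = if (is.null(meta)) NA_real_ else meta$completeness
  )
}

#' Per-site environmental predictability covariates
#'
#' Chains the full metric pipeline — NDVI smoothing, within-year
#' aggregation, state discretization and the entropy decomposition — for
#' every site in a long-format environmental series, returning the six
#' model covariates: constancy and contingency for NDVI, precipitation and
#' temperature.
#'
#' @param series Long-format series (columns `site_id`, `date`, `variable`,
#'   `value`) containing all three variables for every site.
#' @param n_states,strategy Passed to [discretize()].
#' @param sg_window_days,sg_polyorder Passed to [smooth_ndvi()].
#' @return A tibble with one row per site: `site_id`,
#'   `constancy_ndvi`, `contingency_ndvi`, `constancy_precipitation`,
#'   `contingency_precipitation`, `constancy_temperature`,
#'   `contingency_temperature`. Full per-variable metric rows (including
#'   predictability, entropies and completeness) are attached as the
#'   `"metrics"` attribute.
#' @export
site_predictability <- function(series, n_states = 11,
                                strategy = c("equal_width", "equal_frequency"),
                                sg_window_days = 45, sg_polyorder = 2) {
  strategy <- match.arg(strategy)
  series <- check_series(series)
  per_site <- split(series, series$site_id)
  metrics <- purrr::map_dfr(per_site, function(df) {
    have <- unique(df$variable)
    missing <- setdiff(env_variables, have)
    if (length(missing) > 0) {
      abort(paste0(
        "site '", df$site_id[1], "' is missing variable(s): ",
        paste(missing, collapse = ", ")
      ))
    }
    ndvi <- smooth_ndvi(df[df$variable == "ndvi", ],
                        window_days = sg_window_days, polyorder = sg_polyorder)
    prepared <- dplyr::bind_rows(df[df$variable != "ndvi", ], ndvi)
    agg <- aggregate_series(prepared)
    purrr::map_dfr(split(agg, agg$variable), function(m) {
      res <- colwell(discretize(m, n_states = n_states, strategy = strategy))
      dplyr::bind_cols(tibble(site_id = m$site_id[1], variable = m$variable[1]), res)
    })
  })
  wide <- metrics |>
    dplyr::select("site_id", "variable", "constancy", "contingency") |>
    tidyr::pivot_wider(
      names_from = "variable",
      values_from = c("constancy", "contingency"),
      names_sep = "_"
    ) |>
    dplyr::select(
      "site_id",
      "constancy_ndvi", "contingency_ndvi",
      "constancy_precipitation", "contingency_precipitation",
      "constancy_temperature", "contingency_temperature"
    )
  attr(wide, "metrics") <- metrics
  wide
}
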