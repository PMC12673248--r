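# Validation against independently reported parturition distributions: the
# packaged literature table mirrors the layout of published summaries (site,
# period, n, reported mean day-of-year and 80% synchrony, plus model
# predictions), and the report applies the analysis' inclusion rules and
# mean-absolute-error summary.

#' Read a literature validation table
#'
#' Without a path, reads the packaged table of reported parturition
#' distributions across Europe (printed values transcribed from the
#' published validation table) together with the two models' printed
#' predictions.
#'
#' @param path Optional path to a delimited text file with the same column
#'   roles: `site`, `period`, `n`, `reported_mean_doy`,
#'   `reported_synchrony80`, prediction columns and optional `notes`.
#' @return A tibble.
#' @export
read_literature <- function(path = NULL) {
  path <- path %||% system.file("extdata", "table1_literature.csv",
                                package = "phenosync", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}

#' Validate model predictions against reported parturition distributions
#'
#' Applies the inclusion rules (sites with `n <= min_n` are excluded;
#' sites missing a reported value contribute only to the metric they
#' report), computes per-site differences (predicted minus reported) and
#' summarizes each metric by its mean absolute error (MAE). Sites whose
#' `notes` column flags the reported mean as not directly sourced are kept
#' in the headline MAE, and a variant excluding them is attached as the
#' `"mae_excluding_flagged"` attribute of the report.
#'
#' Predictions can come from three places, in order of precedence: a
#' fitted model (`fit`, predicting from covariate columns in `literature`),
#' a `predictions` table (joined by `site`, columns `pred_mean` and
#' `pred_synchrony`), or columns already present in `literature` — either
#' `pred_mean`/`pred_synchrony` or the preset-suffixed columns selected by
#' `model`.
#'
#' @param literature A literature table, e.g. from [read_literature()].
#' @param predictions Optional tibble with `site`, `pred_mean`,
#'   `pred_synchrony`.
#' @param fit Optional [icls_fit()] used to predict from covariates.
#' @param model Preset suffix used to pick prediction columns already in
#'   `literature` (e.g. `"latitude_elevation"`).
#' @param min_n Exclusion threshold on reported sample size (default 30;
#'   sites with unknown `n` are retained).
#' @return An object of class `validation_report`: list with `sites` (per
#'   kept site: reported, predicted, diffs), `excluded` (site, reason),
#'   `mae` (metric, mae, n_sites) and `min_n`. [tidy()] returns the
#'   per-site table, [glance()] the MAEs.
#' @export
validate_predictions <- function(literature, predictions = NULL, fit = NULL,
                                 model = NULL, min_n = 30) {
  lit <- tibble::as_tibble(literature)
  if (!all(c("site", "reported_mean_doy") %in% names(lit))) {
    abort("literature table needs at least columns 'site' and 'reported_mean_doy'")
  }
  if (!"reported_synchrony80" %in% names(lit)) {
    lit$reported_synchrony80 <- NA_real_
  }
  if (!"n" %in% names(lit)) lit$n <- NA_integer_

  if (!is.null(fit)) {
    pred <- predict(fit, lit)
    lit$pred_mean <- pred$mu
    lit$pred_synchrony <- pred$synchrony80
  } else if (!is.null(predictions)) {
    lit <- dplyr::left_join(
      lit,
      dplyr::select(tibble::as_tibble(predictions),
                    "site", "pred_mean", "pred_synchrony"),
      by = "site"
    )
  } else if (!is.null(model)) {
    mc <- paste0("pred_mean_", model)
    sc <- paste0("pred_synchrony_", model)
    if (!all(c(mc, sc) %in% names(lit))) {
      abort(paste0("no prediction columns for model '", model, "' in literature"))
    }
    lit$pred_mean <- lit[[mc]]
    lit$pred_synchrony <- lit[[sc]]
  }
  if (!all(c("pred_mean", "pred_synchrony") %in% names(lit))) {
    abort("no predictions available: supply fit, predictions or model")
  }

  drop <- !is.na(lit$n) & lit$n <= min_n
  excluded <- tibble(
    site = lit$site[drop],
    reason = paste0("n <= ", min_n)
  )
  kept <- lit[!drop, ]
  if (nrow(kept) == 0) {
    abort("no sites remain after exclusions")
  }
  sites <- kept |>
    dplyr::transmute(
      site = .data$site,
      n = .data$n,
      reported_mean = .data$reported_mean_doy,
      predicted_mean = .data$pred_mean,
      diff_mean = .data$pred_mean - .data$reported_mean_doy,
      reported_synchrony = .data$reported_synchrony80,
      predicted_synchrony = .data$pred_synchrony,
      diff_synchrony = .data$pred_synchrony - .data$reported_synchrony80,
      flagged = if ("notes" %in% names(kept)) !is.na(kept$notes) else FALSE
    )
  mae_of <- function(d) mean(abs(d[!is.na(d)]))
  mae <- tibble(
    metric = c("mean", "synchrony"),
    mae = c(mae_of(sites$diff_mean), mae_of(sites$diff_synchrony)),
    n_sites = c(sum(!is.na(sites$diff_mean)), sum(!is.na(sites$diff_synchrony)))
  )
  out <- structure(
    list(sites = sites, excluded = excluded, mae = mae, min_n = min_n),
    class = "validation_report"
  )
  if (any(sites$flagged)) {
    unflagged <- sites[!sites$flagged, ]
    attr(out, "mae_excluding_flagged") <- tibble(
      metric = c("mean", "synchrony"),
      mae = c(mae_of(unflagged$diff_mean), mae_of(unflagged$diff_synchrony)),
      n_sites = c(sum(!is.na(unflagged$diff_mean)),
                  sum(!is.na(unflagged$diff_synchrony)))
    )
  }
  out
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> ", nrow(x$sites), " sites kept, ",
      nrow(x$excluded), " excluded (n <= ", x$min_n, ")\n", sep = "")
  cat("  MAE mean date: ", round(x$mae$mae[1], 3), " days (",
      x$mae$n_sites[1], " sites)\n", sep = "")
  cat("  MAE synchrony: ", round(x$mae$mae[2], 3), " days (",
      x$mae$n_sites[2], " sites)\n", sep = "")
  invisible(x)
}

#' @export
tidy.validation_report <- function(x, ...) {
  x$sites
}

#' @export
glance.validation_report <- function(x, ...) {
  tibble(
    mae_mean = x$mae$mae[x$mae$metric == "mean"],
    mae_synchrony = x$mae$mae[x$mae$metric == "synchrony"],
    n_sites_mean = x$mae$n_sites[x$mae$metric == "mean"],
    n_sites_synchrony = x$mae$n_sites[x$mae$metric == "synchrony"],
    n_excluded = nrow(x$excluded)
  )
}

#' Flat per-site difference table
#'
#' Mirrors the layout of the published validation table: one row per site
#' with reported and predicted values and their differences for both the
#' mean date and synchrony, in a stable column order suitable for writing
#' to delimited text.
#'
#' @param report A `validation_report`.
#' @return A tibble.
#' @export
diff_table <- function(report) {
  stopifnot(inherits(report, "validation_report"))
  report$sites |>
    dplyr::select(
      "site", "n",
      "reported_mean", "predicted_mean", "diff_mean",
      "reported_synchrony", "predicted_synchrony", "diff_synchrony"
    )
}
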