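# Equally spaced prediction grids, phenology surfaces and per-region
# elevation classes. Grid spacing is a physical distance, so points are laid
# out in an azimuthal equidistant projection centred on the extent and
# back-projected to longitude/latitude.

EARTH_RADIUS_KM <- 6371.0088

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Spherical azimuthal equidistant projection (km) centred at (lon0, lat0).
aeqd_project <- function(lon, lat, lon0, lat0, radius = EARTH_RADIUS_KM) {
  phi <- deg2rad(lat)
  lam <- deg2rad(lon)
  phi0 <- deg2rad(lat0)
  dlam <- lam - deg2rad(lon0)
  cosc <- pmin(pmax(sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(dlam), -1), 1)
  c_ang <- acos(cosc)
  k <- ifelse(c_ang < 1e-12, 1, c_ang / sin(c_ang))
  tibble(
    x = radius * k * cos(phi) * sin(dlam),
    y = radius * k * (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(dlam))
  )
}

aeqd_inverse <- function(x, y, lon0, lat0, radius = EARTH_RADIUS_KM) {
  phi0 <- deg2rad(lat0)
  rho <- sqrt(x^2 + y^2)
  c_ang <- rho / radius
  sinc <- sin(c_ang)
  cosc <- cos(c_ang)
  phi <- ifelse(
    rho < 1e-12, phi0,
    asin(pmin(pmax(cosc * sin(phi0) + y * sinc * cos(phi0) / rho, -1), 1))
  )
  lam <- deg2rad(lon0) + ifelse(
    rho < 1e-12, 0,
    atan2(x * sinc, rho * cos(phi0) * cosc - y * sin(phi0) * sinc)
  )
  tibble(lon = rad2deg(lam), lat = rad2deg(phi))
}

# Even-odd ray casting point-in-polygon test (boundary points count inside).
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

read_mask_polygon <- function(mask) {
  if (is.character(mask) && length(mask) == 1) {
    gj <- jsonlite::read_json(mask, simplifyVector = FALSE)
    geom <- if (!is.null(gj$geometry)) gj$geometry else
      if (!is.null(gj$features)) gj$features[[1]]$geometry else gj
    ring <- geom$coordinates[[1]]
    mask <- tibble(
      lon = vapply(ring, function(p) p[[1]], 0),
      lat = vapply(ring, function(p) p[[2]], 0)
    )
  }
  tibble::as_tibble(mask)
}

#' Lay out an equally spaced point grid over a lon/lat extent
#'
#' Points are spaced `spacing_km` apart in the planar azimuthal equidistant
#' projection centred on the extent (so the spacing is a physical distance,
#' not a degree step), then back-projected to longitude/latitude. An
#' optional polygon mask drops points outside a study area.
#'
#' @param extent Numeric vector `c(lon_min, lon_max, lat_min, lat_max)`.
#' @param spacing_km Grid spacing in kilometres (default 50).
#' @param mask Optional polygon: a data frame with `lon`/`lat` vertex
#'   columns, or the path to a GeoJSON file with a single polygon.
#' @return A tibble of grid points: `point_id`, `lon`, `lat` and the planar
#'   coordinates `x_km`, `y_km`.
#' @export
make_grid <- function(extent, spacing_km = 50, mask = NULL) {
  stopifnot(length(extent) == 4, spacing_km > 0)
  lon_min <- extent[1]; lon_max <- extent[2]
  lat_min <- extent[3]; lat_max <- extent[4]
  if (lon_min >= lon_max || lat_min >= lat_max) {
    abort("degenerate extent")
  }
  lon0 <- (lon_min + lon_max) / 2
  lat0 <- (lat_min + lat_max) / 2
  frame <- aeqd_project(
    lon = c(lon_min, lon_max, lon_min, lon_max, lon0, lon0, lon_min, lon_max),
    lat = c(lat_min, lat_min, lat_max, lat_max, lat_min, lat_max, lat0, lat0),
    lon0, lat0
  )
  if (diff(range(frame$x)) < spacing_km && diff(range(frame$y)) < spacing_km) {
    abort("spacing is larger than the extent")
  }
  pts <- tidyr::expand_grid(
    x_km = seq(min(frame$x), max(frame$x), by = spacing_km),
    y_km = seq(min(frame$y), max(frame$y), by = spacing_km)
  )
  ll <- aeqd_inverse(pts$x_km, pts$y_km, lon0, lat0)
  grid <- dplyr::bind_cols(ll, pts)
  if (!is.null(mask)) {
    poly <- read_mask_polygon(mask)
    keep <- point_in_polygon(grid$lon, grid$lat, poly$lon, poly$lat)
    grid <- grid[keep, ]
    if (nrow(grid) == 0) {
      abort("no grid points remain after masking")
    }
  }
  grid |>
    dplyr::mutate(point_id = dplyr::row_number(), .before = 1)
}

#' Predict a phenology surface over grid covariates
#'
#' Applies a fitted model at every grid point (conditional on mean random
#' effects) and attaches grid-wide summaries of the predicted mean date and
#' synchrony.
#'
#' @param fit An [icls_fit()] object.
#' @param grid A grid covariate table carrying the model's covariates
#'   (raw scale) plus any point metadata (`point_id`, `lon`, `lat`, ...).
#' @return A `phenology_surface` tibble: the grid with `mu`, `sigma` and
#'   `synchrony80` columns. Use [surface_summary()] for min/mean/max/std
#'   summaries.
#' @export
predict_surface <- function(fit, grid) {
  surface <- predict(fit, grid, conditional = TRUE)
  class(surface) <- c("phenology_surface", class(surface))
  surface
}

#' Summaries of a predicted phenology surface
#' @param surface A `phenology_surface` from [predict_surface()].
#' @return A tibble with one row per metric (`mu`, `synchrony80`) and
#'   columns `min`, `mean`, `max`, `std`, recomputed from the points.
#' @export
surface_summary <- function(surface) {
  purrr::map_dfr(c("mu", "synchrony80"), function(m) {
    v <- surface[[m]]
    tibble(metric = m, min = min(v), mean = mean(v), max = max(v), std = sd(v))
  })
}

#' @export
autoplot.phenology_surface <- function(object, metric = c("mu", "synchrony80"),
                                       ...) {
  metric <- match.arg(metric)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lon, y = .data$lat,
                                       colour = .data[[metric]])) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(
      colour = if (metric == "mu") "mean date (DoY)" else "synchrony (days)",
      x = "longitude", y = "latitude"
    )
}

#' Representative elevation classes per region
#'
#' For each region, returns three representative elevations of its birth
#' locations: the 10th percentile (lowest class), the mean elevation of
#' records lying between the 45th and 55th percentiles (average class) and
#' the 90th percentile (highest class). Percentiles use linear
#' interpolation (quantile type 7).
#'
#' @param records A data frame with `region_id` and `elevation`.
#' @param min_records Regions with fewer records are skipped with a warning
#'   (default 10).
#' @return A tibble with `region_id`, `class` (`lowest`/`average`/
#'   `highest`) and `elevation`.
#' @export
elevation_classes <- function(records, min_records = 10) {
  records <- tibble::as_tibble(records)
  purrr::map_dfr(split(records, records$region_id), function(df) {
    if (nrow(df) < min_records) {
      warn(paste0("region '", df$region_id[1], "' skipped: fewer than ",
                  min_records, " records"))
      return(tibble())
    }
    e <- df$elevation
    q <- quantile(e, c(0.1, 0.45, 0.55, 0.9), type = 7, names = FALSE)
    band <- e[e >= q[2] & e <= q[3]]
    mid <- if (length(band) > 0) mean(band) else median(e)
    tibble(
      region_id = df$region_id[1],
      class = factor(c("lowest", "average", "highest"),
                     levels = c("lowest", "average", "highest")),
      elevation = c(q[1], mid, q[4])
    )
  })
}
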