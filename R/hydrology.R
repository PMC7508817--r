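#' Fit a power-law catchment-area to discharge rating curve
#'
#' Ungauged tributaries get their mean annual discharge from a regional
#' relation `Q = a * A^b` fitted to nearby gauged stations by ordinary least
#' squares of `log(Q)` on `log(A)`. The power-law form is the standard
#' regionalisation assumption for area-scaling of mean flow.
#'
#' @param gauges Data frame with columns `station_id`, `catchment_area_km2`,
#'   `q_mean_m3s` (both strictly positive); at least two stations with
#'   distinct areas.
#' @return An object of class `rating_curve`: a list with `coef_a`,
#'   `exponent_b`, `n_stations`, `log_space_rmse` (root-mean-square residual
#'   of the natural-log fit) and the underlying `lm` fit. Supports
#'   [predict_discharge()], `predict()`, `tidy()`, `glance()`, `print()` and
#'   `autoplot()`.
#' @examples
#' g <- tibble::tibble(
#'   station_id = letters[1:3],
#'   catchment_area_km2 = c(100, 1000, 10000),
#'   q_mean_m3s = 0.01 * c(100, 1000, 10000)^0.9
#' )
#' fit_rating_curve(g)
#' @export
fit_rating_curve <- function(gauges) {
  gauges <- tibble::as_tibble(gauges)
  need <- c("station_id", "catchment_area_km2", "q_mean_m3s")
  miss <- setdiff(need, names(gauges))
  if (length(miss) > 0) {
    abort(paste0("gauges missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(gauges) < 2) abort("need at least 2 gauge stations")
  if (any(gauges$catchment_area_km2 <= 0 | gauges$q_mean_m3s <= 0)) {
    abort("catchment areas and discharges must be positive")
  }
  if (length(unique(gauges$catchment_area_km2)) < 2) {
    abort("gauge catchment areas must span a nonzero range")
  }
  fit <- lm(log(q_mean_m3s) ~ log(catchment_area_km2), data = gauges)
  res <- stats::residuals(fit)
  structure(
    list(
      coef_a = unname(exp(coef(fit)[1])),
      exponent_b = unname(coef(fit)[2]),
      n_stations = nrow(gauges),
      log_space_rmse = sqrt(mean(res^2)),
      fit = fit,
      gauges = gauges
    ),
    class = "rating_curve"
  )
}

#' Predict mean discharge from catchment area
#'
#' Evaluates a fitted rating curve: `Q = a * A^b`.
#'
#' @param curve A `rating_curve` from [fit_rating_curve()].
#' @param area_km2 Catchment area(s) in km^2, strictly positive.
#' @return Predicted mean discharge(s) in m^3 s^-1.
#' @examples
#' curve <- structure(list(coef_a = 0.01, exponent_b = 0.9),
#'                    class = "rating_curve")
#' predict_discharge(curve, 510)
#' @export
predict_discharge <- function(curve, area_km2) {
  stopifnot(inherits(curve, "rating_curve"))
  if (any(!is.finite(area_km2) | area_km2 <= 0)) {
    abort("area_km2 must be positive")
  }
  curve$coef_a * area_km2^curve$exponent_b
}

#' @export
predict.rating_curve <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) newdata <- newdata$catchment_area_km2
  predict_discharge(object, newdata)
}

#' @export
print.rating_curve <- function(x, ...) {
  cat(sprintf(
    "Area-discharge rating curve: Q = %.4g * A^%.4g  (%d stations, log-space RMSE %.3g)\n",
    x$coef_a, x$exponent_b, x$n_stations, x$log_space_rmse
  ))
  invisible(x)
}

#' @rdname fit_rating_curve
#' @param x A `rating_curve` object.
#' @param ... Unused.
#' @method tidy rating_curve
#' @export
tidy.rating_curve <- function(x, ...) {
  tibble::tibble(
    term = c("coef_a", "exponent_b"),
    estimate = c(x$coef_a, x$exponent_b)
  )
}

#' @rdname fit_rating_curve
#' @method glance rating_curve
#' @export
glance.rating_curve <- function(x, ...) {
  tibble::tibble(
    n_stations = x$n_stations,
    log_space_rmse = x$log_space_rmse,
    r_squared = summary(x$fit)$r.squared
  )
}

#' Monthly climatology of a hydrograph or rainfall series
#'
#' Per-calendar-month arithmetic means across years. Months never observed
#' are reported with `mean_value = NA` and `n_years = 0` rather than imputed.
#'
#' @param series Data frame with columns `year`, `month` (1-12), `value`
#'   (>= 0); at most one entry per (year, month).
#' @return A 12-row tibble: `month`, `mean_value`, `n_years`.
#' @examples
#' s <- tidyr::expand_grid(year = 2011:2017, month = 1:12) |>
#'   dplyr::mutate(value = 100 + 50 * cospi((month - 3) / 6))
#' monthly_climatology(s)
#' @export
monthly_climatology <- function(series) {
  series <- check_monthly_series(series)
  if (nrow(series) == 0) abort("empty series")
  series |>
    dplyr::group_by(.data$month) |>
    dplyr::summarise(mean_value = mean(.data$value), n_years = dplyr::n(),
                     .groups = "drop") |>
    tidyr::complete(month = 1:12,
                    fill = list(mean_value = NA_real_, n_years = 0L)) |>
    dplyr::arrange(.data$month)
}

#' Month of peak value in each year
#'
#' For each year in the series, the calendar month holding the maximum value.
#' Ties are broken toward the earliest month and flagged, so downstream
#' histograms are deterministic.
#'
#' @inheritParams monthly_climatology
#' @return A tibble with one row per year: `year`, `peak_month`,
#'   `peak_value`, `tie` (TRUE when the maximum was attained in more than
#'   one month).
#' @export
annual_peaks <- function(series) {
  series <- check_monthly_series(series)
  if (nrow(series) == 0) abort("empty series")
  series |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(
      peak_value = max(.data$value),
      peak_month = min(.data$month[.data$value == max(.data$value)]),
      tie = sum(.data$value == max(.data$value)) > 1,
      .groups = "drop"
    ) |>
    dplyr::select("year", "peak_month", "peak_value", "tie") |>
    dplyr::arrange(.data$year)
}

#' Histogram of annual peak months
#'
#' Tallies [annual_peaks()] output into 12 monthly counts; counts sum to the
#' number of years.
#'
#' @param peaks Output of [annual_peaks()] (or any data frame with a
#'   `peak_month` column), possibly empty.
#' @return A 12-row tibble: `month`, `n`.
#' @export
peak_month_histogram <- function(peaks) {
  peaks <- tibble::as_tibble(peaks)
  if (nrow(peaks) > 0 && !"peak_month" %in% names(peaks)) {
    abort("peaks must have a peak_month column")
  }
  counts <- if (nrow(peaks) == 0) integer(12) else {
    tabulate(peaks$peak_month, nbins = 12)
  }
  tibble::tibble(month = 1:12, n = counts)
}

check_monthly_series <- function(series) {
  series <- tibble::as_tibble(series)
  miss <- setdiff(c("year", "month", "value"), names(series))
  if (length(miss) > 0) {
    abort(paste0("series missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (any(!series$month %in% 1:12)) abort("month must be in 1..12")
  if (any(series$value < 0, na.rm = TRUE)) abort("values must be >= 0")
  if (anyDuplicated(series[c("year", "month")]) > 0) {
    abort("at most one entry per (year, month)")
  }
  series
}
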