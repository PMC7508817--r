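# ggplot2 methods for the package's result types

#' @describeIn nutrient_budget Stacked plant-bound versus waterborne shares
#'   of total annual export, one bar per (site, nutrient), with the plant
#'   envelope drawn as an error bar on the plant share.
#' @param object A `nutrient_budget` tibble.
#' @param ... Unused.
#' @method autoplot nutrient_budget
#' @export
autoplot.nutrient_budget <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    dplyr::mutate(
      plant_pct = .data$sink_pct,
      water_pct = 100 - .data$sink_pct
    ) |>
    tidyr::pivot_longer(c("plant_pct", "water_pct"),
                        names_to = "component", values_to = "pct") |>
    dplyr::mutate(component = dplyr::recode(.data$component,
                                            plant_pct = "plant-bound",
                                            water_pct = "surface water"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$site, y = .data$pct,
                                     fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(
      data = tibble::as_tibble(object),
      ggplot2::aes(x = .data$site, ymin = .data$sink_lo_pct,
                   ymax = .data$sink_hi_pct),
      inherit.aes = FALSE, width = 0.25
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$nutrient)) +
    ggplot2::labs(y = "share of annual export (%)", x = NULL,
                  fill = NULL,
                  title = "Plant-bound vs waterborne nutrient export") +
    ggplot2::theme_minimal()
}

#' @describeIn fit_rating_curve Log-log scatter of the gauge stations with
#'   the fitted power law.
#' @param object A `rating_curve` object.
#' @method autoplot rating_curve
#' @export
autoplot.rating_curve <- function(object, ...) {
  ggplot2::ggplot(object$gauges,
                  ggplot2::aes(x = .data$catchment_area_km2,
                               y = .data$q_mean_m3s)) +
    ggplot2::geom_point() +
    ggplot2::geom_function(
      fun = function(a) object$coef_a * a^object$exponent_b,
      colour = "steelblue"
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = expression(catchment ~ area ~ (km^2)),
      y = expression(mean ~ discharge ~ (m^3 ~ s^-1)),
      title = sprintf("Q = %.3g A^%.3g (%d stations)",
                      object$coef_a, object$exponent_b, object$n_stations)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the seasonal cycle of a monthly series
#'
#' Monthly climatology from [monthly_climatology()] as a line-and-point
#' seasonal profile; months with no data are left blank.
#'
#' @param series A monthly series (`year`, `month`, `value`).
#' @param kind Axis label for the variable, e.g. `"discharge (m3/s)"`.
#' @return A ggplot object.
#' @export
plot_seasonality <- function(series, kind = "value") {
  clim <- monthly_climatology(series)
  ggplot2::ggplot(clim, ggplot2::aes(x = .data$month, y = .data$mean_value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = 1:12, labels = month.abb) +
    ggplot2::labs(x = NULL, y = kind, title = "Monthly climatology") +
    ggplot2::theme_minimal()
}

#' Plot the histogram of annual peak months
#'
#' @param peaks Output of [annual_peaks()].
#' @return A ggplot object.
#' @export
plot_peak_histogram <- function(peaks) {
  hist <- peak_month_histogram(peaks)
  ggplot2::ggplot(hist, ggplot2::aes(x = factor(.data$month, levels = 1:12),
                                     y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::scale_x_discrete(labels = month.abb) +
    ggplot2::labs(x = NULL, y = "years", title = "Annual peak months") +
    ggplot2::theme_minimal()
}
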