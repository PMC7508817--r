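#' Composite vegetation-cover observations into two-month bins
#'
#' Groups cover observations into six calendar-aligned bimonthly bins per
#' year (Jan-Feb, Mar-Apr, ..., Nov-Dec) and reports the maximum observed
#' cover per bin. The maximum — not the mean — is used because peak standing
#' cover at a choke point is the proxy for plant export; a bin's largest
#' scene is the least cloud- and timing-degraded view of it. Bins with no
#' observations are omitted (flagged absent by their absence).
#'
#' @param obs Data frame with columns `site` (optional), `date` (Date or
#'   ISO-8601 string), `cover_km2` (>= 0).
#' @return A tibble with columns `year`, `bin` (1-6), `bin_label`,
#'   `max_cover_km2`, `n_obs`, ordered by year and bin.
#' @examples
#' obs <- tibble::tibble(
#'   date = as.Date(c("2015-01-10", "2015-02-20", "2015-07-01")),
#'   cover_km2 = c(1, 3, 2)
#' )
#' composite_bimonthly(obs)
#' @export
composite_bimonthly <- function(obs) {
  obs <- check_cover_obs(obs)
  if (nrow(obs) == 0) {
    return(tibble::tibble(year = integer(), bin = integer(),
                          bin_label = character(), max_cover_km2 = double(),
                          n_obs = integer()))
  }
  labels <- c("Jan-Feb", "Mar-Apr", "May-Jun", "Jul-Aug", "Sep-Oct", "Nov-Dec")
  obs |>
    dplyr::mutate(
      year = as.integer(format(.data$date, "%Y")),
      bin = (as.integer(format(.data$date, "%m")) + 1L) %/% 2L
    ) |>
    dplyr::group_by(.data$year, .data$bin) |>
    dplyr::summarise(max_cover_km2 = max(.data$cover_km2),
                     n_obs = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(bin_label = labels[.data$bin], .after = "bin") |>
    dplyr::arrange(.data$year, .data$bin)
}

#' Peak annual vegetation cover
#'
#' Maximum observed cover per calendar year — the conservative proxy for the
#' annual export of plant material from a catchment, on the assumption that
#' the seasonal flush removes the standing crop from the choke point each
#' year. Invariant to observation order and duplicates.
#'
#' @inheritParams composite_bimonthly
#' @return A tibble with one row per observed year: `year`, `peak_cover_km2`.
#' @export
peak_annual_cover <- function(obs) {
  obs <- check_cover_obs(obs)
  if (nrow(obs) == 0) {
    return(tibble::tibble(year = integer(), peak_cover_km2 = double()))
  }
  obs |>
    dplyr::mutate(year = as.integer(format(.data$date, "%Y"))) |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(peak_cover_km2 = max(.data$cover_km2), .groups = "drop") |>
    dplyr::arrange(.data$year)
}

#' Vegetation area from a fully covered channel reach
#'
#' Where repeated imagery shows the channel completely covered by floating
#' plants, the channel's own surface area is the conservative estimate of
#' peak vegetation cover. Supply either the channel area directly or a reach
#' length with a mean channel width.
#'
#' @param site Site label.
#' @param channel_area_km2 Channel surface area (km^2), if known.
#' @param length_km Reach length (km), used with `mean_width_m` when the
#'   channel area is not supplied.
#' @param mean_width_m Mean channel width (m).
#' @return A one-row tibble: `site`, `area_km2`, `basis = "full_coverage"`.
#' @examples
#' full_coverage_area("maramba", channel_area_km2 = 0.087)
#' full_coverage_area("maramba", length_km = 2.3, mean_width_m = 37.83)
#' @export
full_coverage_area <- function(site, channel_area_km2 = NULL,
                               length_km = NULL, mean_width_m = NULL) {
  if (!is.null(channel_area_km2)) {
    if (!is.finite(channel_area_km2) || channel_area_km2 < 0) {
      abort("channel_area_km2 must be >= 0")
    }
    area <- channel_area_km2
  } else if (!is.null(length_km) && !is.null(mean_width_m)) {
    if (!is.finite(length_km) || length_km <= 0) abort("length_km must be > 0")
    if (!is.finite(mean_width_m) || mean_width_m <= 0) {
      abort("mean_width_m must be > 0")
    }
    area <- length_km * mean_width_m / 1000
  } else {
    abort("supply channel_area_km2, or length_km plus mean_width_m")
  }
  tibble::tibble(site = site, area_km2 = area, basis = "full_coverage")
}

#' Vegetation area of a fringing strip
#'
#' Ground-surveyed fringing vegetation along a bank is modelled as a strip of
#' constant width: `area = width_m * length_km / 1000` km^2.
#'
#' @param width_m Strip width in metres (> 0).
#' @param length_km Strip length in km (> 0).
#' @param site Site label.
#' @return A one-row tibble: `site`, `area_km2`, `basis = "fringe"`.
#' @examples
#' fringe_area(0.5, 1.2) # 0.0006 km^2
#' @export
fringe_area <- function(width_m, length_km, site = NA_character_) {
  if (any(!is.finite(width_m) | width_m <= 0)) abort("width_m must be > 0")
  if (any(!is.finite(length_km) | length_km <= 0)) abort("length_km must be > 0")
  tibble::tibble(site = site, area_km2 = width_m * length_km / 1000,
                 basis = "fringe")
}

#' Per-period summaries of a binned cover series
#'
#' Long cover records often show distinct multi-year regimes (e.g. an early
#' high-cover invasion, a post-control lull, a seasonal re-emergence).
#' This restricts the bimonthly-composited series to user-defined year
#' periods and summarises each: mean and maximum bin cover and the fraction
#' of observed bins with nonzero cover. Observations falling outside every
#' period are ignored; their count is attached as the `n_outside` attribute.
#'
#' @inheritParams composite_bimonthly
#' @param periods Data frame with columns `label`, `start_year`, `end_year`
#'   (inclusive, non-overlapping).
#' @return A tibble with one row per period: `label`, `start_year`,
#'   `end_year`, `n_bins`, `mean_cover_km2`, `max_cover_km2`,
#'   `frac_bins_nonzero`. Periods with no observations carry `NA` summaries
#'   and `n_bins = 0`. Attribute `n_outside` counts ignored observations.
#' @export
period_stats <- function(obs, periods) {
  periods <- tibble::as_tibble(periods)
  miss <- setdiff(c("label", "start_year", "end_year"), names(periods))
  if (length(miss) > 0) {
    abort(paste0("periods missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (any(periods$start_year > periods$end_year)) {
    abort("period start_year must be <= end_year")
  }
  yrs <- unlist(purrr::map2(periods$start_year, periods$end_year, seq))
  if (anyDuplicated(yrs) > 0) abort("periods must not overlap")

  binned <- composite_bimonthly(obs)
  assigned <- binned |>
    dplyr::mutate(period = purrr::map_chr(.data$year, function(y) {
      hit <- periods$label[periods$start_year <= y & y <= periods$end_year]
      if (length(hit) == 0) NA_character_ else hit[1]
    }))
  n_outside <- sum(assigned$n_obs[is.na(assigned$period)])

  out <- assigned |>
    dplyr::filter(!is.na(.data$period)) |>
    dplyr::group_by(label = .data$period) |>
    dplyr::summarise(
      n_bins = dplyr::n(),
      mean_cover_km2 = mean(.data$max_cover_km2),
      max_cover_km2 = max(.data$max_cover_km2),
      frac_bins_nonzero = mean(.data$max_cover_km2 > 0),
      .groups = "drop"
    )
  out <- periods |>
    dplyr::select("label", "start_year", "end_year") |>
    dplyr::left_join(out, by = "label") |>
    dplyr::mutate(n_bins = dplyr::coalesce(.data$n_bins, 0L))
  attr(out, "n_outside") <- n_outside
  out
}

check_cover_obs <- function(obs) {
  obs <- tibble::as_tibble(obs)
  miss <- setdiff(c("date", "cover_km2"), names(obs))
  if (length(miss) > 0) {
    abort(paste0("cover observations missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (!inherits(obs$date, "Date")) {
    parsed <- as.Date(as.character(obs$date), format = "%Y-%m-%d")
    if (nrow(obs) > 0 && anyNA(parsed)) {
      abort(paste0("malformed dates in rows: ",
                   paste(which(is.na(parsed)), collapse = ", ")))
    }
    obs$date <- parsed
  }
  if (any(obs$cover_km2 < 0, na.rm = TRUE)) abort("cover_km2 must be >= 0")
  obs
}
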