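#' Scenario configuration for the synthetic-data generators
#'
#' Bundles the ground truth for every generator in one validated list, so a
#' scenario is reproducible from a single seed. Defaults describe a
#' Zambezi-like study setting: a water-hyacinth trait synthesis with
#' substantial between-study spread, a regional gauge network following a
#' power-law area-discharge relation, a vegetation-cover cycle peaking in
#' April with a mid-year flush collapse, quarterly concentration sampling
#' with occasional order-of-magnitude outliers, and blob-structured
#' fractional landcover.
#'
#' @param seed Integer seed; every generator is a pure function of the
#'   configuration, so a fixed seed yields byte-identical output.
#' @param traits,gauges,cover,concentration,landcover Named lists overriding
#'   individual defaults (partial overrides are merged).
#' @return A list of class `scenario_config`.
#' @examples
#' cfg <- scenario_config(seed = 7, gauges = list(sigma = 0))
#' @export
scenario_config <- function(seed = 1L, traits = list(), gauges = list(),
                            cover = list(), concentration = list(),
                            landcover = list()) {
  base <- list(
    seed = as.integer(seed),
    traits = list(
      # truth means equal the packaged calibration; rel_sd reflects the wide
      # between-study spread of hyacinth traits
      means = c(biomass_per_area = 2.0, p_content = 0.004836,
                n_content = 0.02391),
      rel_sd = c(biomass_per_area = 0.3, p_content = 0.3, n_content = 0.3),
      n_studies = c(biomass_per_area = 15L, p_content = 17L, n_content = 14L)
    ),
    gauges = list(
      a = 0.01, b = 0.9, sigma = 0.2, n = 20L,
      area_range_km2 = c(50, 50000)
    ),
    cover = list(
      site = "kafue_gorge", start_year = 2012L, n_years = 7L,
      peak_month = 4L, amplitude_km2 = 5, baseline_km2 = 0.3,
      season_width_months = 2, flush_month = 7L, flush_factor = 0.15,
      noise_sdlog = 0.15
    ),
    concentration = list(
      site = "maramba", start_year = 2018L, n_years = 1L,
      quarter_months = c(3L, 6L, 9L, 12L),
      tp_quarter_means = c(30, 25, 30, 45),
      tn_quarter_means = c(700, 600, 650, 920),
      noise_sdlog = 0.1, outlier_prob = 0.1, outlier_factor = 10
    ),
    landcover = list(
      n_rows = 40L, n_cols = 40L, pixel_size_m = 100,
      background_fraction = 0.05,
      blobs = list(class = "urban", n = 3L, height = 3L, width = 3L,
                   fraction = 0.8),
      mask_rows = c(5L, 35L), mask_cols = c(5L, 35L),
      outlet = c(35L, 35L)
    )
  )
  cfg <- base
  cfg$traits <- modifyList(base$traits, traits)
  cfg$gauges <- modifyList(base$gauges, gauges)
  cfg$cover <- modifyList(base$cover, cover)
  cfg$concentration <- modifyList(base$concentration, concentration)
  cfg$landcover <- modifyList(base$landcover, landcover)
  validate_scenario(cfg)
  structure(cfg, class = c("scenario_config", "list"))
}

validate_scenario <- function(cfg) {
  with(cfg$traits, {
    if (any(means <= 0) || any(rel_sd < 0)) abort("trait truth must be positive")
    if (any(n_studies < 2)) abort("study counts must be >= 2")
  })
  with(cfg$gauges, {
    if (a <= 0 || sigma < 0 || n < 2) abort("invalid gauge config")
    if (any(area_range_km2 <= 0) || diff(area_range_km2) <= 0) {
      abort("invalid gauge area range")
    }
  })
  with(cfg$cover, {
    if (!peak_month %in% 1:12 || !flush_month %in% 1:12) {
      abort("months must be in 1..12")
    }
    if (amplitude_km2 < 0 || baseline_km2 < 0 || noise_sdlog < 0 ||
        flush_factor < 0 || flush_factor > 1) {
      abort("invalid cover config")
    }
  })
  with(cfg$concentration, {
    if (outlier_prob < 0 || outlier_prob > 1) {
      abort("outlier_prob must be in [0, 1]")
    }
    if (any(tp_quarter_means < 0) || any(tn_quarter_means < 0) ||
        outlier_factor <= 0) {
      abort("invalid concentration config")
    }
  })
  with(cfg$landcover, {
    if (background_fraction < 0 || background_fraction > 1 ||
        blobs$fraction < 0 || blobs$fraction > 1) {
      abort("fractions must be in [0, 1]")
    }
  })
  invisible(cfg)
}

# lognormal parameterised by its arithmetic mean and relative sd
rlnorm_mean <- function(n, mean, rel_sd) {
  if (rel_sd == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + rel_sd^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate synthetic literature trait records
#'
#' Draws per-study trait values from lognormal distributions whose arithmetic
#' mean equals the configured truth (positivity-preserving, a generator
#' choice rather than a claim about real literature distributions). With
#' `rel_sd = 0` every record equals the truth and [synthesize_traits()]
#' recovers it exactly.
#'
#' @param cfg A [scenario_config()].
#' @return A tibble: `study_id`, `trait`, `value`, `source_note`.
#' @export
gen_trait_records <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  withr::with_seed(cfg$seed + 101L, {
    tr <- cfg$traits
    purrr::map_dfr(names(tr$means), function(name) {
      n <- tr$n_studies[[name]]
      tibble::tibble(
        study_id = sprintf("%s_study_%02d", name, seq_len(n)),
        trait = name,
        value = rlnorm_mean(n, tr$means[[name]], tr$rel_sd[[name]]),
        source_note = "synthetic"
      )
    })
  })
}

#' Generate a synthetic gauge-station network
#'
#' Station catchment areas are log-uniform over the configured range;
#' discharges follow `Q = a * A^b` with multiplicative lognormal noise
#' `exp(N(0, sigma))`. With `sigma = 0` the stations lie exactly on the
#' curve and [fit_rating_curve()] recovers `(a, b)` to machine precision.
#'
#' @inheritParams gen_trait_records
#' @return A tibble: `station_id`, `catchment_area_km2`, `q_mean_m3s`.
#' @export
gen_gauges <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  withr::with_seed(cfg$seed + 202L, {
    g <- cfg$gauges
    area <- exp(runif(g$n, log(g$area_range_km2[1]), log(g$area_range_km2[2])))
    tibble::tibble(
      station_id = sprintf("st_%03d", seq_len(g$n)),
      catchment_area_km2 = area,
      q_mean_m3s = g$a * area^g$b * exp(rnorm(g$n, 0, g$sigma))
    )
  })
}

#' Generate a synthetic vegetation-cover series
#'
#' One monthly observation per site-month: a Gaussian-bump annual cycle
#' peaking at the configured month on top of a baseline, with cover collapsed
#' by `flush_factor` for the two months starting at `flush_month` (the
#' wet-season flush that exports the mats), times lognormal noise. At zero
#' noise the within-year argmax is exactly the configured peak month.
#'
#' @inheritParams gen_trait_records
#' @return A tibble: `site`, `date`, `cover_km2`, `sensor`.
#' @export
gen_cover_series <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  withr::with_seed(cfg$seed + 303L, {
    cv <- cfg$cover
    grid <- tidyr::expand_grid(
      year = cv$start_year + seq_len(cv$n_years) - 1L,
      month = 1:12
    )
    # circular month distance to the peak
    d <- pmin(abs(grid$month - cv$peak_month),
              12 - abs(grid$month - cv$peak_month))
    cover <- cv$baseline_km2 +
      cv$amplitude_km2 * exp(-d^2 / (2 * cv$season_width_months^2))
    flushed <- grid$month %in% (((cv$flush_month + 0:1 - 1L) %% 12L) + 1L)
    cover[flushed] <- cover[flushed] * cv$flush_factor
    noise <- if (cv$noise_sdlog == 0) 1 else {
      stats::rlnorm(nrow(grid), -cv$noise_sdlog^2 / 2, cv$noise_sdlog)
    }
    tibble::tibble(
      site = cv$site,
      date = as.Date(sprintf("%d-%02d-15", grid$year, grid$month)),
      cover_km2 = cover * noise,
      sensor = "landsat"
    )
  })
}

#' Generate synthetic quarterly concentration samples
#'
#' Four samples per site-year at the configured quarter months, drawn
#' lognormally around per-quarter means; each sample is independently
#' inflated by `outlier_factor` with probability `outlier_prob` (both
#' nutrients together, emulating a contaminated or storm-flow sample).
#'
#' @inheritParams gen_trait_records
#' @return A tibble: `site`, `date`, `tp_ugL`, `tn_ugL`.
#' @export
gen_concentration_samples <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  withr::with_seed(cfg$seed + 404L, {
    cc <- cfg$concentration
    grid <- tidyr::expand_grid(
      year = cc$start_year + seq_len(cc$n_years) - 1L,
      q = seq_along(cc$quarter_months)
    )
    n <- nrow(grid)
    tp <- rlnorm_mean_vec(cc$tp_quarter_means[grid$q], cc$noise_sdlog)
    tn <- rlnorm_mean_vec(cc$tn_quarter_means[grid$q], cc$noise_sdlog)
    out <- runif(n) < cc$outlier_prob
    tp[out] <- tp[out] * cc$outlier_factor
    tn[out] <- tn[out] * cc$outlier_factor
    tibble::tibble(
      site = cc$site,
      date = as.Date(sprintf("%d-%02d-15", grid$year,
                             cc$quarter_months[grid$q])),
      tp_ugL = tp,
      tn_ugL = tn
    )
  })
}

rlnorm_mean_vec <- function(means, rel_sd) {
  if (rel_sd == 0) return(means)
  sdlog <- sqrt(log(1 + rel_sd^2))
  stats::rlnorm(length(means), log(means) - sdlog^2 / 2, sdlog)
}

#' Generate a synthetic fractional-landcover grid and catchment mask
#'
#' A background fraction field with rectangular high-fraction blobs placed
#' uniformly at random, plus a rectangular catchment mask with an outlet
#' pixel — enough structure to exercise thresholded zonal statistics.
#'
#' @inheritParams gen_trait_records
#' @return A list with elements `grid` (a [fraction_grid()]) and `mask`
#'   (a [catchment_mask()]).
#' @export
gen_landcover <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  withr::with_seed(cfg$seed + 505L, {
    lc <- cfg$landcover
    v <- matrix(lc$background_fraction, lc$n_rows, lc$n_cols)
    b <- lc$blobs
    for (i in seq_len(b$n)) {
      r0 <- sample.int(lc$n_rows - b$height + 1L, 1)
      c0 <- sample.int(lc$n_cols - b$width + 1L, 1)
      v[r0:(r0 + b$height - 1L), c0:(c0 + b$width - 1L)] <- b$fraction
    }
    m <- matrix(FALSE, lc$n_rows, lc$n_cols)
    m[lc$mask_rows[1]:lc$mask_rows[2], lc$mask_cols[1]:lc$mask_cols[2]] <- TRUE
    list(
      grid = fraction_grid(v, lc$pixel_size_m, b$class),
      mask = catchment_mask(m, lc$pixel_size_m, outlet = lc$outlet)
    )
  })
}

#' Demo input bundle for the four Zambezi study catchments
#'
#' Reference inputs for the Kafue (below Itezhi-Tezhi), Chongwe, Little
#' Chongwe and Maramba catchments in southern Zambia: peak floating
#' vegetation areas, mean annual discharges, annual mean digestible N and P
#' concentrations, catchment landcover areas, and the packaged trait
#' calibration. Running [nutrient_budget()] on this bundle reproduces the
#' study's per-catchment loads, pools and plant sink fractions. Emission is
#' deterministic (no randomness).
#'
#' @return A named list of tibbles: `traits`, `vegetation`, `discharge`,
#'   `concentrations`, `landcover`.
#' @examples
#' demo <- zambezi_demo()
#' nutrient_budget(demo$vegetation, demo$concentrations, demo$discharge)
#' @export
zambezi_demo <- function() {
  sites <- c("kafue", "chongwe", "little_chongwe", "maramba")
  list(
    traits = default_traits(),
    vegetation = tibble::tibble(
      site = sites,
      area_km2 = c(5.5, 0.006, 0, 0.087),
      basis = c("digitized", "composite", "digitized", "full_coverage")
    ),
    discharge = tibble::tibble(
      site = sites,
      q_mean_m3s = c(989, 11.4, 1.9, 1.9),
      catchment_area_km2 = c(44470, 5130, 530, 510)
    ),
    concentrations = tibble::tibble(
      site = sites,
      tp_ugL = c(7.3, 15.6, 14.1, 32.4),
      tn_ugL = c(289, 333, 642, 718)
    ),
    landcover = tibble::tibble(
      catchment = c("chongwe", "maramba", "little_chongwe", "kafue"),
      catchment_area_km2 = c(5128, 507, 528, 44466),
      urban_area_km2 = c(204.2, 31.4, 0.2, 464.3),
      cropland_area_km2 = c(603.1, 14.5, 6.5, 6257.1),
      distance_to_urban_km = c(82, 2, NA, 16)
    )
  )
}
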