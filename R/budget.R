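#' Multiplicative uncertainty envelope for a plant nutrient pool
#'
#' Compounds the relative standard errors of the two literature-synthesis
#' traits (biomass per area, tissue nutrient content) into a multiplicative
#' envelope around a point estimate:
#' `env_high = mass * (1 + rel_se_biomass) * (1 + rel_se_content)` and
#' `env_low  = mass * (1 - rel_se_biomass) * (1 - rel_se_content)`.
#' The envelope always brackets the point estimate and is asymmetric on the
#' sink-fraction scale, matching how compounded trait uncertainty behaves.
#'
#' @param mass_Mg Point estimate of nutrient mass (Mg). Vectorized.
#' @param rel_se_biomass,rel_se_content Relative standard errors (SE / mean)
#'   of the biomass-per-area and nutrient-content syntheses; each in `[0, 1)`.
#' @return A tibble with columns `env_low_Mg`, `env_high_Mg`.
#' @examples
#' compound_envelope(53.2, 0.13, 0.076)
#' @export
compound_envelope <- function(mass_Mg, rel_se_biomass, rel_se_content) {
  if (any(!is.finite(mass_Mg) | mass_Mg < 0)) abort("mass_Mg must be >= 0")
  for (r in list(rel_se_biomass, rel_se_content)) {
    if (any(!is.finite(r) | r < 0 | r >= 1)) {
      abort("relative standard errors must lie in [0, 1)")
    }
  }
  tibble::tibble(
    env_low_Mg = mass_Mg * (1 - rel_se_biomass) * (1 - rel_se_content),
    env_high_Mg = mass_Mg * (1 + rel_se_biomass) * (1 + rel_se_content)
  )
}

#' Nutrient mass bound in floating-plant biomass
#'
#' Converts an areal vegetation cover into the nutrient mass it contains:
#' `mass_Mg = area_km2 * 1e6 m^2 km^-2 * biomass (kg m^-2) * content
#' (fraction) * 1e-3 Mg kg^-1`, with a compounded uncertainty envelope from
#' the two trait standard errors (see [compound_envelope()]).
#'
#' @param area_km2 Vegetation cover area(s) in km^2 (peak cover at a choke
#'   point is the annual-export proxy). Vectorized.
#' @param biomass One-row trait synthesis (as from [synthesize_traits()] or
#'   [default_traits()]) with `trait == "biomass_per_area"`.
#' @param content One-row trait synthesis with `trait` `"n_content"` or
#'   `"p_content"`.
#' @param site Optional site label(s), recycled against `area_km2`.
#' @return A tibble with columns `site` (if given), `nutrient` (`"N"` or
#'   `"P"`), `area_km2`, `mass_Mg`, `env_low_Mg`, `env_high_Mg`.
#' @examples
#' tr <- default_traits()
#' plant_nutrient_pool(5.5,
#'   biomass = dplyr::filter(tr, trait == "biomass_per_area"),
#'   content = dplyr::filter(tr, trait == "p_content")
#' )
#' @export
plant_nutrient_pool <- function(area_km2, biomass, content, site = NULL) {
  biomass <- check_one_trait(biomass, "biomass_per_area")
  content <- check_one_trait(content, c("n_content", "p_content"))
  if (any(!is.finite(area_km2) | area_km2 < 0)) {
    abort("area_km2 must be >= 0")
  }
  nutrient <- if (content$trait == "n_content") "N" else "P"
  mass <- area_km2 * 1e6 * biomass$mean * content$mean * 1e-3
  env <- compound_envelope(mass, biomass$rel_se, content$rel_se)
  out <- tibble::tibble(
    nutrient = nutrient,
    area_km2 = area_km2,
    mass_Mg = mass,
    env_low_Mg = env$env_low_Mg,
    env_high_Mg = env$env_high_Mg
  )
  if (!is.null(site)) out <- dplyr::mutate(out, site = site, .before = 1)
  out
}

check_one_trait <- function(x, allowed) {
  x <- tibble::as_tibble(x)
  if (nrow(x) != 1) abort("expected a one-row trait synthesis")
  need <- c("trait", "mean", "rel_se")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0("trait synthesis missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (!x$trait %in% allowed) {
    abort(paste0("trait mismatch: got '", x$trait, "', expected one of ",
                 paste(allowed, collapse = ", ")))
  }
  x
}

#' Aggregate seasonal concentration samples per nutrient
#'
#' Collapses repeated (typically quarterly) surface-water samples of
#' digestible phosphorus and nitrogen into a single concentration per
#' nutrient, by arithmetic mean (default) or median. The median is exposed as
#' a sensitivity switch against outlier-driven bias in sparse seasonal
#' sampling; it is never substituted silently.
#'
#' @param samples Data frame with columns `tp_ugL` and `tn_ugL` (one row per
#'   sampling date; `site` and `date` columns are allowed and ignored here).
#' @param method `"mean"` or `"median"`.
#' @return A tibble with columns `nutrient` (`"P"`, `"N"`), `conc_ugL`,
#'   `aggregation`, `n_samples`.
#' @examples
#' s <- tibble::tibble(tp_ugL = c(10, 20, 30, 1000), tn_ugL = c(1, 2, 3, 4))
#' aggregate_concentration(s, "mean")
#' aggregate_concentration(s, "median")
#' @export
aggregate_concentration <- function(samples, method = c("mean", "median")) {
  method <- match.arg(method)
  samples <- tibble::as_tibble(samples)
  miss <- setdiff(c("tp_ugL", "tn_ugL"), names(samples))
  if (length(miss) > 0) {
    abort(paste0("concentration samples missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (nrow(samples) == 0) abort("no concentration samples supplied")
  if (any(samples$tp_ugL < 0 | samples$tn_ugL < 0, na.rm = TRUE)) {
    abort("concentrations must be >= 0")
  }
  agg <- if (method == "mean") mean else median
  tibble::tibble(
    nutrient = c("P", "N"),
    conc_ugL = c(agg(samples$tp_ugL), agg(samples$tn_ugL)),
    aggregation = method,
    n_samples = nrow(samples)
  )
}

#' Annual riverine nutrient load from discharge and concentration
#'
#' Computes the annual waterborne export of a nutrient as mean annual
#' discharge times mean (or median) digestible concentration:
#' `load_Mg_yr = q_mean_m3s * conc_ugL * 0.031536`, the constant being
#' 31,536,000 s in a 365-day year times 1e-9 Mg per (m^3 * ug L^-1).
#'
#' @param q_mean_m3s Mean annual discharge (m^3 s^-1). Vectorized.
#' @param conc_ugL Aggregated digestible nutrient concentration (ug L^-1).
#' @param nutrient `"P"` or `"N"` label(s) for the output.
#' @param aggregation Label recording how `conc_ugL` was aggregated.
#' @param year_seconds Seconds per year used for integration (default
#'   31,536,000, a 365-day year).
#' @return A tibble with columns `nutrient`, `load_Mg_yr`, `q_mean_m3s`,
#'   `conc_ugL`, `aggregation`.
#' @examples
#' annual_load(989, 289, "N")   # ~9014 Mg yr^-1
#' annual_load(11.4, 15.6, "P") # ~5.6 Mg yr^-1
#' @export
annual_load <- function(q_mean_m3s, conc_ugL, nutrient = "P",
                        aggregation = "mean", year_seconds = 31536000) {
  if (any(!is.finite(q_mean_m3s) | q_mean_m3s < 0)) {
    abort("q_mean_m3s must be >= 0")
  }
  if (any(!is.finite(conc_ugL) | conc_ugL < 0)) {
    abort("conc_ugL must be >= 0")
  }
  if (!all(nutrient %in% nutrient_levels)) abort("nutrient must be 'P' or 'N'")
  tibble::tibble(
    nutrient = nutrient,
    load_Mg_yr = q_mean_m3s * conc_ugL * mg_per_q_conc(year_seconds),
    q_mean_m3s = q_mean_m3s,
    conc_ugL = conc_ugL,
    aggregation = aggregation
  )
}

#' Plant-bound share of total annual nutrient export
#'
#' The plant sink fraction is the plant-bound nutrient pool as a percentage
#' of total annual export, where total export is defined as the sum of the
#' plant-bound pool and the waterborne load:
#' `fraction_pct = 100 * mass_Mg / (mass_Mg + load_Mg_yr)`.
#' Confidence bounds substitute the pool's envelope ends for the point
#' estimate with the load held fixed, so the interval inherits the
#' asymmetry of the compounded trait envelope.
#'
#' @param pool A pool tibble from [plant_nutrient_pool()] (columns `nutrient`,
#'   `mass_Mg`, `env_low_Mg`, `env_high_Mg`).
#' @param load A load tibble from [annual_load()] (columns `nutrient`,
#'   `load_Mg_yr`).
#' @return A tibble with columns `nutrient`, `fraction_pct`, `ci_low_pct`,
#'   `ci_high_pct`, `mass_Mg`, `load_Mg_yr`.
#' @examples
#' tr <- default_traits()
#' pool <- plant_nutrient_pool(5.5,
#'   dplyr::filter(tr, trait == "biomass_per_area"),
#'   dplyr::filter(tr, trait == "p_content")
#' )
#' sink_fraction(pool, annual_load(989, 7.3, "P")) # ~19 %
#' @export
sink_fraction <- function(pool, load) {
  pool <- tibble::as_tibble(pool)
  load <- tibble::as_tibble(load)
  if (!setequal(pool$nutrient, load$nutrient)) {
    abort(paste0("nutrient mismatch between pool (",
                 paste(pool$nutrient, collapse = ","), ") and load (",
                 paste(load$nutrient, collapse = ","), ")"))
  }
  by <- intersect(c("site", "nutrient"), intersect(names(pool), names(load)))
  joined <- dplyr::inner_join(
    dplyr::select(pool, dplyr::any_of(c("site", "nutrient", "mass_Mg",
                                        "env_low_Mg", "env_high_Mg"))),
    dplyr::select(load, dplyr::any_of(c("site", "nutrient", "load_Mg_yr"))),
    by = by
  )
  if (any(joined$mass_Mg + joined$load_Mg_yr <= 0)) {
    abort("sink fraction undefined: pool + load must be > 0")
  }
  pct <- function(m, l) 100 * m / (m + l)
  joined |>
    dplyr::mutate(
      fraction_pct = pct(.data$mass_Mg, .data$load_Mg_yr),
      ci_low_pct = pct(.data$env_low_Mg, .data$load_Mg_yr),
      ci_high_pct = pct(.data$env_high_Mg, .data$load_Mg_yr)
    ) |>
    dplyr::select(dplyr::any_of("site"), "nutrient", "fraction_pct",
                  "ci_low_pct", "ci_high_pct", "mass_Mg", "load_Mg_yr")
}

#' Sensitivity of the sink fraction to mean versus median concentration
#'
#' Sparse quarterly sampling makes the annual mean concentration vulnerable
#' to single outliers. This computes, per nutrient, the difference in sink
#' fraction when the waterborne load is built from the mean versus the median
#' concentration (mean-based minus median-based, in percentage points).
#'
#' @param samples Concentration samples as for [aggregate_concentration()].
#' @param pool Pool tibble with one row per nutrient
#'   (see [plant_nutrient_pool()]).
#' @param q_mean_m3s Mean annual discharge (m^3 s^-1).
#' @param year_seconds Seconds per year (see [annual_load()]).
#' @return A tibble with columns `nutrient`, `fraction_mean_pct`,
#'   `fraction_median_pct`, `delta_pct_points`.
#' @export
sensitivity_mean_vs_median <- function(samples, pool, q_mean_m3s,
                                       year_seconds = 31536000) {
  one <- function(method, col) {
    conc <- aggregate_concentration(samples, method)
    load <- annual_load(q_mean_m3s, conc$conc_ugL, conc$nutrient,
                        aggregation = method, year_seconds = year_seconds)
    sink_fraction(pool, load) |>
      dplyr::select("nutrient", !!col := "fraction_pct")
  }
  dplyr::inner_join(
    one("mean", "fraction_mean_pct"),
    one("median", "fraction_median_pct"),
    by = "nutrient"
  ) |>
    dplyr::mutate(
      delta_pct_points = .data$fraction_mean_pct - .data$fraction_median_pct
    )
}

#' Full per-catchment nutrient budget
#'
#' Orchestrates the mass balance for one or more catchments: converts peak
#' vegetation cover to plant-bound N and P pools via the trait synthesis,
#' aggregates seasonal concentrations, computes annual waterborne loads from
#' mean discharge, and reports the plant sink fraction with its uncertainty
#' envelope — one row per (site, nutrient).
#'
#' @param veg Data frame with columns `site`, `area_km2` (peak vegetation
#'   cover; see [full_coverage_area()], [fringe_area()],
#'   [peak_annual_cover()]).
#' @param conc Either per-sample concentrations (`site`, `date`, `tp_ugL`,
#'   `tn_ugL`; aggregated here per `aggregation`) or pre-aggregated means
#'   (`site`, `tp_ugL`, `tn_ugL`, one row per site).
#' @param discharge Data frame with columns `site`, `q_mean_m3s`.
#' @param traits Trait synthesis tibble covering `biomass_per_area` and both
#'   contents; defaults to the packaged calibration ([default_traits()]).
#' @param aggregation `"mean"` (default) or `"median"`.
#' @param year_seconds Seconds per year (see [annual_load()]).
#' @return A tibble of class `nutrient_budget`, one row per (site, nutrient):
#'   `site`, `nutrient`, `veg_area_km2`, `pool_Mg`, `pool_lo_Mg`,
#'   `pool_hi_Mg`, `q_m3s`, `conc_ugL`, `load_Mg_yr`, `sink_pct`,
#'   `sink_lo_pct`, `sink_hi_pct`.
#' @examples
#' demo <- zambezi_demo()
#' nutrient_budget(demo$vegetation, demo$concentrations, demo$discharge)
#' @export
nutrient_budget <- function(veg, conc, discharge, traits = default_traits(),
                            aggregation = c("mean", "median"),
                            year_seconds = 31536000) {
  aggregation <- match.arg(aggregation)
  veg <- tibble::as_tibble(veg)
  conc <- tibble::as_tibble(conc)
  discharge <- tibble::as_tibble(discharge)
  if (!all(c("site", "area_km2") %in% names(veg))) {
    abort("veg needs columns site, area_km2")
  }
  if (!all(c("site", "q_mean_m3s") %in% names(discharge))) {
    abort("discharge needs columns site, q_mean_m3s")
  }
  if (!all(c("site", "tp_ugL", "tn_ugL") %in% names(conc))) {
    abort("conc needs columns site, tp_ugL, tn_ugL")
  }

  biomass <- dplyr::filter(traits, .data$trait == "biomass_per_area")
  contents <- list(
    P = dplyr::filter(traits, .data$trait == "p_content"),
    N = dplyr::filter(traits, .data$trait == "n_content")
  )
  if (nrow(biomass) != 1 || any(vapply(contents, nrow, 1L) != 1)) {
    abort("traits must contain exactly one row each for biomass_per_area, p_content, n_content")
  }

  conc_agg <- conc |>
    dplyr::group_by(.data$site) |>
    dplyr::group_modify(~ aggregate_concentration(.x, aggregation)) |>
    dplyr::ungroup()

  # sites come from the discharge table; a site absent from the vegetation
  # table simply carries no observed floating plants (area 0)
  sites <- dplyr::select(discharge, "site", "q_mean_m3s") |>
    dplyr::left_join(
      dplyr::summarise(dplyr::group_by(veg, .data$site),
                       area_km2 = sum(.data$area_km2), .groups = "drop"),
      by = "site"
    ) |>
    dplyr::mutate(area_km2 = dplyr::coalesce(.data$area_km2, 0))

  purrr::map_dfr(nutrient_levels, function(nu) {
    pool <- plant_nutrient_pool(sites$area_km2, biomass, contents[[nu]],
                                site = sites$site)
    load <- conc_agg |>
      dplyr::filter(.data$nutrient == nu) |>
      dplyr::inner_join(dplyr::select(sites, "site", "q_mean_m3s"), by = "site")
    load <- annual_load(load$q_mean_m3s, load$conc_ugL, nutrient = nu,
                        aggregation = aggregation,
                        year_seconds = year_seconds) |>
      dplyr::mutate(site = load$site)
    sink_fraction(pool, load) |>
      dplyr::left_join(dplyr::select(pool, "site", "area_km2",
                                     "env_low_Mg", "env_high_Mg"),
                       by = "site") |>
      dplyr::left_join(dplyr::select(load, "site", "q_mean_m3s", "conc_ugL"),
                       by = "site")
  }) |>
    dplyr::transmute(
      site = .data$site,
      nutrient = .data$nutrient,
      veg_area_km2 = .data$area_km2,
      pool_Mg = .data$mass_Mg,
      pool_lo_Mg = .data$env_low_Mg,
      pool_hi_Mg = .data$env_high_Mg,
      q_m3s = .data$q_mean_m3s,
      conc_ugL = .data$conc_ugL,
      load_Mg_yr = .data$load_Mg_yr,
      sink_pct = .data$fraction_pct,
      sink_lo_pct = .data$ci_low_pct,
      sink_hi_pct = .data$ci_high_pct
    ) |>
    dplyr::arrange(.data$site, .data$nutrient) |>
    structure(class = c("nutrient_budget", "tbl_df", "tbl", "data.frame"),
              aggregation = aggregation)
}
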