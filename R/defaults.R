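#' Load the package's default configuration
#'
#' Reads the YAML configuration shipped in `inst/extdata/defaults.yaml` (or a
#' user-supplied file with the same structure). The configuration carries the
#' year-length constant used for load integration and the default trait
#' synthesis values (mean, relative standard error, study count) for dry
#' biomass per area and tissue N/P content of free-floating macrophytes.
#'
#' The shipped trait values are calibrated synthetic stand-ins for a
#' literature synthesis; replace them with your own study records via
#' [synthesize_traits()] whenever primary data are available.
#'
#' @param path Optional path to a YAML file overriding the packaged defaults.
#' @return A list with elements `year_seconds` (numeric) and `traits`
#'   (named list of `mean`, `rel_se`, `n_studies` per trait).
#' @examples
#' cfg <- floatload_defaults()
#' cfg$traits$biomass_per_area$mean
#' @export
floatload_defaults <- function(path = NULL) {
  path <- path %||% system.file("extdata", "defaults.yaml", package = "floatload")
  if (!nzchar(path) || !file.exists(path)) {
    abort("defaults.yaml not found; is the package installed correctly?")
  }
  cfg <- yaml::read_yaml(path)
  stopifnot(is.numeric(cfg$year_seconds), cfg$year_seconds > 0)
  cfg
}

#' Default trait synthesis table
#'
#' Returns the packaged default traits as a trait-synthesis tibble in the same
#' shape produced by [synthesize_traits()], ready to feed into
#' [plant_nutrient_pool()] or [nutrient_budget()].
#'
#' @inheritParams floatload_defaults
#' @return A tibble with columns `trait`, `mean`, `se`, `rel_se`, `n_studies`,
#'   `se_degenerate`.
#' @examples
#' default_traits()
#' @export
default_traits <- function(path = NULL) {
  cfg <- floatload_defaults(path)
  purrr::imap_dfr(cfg$traits, function(tr, name) {
    tibble::tibble(
      trait = name,
      mean = tr$mean,
      se = tr$mean * tr$rel_se,
      rel_se = tr$rel_se,
      n_studies = as.integer(tr$n_studies),
      se_degenerate = FALSE
    )
  })
}

# Conversion constant: (m^3 s^-1) x (ug L^-1) -> Mg yr^-1 for a 365-day year.
# 31,536,000 s yr^-1 x 1e-9 Mg per (m^3 * ug L^-1) = 0.031536.
mg_per_q_conc <- function(year_seconds = 31536000) year_seconds * 1e-9

trait_levels <- c("biomass_per_area", "n_content", "p_content")
nutrient_levels <- c("P", "N")
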