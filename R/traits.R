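#' Synthesize plant trait values across literature studies
#'
#' Collapses per-study trait records (dry biomass per area, tissue nitrogen or
#' phosphorus content) into a cross-study mean with its standard error, one
#' row per trait. This is the "synthetic mean" that converts areal vegetation
#' cover into biomass and nutrient mass: uncertainty in the synthesis is
#' carried forward as the standard error of the mean across studies.
#'
#' @param records A data frame with columns `study_id` (character), `trait`
#'   (one of `"biomass_per_area"`, `"n_content"`, `"p_content"`) and `value`
#'   (kg dry weight m^-2 for biomass; dry-weight fraction for contents).
#'   Extra columns are ignored.
#' @param traits Optional character vector restricting which traits to
#'   synthesize; defaults to all traits present in `records`.
#' @return A tibble with one row per trait: `trait`, `mean`, `se` (sample
#'   standard deviation / sqrt(n)), `rel_se` (`se / mean`), `n_studies`, and
#'   `se_degenerate` (TRUE when only one study was available so the standard
#'   error collapses to zero; a warning is raised in that case).
#' @examples
#' recs <- tibble::tibble(
#'   study_id = c("a", "b", "c"),
#'   trait = "biomass_per_area",
#'   value = c(1, 2, 3)
#' )
#' synthesize_traits(recs) # mean 2, se 0.577
#' @export
synthesize_traits <- function(records, traits = NULL) {
  records <- check_trait_records(records)
  if (!is.null(traits)) {
    unknown <- setdiff(traits, trait_levels)
    if (length(unknown) > 0) {
      abort(paste0("unknown trait(s): ", paste(unknown, collapse = ", ")))
    }
    records <- dplyr::filter(records, .data$trait %in% traits)
    missing <- setdiff(traits, unique(records$trait))
    if (length(missing) > 0) {
      abort(paste0("no records for requested trait(s): ",
                   paste(missing, collapse = ", ")))
    }
  }
  if (nrow(records) == 0) abort("no trait records supplied")

  out <- records |>
    dplyr::group_by(.data$trait) |>
    dplyr::summarise(
      mean = mean(.data$value),
      se = if (dplyr::n() > 1) sd(.data$value) / sqrt(dplyr::n()) else 0,
      n_studies = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      rel_se = ifelse(.data$mean > 0, .data$se / .data$mean, 0),
      se_degenerate = .data$n_studies == 1L
    ) |>
    dplyr::select("trait", "mean", "se", "rel_se", "n_studies", "se_degenerate")

  if (any(out$se_degenerate)) {
    warn(paste0(
      "single-study synthesis for: ",
      paste(out$trait[out$se_degenerate], collapse = ", "),
      "; standard error reported as 0"
    ))
  }
  out
}

check_trait_records <- function(records) {
  records <- tibble::as_tibble(records)
  required <- c("study_id", "trait", "value")
  miss <- setdiff(required, names(records))
  if (length(miss) > 0) {
    abort(paste0("trait records missing column(s): ", paste(miss, collapse = ", ")))
  }
  bad_trait <- !records$trait %in% trait_levels
  if (any(bad_trait)) {
    abort(paste0("invalid trait value(s) in rows: ",
                 paste(which(bad_trait), collapse = ", ")))
  }
  if (any(!is.finite(records$value) | records$value <= 0)) {
    abort("trait values must be positive and finite")
  }
  content <- records$trait %in% c("n_content", "p_content")
  if (any(content & records$value >= 1)) {
    abort("tissue content must be a dry-weight fraction < 1")
  }
  records
}
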