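#' Run the end-to-end nutrient budget from input files
#'
#' Reads the vegetation, concentration and discharge tables, runs
#' [nutrient_budget()], and writes `budget.csv` plus a JSON run manifest
#' recording input checksums, the configuration used and the package
#' version — so a rerun on identical inputs yields identical result
#' checksums (the manifest's timestamp is informational and excluded from
#' that guarantee).
#'
#' Concentrations may be per-sample (`site`, `date`, `tp_ugL`, `tn_ugL`) or
#' pre-aggregated per site (`site`, `tp_ugL`, `tn_ugL`). A vegetation table
#' with no rows for a site means no floating plants were observed there: its
#' pools, and hence sink fractions, are zero.
#'
#' @param veg_path,conc_path,discharge_path Input CSV paths. The discharge
#'   table needs columns `site`, `q_mean_m3s`.
#' @param out_dir Output directory (created if needed).
#' @param traits_path Optional traits CSV run through [synthesize_traits()];
#'   defaults to the packaged calibration.
#' @param aggregation `"mean"` (default) or `"median"` concentration
#'   aggregation.
#' @param config_path Optional defaults YAML overriding the packaged one
#'   (year length, default traits).
#' @return Invisibly, a list with elements `budget` (the
#'   [nutrient_budget()] tibble) and `manifest` (named list).
#' @export
run_report <- function(veg_path, conc_path, discharge_path,
                       out_dir = ".", traits_path = NULL,
                       aggregation = c("mean", "median"),
                       config_path = NULL) {
  aggregation <- match.arg(aggregation)
  cfg <- floatload_defaults(config_path)

  veg <- read_vegetation(veg_path)
  conc <- read_concentration_any(conc_path)
  discharge <- read_checked_csv(
    discharge_path, c("site", "q_mean_m3s"),
    numeric_cols = "q_mean_m3s", nonneg_cols = "q_mean_m3s",
    what = "discharge"
  )
  traits <- if (is.null(traits_path)) {
    default_traits(config_path)
  } else {
    synthesize_traits(read_traits(traits_path))
  }

  budget <- nutrient_budget(veg, conc, discharge, traits = traits,
                            aggregation = aggregation,
                            year_seconds = cfg$year_seconds)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  budget_path <- file.path(out_dir, "budget.csv")
  readr::write_csv(as.data.frame(budget), budget_path)

  inputs <- c(vegetation = veg_path, concentrations = conc_path,
              discharge = discharge_path)
  if (!is.null(traits_path)) inputs <- c(inputs, traits = traits_path)
  manifest <- list(
    package_version = as.character(packageVersion("floatload")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    aggregation = aggregation,
    year_seconds = cfg$year_seconds,
    traits = as.data.frame(traits),
    inputs = lapply(seq_along(inputs), function(i) {
      list(role = names(inputs)[i], path = unname(inputs[i]),
           md5 = unname(tools::md5sum(inputs[i])))
    }),
    outputs = list(list(path = budget_path,
                        md5 = unname(tools::md5sum(budget_path))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(budget = budget, manifest = manifest))
}

# accepts per-sample (with date) or pre-aggregated per-site concentrations
read_concentration_any <- function(path) {
  probe <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                           comment = "#", n_max = 0)
  if ("date" %in% names(probe)) {
    read_concentrations(path)
  } else {
    read_checked_csv(path, c("site", "tp_ugL", "tn_ugL"),
                     numeric_cols = c("tp_ugL", "tn_ugL"),
                     nonneg_cols = c("tp_ugL", "tn_ugL"),
                     what = "concentrations")
  }
}
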