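# CSV readers with strict schema validation. Files are UTF-8, "." decimal,
# ISO-8601 dates; unknown columns are preserved; malformed rows are reported
# with their line numbers (header = line 1).

read_checked_csv <- function(path, required, numeric_cols = character(),
                             nonneg_cols = character(),
                             date_cols = character(), what = "table") {
  if (!file.exists(path)) abort(paste0(what, " file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        comment = "#")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    abort(paste0(path, ": missing required column(s): ",
                 paste(miss, collapse = ", ")))
  }
  bad_lines <- integer()
  for (col in numeric_cols) {
    vals <- df[[col]]
    if (!is.numeric(vals)) {
      suppressWarnings(conv <- as.numeric(vals))
      bad_lines <- c(bad_lines, which(is.na(conv) & !is.na(vals)) + 1L)
      df[[col]] <- conv
    }
    bad_lines <- c(bad_lines, which(is.na(df[[col]])) + 1L)
  }
  for (col in nonneg_cols) {
    bad_lines <- c(bad_lines, which(!is.na(df[[col]]) & df[[col]] < 0) + 1L)
  }
  for (col in date_cols) {
    if (!inherits(df[[col]], "Date")) {
      conv <- as.Date(as.character(df[[col]]), format = "%Y-%m-%d")
      bad_lines <- c(bad_lines, which(is.na(conv)) + 1L)
      df[[col]] <- conv
    }
  }
  bad_lines <- sort(unique(bad_lines))
  if (length(bad_lines) > 0) {
    abort(paste0(path, ": malformed value(s) at line(s) ",
                 paste(bad_lines, collapse = ", ")))
  }
  df
}

#' Read pipeline input tables
#'
#' Strict CSV readers for each input schema. All insist on their required
#' columns (erroring with the column name), preserve unknown columns, and
#' report malformed or negative values with the offending line numbers.
#' Lines starting with `#` are treated as comments.
#'
#' * `read_traits()`: `study_id`, `trait`, `value`
#' * `read_concentrations()`: `site`, `date`, `tp_ugL`, `tn_ugL`
#' * `read_vegetation()`: `site`, `area_km2` (optional `date`, `basis`)
#' * `read_gauges()`: `station_id`, `catchment_area_km2`, `q_mean_m3s`
#' * `read_hydrograph()`: `year`, `month`, `value` (optional `kind`)
#' * `read_cover()`: `site`, `date`, `cover_km2` (optional `sensor`)
#' * `read_periods()`: `label`, `start_year`, `end_year`
#'
#' @param path Path to a CSV file.
#' @return A tibble with the validated schema.
#' @name readers
NULL

#' @rdname readers
#' @export
read_traits <- function(path) {
  df <- read_checked_csv(path, c("study_id", "trait", "value"),
                         numeric_cols = "value", what = "traits")
  check_trait_records(df)
}

#' @rdname readers
#' @export
read_concentrations <- function(path) {
  read_checked_csv(path, c("site", "date", "tp_ugL", "tn_ugL"),
                   numeric_cols = c("tp_ugL", "tn_ugL"),
                   nonneg_cols = c("tp_ugL", "tn_ugL"),
                   date_cols = "date", what = "concentrations")
}

#' @rdname readers
#' @export
read_vegetation <- function(path) {
  read_checked_csv(path, c("site", "area_km2"),
                   numeric_cols = "area_km2", nonneg_cols = "area_km2",
                   what = "vegetation")
}

#' @rdname readers
#' @export
read_gauges <- function(path) {
  read_checked_csv(path, c("station_id", "catchment_area_km2", "q_mean_m3s"),
                   numeric_cols = c("catchment_area_km2", "q_mean_m3s"),
                   nonneg_cols = c("catchment_area_km2", "q_mean_m3s"),
                   what = "gauges")
}

#' @rdname readers
#' @export
read_hydrograph <- function(path) {
  df <- read_checked_csv(path, c("year", "month", "value"),
                         numeric_cols = c("year", "month", "value"),
                         nonneg_cols = "value", what = "hydrograph")
  check_monthly_series(df)
}

#' @rdname readers
#' @export
read_cover <- function(path) {
  df <- read_checked_csv(path, c("site", "date", "cover_km2"),
                         numeric_cols = "cover_km2", nonneg_cols = "cover_km2",
                         date_cols = "date", what = "cover")
  check_cover_obs(df)
}

#' @rdname readers
#' @export
read_periods <- function(path) {
  read_checked_csv(path, c("label", "start_year", "end_year"),
                   numeric_cols = c("start_year", "end_year"),
                   what = "periods")
}

#' Read and write Esri ASCII grids
#'
#' Minimal reader/writer for single-band Esri ASCII-grid rasters
#' (`ncols`/`nrows`/`xllcorner`/`yllcorner`/`cellsize` header, row-major
#' values from the upper-left). Square pixels only. `NODATA_value` cells
#' become `NA`.
#'
#' @param path File path.
#' @param class_name Class label attached to the returned grid.
#' @param as_mask Read as a logical [catchment_mask()] (nonzero = member)
#'   instead of a [fraction_grid()].
#' @param outlet Optional `(row, col)` outlet when reading a mask.
#' @return `read_ascii_grid()` returns a [fraction_grid()] or
#'   [catchment_mask()]; `write_ascii_grid()` returns `path` invisibly.
#' @export
read_ascii_grid <- function(path, class_name = "other", as_mask = FALSE,
                            outlet = NULL) {
  if (!file.exists(path)) abort(paste0("grid file not found: ", path))
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss) > 0) {
    abort(paste0(path, ": ASCII grid header missing ",
                 paste(miss, collapse = ", ")))
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    abort(sprintf("%s: expected %d values, found %d", path,
                  hdr$ncols * hdr$nrows, length(vals)))
  }
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (as_mask) {
    catchment_mask(!is.na(m) & m != 0, hdr$cellsize, outlet = outlet)
  } else {
    fraction_grid(m, hdr$cellsize, class_name)
  }
}

#' @rdname read_ascii_grid
#' @param grid A [fraction_grid()] or [catchment_mask()] to write.
#' @export
write_ascii_grid <- function(grid, path) {
  v <- grid$values
  if (is.logical(v)) v <- v * 1
  v[is.na(v)] <- -9999
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    "xllcorner 0",
    "yllcorner 0",
    sprintf("cellsize %.10g", grid$pixel_size_m),
    "NODATA_value -9999"
  )
  body <- apply(v, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a scenario's synthetic inputs to a directory
#'
#' Materialises every generator of a [scenario_config()] as the CSV/ASCII
#' files the pipeline reads: `traits.csv`, `gauges.csv`, `cover.csv`,
#' `concentrations.csv`, `urban.asc`, `mask.asc`.
#'
#' @param cfg A [scenario_config()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_scenario_data <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(gen_trait_records(cfg), file.path(dir, "traits.csv"))
  readr::write_csv(gen_gauges(cfg), file.path(dir, "gauges.csv"))
  readr::write_csv(gen_cover_series(cfg), file.path(dir, "cover.csv"))
  readr::write_csv(gen_concentration_samples(cfg),
                   file.path(dir, "concentrations.csv"))
  lc <- gen_landcover(cfg)
  write_ascii_grid(lc$grid, file.path(dir, "urban.asc"))
  write_ascii_grid(lc$mask, file.path(dir, "mask.asc"))
  invisible(dir)
}

#' Write the Zambezi demo bundle to a directory
#'
#' Emits [zambezi_demo()] as `vegetation.csv`, `discharge.csv`,
#' `concentrations_mean.csv` and `landcover.csv` (deterministic).
#'
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_zambezi_demo <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  demo <- zambezi_demo()
  readr::write_csv(demo$vegetation, file.path(dir, "vegetation.csv"))
  readr::write_csv(demo$discharge, file.path(dir, "discharge.csv"))
  readr::write_csv(demo$concentrations,
                   file.path(dir, "concentrations_mean.csv"))
  readr::write_csv(demo$landcover, file.path(dir, "landcover.csv"))
  invisible(dir)
}
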