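#' Fractional landcover grid
#'
#' A light container for a single-class fractional landcover layer: a numeric
#' matrix of per-pixel class fractions in `[0, 1]`, row-major with the origin
#' at the upper-left, plus the pixel size. Pixel centres sit at
#' `(row - 0.5, col - 0.5) * pixel_size_m` from the upper-left corner.
#'
#' @param values Numeric matrix of fractions in `[0, 1]`.
#' @param pixel_size_m Pixel edge length in metres (> 0).
#' @param class_name Class label, e.g. `"urban"`, `"cropland"`, `"other"`.
#' @return An object of class `fraction_grid`.
#' @examples
#' g <- fraction_grid(matrix(runif(100), 10, 10), 100, "urban")
#' @export
fraction_grid <- function(values, pixel_size_m, class_name = "other") {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("values must be a numeric matrix")
  }
  if (any(values < 0 | values > 1, na.rm = TRUE)) {
    abort("fractions must lie in [0, 1]")
  }
  if (!is.finite(pixel_size_m) || pixel_size_m <= 0) {
    abort("pixel_size_m must be > 0")
  }
  structure(
    list(values = values, pixel_size_m = pixel_size_m,
         class_name = class_name),
    class = "fraction_grid"
  )
}

#' Catchment membership mask
#'
#' A logical matrix marking which pixels of a companion [fraction_grid()]
#' fall inside a catchment, plus the outlet pixel used for distance
#' calculations.
#'
#' @param values Logical matrix; at least one `TRUE` pixel.
#' @param pixel_size_m Pixel edge length in metres (must match companion
#'   grids).
#' @param outlet Integer `(row, col)` of the catchment outlet pixel.
#' @return An object of class `catchment_mask`.
#' @export
catchment_mask <- function(values, pixel_size_m, outlet = NULL) {
  if (!is.matrix(values) || !is.logical(values)) {
    abort("mask values must be a logical matrix")
  }
  if (!any(values)) abort("mask must contain at least one member pixel")
  if (!is.finite(pixel_size_m) || pixel_size_m <= 0) {
    abort("pixel_size_m must be > 0")
  }
  if (!is.null(outlet)) {
    outlet <- as.integer(outlet)
    if (length(outlet) != 2 || outlet[1] < 1 || outlet[1] > nrow(values) ||
        outlet[2] < 1 || outlet[2] > ncol(values)) {
      abort("outlet must be a (row, col) pair inside the grid")
    }
  }
  structure(
    list(values = values, pixel_size_m = pixel_size_m, outlet = outlet),
    class = "catchment_mask"
  )
}

#' @export
print.fraction_grid <- function(x, ...) {
  cat(sprintf("fraction_grid '%s': %d x %d pixels @ %g m\n",
              x$class_name, nrow(x$values), ncol(x$values), x$pixel_size_m))
  invisible(x)
}

#' @export
print.catchment_mask <- function(x, ...) {
  cat(sprintf("catchment_mask: %d x %d pixels @ %g m, %d member pixels\n",
              nrow(x$values), ncol(x$values), x$pixel_size_m,
              sum(x$values)))
  invisible(x)
}

check_same_shape <- function(grid, mask) {
  if (!identical(dim(grid$values), dim(mask$values))) {
    abort(sprintf("shape mismatch: grid %dx%d vs mask %dx%d",
                  nrow(grid$values), ncol(grid$values),
                  nrow(mask$values), ncol(mask$values)))
  }
  if (!isTRUE(all.equal(grid$pixel_size_m, mask$pixel_size_m))) {
    abort("pixel sizes differ between grid and mask")
  }
  invisible(TRUE)
}

#' Thresholded class area within a catchment
#'
#' Area of a landcover class inside a catchment, counting member pixels whose
#' class fraction strictly exceeds the threshold (default 50%):
#' `area = count * pixel_size_m^2 * 1e-6` km^2. The strict inequality means
#' pixels at exactly the threshold do not count.
#'
#' @param grid A [fraction_grid()].
#' @param mask A [catchment_mask()] of the same shape.
#' @param threshold Fraction threshold in `[0, 1)`; default 0.5.
#' @return Class area in km^2.
#' @examples
#' v <- matrix(0, 10, 10); v[1, 1:7] <- 0.6
#' g <- fraction_grid(v, 100, "urban")
#' m <- catchment_mask(matrix(TRUE, 10, 10), 100)
#' class_area(g, m) # 0.07 km^2
#' @export
class_area <- function(grid, mask, threshold = 0.5) {
  stopifnot(inherits(grid, "fraction_grid"), inherits(mask, "catchment_mask"))
  check_same_shape(grid, mask)
  if (!is.finite(threshold) || threshold < 0 || threshold >= 1) {
    abort("threshold must lie in [0, 1)")
  }
  n <- sum(mask$values & grid$values > threshold, na.rm = TRUE)
  n * grid$pixel_size_m^2 * 1e-6
}

#' Class area as a percentage of catchment area
#'
#' @param class_area_km2 Thresholded class area (km^2), from [class_area()]
#'   or a published table.
#' @param catchment_area_km2 Total catchment area (km^2), > 0.
#' @return Percentage `100 * class / catchment`.
#' @examples
#' class_ratio(204.2, 5128) # 4.0 %
#' @export
class_ratio <- function(class_area_km2, catchment_area_km2) {
  if (any(!is.finite(catchment_area_km2) | catchment_area_km2 <= 0)) {
    abort("catchment_area_km2 must be > 0")
  }
  if (any(class_area_km2 < 0)) abort("class_area_km2 must be >= 0")
  100 * class_area_km2 / catchment_area_km2
}

#' Straight-line distance from a catchment outlet to the nearest urban pixel
#'
#' Euclidean distance (km) between the outlet pixel centre and the centre of
#' the nearest pixel whose urban fraction strictly exceeds the threshold.
#' Returns `NA` when no pixel qualifies (no urban cover in the layer).
#'
#' @param mask A [catchment_mask()] carrying the outlet.
#' @param urban_grid A [fraction_grid()] of the same shape.
#' @param threshold Urban-fraction threshold; default 0.5.
#' @return Distance in km, or `NA_real_` when no urban pixel exists.
#' @export
distance_to_nearest_urban <- function(mask, urban_grid, threshold = 0.5) {
  stopifnot(inherits(mask, "catchment_mask"),
            inherits(urban_grid, "fraction_grid"))
  check_same_shape(urban_grid, mask)
  if (is.null(mask$outlet)) abort("mask carries no outlet pixel")
  hits <- which(urban_grid$values > threshold, arr.ind = TRUE)
  if (nrow(hits) == 0) return(NA_real_)
  d2 <- (hits[, 1] - mask$outlet[1])^2 + (hits[, 2] - mask$outlet[2])^2
  sqrt(min(d2)) * mask$pixel_size_m / 1000
}

#' Per-catchment landcover summary table
#'
#' Convenience wrapper producing one row per class: thresholded area and its
#' ratio to the catchment area (taken as the mask's member-pixel area).
#'
#' @param grids Named list of [fraction_grid()] objects (names are class
#'   labels).
#' @param mask A [catchment_mask()].
#' @param catchment Catchment label for the output.
#' @param threshold Fraction threshold; default 0.5.
#' @return A tibble: `catchment`, `class`, `area_km2`, `ratio_pct`.
#' @export
landcover_table <- function(grids, mask, catchment = "catchment",
                            threshold = 0.5) {
  total <- sum(mask$values) * mask$pixel_size_m^2 * 1e-6
  purrr::imap_dfr(grids, function(g, nm) {
    a <- class_area(g, mask, threshold)
    tibble::tibble(catchment = catchment, class = nm, area_km2 = a,
                   ratio_pct = class_ratio(a, total))
  })
}
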