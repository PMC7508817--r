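# Independent brute-force oracles, deliberately written with explicit loops
# and first-principles formulas so they share no code path with the package.

oracle_mean_se <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  ss <- 0
  for (v in x) ss <- ss + (v - m)^2
  list(mean = m, se = if (n > 1) sqrt(ss / (n - 1)) / sqrt(n) else 0)
}

oracle_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# log-log least squares from explicit sums
oracle_loglog_fit <- function(area, q) {
  x <- log(area); y <- log(q); n <- length(x)
  sx <- sum(x); sy <- sum(y)
  b <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  a <- exp((sy - b * sx) / n)
  list(a = a, b = b)
}

# per-(year, bin) maximum by exhaustive scan
oracle_bin_max <- function(dates, cover) {
  yr <- as.integer(format(dates, "%Y"))
  bin <- (as.integer(format(dates, "%m")) + 1L) %/% 2L
  out <- list()
  for (y in sort(unique(yr))) {
    for (b in 1:6) {
      sel <- yr == y & bin == b
      if (any(sel)) {
        out[[length(out) + 1]] <- data.frame(year = y, bin = b,
                                             max_cover = max(cover[sel]))
      }
    }
  }
  do.call(rbind, out)
}

# per-year argmax month, earliest month on ties
oracle_peaks <- function(year, month, value) {
  out <- list()
  for (y in sort(unique(year))) {
    sel <- year == y
    best <- max(value[sel])
    out[[length(out) + 1]] <- data.frame(
      year = y, peak_month = min(month[sel][value[sel] == best])
    )
  }
  do.call(rbind, out)
}

# thresholded pixel count by double loop
oracle_class_area <- function(vals, mask, pixel_m, threshold) {
  count <- 0
  for (i in seq_len(nrow(vals))) {
    for (j in seq_len(ncol(vals))) {
      if (mask[i, j] && vals[i, j] > threshold) count <- count + 1
    }
  }
  count * pixel_m^2 * 1e-6
}

# all-pairs nearest urban pixel from the outlet
oracle_nearest_urban_km <- function(vals, outlet, pixel_m, threshold) {
  best <- Inf
  for (i in seq_len(nrow(vals))) {
    for (j in seq_len(ncol(vals))) {
      if (vals[i, j] > threshold) {
        d <- sqrt((i - outlet[1])^2 + (j - outlet[2])^2)
        if (d < best) best <- d
      }
    }
  }
  if (is.infinite(best)) NA_real_ else best * pixel_m / 1000
}

# sink fraction from first principles
oracle_sink_pct <- function(pool_Mg, load_Mg_yr) {
  100 * pool_Mg / (pool_Mg + load_Mg_yr)
}

demo_traits <- function() default_traits()
trait_row <- function(traits, name) traits[traits$trait == name, ]
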