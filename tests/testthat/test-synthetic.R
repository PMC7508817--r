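test_that("generators are pure functions of the scenario seed", {
  cfg <- scenario_config(seed = 42)
  expect_identical(gen_trait_records(cfg), gen_trait_records(cfg))
  expect_identical(gen_gauges(cfg), gen_gauges(cfg))
  expect_identical(gen_cover_series(cfg), gen_cover_series(cfg))
  expect_identical(gen_concentration_samples(cfg),
                   gen_concentration_samples(cfg))
  l1 <- gen_landcover(cfg)
  l2 <- gen_landcover(cfg)
  expect_identical(l1$grid$values, l2$grid$values)

  # different seeds give different draws
  other <- scenario_config(seed = 43)
  expect_false(identical(gen_gauges(cfg)$q_mean_m3s,
                         gen_gauges(other)$q_mean_m3s))
  # generators do not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(gen_trait_records(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("generated data satisfies the consuming types' invariants", {
  cfg <- scenario_config(seed = 8)
  tr <- gen_trait_records(cfg)
  expect_true(all(tr$value > 0))
  expect_true(all(tr$value[tr$trait != "biomass_per_area"] < 1))
  expect_equal(nrow(tr), 15 + 17 + 14)

  g <- gen_gauges(cfg)
  expect_true(all(g$catchment_area_km2 > 0 & g$q_mean_m3s > 0))

  cov <- gen_cover_series(cfg)
  expect_true(all(cov$cover_km2 >= 0))
  expect_true(all(format(cov$date, "%d") == "15"))

  cs <- gen_concentration_samples(cfg)
  expect_true(all(cs$tp_ugL >= 0 & cs$tn_ugL >= 0))
  expect_equal(nrow(cs), 4)

  lc <- gen_landcover(cfg)
  expect_true(all(lc$grid$values >= 0 & lc$grid$values <= 1))
  expect_true(any(lc$mask$values))
})

test_that("trait synthesis recovers generator truth", {
  # zero spread: every record equals the truth, recovery is exact
  exact <- scenario_config(
    seed = 2,
    traits = list(rel_sd = c(biomass_per_area = 0, p_content = 0,
                             n_content = 0))
  )
  syn <- synthesize_traits(gen_trait_records(exact))
  expect_equal(syn$mean[syn$trait == "biomass_per_area"], 2.0)
  expect_equal(syn$mean[syn$trait == "p_content"], 0.004836)
  expect_equal(syn$se, rep(0, 3))

  # sampling-distribution check: the mean of 200 replicate synthesized means
  # sits within 2 standard errors of the truth
  means <- vapply(1:200, function(r) {
    recs <- gen_trait_records(scenario_config(seed = 5000 + r))
    syn <- synthesize_traits(recs)
    syn$mean[syn$trait == "biomass_per_area"]
  }, numeric(1))
  se_of_mean <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 2.0), 2 * se_of_mean + 1e-9)
})

test_that("cover generator seasonality is recoverable by the peaks pipeline", {
  # zero noise: the within-year argmax is exactly the configured peak month
  quiet <- scenario_config(seed = 3, cover = list(noise_sdlog = 0,
                                                  n_years = 20L))
  pk <- annual_peaks(
    gen_cover_series(quiet) |>
      dplyr::transmute(year = as.integer(format(date, "%Y")),
                       month = as.integer(format(date, "%m")),
                       value = cover_km2)
  )
  expect_equal(pk$peak_month, rep(4L, 20))
  hist <- peak_month_histogram(pk)
  expect_equal(hist$n[4], 20L)
  expect_equal(sum(hist$n), 20L)

  # moderate noise still concentrates histogram mass at the configured month
  noisy <- scenario_config(seed = 3, cover = list(n_years = 20L))
  pk2 <- annual_peaks(
    gen_cover_series(noisy) |>
      dplyr::transmute(year = as.integer(format(date, "%Y")),
                       month = as.integer(format(date, "%m")),
                       value = cover_km2)
  )
  h2 <- peak_month_histogram(pk2)
  expect_gte(sum(h2$n[3:5]), 0.9 * sum(h2$n))

  # the flush collapses cover after the peak
  series <- gen_cover_series(quiet)
  m <- as.integer(format(series$date, "%m"))
  expect_lt(mean(series$cover_km2[m == 7]), mean(series$cover_km2[m == 5]))
})

test_that("outlier-free concentration samples have mean near median", {
  clean <- scenario_config(
    seed = 6,
    concentration = list(outlier_prob = 0, noise_sdlog = 0,
                         tp_quarter_means = rep(30, 4),
                         tn_quarter_means = rep(700, 4))
  )
  s <- gen_concentration_samples(clean)
  agg_mean <- aggregate_concentration(s, "mean")
  agg_med <- aggregate_concentration(s, "median")
  expect_equal(agg_mean$conc_ugL, agg_med$conc_ugL, tolerance = 1e-12)
})

test_that("landcover generator produces the configured blob structure", {
  # a single blob of 7 pixels at 0.6 on a zero background
  cfg <- scenario_config(
    seed = 12,
    landcover = list(background_fraction = 0,
                     blobs = list(class = "urban", n = 1L, height = 1L,
                                  width = 7L, fraction = 0.6),
                     mask_rows = c(1L, 40L), mask_cols = c(1L, 40L))
  )
  lc <- gen_landcover(cfg)
  expect_equal(class_area(lc$grid, lc$mask), 7 * 100^2 * 1e-6)
  expect_equal(sum(lc$grid$values > 0.5), 7)
})

test_that("scenario configuration validates its parameters", {
  expect_error(scenario_config(gauges = list(n = 1L)), "invalid gauge")
  expect_error(scenario_config(cover = list(peak_month = 13L)), "1..12")
  expect_error(scenario_config(concentration = list(outlier_prob = 2)),
               "outlier_prob")
  expect_error(
    scenario_config(traits = list(n_studies = c(biomass_per_area = 1L,
                                                p_content = 17L,
                                                n_content = 14L))),
    ">= 2"
  )
})

test_that("the demo bundle regenerates the published loads and sinks", {
  demo <- zambezi_demo()
  # deterministic emission
  expect_identical(zambezi_demo(), demo)

  # all eight load cells match the published table within last-digit rounding
  b <- nutrient_budget(demo$vegetation, demo$concentrations, demo$discharge)
  printed <- tibble::tribble(
    ~site,            ~nutrient, ~load, ~tol,
    "kafue",          "P",       227,   1,
    "kafue",          "N",       9014,  1,
    "chongwe",        "P",       5.6,   0.1,
    "chongwe",        "N",       119,   1,
    "little_chongwe", "P",       0.9,   0.1,
    "little_chongwe", "N",       39,    1,
    "maramba",        "P",       1.9,   0.1,
    "maramba",        "N",       43,    1
  )
  joined <- dplyr::inner_join(tibble::as_tibble(b), printed,
                              by = c("site", "nutrient"))
  expect_equal(nrow(joined), 8)
  expect_true(all(abs(joined$load_Mg_yr - joined$load) <= joined$tol))

  # landcover ratios recompute from the bundle's printed areas
  lc <- demo$landcover
  ratios <- class_ratio(lc$urban_area_km2, lc$catchment_area_km2)
  expect_equal(round(ratios[lc$catchment == "chongwe"], 1), 4.0)
  expect_equal(round(ratios[lc$catchment == "maramba"], 1), 6.2)
})
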