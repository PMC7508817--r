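# Reference values used throughout: the four Zambezi study catchments, whose
# printed discharges, concentrations, pools and sink fractions the pipeline
# must reproduce.

test_that("plant nutrient pool converts area through biomass and content", {
  tr <- demo_traits()
  bio <- trait_row(tr, "biomass_per_area")
  pc <- trait_row(tr, "p_content")
  nc <- trait_row(tr, "n_content")

  # 5.5 km2 at 2.0 kg/m2 and 0.4836% P -> 53.2 Mg P (9.67 g P m^-2)
  p_kafue <- plant_nutrient_pool(5.5, bio, pc)
  expect_equal(p_kafue$mass_Mg, 53.196, tolerance = 1e-9)
  expect_equal(p_kafue$nutrient, "P")

  n_kafue <- plant_nutrient_pool(5.5, bio, nc)
  expect_equal(n_kafue$mass_Mg, 263.01, tolerance = 1e-9)

  # 0.087 km2 -> 0.84 Mg P (rounds to the printed 0.8)
  p_maramba <- plant_nutrient_pool(0.087, bio, pc)
  expect_equal(p_maramba$mass_Mg, 0.087 * 9.672, tolerance = 1e-9)
  expect_equal(round(p_maramba$mass_Mg, 1), 0.8)

  zero <- plant_nutrient_pool(0, bio, pc)
  expect_equal(zero$mass_Mg, 0)
  expect_equal(zero$env_low_Mg, 0)
  expect_equal(zero$env_high_Mg, 0)

  expect_error(plant_nutrient_pool(1, pc, pc), "trait mismatch")
  expect_error(plant_nutrient_pool(1, bio, bio), "trait mismatch")
  expect_error(plant_nutrient_pool(-1, bio, pc), ">= 0")
})

test_that("compound envelope brackets the estimate and collapses at zero", {
  point <- compound_envelope(53.2, 0, 0)
  expect_equal(point$env_low_Mg, 53.2)
  expect_equal(point$env_high_Mg, 53.2)

  set.seed(7)
  for (i in 1:25) {
    m <- runif(1, 0, 100)
    a <- runif(1, 0, 0.9)
    b <- runif(1, 0, 0.9)
    env <- compound_envelope(m, a, b)
    expect_lte(env$env_low_Mg, m)
    expect_gte(env$env_high_Mg, m)
    # width grows with each relative SE
    wider <- compound_envelope(m, min(a + 0.05, 0.95), b)
    expect_gte(wider$env_high_Mg - wider$env_low_Mg,
               env$env_high_Mg - env$env_low_Mg)
  }

  expect_error(compound_envelope(10, -0.1, 0), "\\[0, 1\\)")
  expect_error(compound_envelope(10, 0, 1), "\\[0, 1\\)")
})

test_that("concentration aggregation matches direct arithmetic and a sort oracle", {
  s <- tibble::tibble(tp_ugL = c(10, 20, 30, 1000), tn_ugL = c(5, 5, 5, 5))
  m <- aggregate_concentration(s, "mean")
  expect_equal(m$conc_ugL[m$nutrient == "P"], 265)
  md <- aggregate_concentration(s, "median")
  expect_equal(md$conc_ugL[md$nutrient == "P"], 25)

  one <- tibble::tibble(tp_ugL = 12.5, tn_ugL = 300)
  expect_equal(aggregate_concentration(one, "mean")$conc_ugL,
               aggregate_concentration(one, "median")$conc_ugL)

  set.seed(11)
  tp <- rlnorm(8, log(20), 0.4)
  tp[3] <- tp[3] * 10 # outlier
  s2 <- tibble::tibble(tp_ugL = tp, tn_ugL = rlnorm(8, log(500), 0.3))
  expect_equal(aggregate_concentration(s2, "median")$conc_ugL[1],
               oracle_median(tp))
  expect_equal(aggregate_concentration(s2, "mean")$conc_ugL[1],
               sum(tp) / length(tp))

  expect_error(aggregate_concentration(s[0, ], "mean"), "no concentration")
})

test_that("annual load reproduces the published per-catchment loads", {
  # (site, Q m3/s, TP ug/L, TN ug/L, printed TP load, printed TN load)
  tab <- tibble::tribble(
    ~q,   ~tp,  ~tn, ~tp_load, ~tp_tol, ~tn_load, ~tn_tol,
    989,  7.3,  289, 227,      1,       9014,     1,
    11.4, 15.6, 333, 5.6,      0.1,     119,      1,
    1.9,  14.1, 642, 0.9,      0.1,     39,       1,
    1.9,  32.4, 718, 1.9,      0.1,     43,       1
  )
  for (i in seq_len(nrow(tab))) {
    lp <- annual_load(tab$q[i], tab$tp[i], "P")
    ln <- annual_load(tab$q[i], tab$tn[i], "N")
    # within one unit in the last printed digit
    expect_lte(abs(lp$load_Mg_yr - tab$tp_load[i]), tab$tp_tol[i])
    expect_lte(abs(ln$load_Mg_yr - tab$tn_load[i]), tab$tn_tol[i])
    # internal consistency invariant
    expect_equal(lp$load_Mg_yr, lp$q_mean_m3s * lp$conc_ugL * 0.031536)
  }
  expect_equal(annual_load(989, 289, "N")$load_Mg_yr, 9013.6, tolerance = 1e-4)
  expect_equal(annual_load(0, 500, "P")$load_Mg_yr, 0)
  expect_error(annual_load(-1, 10, "P"), ">= 0")
  expect_error(annual_load(1, -10, "P"), ">= 0")
})

test_that("annual load is bilinear in discharge and concentration", {
  set.seed(3)
  for (i in 1:10) {
    q <- runif(1, 0.1, 1000)
    cc <- runif(1, 1, 800)
    base <- annual_load(q, cc, "N")$load_Mg_yr
    expect_equal(annual_load(2 * q, cc, "N")$load_Mg_yr, 2 * base)
    expect_equal(annual_load(q, 2 * cc, "N")$load_Mg_yr, 2 * base)
  }
})

test_that("sink fraction reproduces the published plant-sink percentages", {
  mk_pool <- function(nu, m, lo = m, hi = m) {
    tibble::tibble(nutrient = nu, mass_Mg = m, env_low_Mg = lo,
                   env_high_Mg = hi)
  }
  # printed pools and loads
  expect_equal(
    sink_fraction(mk_pool("P", 53.2),
                  annual_load(989, 7.3, "P"))$fraction_pct,
    19.0, tolerance = 0.01
  )
  expect_equal(
    sink_fraction(mk_pool("N", 263),
                  annual_load(989, 289, "N"))$fraction_pct,
    2.8, tolerance = 0.02
  )
  expect_equal(
    sink_fraction(mk_pool("N", 4.2),
                  tibble::tibble(nutrient = "N", load_Mg_yr = 43))$fraction_pct,
    8.9, tolerance = 0.01
  )
  # zero pool -> 0 %
  z <- sink_fraction(mk_pool("P", 0, 0, 0),
                     tibble::tibble(nutrient = "P", load_Mg_yr = 10))
  expect_equal(z$fraction_pct, 0)

  expect_error(
    sink_fraction(mk_pool("P", 1),
                  tibble::tibble(nutrient = "N", load_Mg_yr = 1)),
    "mismatch"
  )
  expect_error(
    sink_fraction(mk_pool("P", 0, 0, 0),
                  tibble::tibble(nutrient = "P", load_Mg_yr = 0)),
    "undefined"
  )
})

test_that("sink fraction is monotone, bounded, and conserves total export", {
  mk_pool <- function(m) tibble::tibble(nutrient = "P", mass_Mg = m,
                                        env_low_Mg = m, env_high_Mg = m)
  mk_load <- function(l) tibble::tibble(nutrient = "P", load_Mg_yr = l)
  set.seed(5)
  for (i in 1:20) {
    m <- runif(1, 0.01, 100)
    l <- runif(1, 0.01, 1000)
    f <- sink_fraction(mk_pool(m), mk_load(l))$fraction_pct
    expect_gte(f, 0); expect_lte(f, 100)
    expect_gt(sink_fraction(mk_pool(m * 1.1), mk_load(l))$fraction_pct, f)
    expect_lt(sink_fraction(mk_pool(m), mk_load(l * 1.1))$fraction_pct, f)
    # plant and water shares sum to 100% of total export
    water <- 100 * l / (m + l)
    expect_equal(f + water, 100, tolerance = 1e-9)
    expect_equal(f, oracle_sink_pct(m, l), tolerance = 1e-12)
  }
})

test_that("mean-vs-median sensitivity matches brute-force recomputation", {
  tr <- demo_traits()
  pool <- dplyr::bind_rows(
    plant_nutrient_pool(0.087, trait_row(tr, "biomass_per_area"),
                        trait_row(tr, "p_content")),
    plant_nutrient_pool(0.087, trait_row(tr, "biomass_per_area"),
                        trait_row(tr, "n_content"))
  )
  # all samples equal -> no sensitivity
  flat <- tibble::tibble(tp_ugL = rep(30, 4), tn_ugL = rep(700, 4))
  out <- sensitivity_mean_vs_median(flat, pool, 1.9)
  expect_equal(out$delta_pct_points, c(0, 0), tolerance = 1e-12)

  # symmetric samples (mean = median) -> zero delta
  sym <- tibble::tibble(tp_ugL = c(10, 20, 30, 40), tn_ugL = c(1, 2, 3, 4))
  expect_equal(sensitivity_mean_vs_median(sym, pool, 1.9)$delta_pct_points,
               c(0, 0), tolerance = 1e-12)

  # outlier-bearing series equals independent recomputation
  set.seed(19)
  cfg <- scenario_config(seed = 19,
                         concentration = list(outlier_prob = 0.25))
  samples <- gen_concentration_samples(cfg)
  out <- sensitivity_mean_vs_median(samples, pool, 1.9)
  for (nu in c("P", "N")) {
    col <- if (nu == "P") samples$tp_ugL else samples$tn_ugL
    p <- pool$mass_Mg[pool$nutrient == nu]
    f_mean <- oracle_sink_pct(p, 1.9 * (sum(col) / length(col)) * 0.031536)
    f_med <- oracle_sink_pct(p, 1.9 * oracle_median(col) * 0.031536)
    expect_equal(out$delta_pct_points[out$nutrient == nu], f_mean - f_med,
                 tolerance = 1e-12)
  }
})

test_that("monte-carlo propagation agrees with the analytic envelope", {
  # independent normal draws on the two traits, propagated through
  # pool -> sink fraction; mean +/- 1 sd of the simulated fractions must sit
  # within 1 percentage point of the analytic envelope for rel-SE <= 0.15
  cases <- list(c(0.13, 0.076), c(0.10, 0.10), c(0.15, 0.05))
  mass <- 53.196; load <- 227.6805
  for (cs in cases) {
    a <- cs[1]; b <- cs[2]
    env <- compound_envelope(mass, a, b)
    analytic <- c(oracle_sink_pct(env$env_low_Mg, load),
                  oracle_sink_pct(env$env_high_Mg, load))
    set.seed(97)
    n <- 1e5
    draws <- mass * rnorm(n, 1, a) * rnorm(n, 1, b)
    frac <- oracle_sink_pct(draws, load)
    mc <- c(mean(frac) - sd(frac), mean(frac) + sd(frac))
    expect_lt(abs(mc[1] - analytic[1]), 1)
    expect_lt(abs(mc[2] - analytic[2]), 1)
  }
})

test_that("nutrient_budget assembles per-site rows and treats missing veg as zero", {
  demo <- zambezi_demo()
  b <- nutrient_budget(demo$vegetation, demo$concentrations, demo$discharge)
  expect_equal(nrow(b), 8)
  expect_setequal(unique(b$site),
                  c("kafue", "chongwe", "little_chongwe", "maramba"))

  kp <- b[b$site == "kafue" & b$nutrient == "P", ]
  expect_equal(kp$sink_pct, 18.94, tolerance = 1e-3)
  expect_equal(kp$load_Mg_yr, 227.68, tolerance = 1e-4)

  # a site absent from the vegetation table carries a zero pool
  no_veg <- demo$vegetation[demo$vegetation$site != "maramba", ]
  b2 <- nutrient_budget(no_veg, demo$concentrations, demo$discharge)
  mar <- b2[b2$site == "maramba", ]
  expect_equal(mar$pool_Mg, c(0, 0))
  expect_equal(mar$sink_pct, c(0, 0))

  # median aggregation is an explicit switch, recorded on the result
  b3 <- nutrient_budget(demo$vegetation, demo$concentrations, demo$discharge,
                        aggregation = "median")
  expect_identical(attr(b3, "aggregation"), "median")
})
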