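test_that("delta notation converts to and from isotopologue ratios", {
  R <- 0.0111797
  expect_equal(delta13C(400, 400 * R), 0)
  expect_equal(delta13C(400, 400 * R * 0.99), -10)
  # generator convention: a gas mixed at -8 permil reads back -8
  c12 <- 500
  c13 <- c12 * R * (1 - 8 / 1000)
  expect_equal(delta13C(c12, c13), -8, tolerance = 1e-12)
  expect_error(delta13C(0, 1), "c12")
})

test_that("xi and the observed discrimination follow their definitions", {
  expect_equal(xi(800, 400), 2)
  expect_equal(xi(800, 480), 2.5)
  expect_true(is.na(xi(800, 800)))           # zero drawdown flagged
  expect_equal(observed_discrimination(2, -8, -8), 0)
  expect_equal(observed_discrimination(2, -6, -8), 4000 / 990)
  # net uptake implies xi > 1
  set.seed(5)
  cr <- runif(200, 300, 900)
  cs <- cr * runif(200, 0.05, 0.95)
  expect_true(all(xi(cr, cs) > 1))
})

test_that("the instrument error model scales as 2 xi X", {
  expect_equal(discrimination_error(2.5, 0.24)$error, 1.2)
  expect_equal(discrimination_error(15, 0.24)$error, 7.2)
  expect_equal(discrimination_error(5, 0)$error, 0)
  # relative error: monotone in xi at fixed Delta, infinite at zero signal
  e <- discrimination_error(c(2, 4, 8), 0.24, delta_obs = 4)
  expect_true(all(diff(e$error_pct) > 0))
  expect_equal(discrimination_error(2, 0.24, delta_obs = 0)$error_pct, Inf)
  # sensitivity variant
  cst <- c4_constants(error_model = "sqrt2xiX")
  expect_equal(discrimination_error(2.5, 0.24, constants = cst)$error,
               sqrt(2) * 2.5 * 0.24)
})

test_that("the exclusion rule is strictly greater-than 50%", {
  pts <- data.frame(error_pct = c(60, 50, 49.9, Inf, NA))
  out <- filter_by_error(pts)
  expect_identical(out$included, c(FALSE, TRUE, TRUE, FALSE, FALSE))
})

test_that("concentration-series calibration recovers the instrument map", {
  truths <- list(cal_points = data.frame(site_id = c("cal1", "cal2", "cal3"),
                                         co2 = c(300, 500, 700),
                                         delta = -35),
                 tank = list(co2 = 420, delta = -8.5))
  R <- 0.0111797
  r <- R * (1 - 35 / 1000)
  t12 <- c(0, truths$cal_points$co2 / (1 + r))
  t13 <- c(0, truths$cal_points$co2 * r / (1 + r))
  mk_blocks <- function(g12 = 1, o12 = 0, g13 = 1, o13 = 0) {
    rt <- R * (1 - 8.5 / 1000)
    tank12 <- 420 / (1 + rt); tank13 <- 420 * rt / (1 + rt)
    data.frame(site_id = c("zero_air", "cal1", "cal2", "cal3", "tank"),
               time_s = c(15, 35, 55, 75, 95),
               c12 = c(g12 * t12 + o12, g12 * tank12 + o12),
               c13 = c(g13 * t13 + o13, g13 * tank13 + o13))
  }
  ident <- fit_concentration_series(mk_blocks(), truths)
  expect_equal(ident$gain12, 1, tolerance = 1e-12)
  expect_equal(ident$offset12, 0, tolerance = 1e-9)
  expect_true(all(abs(ident$residuals12) < 1e-9))
  expect_equal(ident$tank_qc_delta, 0, tolerance = 1e-8)

  skew <- fit_concentration_series(mk_blocks(g12 = 1.02, o12 = -0.5,
                                             g13 = 0.98, o13 = 0.1), truths)
  expect_equal(skew$gain12, 1.02, tolerance = 1e-4)
  expect_equal(skew$offset12, -0.5, tolerance = 1e-4)
  expect_equal(skew$gain13, 0.98, tolerance = 1e-4)

  one <- mk_blocks()[1, ]
  expect_error(fit_concentration_series(one, truths), "two distinct")
  neg <- mk_blocks(g12 = -1)
  expect_error(fit_concentration_series(neg, truths), "negative")
})

test_that("drift correction interpolates the calibration map in time", {
  truths <- list(cal_points = data.frame(site_id = "cal1", co2 = 500,
                                         delta = -35))
  r <- 0.0111797 * (1 - 35 / 1000)
  t12 <- 500 / (1 + r)
  t13 <- 500 * r / (1 + r)
  mk_fit <- function(gain, t) {
    blocks <- data.frame(site_id = c("zero_air", "cal1"),
                         time_s = c(t, t),
                         c12 = gain * c(0, t12), c13 = gain * c(0, t13))
    fit_concentration_series(blocks, truths)
  }
  f0 <- mk_fit(1, 0)
  f1 <- mk_fit(1.01, 740)
  blocks <- data.frame(time_s = c(0, 370, 740), c12 = 400, c13 = 4.4)
  # identical fits: constant correction; identity fits: unchanged values
  same <- apply_drift_correction(blocks, f0, f0)
  expect_equal(same$c12, blocks$c12 / 1, tolerance = 1e-9)
  # interpolated gain halves the drift mid-cycle
  cor <- apply_drift_correction(blocks, f0, f1)
  expect_equal(cor$c12, 400 / c(1, 1.005, 1.01), tolerance = 1e-6)
  expect_error(apply_drift_correction(blocks, f1, f0), "order")
})

test_that("a linear gain drift across a cycle is corrected to < 0.05 permil", {
  sc <- synthetic_scenario(noise = FALSE, seed = 4,
                           drift_slope13 = 0.01 / 740)
  d <- tempfile()
  sim <- simulate_run(sc, d)
  cfg <- config_from_scenario(sc)
  cfg$paths$gasex <- sim$paths$gasex
  cfg$paths$tdl <- sim$paths$tdl
  for (mode in c("per_cycle", "global")) {
    cfg$calibration_drift <- mode
    run <- run_analysis(cfg)
    s <- run$series[run$series$matched, ]
    ti <- match(round(s$time_s, 6), round(sim$truth$time_s, 6))
    bias <- s$delta_samp - sim$truth$delta_samp[ti]
    expect_lt(max(abs(bias)), 0.05)
  }
})

test_that("reference pairing averages the bracketing phases", {
  R <- 0.0111797
  mk_ref <- function(c12, delta) {
    data.frame(site_id = "reference", time_s = 0, c12 = c12,
               c13 = c12 * R * (1 + delta / 1000))
  }
  cy <- list(cycle_index = 0,
             reference_before = mk_ref(798, -8.2),
             reference_after = mk_ref(802, -7.8))
  ref <- pair_reference(cy)
  expect_equal(ref$Cref, 800)
  expect_equal(ref$delta_ref, -8, tolerance = 1e-9)

  cy$reference_after <- NULL
  expect_warning(ref1 <- pair_reference(cy), "one bracketing")
  expect_equal(ref1$Cref, 798)
  expect_error(pair_reference(list(cycle_index = 0)), "no reference")
})
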