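test_that("washout follows the first-order mixing solution", {
  ch <- chamber_model(0.5, 300)
  expect_equal(washout(0, 500, 800, ch), 500)
  expect_equal(washout(1e6, 500, 800, ch), 800)
  expect_equal(washout(ch$tau_s, 500, 800, ch), 800 + (500 - 800) / exp(1))
  expect_equal(ch$tau_s, 0.5 / (300e-6 * 24.6), tolerance = 1e-9)
})

test_that("chamber constants are recovered from multi-flow step series", {
  V_true <- 0.5
  mk_series <- function(flow, noise_sd = 0) {
    ch <- chamber_model(V_true, flow)
    tt <- seq(0, 240, by = 2)
    co2 <- washout(tt, 800, 400, ch)
    if (noise_sd > 0) co2 <- co2 + rnorm(length(tt), 0, noise_sd)
    list(flow_umol_s = flow, data = data.frame(time_s = tt, co2 = co2))
  }
  clean <- lapply(c(300, 500, 700), mk_series)
  fit <- fit_chamber_constants(clean)
  expect_equal(fit$volume_l, V_true, tolerance = 1e-6)
  # tau scales as 1/flow at the shared volume
  expect_equal(fit$series$tau_s * fit$series$flow_umol_s,
               rep(fit$series$tau_s[1] * 300, 3), tolerance = 1e-6)

  set.seed(21)
  noisy <- lapply(rep(c(300, 500, 700), each = 3), mk_series, noise_sd = 1)
  fitn <- fit_chamber_constants(noisy)
  expect_lt(abs(fitn$volume_l - V_true) / V_true, 0.02)

  flat <- list(list(flow_umol_s = 300,
                    data = data.frame(time_s = 0:100, co2 = 400)))
  expect_error(fit_chamber_constants(flat), "unidentifiable")
})

test_that("the delay model collapses to instantaneous response as V -> 0", {
  tiny <- chamber_model(1e-8, 300)
  out <- simulate_delay(list(A_f = 40, tau_A = 300, S_leaf = 0.0024),
                        tiny, t_grid = seq(1, 1800, by = 10))
  expect_lt(max(abs(out$A_apparent - out$A_true)), 1e-6)

  # no assimilation: chamber stays at the inlet concentration
  still <- simulate_delay(list(A_f = 0, tau_A = 300, S_leaf = 0.0024),
                          chamber_model(0.5, 300), seq(1, 300, 10))
  expect_true(all(abs(still$C - 800) < 1e-12))
})

test_that("the delay model conserves mass and matches the analytic washout", {
  ch <- chamber_model(0.5, 300)
  sc <- list(A_f = 40, tau_A = 300, S_leaf = 0.0024)
  tt <- seq(0, 1800, by = 0.1)
  out <- simulate_delay(sc, ch, tt[-1])
  # cumulative inlet - outlet - storage equals cumulative leaf uptake
  f <- ch$flow_mol_s
  uptake <- sc$S_leaf * sc$A_f *
    (1800 - sc$tau_A * (1 - exp(-1800 / sc$tau_A)))          # closed form
  drawdown <- f * sum((800 - out$C) * 0.1)                   # trapezoid-ish
  storage <- ch$volume_l / ch$vm_l_per_mol * (out$C[nrow(out)] - 800)
  expect_equal(drawdown - storage, uptake, tolerance = 1e-4 * uptake)

  # with the leaf off and a concentration offset it reduces to washout
  wash <- simulate_delay(list(A_f = 0, tau_A = 300, S_leaf = 0.0024,
                              cin = 800, c0 = 500),
                         ch, seq(1, 300, 1))
  expect_equal(wash$C, washout(seq(1, 300, 1), 500, 800, ch),
               tolerance = 1e-6)
})

test_that("the apparent signal lags the leaf by about the mixing constant", {
  ch <- chamber_model(0.3, 300)   # tau ~ 41 s << tau_A
  out <- simulate_delay(list(A_f = 40, tau_A = 300, S_leaf = 0.0024),
                        ch, seq(1, 1800, 1))
  cross <- function(v) out$time_s[which(v >= 20)[1]]
  lag <- cross(out$A_apparent) - cross(out$A_true)
  expect_lt(abs(lag - ch$tau_s), 0.35 * ch$tau_s)
})

test_that("the transport lag is recovered from spike cross-correlation", {
  tt <- seq(0, 600, by = 0.5)
  spike <- function(t0) 400 + 300 * exp(-((tt - t0) / 30)^2)
  a <- data.frame(time_s = tt, value = spike(100))
  b <- data.frame(time_s = tt, value = spike(112))
  expect_equal(estimate_lag(a, b), 12, tolerance = 0.5)
  expect_equal(estimate_lag(a, a), 0, tolerance = 1e-9)
  # a lag of exactly half the record puts the peak on the search boundary
  mid <- data.frame(time_s = tt, value = spike(150))
  far <- data.frame(time_s = tt, value = spike(450))
  expect_error(estimate_lag(mid, far), "boundary")
})

test_that("stream alignment shifts, pairs and optionally deconvolves", {
  gasex <- data.frame(time_s = seq(5, 95, 10), A = 1:10, E = 0.005,
                      gs = 0.3, gact = 0.2, Ca = 480, Ci = 320, Cs = 470,
                      Tleaf = 27, flow = 300, Rd = 1.5)
  blocks <- data.frame(time_s = seq(5, 95, 10), c12 = 450, c13 = 5)
  al <- align_streams(gasex, blocks, transport_lag_s = 0)
  expect_identical(al$gasex_row, 1:10)
  expect_true(all(al$matched))

  # an unmatched block is retained but flagged
  blocks2 <- rbind(blocks, data.frame(time_s = 300, c12 = 450, c13 = 5))
  al2 <- align_streams(gasex, blocks2, transport_lag_s = 0)
  expect_false(al2$matched[11])

  # deconvolution is a no-op for a vanishing chamber volume
  ch <- chamber_model(1e-9, 300)
  al3 <- align_streams(gasex, blocks, 0, deconvolve = TRUE, chamber = ch)
  expect_equal(al3$c12, al$c12, tolerance = 1e-9)

  expect_error(align_streams(gasex, blocks, transport_lag_s = 1e5),
               "overlap")
})

test_that("an injected 15 s transport lag is corrected end to end", {
  sc <- synthetic_scenario(noise = FALSE, seed = 3, transport_lag_s = 15)
  rec <- run_simulate_then_analyze(sc, n_replicates = 1)
  # pairing at half-block offset leaves only sub-block errors
  expect_lt(rec$rmse, 0.01)
  expect_lt(abs(rec$t_peak_error_s), 10)
})
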