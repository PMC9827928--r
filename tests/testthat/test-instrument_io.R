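test_that("gas-exchange log reading preserves records and converts units", {
  tt <- seq(0, 1800, by = 10)
  log <- data.frame(time_s = tt, A = seq(0, 40, length.out = length(tt)),
                    E = 0.006, gs = 0.4, gact = 0.25, Ca = 480, Ci = 320,
                    Cs = 470, Tleaf = 27, flow = 300, Rd = 1.5)
  f <- tempfile(fileext = ".csv")
  write.csv(log, f, row.names = FALSE)
  rec <- read_gas_exchange_log(f)
  expect_equal(nrow(rec), 181)
  expect_equal(diff(range(rec$time_s)), 1800)
  expect_equal(rec$A, log$A)

  # LI-6400-style dialect with unit conversions (mmol -> mol for E)
  li <- data.frame(FTime = tt[1:5], Photo = 10, Trmmol = 4, Cond = 0.3,
                   CO2S = 480, Ci = 320, Tleaf = 27, Flow = 300)
  f2 <- tempfile(fileext = ".csv")
  write.csv(li, f2, row.names = FALSE)
  rec2 <- read_gas_exchange_log(f2, dialect = "li6400", rd = 1.5)
  expect_equal(rec2$E, rep(0.004, 5))
  expect_setequal(attr(rec2, "derived"), c("gact", "Cs", "Rd"))
  # derived gact is the series combination of the two CO2 conductances
  expect_equal(rec2$gact[1], 1 / (1.37 / 3 + 1.6 / 0.3))

  # missing mandatory column
  f3 <- tempfile(fileext = ".csv")
  write.csv(log[, setdiff(names(log), "A")], f3, row.names = FALSE)
  expect_error(read_gas_exchange_log(f3), "mandatory")

  # non-monotone time names the offending rows
  bad <- log[c(1, 3, 2, 4:10), ]
  f4 <- tempfile(fileext = ".csv")
  write.csv(bad, f4, row.names = FALSE)
  expect_error(read_gas_exchange_log(f4), "increasing")
})

test_that("cycle segmentation yields the documented block structure", {
  stream <- make_cycle_stream(values = list(
    zero_air = c(0, 0), cal1 = c(400, 4.4), cal2 = c(400, 4.4),
    cal3 = c(400, 4.4), tank = c(400, 4.4), reference = c(400, 4.4),
    sample = c(400, 4.4)))
  cycles <- segment_cycles(stream)
  expect_length(cycles, 1)
  blocks <- cycles[[1]]$blocks
  expect_equal(sum(blocks$site_id == "sample"), 59)
  expect_equal(sum(blocks$site_id == "zero_air"), 1)
  # constant input -> every block mean equals the input (CO2-free air aside)
  expect_true(all(abs(blocks$c12[blocks$site_id != "zero_air"] - 400) < 1e-12))
  expect_false(any(blocks$low_coverage))
  # reference phases bracketing the sample phase are identified
  expect_equal(nrow(cycles[[1]]$reference_before), 1)
  expect_equal(nrow(cycles[[1]]$reference_after), 1)
})

test_that("block averaging is mean-preserving and loses no sample", {
  set.seed(3)
  stream <- make_cycle_stream()
  stream$c12 <- stream$c12 + rnorm(nrow(stream), 0, 5)
  cycles <- segment_cycles(stream)
  blocks <- cycles[[1]]$blocks
  sch <- cycle_schedule()
  # totality: averaged + discarded-head samples account for every raw row
  n_discarded <- nrow(sch$phases) * sch$discard_head_s * 10
  expect_equal(sum(blocks$n_samples) + n_discarded, nrow(stream))
  # mean preservation per phase over retained samples (exact)
  off <- cumsum(c(0, sch$phases$duration_s))
  for (p in seq_len(nrow(sch$phases))) {
    keep <- stream$time_s >= off[p] + sch$discard_head_s &
      stream$time_s < off[p + 1]
    b <- blocks[blocks$phase == p, ]
    expect_equal(sum(b$c12 * b$n_samples) / sum(b$n_samples),
                 mean(stream$c12[keep]), tolerance = 1e-12)
  }
})

test_that("cycle segmentation rejects inconsistent inputs", {
  stream <- make_cycle_stream()
  stream$site_id[stream$site_id == "tank"] <- "cal3"
  expect_error(segment_cycles(stream), "site sequence mismatch")
  expect_error(cycle_schedule(data.frame(site_id = "sample",
                                         duration_s = 8)),
               "discard_head_s")
})

test_that("leakiness table round-trips through write and read", {
  set.seed(1)
  n <- 150
  series <- data.frame(
    time_s = seq(5, by = 10, length.out = n), A = runif(n, 0, 40),
    gs = runif(n, 0.04, 0.6), Ci = runif(n, 200, 700),
    xi = runif(n, 2, 15), Delta_obs = runif(n, 1, 10),
    error = runif(n, 0.5, 7), error_pct = runif(n, 10, 90),
    included = sample(c(TRUE, FALSE), n, TRUE),
    phi = runif(n, 0.1, 0.4), Cbs = runif(n, 1500, 4000),
    Jt = runif(n, 50, 250), Vp = runif(n, 5, 50),
    Vc = runif(n, 5, 45), Vo = runif(n, 0, 3))
  f <- tempfile(fileext = ".csv")
  write_leakiness_table(series, f)
  expect_equal(length(readLines(f)), n + 2)  # units comment + header + rows
  back <- read_leakiness_table(f)
  for (col in setdiff(names(series), "included"))
    expect_equal(signif(back[[col]], 6), signif(series[[col]], 6))
  expect_identical(back$included, series$included)

  # empty series -> header-only table
  f2 <- tempfile(fileext = ".csv")
  write_leakiness_table(series[0, ], f2)
  expect_equal(nrow(read_leakiness_table(f2)), 0)
})

test_that("synthetic gas-exchange stream re-reads field-identically", {
  fx <- noise_free_sim()
  rec <- read_gas_exchange_log(fx$sim$paths$gasex)
  truth <- fx$sim$truth
  tr <- truth[truth$time_s <= fx$scenario$t_end_s, ]
  expect_equal(rec$time_s, tr$time_s)
  expect_equal(rec$A, tr$A, tolerance = 1e-12)
  expect_equal(rec$Ci, tr$Ci, tolerance = 1e-12)
  expect_equal(rec$gs, tr$gs, tolerance = 1e-12)
})
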