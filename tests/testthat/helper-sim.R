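# Shared simulation fixtures, built once per test session.

.fixture_cache <- new.env(parent = emptyenv())

# Noise-free sorghum-like run: streams on disk plus the hidden truth.
noise_free_sim <- function() {
  if (is.null(.fixture_cache$nf)) {
    sc <- synthetic_scenario(noise = FALSE, seed = 1)
    dir <- file.path(tempdir(), "c4leak-nf")
    .fixture_cache$nf <- list(scenario = sc, sim = simulate_run(sc, dir))
  }
  .fixture_cache$nf
}

# Full analysis of the noise-free run.
noise_free_analysis <- function() {
  if (is.null(.fixture_cache$nf_run)) {
    fx <- noise_free_sim()
    cfg <- config_from_scenario(fx$scenario)
    cfg$paths$gasex <- fx$sim$paths$gasex
    cfg$paths$tdl <- fx$sim$paths$tdl
    .fixture_cache$nf_run <- run_analysis(cfg)
  }
  .fixture_cache$nf_run
}

# One raw 740 s calibration cycle at 10 Hz with constant gas values.
make_cycle_stream <- function(n_cycles = 1, hz = 10, start_s = 0,
                              values = NULL) {
  sch <- cycle_schedule()
  if (is.null(values))
    values <- list(zero_air = c(0, 0), cal1 = c(297, 3.3),
                   cal2 = c(495, 5.5), cal3 = c(693, 7.7),
                   tank = c(416, 4.6), reference = c(791, 8.8),
                   sample = c(450, 5.0))
  rows <- list()
  for (k in seq_len(n_cycles) - 1) {
    off <- cumsum(c(0, sch$phases$duration_s))
    for (p in seq_len(nrow(sch$phases))) {
      site <- sch$phases$site_id[p]
      tt <- start_s + k * sch$total_duration_s + off[p] +
        (seq_len(sch$phases$duration_s[p] * hz) - 1) / hz
      v <- values[[site]]
      rows[[length(rows) + 1L]] <- data.frame(
        time_s = tt, site_id = site, c12 = v[1], c13 = v[2],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Random admissible leaf states for the inversion oracle.
random_states <- function(n, seed = 42, constants = c4_constants()) {
  set.seed(seed)
  out <- data.frame(
    A = runif(n, 5, 40), Rd = runif(n, 0.5, 2.5),
    Ca = runif(n, 400, 800), Tleaf = runif(n, 25, 30),
    E = runif(n, 0.001, 0.008), gact = runif(n, 0.05, 0.5),
    delta_ref = runif(n, -9.9, -6.6), phi = runif(n, 0.05, 0.45))
  out$Ci <- out$Ca * runif(n, 0.4, 0.85)
  out$Cs <- out$Ci + (out$Ca - out$Ci) * runif(n, 0.7, 0.99)
  out
}
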