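#' Scenario for a forward-simulated induction experiment
#'
#' Defines the physiological trajectories, chamber, instrument and noise
#' parameters of a synthetic dark-to-high-light induction run. The defaults
#' describe a sorghum-like measurement: steady-state assimilation
#' 40 umol m-2 s-1 approached with a 300 s time constant, stomatal
#' conductance opening sigmoidally from 0.04 to 0.57 mol m-2 s-1, reference
#' CO2 800 umol mol-1 at 300 umol s-1 flow, leaf at 27 C, and a true
#' leakiness that rises linearly from 0.30 to 0.35 at 290 s before decaying
#' exponentially (time constant 500 s) to a steady state of 0.18. The TDL
#' stream is organised in 740 s calibration cycles and carries Gaussian
#' noise giving a 10 s block delta-13C precision of 0.24 permil.
#'
#' @param ... Named overrides of any default field (see the function body
#'   for the full list).
#' @param noise If `FALSE`, all instrument noise and drift terms are zeroed
#'   (a noise-free run for exactness checks).
#' @return A list with class `"synthetic_scenario"`.
#' @export
#' @examples
#' sc <- synthetic_scenario(seed = 42)
#' sc$phi$t_peak_s
synthetic_scenario <- function(..., noise = TRUE) {
  sc <- list(
    # physiology
    A_f = 40, tau_A = 300, initial_lag_s = 0, Rd = 1.5,
    gs0 = 0.04, gsf = 0.57, gs_half_time_s = 300, gs_slope_s = 100,
    vpd_frac = 0.015, gbw = 3, ci_floor = 150,
    phi = list(phi0 = 0.23, phi_max = 0.35, t_peak_s = 290,
               tau_phi_s = 500, phi_ss = 0.18),
    # chamber / gas supply
    Ca_ref = 800, delta_ref = -8, flow_umol_s = 300, S_leaf_m2 = 0.0024,
    Tleaf_C = 27, chamber_volume_l = 0.3, vm_l_per_mol = 24.6,
    transport_lag_s = 20,
    # TDL cycle and calibration gases
    n_cycles = 3, tdl_hz = 10,
    cal_points = data.frame(site_id = c("cal1", "cal2", "cal3"),
                            co2 = c(300, 500, 700), delta = -35,
                            stringsAsFactors = FALSE),
    tank = list(co2 = 420, delta = -8.5),
    # instrument imperfections
    precision_permil = 0.24, noise_c12 = 0.5,
    gain0_12 = 1, gain0_13 = 1, offset12 = 0, offset13 = 0,
    drift_slope12 = 1e-6, drift_slope13 = 1e-6,
    gasex_noise_A = 0.2, gasex_noise_gs = 0.005,
    # run layout
    t_end_s = 1800, log_dt_s = 10, seed = 1, n_replicates = 8)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(sc))
  if (length(unknown))
    stop("unknown scenario field(s): ", paste(unknown, collapse = ", "))
  sc[names(dots)] <- dots
  if (!noise) {
    sc$precision_permil <- 0
    sc$noise_c12 <- 0
    sc$drift_slope12 <- 0
    sc$drift_slope13 <- 0
    sc$gasex_noise_A <- 0
    sc$gasex_noise_gs <- 0
  }
  with(sc$phi, stopifnot(phi_ss > 0, phi_ss <= phi_max, phi_max < 1,
                         tau_phi_s > 0, t_peak_s > 0))
  stopifnot(sc$A_f >= 0, sc$tau_A > 0, sc$flow_umol_s > 0, sc$S_leaf_m2 > 0)
  class(sc) <- "synthetic_scenario"
  sc
}

#' True leakiness trajectory of a scenario
#'
#' Linear rise from `phi0` at illumination to `phi_max` at `t_peak_s`, then
#' exponential decay with time constant `tau_phi_s` towards `phi_ss`;
#' constant `phi0` before time 0.
#'
#' @param t Time since illumination (s).
#' @param scenario A [synthetic_scenario()].
#' @return phi_true at `t`.
#' @export
phi_trajectory <- function(t, scenario) {
  p <- scenario$phi
  ifelse(t <= 0, p$phi0,
         ifelse(t <= p$t_peak_s,
                p$phi0 + (p$phi_max - p$phi0) * t / p$t_peak_s,
                p$phi_ss + (p$phi_max - p$phi_ss) *
                  exp(-(t - p$t_peak_s) / p$tau_phi_s)))
}

# True leaf net assimilation: -Rd in darkness, exponential induction after.
.a_leaf_true <- function(t, sc) {
  tt <- t - sc$initial_lag_s
  ifelse(tt <= 0, -sc$Rd,
         -sc$Rd + (sc$A_f + sc$Rd) * (1 - exp(-tt / sc$tau_A)))
}

# Integrate the chamber mixing ODE over the whole TDL record and return an
# interpolator for chamber CO2 (total, dry).
.prepare_chamber <- function(sc) {
  ch <- chamber_model(sc$chamber_volume_l, sc$flow_umol_s, sc$vm_l_per_mol)
  f <- ch$flow_mol_s
  t0 <- -120
  t1 <- sc$n_cycles * 740 - 120 + 10
  fine <- seq(t0, t1, by = 0.1)
  cstar <- sc$Ca_ref - sc$S_leaf_m2 * .a_leaf_true(fine, sc) / f
  C <- numeric(length(fine))
  C[1] <- cstar[1]  # dark equilibrium (slight respiratory enrichment)
  for (i in seq_len(length(fine) - 1))
    C[i + 1] <- .mix_step(C[i], cstar[i], cstar[i + 1], 0.1, ch$tau_s)
  stats::approxfun(fine, C, rule = 2)
}

# Leaf/chamber state at arbitrary times. `A` is the apparent assimilation
# the gas-exchange system reports from the instantaneous chamber mass
# balance; all downstream CO2 fields are derived from it so that logged
# records are self-consistent.
.physio_state <- function(t, sc, chamber_fun) {
  f <- sc$flow_umol_s * 1e-6
  Ca <- chamber_fun(t)
  A <- f * (sc$Ca_ref - Ca) / sc$S_leaf_m2
  gs <- sc$gs0 + (sc$gsf - sc$gs0) /
    (1 + exp(-(t - sc$gs_half_time_s) / sc$gs_slope_s))
  E <- gs * sc$vpd_frac
  gbc <- sc$gbw / 1.37
  gsc <- gs / 1.6
  gact <- 1 / (1 / gbc + 1 / gsc)
  Cs <- Ca - A / gbc
  Ci <- Ca - A / gact
  data.frame(time_s = t, A = A, A_leaf_true = .a_leaf_true(t, sc),
             E = E, gs = gs, gact = gact, Ca = Ca, Ci = Ci, Cs = Cs,
             Csamp = Ca, Tleaf = sc$Tleaf_C, flow = sc$flow_umol_s,
             Rd = sc$Rd, phi_true = phi_trajectory(t, sc))
}

# Add the isotopic truth: Delta_true from phi_true through the forward
# discrimination model, delta_samp closed-form from the online
# discrimination definition, xi from 12CO2 mole fractions.
.isotope_state <- function(phys, sc, constants) {
  cst <- constants
  n <- nrow(phys)
  valid <- phys$time_s > 0 & (phys$A + phys$Rd) > 1e-9
  Jt <- rep(NA_real_, n)
  Jt[valid] <- electron_transport(phys$A[valid], phys$Rd[valid],
                                  phys$Ci[valid], cst)
  st <- bundle_sheath_state(phys$A, phys$Rd, Jt, cst)
  ap <- combined_a_prime(phys$Ca, phys$Cs, phys$Ci, cst)
  tern <- ternary_t(ap, phys$E, phys$gact, cst)
  ep <- e_prime(sc$delta_ref, cst)
  bb <- b3_b4(st, ep, phys$Rd, phys$Tleaf, cst)
  Delta <- forward_discrimination(phys$phi_true, phys$Ca, phys$Ci, st$Cbs,
                                  tern, ap, bb$b3, bb$b4, cst)
  Delta[!valid] <- NA_real_

  r_ref <- ratio_from_delta(sc$delta_ref, cst$r_standard)
  c12ref <- sc$Ca_ref / (1 + r_ref)
  ds <- rep(sc$delta_ref, n)
  for (it in 1:8) {
    rs <- ratio_from_delta(ds, cst$r_standard)
    c12s <- phys$Csamp / (1 + rs)
    x <- c12ref / (c12ref - c12s)
    ds_new <- sc$delta_ref + Delta * (1000 + sc$delta_ref) /
      (x * (1000 + Delta) - Delta)
    ds <- ifelse(valid & !is.na(ds_new), ds_new, sc$delta_ref)
  }
  rs <- ratio_from_delta(ds, cst$r_standard)
  out <- phys
  out$Jt <- st$Jt
  out$Cbs <- st$Cbs
  out$delta_samp <- ds
  out$c12_samp <- phys$Csamp / (1 + rs)
  out$c13_samp <- phys$Csamp * rs / (1 + rs)
  out$xi_true <- c12ref / (c12ref - out$c12_samp)
  out$Delta_true <- Delta
  out$valid <- valid & !is.na(Delta)
  out
}

#' Forward-simulate the leaf and chamber physiology
#'
#' Produces the noise-free physiological truth of a scenario at the logging
#' timepoints: apparent assimilation through chamber mixing, stomatal
#' conductance, transpiration, conductances and the CO2 cascade
#' (chamber = ambient, leaf surface, intercellular), plus the prescribed
#' true leakiness. Timepoints are the 10 s block centres of the TDL sample
#' phases, extended over the full cycle record.
#'
#' @param scenario A [synthetic_scenario()].
#' @param t_grid Optional output times (s). Default: block centres from
#'   -115 s (dark) to the end of the last cycle.
#' @return Data frame of truth records with the chamber interpolator
#'   attached as attribute `"chamber_fun"`.
#' @export
simulate_physiology <- function(scenario, t_grid = NULL) {
  sc <- scenario
  if (is.null(t_grid))
    t_grid <- seq(-115, sc$n_cycles * 740 - 120 - 5, by = sc$log_dt_s)
  chf <- .prepare_chamber(sc)
  out <- .physio_state(t_grid, sc, chf)
  lit <- out$time_s > 60
  if (any(lit & out$Ci < sc$ci_floor))
    stop("scenario infeasible: intercellular CO2 falls below the ",
         sc$ci_floor, " umol mol-1 floor")
  attr(out, "chamber_fun") <- chf
  out
}

#' Add the isotopic truth to a physiological simulation
#'
#' For every timepoint, the true observed discrimination is computed from
#' the prescribed leakiness through the forward discrimination model, and
#' the chamber-air delta-13C is solved in closed form from the online
#' discrimination definition, so that inverting the analysis pipeline on
#' noise-free streams returns exactly the prescribed phi. Dark or
#' non-assimilating timepoints carry no isotopic signal (delta_samp =
#' delta_ref) and are marked invalid.
#'
#' @param truth Result of [simulate_physiology()].
#' @param scenario The same [synthetic_scenario()].
#' @param constants A [c4_constants()] set.
#' @return `truth` with columns `Jt`, `Cbs`, `delta_samp`, `c12_samp`,
#'   `c13_samp`, `xi_true`, `Delta_true`, `valid`.
#' @export
simulate_isotopes <- function(truth, scenario, constants = c4_constants()) {
  out <- .isotope_state(truth, scenario, constants)
  attr(out, "chamber_fun") <- attr(truth, "chamber_fun")
  out
}

# True isotopologue content of the constant calibration gases.
.cal_gas_truth <- function(sc, r_standard) {
  r <- ratio_from_delta(sc$cal_points$delta, r_standard)
  rt <- ratio_from_delta(sc$tank$delta, r_standard)
  rr <- ratio_from_delta(sc$delta_ref, r_standard)
  rbind(
    data.frame(site_id = "zero_air", c12 = 0, c13 = 0),
    data.frame(site_id = sc$cal_points$site_id,
               c12 = sc$cal_points$co2 / (1 + r),
               c13 = sc$cal_points$co2 * r / (1 + r)),
    data.frame(site_id = "tank", c12 = sc$tank$co2 / (1 + rt),
               c13 = sc$tank$co2 * rt / (1 + rt)),
    data.frame(site_id = "reference", c12 = sc$Ca_ref / (1 + rr),
               c13 = sc$Ca_ref * rr / (1 + rr)))
}

#' Write the two synthetic instrument streams
#'
#' Emits the 10 Hz TDL stream with the full eight-phase 740 s cycle
#' structure (CO2-free air, three calibration dilutions, certified tank,
#' reference, 600 s of chamber air, reference), the 10 s gas-exchange log,
#' the hidden-truth table and a scenario echo. The TDL signal within each
#' 10 s averaging block carries the block-centre truth (the induction signal
#' has no sub-block structure) sampled `transport_lag_s` earlier at the
#' chamber; per-sample Gaussian noise, gain/offset maps and linear gain
#' drift are applied on top. All randomness derives from the scenario seed,
#' so a fixed seed reproduces the files byte for byte.
#'
#' @param truth Result of [simulate_isotopes()].
#' @param scenario The same [synthetic_scenario()].
#' @param dir Output directory (created if needed).
#' @param constants A [c4_constants()] set.
#' @return Invisibly, a list of the file paths (`gasex`, `tdl`, `truth`,
#'   `scenario`).
#' @export
emit_streams <- function(truth, scenario, dir,
                         constants = c4_constants()) {
  sc <- scenario
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(sc$seed)
  chf <- attr(truth, "chamber_fun")
  if (is.null(chf)) chf <- .prepare_chamber(sc)
  sch <- cycle_schedule()
  gases <- .cal_gas_truth(sc, constants$r_standard)
  hz <- sc$tdl_hz
  blk <- sch$block_s

  rows <- vector("list", sc$n_cycles * nrow(sch$phases))
  ri <- 0
  for (k in seq_len(sc$n_cycles) - 1) {
    cyc_start <- -120 + k * 740
    off <- cumsum(c(0, sch$phases$duration_s))
    for (p in seq_len(nrow(sch$phases))) {
      site <- sch$phases$site_id[p]
      dur <- sch$phases$duration_s[p]
      t_raw <- cyc_start + off[p] + (seq_len(dur * hz) - 1) / hz
      if (site == "sample") {
        centre <- cyc_start + off[p] +
          floor((t_raw - cyc_start - off[p]) / blk) * blk + blk / 2
        st <- .physio_state(unique(centre) - sc$transport_lag_s, sc, chf)
        iso <- .isotope_state(st, sc, constants)
        i <- match(centre, unique(centre))
        v12 <- iso$c12_samp[i]
        v13 <- iso$c13_samp[i]
      } else {
        g <- gases[gases$site_id == site, ]
        v12 <- rep(g$c12, length(t_raw))
        v13 <- rep(g$c13, length(t_raw))
      }
      ri <- ri + 1
      rows[[ri]] <- data.frame(time_s = t_raw, site_id = site,
                               c12 = v12, c13 = v13,
                               stringsAsFactors = FALSE)
    }
  }
  tdl <- do.call(rbind, rows[seq_len(ri)])
  # instrument map with linear gain drift, then per-sample noise
  g12 <- sc$gain0_12 + sc$drift_slope12 * tdl$time_s
  g13 <- sc$gain0_13 + sc$drift_slope13 * tdl$time_s
  true13 <- tdl$c13
  tdl$c12 <- g12 * tdl$c12 + sc$offset12
  tdl$c13 <- g13 * tdl$c13 + sc$offset13
  if (sc$noise_c12 > 0 || sc$precision_permil > 0) {
    n <- nrow(tdl)
    tdl$c12 <- tdl$c12 + stats::rnorm(n, 0, sc$noise_c12)
    # apportion delta noise: the 10 s block precision X implies a raw
    # per-sample delta sigma of 10 X; the 12CO2 noise already contributes
    sd12 <- ifelse(tdl$c12 > 1, 1000 * sc$noise_c12 / pmax(tdl$c12, 1), 0)
    sd13 <- sqrt(pmax((10 * sc$precision_permil)^2 - sd12^2, 0))
    sig13 <- ifelse(true13 > 0, true13 * sd13 / 1000,
                    0.011 * sc$noise_c12)
    tdl$c13 <- tdl$c13 + stats::rnorm(n, 0, sig13)
  }

  gx <- truth[truth$time_s <= sc$t_end_s, , drop = FALSE]
  A_n <- gx$A + stats::rnorm(nrow(gx), 0, sc$gasex_noise_A)
  gs_n <- pmax(gx$gs + stats::rnorm(nrow(gx), 0, sc$gasex_noise_gs), 1e-4)
  gbc <- sc$gbw / 1.37
  gact_n <- 1 / (1 / gbc + 1.6 / gs_n)
  gasex <- data.frame(
    time_s = gx$time_s, A = A_n, E = gs_n * sc$vpd_frac, gs = gs_n,
    gact = gact_n, Ca = gx$Ca, Ci = gx$Ca - A_n / gact_n,
    Cs = gx$Ca - A_n / gbc, Tleaf = gx$Tleaf, flow = gx$flow, Rd = gx$Rd)

  paths <- list(gasex = file.path(dir, "gasex.csv"),
                tdl = file.path(dir, "tdl.csv"),
                truth = file.path(dir, "truth.csv"),
                scenario = file.path(dir, "scenario-echo.yaml"))
  utils::write.csv(gasex, paths$gasex, row.names = FALSE, quote = FALSE)
  utils::write.csv(tdl, paths$tdl, row.names = FALSE, quote = FALSE)
  tr <- truth[, setdiff(names(truth), "chamber_fun"), drop = FALSE]
  utils::write.csv(tr, paths$truth, row.names = FALSE, quote = FALSE)
  echo <- unclass(sc)
  echo$cal_points <- as.list(as.data.frame(echo$cal_points))
  yaml::write_yaml(echo, paths$scenario)
  invisible(paths)
}

#' Simulate a complete synthetic run
#'
#' Convenience wrapper: [simulate_physiology()], [simulate_isotopes()] and
#' [emit_streams()] in sequence.
#'
#' @inheritParams emit_streams
#' @param scenario A [synthetic_scenario()].
#' @param dir Output directory.
#' @return List with `paths` (output files) and `truth` (the hidden truth
#'   table).
#' @export
simulate_run <- function(scenario, dir, constants = c4_constants()) {
  truth <- simulate_physiology(scenario)
  truth <- simulate_isotopes(truth, scenario, constants)
  paths <- emit_streams(truth, scenario, dir, constants)
  list(paths = paths, truth = truth)
}
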