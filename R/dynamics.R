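#' Well-mixed chamber model
#'
#' Describes the first-order mixing of an open, flow-through leaf chamber:
#' time constant `tau = V_chamber / (flow_mol * Vm)` where `flow_mol` is the
#' air flow in mol s-1 and `Vm` the molar volume of air (24.6 L mol-1 at
#' standard pressure and 27 degrees C).
#'
#' @param volume_l Chamber volume (L).
#' @param flow_umol_s Air flow (umol s-1).
#' @param vm_l_per_mol Molar volume of air (L mol-1). Default 24.6.
#' @return List with class `"chamber_model"`: `volume_l`, `flow_umol_s`,
#'   `vm_l_per_mol`, `flow_mol_s`, `tau_s`.
#' @export
#' @examples
#' chamber_model(0.5, 300)$tau_s
chamber_model <- function(volume_l, flow_umol_s, vm_l_per_mol = 24.6) {
  stopifnot(volume_l > 0, flow_umol_s > 0, vm_l_per_mol > 0)
  flow_mol <- flow_umol_s * 1e-6
  out <- list(volume_l = volume_l, flow_umol_s = flow_umol_s,
              vm_l_per_mol = vm_l_per_mol, flow_mol_s = flow_mol,
              tau_s = volume_l / (flow_mol * vm_l_per_mol))
  class(out) <- "chamber_model"
  out
}

#' Washout curve of a well-mixed flow-through chamber
#'
#' `C(t) = Cin - (Cin - C0) * exp(-t * flow_mol * Vm / V_chamber)`: the
#' chamber CO2 relaxes exponentially from `C0` to the incoming `Cin` with
#' the chamber time constant.
#'
#' @param t Time since the step (s), >= 0.
#' @param c0 Initial chamber CO2 (umol mol-1).
#' @param cin Incoming CO2 (umol mol-1).
#' @param chamber A [chamber_model()].
#' @return CO2 mole fraction at `t` (umol mol-1).
#' @export
washout <- function(t, c0, cin, chamber) {
  stopifnot(inherits(chamber, "chamber_model"), all(t >= 0))
  cin - (cin - c0) * exp(-t / chamber$tau_s)
}

#' Estimate chamber volume from step-change series at several flows
#'
#' Jointly fits the washout model to CO2 step-change time series recorded at
#' several known flow rates (bench characterisation used 300, 500 and
#' 700 umol s-1, three repeats each), sharing a single chamber volume across
#' all series while estimating each series' initial and incoming CO2.
#'
#' @param step_series List of series; each element a list with `flow_umol_s`
#'   and `data` (data frame `time_s`, `co2`).
#' @param vm_l_per_mol Molar volume of air (L mol-1). Default 24.6.
#' @return List: `volume_l`, `series` (data frame of per-series `flow_umol_s`,
#'   `c0`, `cin`, `tau_s`), and the `minpack.lm` fit object.
#' @export
fit_chamber_constants <- function(step_series, vm_l_per_mol = 24.6) {
  stopifnot(is.list(step_series), length(step_series) >= 1)
  spans <- vapply(step_series, function(s) diff(range(s$data$co2)), 0)
  if (all(spans < 1))
    stop("no concentration step in the supplied series: ",
         "chamber volume is unidentifiable")
  ns <- length(step_series)
  p0 <- c(V = 1,
          c0 = vapply(step_series, function(s) s$data$co2[1], 0),
          cin = vapply(step_series, function(s)
            s$data$co2[nrow(s$data)], 0))
  resid_fun <- function(p) {
    V <- p[1]
    unlist(lapply(seq_len(ns), function(i) {
      s <- step_series[[i]]
      tau <- V / (s$flow_umol_s * 1e-6 * vm_l_per_mol)
      c0 <- p[1 + i]; cin <- p[1 + ns + i]
      s$data$co2 - (cin - (cin - c0) * exp(-s$data$time_s / tau))
    }))
  }
  fit <- minpack.lm::nls.lm(par = p0, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200))
  if (fit$info %in% c(0, 5))
    stop("chamber-constant fit did not converge: ", fit$message)
  p <- stats::coef(fit)
  V <- unname(p[1])
  if (V <= 0) stop("chamber-constant fit returned non-positive volume")
  flows <- vapply(step_series, `[[`, 0, "flow_umol_s")
  list(volume_l = V,
       series = data.frame(flow_umol_s = flows,
                           c0 = unname(p[1 + seq_len(ns)]),
                           cin = unname(p[1 + ns + seq_len(ns)]),
                           tau_s = V / (flows * 1e-6 * vm_l_per_mol)),
       fit = fit)
}

# One step of the exact integrator for dC/dt = -(C - Cstar(t))/tau with
# Cstar linear within the step. Unconditionally stable, exact in the
# stiff (tau -> 0) limit, second order in the forcing curvature.
.mix_step <- function(C, cstar0, cstar1, h, tau) {
  if (tau <= 0) return(cstar1)
  m <- (cstar1 - cstar0) / h
  E <- exp(-h / tau)
  cstar1 - m * tau + (C - cstar0 + m * tau) * E
}

#' Simulate the apparent assimilation signal through chamber mixing
#'
#' Integrates the chamber CO2 balance
#' `dC/dt = S_leaf * (A_app(C) - A'_leaf(t)) * Vm / V_chamber`, where
#' `A_app(C) = flow_mol * (Cin - C) / S_leaf` is the assimilation rate the
#' gas-exchange system reports from the instantaneous mass balance and
#' `A'_leaf(t) = A_f * (1 - exp(-t / tau_A))` is the true leaf rate during
#' induction. The linear ODE is advanced on a fixed 0.1 s grid by an exact
#' exponential step (piecewise-linear forcing), which remains stable and
#' collapses to the instantaneous response in the `V_chamber -> 0` limit.
#'
#' @param scenario List with `A_f` (umol m-2 s-1, default 40), `tau_A`
#'   (s, default 300), `S_leaf` (m2), optional `cin` (umol mol-1,
#'   default 800).
#' @param chamber A [chamber_model()].
#' @param t_grid Increasing output times (s) starting at >= 0.
#' @param step_s Integrator step (s). Default 0.1.
#' @return Data frame `time_s`, `C` (chamber CO2), `A_true`, `A_apparent`.
#' @export
simulate_delay <- function(scenario, chamber, t_grid, step_s = 0.1) {
  stopifnot(inherits(chamber, "chamber_model"),
            !is.unsorted(t_grid, strictly = TRUE), t_grid[1] >= 0)
  A_f <- if (is.null(scenario$A_f)) 40 else scenario$A_f
  tau_A <- if (is.null(scenario$tau_A)) 300 else scenario$tau_A
  S <- scenario$S_leaf
  cin <- if (is.null(scenario$cin)) 800 else scenario$cin
  c0 <- if (is.null(scenario$c0)) cin else scenario$c0
  stopifnot(tau_A > 0, S > 0)
  f <- chamber$flow_mol_s
  A_leaf <- function(t) A_f * (1 - exp(-pmax(t, 0) / tau_A))
  cstar <- function(t) cin - S * A_leaf(t) / f

  tmax <- t_grid[length(t_grid)]
  fine <- seq(0, tmax, by = step_s)
  if (fine[length(fine)] < tmax) fine <- c(fine, tmax)
  C <- numeric(length(fine))
  C[1] <- c0  # dark equilibrium unless an initial offset is prescribed
  cs <- cstar(fine)
  for (i in seq_len(length(fine) - 1)) {
    C[i + 1] <- .mix_step(C[i], cs[i], cs[i + 1],
                          fine[i + 1] - fine[i], chamber$tau_s)
  }
  Cout <- stats::approx(fine, C, xout = t_grid)$y
  data.frame(time_s = t_grid, C = Cout, A_true = A_leaf(t_grid),
             A_apparent = f * (cin - Cout) / S)
}

#' Transport lag between chamber and analyzer from a spike experiment
#'
#' Estimates the plumbing delay by cross-correlating a CO2 transient
#' recorded at the chamber outlet with the same transient seen by the TDL,
#' refining the integer-lag peak by parabolic interpolation.
#'
#' @param spike_chamber,spike_tdl Data frames `time_s`, `value` sampled on a
#'   uniform grid; the TDL series is delayed relative to the chamber.
#' @return Transport lag in seconds (positive: TDL later).
#' @export
estimate_lag <- function(spike_chamber, spike_tdl) {
  dt <- stats::median(diff(spike_chamber$time_s))
  lo <- max(min(spike_chamber$time_s), min(spike_tdl$time_s))
  hi <- min(max(spike_chamber$time_s), max(spike_tdl$time_s))
  if (hi <= lo) stop("spike series do not overlap in time")
  grid <- seq(lo, hi, by = dt)
  x <- stats::approx(spike_chamber$time_s, spike_chamber$value, grid)$y
  y <- stats::approx(spike_tdl$time_s, spike_tdl$value, grid)$y
  x <- x - mean(x); y <- y - mean(y)
  max_lag <- floor(length(grid) / 2)
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(L) {
    if (L >= 0) sum(x[seq_len(length(x) - L)] * y[seq_len(length(y) - L) + L])
    else sum(y[seq_len(length(y) + L)] * x[seq_len(length(x) + L) - L])
  }, 0)
  k <- which.max(cc)
  if (k == 1 || k == length(lags))
    stop("cross-correlation peak at the search boundary: ",
         "series appear uncorrelated or the lag exceeds half the record")
  # parabolic refinement around the discrete peak
  num <- cc[k - 1] - cc[k + 1]
  den <- cc[k - 1] - 2 * cc[k] + cc[k + 1]
  frac <- if (den != 0) 0.5 * num / den else 0
  (lags[k] + frac) * dt
}

#' Align TDL blocks with gas-exchange records
#'
#' Shifts TDL block timestamps back by the transport lag, optionally
#' deconvolves first-order chamber mixing (adds `tau * dC/dt` using a
#' central-difference derivative of the block means), and pairs each block
#' with the nearest gas-exchange record within the tolerance. Unmatched
#' blocks are retained with `matched = FALSE`.
#'
#' @param gasex Canonical gas-exchange records ([read_gas_exchange_log()]).
#' @param blocks Data frame of sample blocks with `time_s` plus signal
#'   columns (`c12`, `c13`).
#' @param transport_lag_s Plumbing delay (s) to remove from block times.
#' @param tolerance_s Maximum pairing distance (s). Default 5.
#' @param deconvolve Logical; default `FALSE` (pure time shift).
#' @param chamber [chamber_model()], required when `deconvolve = TRUE`.
#' @return `blocks` with shifted `time_s`, a `gasex_row` index, `matched`
#'   flag, and the paired gas-exchange columns.
#' @export
align_streams <- function(gasex, blocks, transport_lag_s, tolerance_s = 5,
                          deconvolve = FALSE, chamber = NULL) {
  blocks$time_s <- blocks$time_s - transport_lag_s
  if (deconvolve) {
    stopifnot(inherits(chamber, "chamber_model"))
    for (col in intersect(c("c12", "c13"), names(blocks))) {
      v <- blocks[[col]]
      tt <- blocks$time_s
      n <- length(v)
      if (n >= 3) {
        dv <- c((v[2] - v[1]) / (tt[2] - tt[1]),
                (v[3:n] - v[1:(n - 2)]) / (tt[3:n] - tt[1:(n - 2)]),
                (v[n] - v[n - 1]) / (tt[n] - tt[n - 1]))
        blocks[[col]] <- v + chamber$tau_s * dv
      }
    }
  }
  idx <- vapply(blocks$time_s, function(t) {
    j <- which.min(abs(gasex$time_s - t))
    if (abs(gasex$time_s[j] - t) <= tolerance_s) j else NA_integer_
  }, 0L)
  if (all(is.na(idx)))
    stop("no TDL block matches any gas-exchange record after the time ",
         "shift: streams do not overlap")
  out <- cbind(blocks, gasex_row = idx, matched = !is.na(idx))
  safe <- ifelse(is.na(idx), 1L, idx)
  gx <- gasex[safe, setdiff(names(gasex), "time_s"), drop = FALSE]
  gx[is.na(idx), ] <- NA
  rownames(gx) <- NULL
  cbind(out, gx)
}
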