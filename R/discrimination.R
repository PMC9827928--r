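#' delta-13C from isotopologue mole fractions
#'
#' Converts 12CO2 and 13CO2 mole fractions to delta notation relative to the
#' VPDB standard: delta = ((c13/c12)/R_standard - 1) * 1000 permil.
#'
#' @param c12,c13 Isotopologue mole fractions (umol mol-1); `c12` must be
#'   strictly positive.
#' @param r_standard 13C/12C ratio of the standard. Default VPDB, 0.0111797.
#' @return delta-13C in permil.
#' @export
#' @examples
#' delta13C(400, 400 * 0.0111797)           # 0 permil
#' delta13C(400, 400 * 0.0111797 * 0.99)    # -10 permil
delta13C <- function(c12, c13, r_standard = 0.0111797) {
  if (any(c12 <= 0)) stop("c12 must be > 0 to form an isotope ratio")
  ((c13 / c12) / r_standard - 1) * 1000
}

# inverse of delta13C: isotope ratio for a given delta (permil)
ratio_from_delta <- function(delta, r_standard = 0.0111797) {
  r_standard * (1 + delta / 1000)
}

#' Fit the concentration-series calibration of the TDL
#'
#' The TDL is calibrated by stepping through CO2-free air and three dilutions
#' of a single CO2 source (identical isotopic composition), whose true
#' isotopologue mole fractions are known from the flow-controller set points
#' and the source delta-13C. A straight line `measured = gain * true +
#' offset` is fitted per isotopologue; corrected readings are
#' `(measured - offset) / gain`. A certified tank measured in the same cycle
#' provides an independent QC residual.
#'
#' The fit's `valid_time_s` is the leverage-weighted mean time of the
#' calibration blocks, `sum(t * v * (v - mean(v))) / sum((v - mean(v))^2)`;
#' with this attribution a gain drifting linearly in time is recovered
#' exactly by linear interpolation between consecutive cycle fits.
#'
#' @param cal_blocks Data frame of calibration-phase block means with columns
#'   `site_id`, `time_s`, `c12`, `c13` covering `zero_air` and the `cal*`
#'   phases (a `tank` row, if present, is used only for QC).
#' @param truths List describing the true gas composition:
#'   `cal_points` (data frame `site_id`, `co2` total umol mol-1, `delta`
#'   permil) and optionally `tank` (list `co2`, `delta`).
#' @param r_standard VPDB ratio used to split total CO2 into isotopologues.
#' @return A list with class `"calibration_fit"`: per-isotopologue `gain`
#'   and `offset`, fit `residuals`, `tank_qc_delta` (permil, `NA` without a
#'   tank), and `valid_time_s`.
#' @export
fit_concentration_series <- function(cal_blocks, truths,
                                     r_standard = 0.0111797) {
  stopifnot(is.data.frame(cal_blocks),
            all(c("site_id", "time_s", "c12", "c13") %in% names(cal_blocks)))
  tp <- truths$cal_points
  stopifnot(is.data.frame(tp), all(c("site_id", "co2", "delta") %in% names(tp)))
  use <- cal_blocks[cal_blocks$site_id %in% c("zero_air", tp$site_id), ,
                    drop = FALSE]
  r <- ratio_from_delta(tp$delta, r_standard)
  true12 <- c(zero_air = 0, stats::setNames(tp$co2 / (1 + r), tp$site_id))
  true13 <- c(zero_air = 0, stats::setNames(tp$co2 * r / (1 + r), tp$site_id))
  v12 <- true12[use$site_id]
  v13 <- true13[use$site_id]
  if (length(unique(v12)) < 2)
    stop("need at least two distinct calibration concentrations ",
         "(zero air plus one dilution)")

  fit_iso <- function(v, m) {
    co <- stats::coef(stats::lm(m ~ v))
    list(gain = unname(co[2]), offset = unname(co[1]),
         residuals = m - (co[1] + co[2] * v))
  }
  f12 <- fit_iso(v12, use$c12)
  f13 <- fit_iso(v13, use$c13)
  if (f12$gain <= 0 || f13$gain <= 0)
    stop("negative calibration gain: calibration phases are likely ",
         "mis-assigned")

  dv <- v12 - mean(v12)
  valid_time <- sum(use$time_s * v12 * dv) / sum(dv^2)

  tank_qc <- NA_real_
  tank_row <- cal_blocks[cal_blocks$site_id == "tank", , drop = FALSE]
  if (nrow(tank_row) && !is.null(truths$tank)) {
    c12c <- (mean(tank_row$c12) - f12$offset) / f12$gain
    c13c <- (mean(tank_row$c13) - f13$offset) / f13$gain
    tank_qc <- abs(delta13C(c12c, c13c, r_standard) - truths$tank$delta)
  }
  out <- list(gain12 = f12$gain, offset12 = f12$offset,
              gain13 = f13$gain, offset13 = f13$offset,
              residuals12 = f12$residuals, residuals13 = f13$residuals,
              tank_qc_delta = tank_qc, valid_time_s = valid_time)
  class(out) <- "calibration_fit"
  out
}

# Global drift-calibration: one weighted regression per isotopologue over
# the calibration blocks of every cycle, with the instrument model
# measured = (g0 + g1 t) * true + offset (g1 dropped when only one cycle
# is available). Pooling all cycles suppresses the independent per-cycle
# parameter noise that a cycle-by-cycle fit leaves in the corrected
# series. Returns per-isotopologue correction closures (measured, t) ->
# true.
.fit_calibration_global <- function(cal_blocks, truths, r_standard) {
  tp <- truths$cal_points
  r <- ratio_from_delta(tp$delta, r_standard)
  true12 <- c(zero_air = 0, stats::setNames(tp$co2 / (1 + r), tp$site_id))
  true13 <- c(zero_air = 0, stats::setNames(tp$co2 * r / (1 + r), tp$site_id))
  use <- cal_blocks[cal_blocks$site_id %in% names(true12), , drop = FALSE]
  n_cycles <- length(unique(use$cycle_index))
  fit_iso <- function(v, m, t) {
    if (length(unique(v)) < 2)
      stop("need at least two distinct calibration concentrations")
    df <- data.frame(m = m, v = v, vt = v * t)
    co <- if (n_cycles >= 2) stats::coef(stats::lm(m ~ v + vt, data = df))
          else c(stats::coef(stats::lm(m ~ v, data = df)), vt = 0)
    if (co[2] <= 0)
      stop("negative calibration gain: calibration phases are likely ",
           "mis-assigned")
    function(meas, tt) (meas - co[1]) / (co[2] + co[3] * tt)
  }
  list(correct12 = fit_iso(true12[use$site_id], use$c12, use$time_s),
       correct13 = fit_iso(true13[use$site_id], use$c13, use$time_s))
}

#' Apply drift-corrected calibration to averaged TDL blocks
#'
#' Corrects block means using the calibration maps of the two cycles
#' bracketing them, with gain and offset interpolated linearly in time
#' between `fit_before$valid_time_s` and `fit_after$valid_time_s` (constant
#' outside that interval, and constant everywhere when the two fits
#' coincide).
#'
#' @param blocks Data frame with `time_s`, `c12`, `c13`.
#' @param fit_before,fit_after [fit_concentration_series()] results;
#'   `fit_before` must not be later than `fit_after`.
#' @return `blocks` with corrected `c12`, `c13`.
#' @export
apply_drift_correction <- function(blocks, fit_before, fit_after = fit_before) {
  stopifnot(inherits(fit_before, "calibration_fit"),
            inherits(fit_after, "calibration_fit"))
  t0 <- fit_before$valid_time_s
  t1 <- fit_after$valid_time_s
  if (t1 < t0) stop("fit_after precedes fit_before: fits in wrong order")
  w <- if (t1 > t0) pmin(1, pmax(0, (blocks$time_s - t0) / (t1 - t0))) else 0
  lin <- function(a, b) a + w * (b - a)
  blocks$c12 <- (blocks$c12 - lin(fit_before$offset12, fit_after$offset12)) /
    lin(fit_before$gain12, fit_after$gain12)
  blocks$c13 <- (blocks$c13 - lin(fit_before$offset13, fit_after$offset13)) /
    lin(fit_before$gain13, fit_after$gain13)
  blocks
}

#' Reference air for one cycle
#'
#' Averages the CO2 and delta-13C of the reference air measured before and
#' after the sample phase of a cycle. If one bracketing phase is missing the
#' other is used alone, with a warning.
#'
#' @param cycle One element of a [segment_cycles()] result (fields
#'   `reference_before`, `reference_after`), with blocks already
#'   drift-corrected.
#' @param r_standard VPDB ratio.
#' @return List with `Cref` (12CO2, umol mol-1) and `delta_ref` (permil).
#' @export
pair_reference <- function(cycle, r_standard = 0.0111797) {
  b <- cycle$reference_before
  a <- cycle$reference_after
  if (is.null(b) && is.null(a))
    stop("cycle ", cycle$cycle_index, " has no reference phase")
  if (is.null(b) || is.null(a)) {
    warning("cycle ", cycle$cycle_index,
            ": only one bracketing reference phase present")
    one <- if (is.null(b)) a else b
    return(list(Cref = mean(one$c12),
                delta_ref = delta13C(mean(one$c12), mean(one$c13),
                                     r_standard)))
  }
  d_b <- delta13C(mean(b$c12), mean(b$c13), r_standard)
  d_a <- delta13C(mean(a$c12), mean(a$c13), r_standard)
  list(Cref = (mean(b$c12) + mean(a$c12)) / 2,
       delta_ref = (d_b + d_a) / 2)
}

#' xi, the drawdown ratio amplifying instrument noise
#'
#' `xi = Cref / (Cref - Csamp)`: the ratio of the 12CO2 mole fraction
#' entering the chamber to the photosynthetic drawdown across it. Points
#' with negligible drawdown (|Cref - Csamp| below `eps`, e.g. in darkness)
#' are returned as `NA` -- they carry no discrimination signal.
#'
#' @param cref,csamp 12CO2 mole fractions of air entering and leaving the
#'   chamber (umol mol-1).
#' @param eps Minimum absolute drawdown (umol mol-1). Default 0.5.
#' @return xi (dimensionless), `NA` where non-computable.
#' @export
#' @examples
#' xi(800, 400)  # 2
#' xi(800, 480)  # 2.5
xi <- function(cref, csamp, eps = 0.5) {
  dd <- cref - csamp
  ifelse(abs(dd) < eps, NA_real_, cref / dd)
}

#' Observed online 13C photosynthetic discrimination
#'
#' `Delta = 1000 * xi * (ds - dr) / (1000 + ds - xi * (ds - dr))` permil,
#' from the delta-13C of sample and reference air and the drawdown ratio xi.
#' Points whose denominator is not positive are returned as `NA`.
#'
#' @param xi Drawdown ratio, see [xi()].
#' @param delta_samp,delta_ref delta-13C of chamber and reference air
#'   (permil).
#' @return Delta13C_obs in permil, `NA` where non-computable.
#' @export
#' @examples
#' observed_discrimination(2, -6, -8)  # 4000/990 = 4.0404 permil
observed_discrimination <- function(xi, delta_samp, delta_ref) {
  d <- delta_samp - delta_ref
  den <- 1000 + delta_samp - xi * d
  ifelse(!is.na(den) & den > 0, 1000 * xi * d / den, NA_real_)
}

#' Instrument error of the observed discrimination
#'
#' The error of Delta13C_obs grows with xi: `error = 2 * xi * X` permil,
#' where `X` is the instrument precision of a 10 s data point (0.24 permil
#' and 0.14 permil for the two laser configurations used at the bench).
#' The relative error is `100 * error / Delta13C_obs`; it is `Inf` when
#' Delta13C_obs is zero (a zero-signal point carries no information) and is
#' reported as an absolute percentage.
#'
#' The alternative form `sqrt(2) * xi * X` is available through
#' `c4_constants(error_model = "sqrt2xiX")` for sensitivity analysis.
#'
#' @param xi Drawdown ratio.
#' @param precision Instrument precision X (permil).
#' @param delta_obs Optional Delta13C_obs (permil) for the relative error.
#' @param constants A [c4_constants()] set (for `error_model`).
#' @return Data frame with `error` (permil) and `error_pct`.
#' @export
#' @examples
#' discrimination_error(2.5, 0.24)$error  # 1.2 permil
discrimination_error <- function(xi, precision, delta_obs = NA_real_,
                                 constants = c4_constants()) {
  stopifnot(precision >= 0)
  fac <- if (identical(constants$error_model, "sqrt2xiX")) sqrt(2) else 2
  err <- fac * abs(xi) * precision
  delta_obs <- rep_len(delta_obs, length(err))
  pct <- ifelse(is.na(delta_obs) | delta_obs == 0, Inf,
                100 * abs(err / delta_obs))
  data.frame(error = err, error_pct = pct)
}

#' Exclusion rule for high-error discrimination points
#'
#' Flags points whose relative error of Delta13C_obs exceeds the threshold
#' (strictly greater than, so a point at exactly the threshold is kept).
#' Excluded points are retained in the output with `included = FALSE`.
#'
#' @param points Data frame containing an `error_pct` column.
#' @param threshold_pct Exclusion threshold in percent. Default 50.
#' @return `points` with a logical `included` column.
#' @export
filter_by_error <- function(points, threshold_pct = 50) {
  stopifnot("error_pct" %in% names(points))
  points$included <- !is.na(points$error_pct) &
    points$error_pct <= threshold_pct
  points
}
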