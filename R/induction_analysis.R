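# Per-segment fitters. Each returns list(type, par, fitted, sse, r2).
.fit_flat <- function(t, y, w = rep(1, length(y))) {
  mu <- stats::weighted.mean(y, w)
  list(type = "flat", par = c(mean = mu), sse = sum(w * (y - mu)^2), r2 = 0)
}

.fit_linear <- function(t, y, w = rep(1, length(y))) {
  if (length(y) < 3) {
    mu <- stats::weighted.mean(y, w)
    return(list(type = "linear",
                par = c(intercept = mu, slope = 0, slope_p = NA_real_),
                sse = sum(w * (y - mu)^2), r2 = 0))
  }
  df <- data.frame(t = t, y = y, w = w)
  fit <- stats::lm(y ~ t, data = df, weights = w)
  res <- stats::residuals(fit)
  tss <- sum(w * (y - stats::weighted.mean(y, w))^2)
  sse <- sum(w * res^2)
  list(type = "linear",
       par = c(intercept = unname(stats::coef(fit)[1]),
               slope = unname(stats::coef(fit)[2]),
               slope_p = suppressWarnings(
                 summary(fit)$coefficients[2, 4])),
       sse = sse, r2 = if (tss > 0) 1 - sse / tss else 0)
}

.fit_exponential <- function(t, y, w = rep(1, length(y))) {
  tb <- t[1]
  n <- length(y)
  if (diff(range(y)) < 1e-12) {
    # degenerate constant segment: no decline to fit
    return(list(type = "exponential",
                par = c(y0 = mean(y), A1 = 0, t1 = diff(range(t)) + 1,
                        tb = tb),
                sse = 0, r2 = 0, fallback = FALSE))
  }
  tail_mean <- mean(y[max(1, n - max(3, floor(n / 4)) + 1):n])
  start <- list(y0 = tail_mean, A1 = y[1] - tail_mean,
                t1 = diff(range(t)) / 3)
  df <- data.frame(t = t, y = y, w = w)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ y0 + A1 * exp(-(t - tb) / t1), data = df,
                      start = start, weights = w,
                      lower = c(-Inf, -Inf, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  tss <- sum(w * (y - stats::weighted.mean(y, w))^2)
  if (!is.null(fit)) {
    res <- y - stats::predict(fit)
    p <- stats::coef(fit)
    sse <- sum(w * res^2)
    return(list(type = "exponential",
                par = c(y0 = unname(p["y0"]), A1 = unname(p["A1"]),
                        t1 = unname(p["t1"]), tb = tb),
                sse = sse,
                r2 = if (tss > 0) 1 - sse / tss else 0,
                fallback = FALSE))
  }
  # fall back to a log-linear fit of (y - tail mean), flagged
  z <- y - tail_mean
  ok <- z > 0
  if (sum(ok) < 3)
    stop("exponential segment fit failed and too few points for the ",
         "log-linear fallback")
  lf <- stats::lm(lz ~ tt, data = data.frame(lz = log(z[ok]), tt = t[ok]))
  slope <- unname(stats::coef(lf)[2])
  t1 <- -1 / slope
  A1 <- exp(unname(stats::coef(lf)[1]) + slope * tb)
  yhat <- tail_mean + A1 * exp(-(t - tb) / t1)
  sse <- sum(w * (y - yhat)^2)
  list(type = "exponential",
       par = c(y0 = tail_mean, A1 = unname(A1), t1 = unname(t1), tb = tb),
       sse = sse, r2 = if (tss > 0) 1 - sse / tss else 0, fallback = TRUE)
}

.fit_segment <- function(type, t, y, w = rep(1, length(y))) {
  switch(type,
         flat = .fit_flat(t, y, w),
         linear = .fit_linear(t, y, w),
         exponential = .fit_exponential(t, y, w),
         stop("unknown segment type '", type, "'"))
}

#' Piecewise characterisation of a leakiness time course
#'
#' Fits a 2- or 3-segment piecewise model to an included-only (time, phi)
#' series: e.g. linear growth followed by exponential decline, or
#' flat / linear / exponential. Breakpoints are found by exhaustive grid
#' search over the observed timestamps, minimising the total sum of squared
#' errors; each segment is fitted independently by least squares (no
#' continuity constraint, so per-segment R2 values are reported as fitted).
#' The exponential segment is `y = y0 + A1 * exp(-(t - tb) / t1)` fitted by
#' nonlinear least squares (initialised from the tail mean, the first-point
#' offset and a third of the span), with a flagged log-linear fallback.
#'
#' The time constant `t1` of the declining segment and the time `t_peak` at
#' which the rising segment ends (the last breakpoint) are the headline
#' kinetic parameters.
#'
#' @param series Data frame with `time_s` and `phi` (already filtered to
#'   included points).
#' @param segment_types Character vector of segment types in order, from
#'   `"flat"`, `"linear"`, `"exponential"`. Default
#'   `c("linear", "exponential")`.
#' @param min_points Minimum points per segment. Default 10.
#' @param weights Optional per-point weights (e.g. inverse variances of
#'   replicate means); the default is an unweighted fit.
#' @param continuity If `TRUE` (2-segment linear/exponential only), the two
#'   segments are constrained to meet at the breakpoint
#'   (`y = y_b + s (t - b)` before, `y0 + (y_b - y0) exp(-(t - b)/t1)`
#'   after, fitted jointly per candidate breakpoint). The constrained form
#'   has fewer free parameters and locates the kink more stably on noisy
#'   data; the default independent fit matches how per-segment R2 values
#'   are conventionally reported.
#' @return List with class `"piecewise_fit"`: `n_segments`, `breakpoints`
#'   (s), `segments` (per-segment fit lists), `t1` (s), `t_peak` (s),
#'   `sse`.
#' @export
fit_piecewise <- function(series, segment_types = c("linear", "exponential"),
                          min_points = 10, weights = NULL,
                          continuity = FALSE) {
  stopifnot(all(c("time_s", "phi") %in% names(series)))
  o <- order(series$time_s)
  t <- series$time_s[o]
  y <- series$phi[o]
  w <- if (is.null(weights)) rep(1, length(t)) else weights[o]
  stopifnot(all(w >= 0), length(w) == length(t))
  if (continuity) {
    if (!identical(segment_types, c("linear", "exponential")))
      stop("continuity-constrained fitting is implemented for the ",
           "linear/exponential two-segment model only")
    return(.fit_piecewise_continuous(t, y, w, min_points))
  }
  n <- length(t)
  k <- length(segment_types)
  stopifnot(k %in% c(1, 2, 3))
  if (n < k * min_points)
    stop("too few included points (", n, ") for ", k,
         " segments of at least ", min_points, " points each")

  seg_fit_cache <- new.env()
  fit_range <- function(type, i0, i1) {
    key <- paste(type, i0, i1)
    if (!is.null(seg_fit_cache[[key]])) return(seg_fit_cache[[key]])
    f <- .fit_segment(type, t[i0:i1], y[i0:i1], w[i0:i1])
    seg_fit_cache[[key]] <- f
    f
  }

  best <- NULL
  consider <- function(cuts) {
    # cuts: indices of first point of segments 2..k; candidates whose
    # segment fit fails outright are skipped
    bounds <- c(1, cuts, n + 1)
    fits <- vector("list", k)
    sse <- 0
    for (s in seq_len(k)) {
      i0 <- bounds[s]; i1 <- bounds[s + 1] - 1
      f <- tryCatch(fit_range(segment_types[s], i0, i1),
                    error = function(e) NULL)
      if (is.null(f)) return(invisible())
      fits[[s]] <- f
      sse <- sse + f$sse
    }
    if (is.null(best) || sse < best$sse)
      best <<- list(cuts = cuts, fits = fits, sse = sse)
  }

  if (k == 1) {
    consider(integer())
  } else if (k == 2) {
    for (c1 in (min_points + 1):(n - min_points + 1)) consider(c1)
  } else {
    for (c2 in (2 * min_points + 1):(n - min_points + 1))
      for (c1 in (min_points + 1):(c2 - min_points)) consider(c(c1, c2))
  }

  if (is.null(best))
    stop("no breakpoint candidate produced a valid piecewise fit")
  cuts <- best$cuts
  breakpoints <- if (length(cuts)) t[cuts] else numeric()
  exp_idx <- which(segment_types == "exponential")
  t1 <- if (length(exp_idx)) unname(best$fits[[exp_idx[1]]]$par["t1"]) else NA_real_
  t_peak <- if (length(cuts)) breakpoints[length(cuts)] else t[1]
  out <- list(n_segments = k, breakpoints = breakpoints,
              segments = best$fits, t1 = t1, t_peak = t_peak,
              sse = best$sse, segment_types = segment_types)
  class(out) <- "piecewise_fit"
  out
}

# Joint linear-then-exponential fit with continuity at the breakpoint:
# grid search over observed timestamps, nonlinear least squares per
# candidate (y_b, slope, y0, t1 shared across segments).
.fit_piecewise_continuous <- function(t, y, w, min_points) {
  n <- length(t)
  if (n < 2 * min_points)
    stop("too few included points (", n, ") for 2 segments of at least ",
         min_points, " points each")
  tail_mean <- mean(y[t >= stats::quantile(t, 0.8)])
  best <- NULL
  for (ci in (min_points + 1):(n - min_points + 1)) {
    bp <- t[ci]
    st <- list(yb = max(stats::median(y[abs(t - bp) <= 60]), tail_mean),
               s = (y[ci] - y[1]) / max(bp - t[1], 1),
               y0 = tail_mean, t1 = diff(range(t)) / 3)
    df <- data.frame(t = t, y = y, w = w)
    m <- tryCatch(minpack.lm::nlsLM(
      y ~ ifelse(t < bp, yb + s * (t - bp),
                 y0 + (yb - y0) * exp(-(t - bp) / t1)),
      data = df, start = st, weights = w,
      lower = c(-Inf, -Inf, -Inf, 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 150)),
      error = function(e) NULL)
    if (is.null(m)) next
    sse <- sum(w * (y - stats::predict(m))^2)
    if (is.null(best) || sse < best$sse)
      best <- list(bp = bp, sse = sse, par = stats::coef(m))
  }
  if (is.null(best))
    stop("no breakpoint candidate produced a valid piecewise fit")
  p <- best$par
  tssw <- sum(w * (y - stats::weighted.mean(y, w))^2)
  out <- list(n_segments = 2L, breakpoints = best$bp,
              segments = list(
                list(type = "linear",
                     par = c(intercept = unname(p["yb"] - p["s"] * best$bp),
                             slope = unname(p["s"])),
                     sse = NA_real_, r2 = NA_real_),
                list(type = "exponential",
                     par = c(y0 = unname(p["y0"]),
                             A1 = unname(p["yb"] - p["y0"]),
                             t1 = unname(p["t1"]), tb = best$bp),
                     sse = NA_real_, r2 = NA_real_)),
              t1 = unname(p["t1"]), t_peak = best$bp, sse = best$sse,
              r2 = if (tssw > 0) 1 - best$sse / tssw else 0,
              segment_types = c("linear", "exponential"),
              continuity = TRUE)
  class(out) <- "piecewise_fit"
  out
}

#' @export
print.piecewise_fit <- function(x, ...) {
  cat("Piecewise fit:", paste(x$segment_types, collapse = " / "), "\n")
  cat("  breakpoints (s):", paste(signif(x$breakpoints, 6), collapse = ", "),
      "\n  t_peak:", signif(x$t_peak, 6), "s   t1:", signif(x$t1, 6),
      "s   SSE:", signif(x$sse, 6), "\n")
  invisible(x)
}

#' Induction times IT50 and IT90
#'
#' The times at which assimilation first reaches 50% and 90% of its
#' steady-state value, by linear interpolation between the bracketing
#' samples. The steady state defaults to the mean of A after 1500 s.
#'
#' @param series Data frame with `time_s` and `A`.
#' @param A_steady Steady-state assimilation; default mean of `A` at
#'   `time_s >= 1500`.
#' @return List with `IT50` and `IT90` (s).
#' @export
induction_times <- function(series, A_steady = NULL) {
  o <- order(series$time_s)
  t <- series$time_s[o]; A <- series$A[o]
  if (is.null(A_steady)) {
    tail_sel <- t >= 1500
    if (!any(tail_sel)) stop("no data after 1500 s to define steady state")
    A_steady <- mean(A[tail_sel])
  }
  crossing <- function(frac, label) {
    thr <- frac * A_steady
    above <- A >= thr
    if (!any(above))
      stop("assimilation never reaches ", label, " (", signif(thr, 4),
           " umol m-2 s-1)")
    i <- which(above)[1]
    if (i == 1) return(t[1])
    t[i - 1] + (thr - A[i - 1]) * (t[i] - t[i - 1]) / (A[i] - A[i - 1])
  }
  list(IT50 = crossing(0.5, "50% of steady state"),
       IT90 = crossing(0.9, "90% of steady state"))
}

#' Rubisco-activation time constant from the semilog induction slope
#'
#' When the later phase of induction is Rubisco-limited, `ln(A_f - A)`
#' declines linearly with time and the activation time constant is the
#' negative reciprocal of its slope. The regression uses the measurements in
#' the fitting window (300--900 s by default); points where `A_f - A <= 0`
#' are clipped out.
#'
#' @param series Data frame with `time_s` and `A`.
#' @param A_f Steady-state assimilation at high light (umol m-2 s-1).
#' @param window Fitting window in s. Default `c(300, 900)`.
#' @return List with `tau_A` (s), `r2`, `n`, and `poor_fit` (`TRUE` when
#'   R2 < 0.9, signalling a non-exponential time course).
#' @export
rubisco_tau <- function(series, A_f, window = c(300, 900)) {
  sel <- series$time_s >= window[1] & series$time_s <= window[2] &
    (A_f - series$A) > 0
  t <- series$time_s[sel]
  z <- log(A_f - series$A[sel])
  if (length(t) < 5)
    stop("fewer than 5 usable points in the semilog window")
  fit <- stats::lm(z ~ t)
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0) stop("semilog slope is non-negative: A is not ",
                       "approaching A_f in the window")
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(tau_A = -1 / slope, r2 = r2, n = length(t), poor_fit = r2 < 0.9)
}

#' Window means of leakiness during and after induction
#'
#' Arithmetic mean and standard error of included leakiness points over the
#' first 600 s of induction, the full 1500 s induction period, and the
#' steady state (after 1500 s). Excluded points (discrimination error
#' > 50%) are omitted.
#'
#' @param series Data frame with `time_s`, `phi` and logical `included`.
#' @param steady_start_s Start of the steady-state window (s). Default 1500.
#' @return Data frame with rows `mean_600`, `mean_1500`, `steady` and
#'   columns `mean`, `se`, `n`.
#' @export
window_means <- function(series, steady_start_s = 1500) {
  stopifnot(all(c("time_s", "phi", "included") %in% names(series)))
  use <- series[series$included & !is.na(series$phi), , drop = FALSE]
  windows <- list(
    mean_600 = c(0, 600),
    mean_1500 = c(0, steady_start_s),
    steady = c(steady_start_s, Inf))
  rows <- lapply(names(windows), function(nm) {
    w <- windows[[nm]]
    v <- use$phi[use$time_s > w[1] & use$time_s <= w[2]]
    if (!length(v)) stop("no included points in window '", nm, "'")
    data.frame(window = nm, mean = mean(v),
               se = stats::sd(v) / sqrt(length(v)), n = length(v))
  })
  do.call(rbind, rows)
}

#' Percent elevation of a window mean over the steady state
#'
#' `100 * (mean_window / mean_steady - 1)`, reported at full precision;
#' round to the nearest integer for reporting.
#'
#' @param mean_window,mean_steady Window and steady-state means;
#'   `mean_steady` must be positive.
#' @return Percent elevation.
#' @export
#' @examples
#' percent_increase(0.237, 0.180)  # 31.7 -> 32%
percent_increase <- function(mean_window, mean_steady) {
  if (any(mean_steady <= 0))
    stop("steady-state mean must be positive")
  100 * (mean_window / mean_steady - 1)
}

#' Compare two groups of leakiness summaries
#'
#' Thin wrapper over the standard routines: Shapiro--Wilk normality test per
#' group, Levene's test of variance homogeneity across groups, and
#' Student's (equal-variance) two-sample t-test.
#'
#' @param values_a,values_b Numeric vectors, n >= 3 each.
#' @return List with `shapiro_p` (length 2), `levene_p`, `t_p`, `t_statistic`.
#' @export
group_compare <- function(values_a, values_b) {
  if (length(values_a) < 3 || length(values_b) < 3)
    stop("need at least 3 values per group")
  sw <- function(v) tryCatch(stats::shapiro.test(v)$p.value,
                             error = function(e) NA_real_)
  g <- factor(rep(c("a", "b"), c(length(values_a), length(values_b))))
  lev <- car::leveneTest(c(values_a, values_b) ~ g)
  tt <- stats::t.test(values_a, values_b, var.equal = TRUE)
  list(shapiro_p = c(a = sw(values_a), b = sw(values_b)),
       levene_p = lev[["Pr(>F)"]][1],
       t_p = tt$p.value, t_statistic = unname(tt$statistic))
}
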