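#' Construct a processed trace
#'
#' A time series of percent change (dF/F0 or dR/R0) or calibrated
#' millivolts, carrying its baseline window and provenance.
#'
#' @param time_s Time grid (s).
#' @param value Values.
#' @param baseline_window `c(start, end)` in s (or `NULL`).
#' @param units `"%"` or `"mV"`.
#' @param provenance Character notes on the operations applied.
#' @return An object of class `"processed_trace"` (also a data frame).
#' @export
processed_trace <- function(time_s, value, baseline_window = NULL,
                            units = "%", provenance = character(0)) {
  d <- data.frame(time_s = as.numeric(time_s), value = as.numeric(value))
  structure(d, baseline_window = baseline_window, units = units,
            provenance = provenance,
            class = c("processed_trace", "data.frame"))
}

# accept a processed_trace, a (time, value) data frame, or value vector + time
.as_tv <- function(trace, time_s = NULL) {
  if (inherits(trace, "processed_trace") ||
      (is.data.frame(trace) && all(c("time_s", "value") %in% names(trace)))) {
    list(time_s = trace$time_s, value = trace$value)
  } else {
    if (is.null(time_s)) stop("time_s required for a bare numeric trace", call. = FALSE)
    list(time_s = as.numeric(time_s), value = as.numeric(trace))
  }
}

.window_idx <- function(time_s, window) {
  which(time_s >= window[1] & time_s <= window[2])
}

#' Percent fluorescence change relative to baseline (dF/F0)
#'
#' `100 (F - F0bar) / F0bar` with `F0bar` the mean over the baseline
#' window (conventionally the first 5--10 valid points before signal
#' onset). Invariant under any positive gain applied to the raw trace.
#'
#' @param trace Fluorescence trace: `"processed_trace"`, a
#'   `time_s`/`value` data frame (e.g. from [channel_trace()]), or a bare
#'   numeric vector with `time_s` supplied.
#' @param baseline_window `c(start, end)` in s; must contain >= 3 samples.
#' @param time_s Time grid when `trace` is a bare vector.
#' @return A `"processed_trace"` in percent.
#' @export
dff0 <- function(trace, baseline_window, time_s = NULL) {
  tv <- .as_tv(trace, time_s)
  idx <- .window_idx(tv$time_s, baseline_window)
  if (length(idx) < 3L) {
    stop("baseline window must contain at least 3 samples", call. = FALSE)
  }
  f0 <- mean(tv$value[idx])
  if (!is.finite(f0) || f0 <= 0) {
    stop("baseline mean is not positive; check background subtraction",
         call. = FALSE)
  }
  processed_trace(tv$time_s, 100 * (tv$value - f0) / f0,
                  baseline_window = baseline_window, units = "%",
                  provenance = "dff0")
}

#' Subtract a control response
#'
#' Pointwise subtraction of the control trace (e.g. the response to mixing
#' with plain medium), setting the control level to 0. The control is
#' resampled onto the stimulated trace's grid by linear interpolation if
#' needed.
#'
#' @param stim,control Processed traces (or `time_s`/`value` data frames).
#' @return A `"processed_trace"`.
#' @export
subtract_control <- function(stim, control) {
  s <- .as_tv(stim); ctl <- .as_tv(control)
  if (max(ctl$time_s) < min(s$time_s) || min(ctl$time_s) > max(s$time_s)) {
    stop("stimulated and control traces cover disjoint time ranges", call. = FALSE)
  }
  cv <- if (length(ctl$time_s) == length(s$time_s) &&
            all(abs(ctl$time_s - s$time_s) < 1e-12)) {
    ctl$value
  } else {
    stats::approx(ctl$time_s, ctl$value, xout = s$time_s, rule = 2)$y
  }
  processed_trace(s$time_s, s$value - cv,
                  baseline_window = attr(stim, "baseline_window"),
                  units = if (inherits(stim, "processed_trace")) attr(stim, "units") else "%",
                  provenance = c(attr(stim, "provenance"), "subtract_control"))
}

#' Centered sliding average
#'
#' Centered moving mean over a window of `window_s` seconds; at the trace
#' ends the window shrinks symmetrically so the output has full length.
#'
#' @param trace Trace (`processed_trace`, data frame, or vector).
#' @param window_s Window length (s); must cover >= 3 samples and not
#'   exceed the trace.
#' @param time_s Time grid for a bare vector.
#' @return Same shape as the input trace type (a `"processed_trace"`).
#' @export
sliding_average <- function(trace, window_s, time_s = NULL) {
  tv <- .as_tv(trace, time_s)
  n <- length(tv$value)
  dt <- stats::median(diff(tv$time_s))
  m <- round(window_s / dt)
  if (m < 3L) stop("window must cover at least 3 samples", call. = FALSE)
  if (m > n) stop("window longer than the trace", call. = FALSE)
  half <- (m - 1L) %/% 2L
  cs <- cumsum(c(0, tv$value))
  i <- seq_len(n)
  h <- pmin(half, i - 1L, n - i)       # symmetric shrink at the edges
  out <- (cs[i + h + 1L] - cs[i - h]) / (2 * h + 1L)
  processed_trace(tv$time_s, out,
                  baseline_window = attr(trace, "baseline_window"),
                  units = if (inherits(trace, "processed_trace")) attr(trace, "units") else "%",
                  provenance = c(attr(trace, "provenance"),
                                 sprintf("sliding_average(%gs)", window_s)))
}

#' Slope-based crosstalk between two channels
#'
#' Ordinary least-squares fit `target = slope * source + intercept` over
#' the stated window; the crosstalk percentage is 100 times the slope. The
#' estimator is intentionally asymmetric: the loaded probe's channel is
#' the regressor. Perfectly correlated channels give 100%; an unrelated
#' flat target gives 0%. Both traces are expected on a common grid and on
#' a common (baseline-referenced) scale.
#'
#' @param source,target Traces (`processed_trace`, `time_s`/`value` data
#'   frames, or bare vectors sharing `time_s`).
#' @param window_s `c(start, end)` window in s (default: full overlap);
#'   must contain >= 10 points.
#' @param time_s Time grid for bare vectors.
#' @return An object of class `"crosstalk_result"` with `slope`,
#'   `percent` (= 100 * slope), `intercept`, `window_s`, `n_points`.
#' @export
crosstalk <- function(source, target, window_s = NULL, time_s = NULL) {
  s <- .as_tv(source, time_s); g <- .as_tv(target, time_s)
  if (length(s$value) != length(g$value)) {
    stop("source and target must share a time grid", call. = FALSE)
  }
  if (is.null(window_s)) window_s <- range(s$time_s)
  idx <- .window_idx(s$time_s, window_s)
  if (length(idx) < 10L) stop("crosstalk window must contain >= 10 points", call. = FALSE)
  x <- s$value[idx]; y <- g$value[idx]
  if (stats::var(x) == 0) stop("source trace has zero variance in the window", call. = FALSE)
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  structure(list(slope = slope, percent = 100 * slope,
                 intercept = unname(stats::coef(fit)[1]),
                 window_s = window_s, n_points = length(idx)),
            class = "crosstalk_result")
}

#' @export
print.crosstalk_result <- function(x, ...) {
  cat(sprintf("<crosstalk> %.3g%% (slope %.4g, intercept %.3g, n = %d)\n",
              x$percent, x$slope, x$intercept, x$n_points))
  invisible(x)
}

#' Signal-to-noise ratio
#'
#' Mean divided by standard deviation over a window of stationary signal
#' (200 data points by convention).
#'
#' @param trace Trace (vector or data frame).
#' @param window_points Number of points (default 200).
#' @param start Index of the first point of the window (default 1).
#' @return S/N ratio; `Inf` with a warning when the SD is zero.
#' @export
snr <- function(trace, window_points = 200L, start = 1L) {
  v <- if (is.data.frame(trace)) trace$value else as.numeric(trace)
  if (start + window_points - 1L > length(v)) {
    stop("window extends past the trace", call. = FALSE)
  }
  w <- v[start:(start + window_points - 1L)]
  s <- stats::sd(w)
  if (s == 0) {
    warning("zero standard deviation in S/N window; reporting Inf")
    return(Inf)
  }
  mean(w) / s
}

#' Percent change in an excitation ratio (dR/R0)
#'
#' `R = num/den` pointwise, reported as `100 (R - R0bar)/R0bar` with
#' `R0bar` the baseline-window mean of the ratio. Invariant under
#' independent positive gains on numerator and denominator.
#'
#' @param num,den Traces on a common grid (data frames or vectors).
#' @param baseline_window `c(start, end)` in s.
#' @param time_s Time grid for bare vectors.
#' @return A `"processed_trace"` in percent.
#' @export
ratio_trace <- function(num, den, baseline_window, time_s = NULL) {
  a <- .as_tv(num, time_s); b <- .as_tv(den, time_s)
  if (length(a$value) != length(b$value)) {
    stop("numerator and denominator must share a time grid", call. = FALSE)
  }
  bad <- which(b$value <= 0)
  if (length(bad)) {
    stop("nonpositive denominator sample at index ", bad[1], call. = FALSE)
  }
  r <- a$value / b$value
  idx <- .window_idx(a$time_s, baseline_window)
  if (length(idx) < 3L) stop("baseline window must contain at least 3 samples", call. = FALSE)
  r0 <- mean(r[idx])
  processed_trace(a$time_s, 100 * (r - r0) / r0,
                  baseline_window = baseline_window, units = "%",
                  provenance = "ratio_trace")
}

#' Unconstrained monoexponential fit
#'
#' Least-squares fit of `y(t) = offset + amplitude exp(-k (t - t1))` over
#' `t_range` (with `t1 = t_range[1]` as the amplitude reference), the
#' standard model for chelator-quench dissociation kinetics. Initial
#' values come from a log-linear regression of `|y - tail mean|`; the fit
#' itself is unweighted Levenberg-Marquardt with no constraints.
#'
#' @param trace Trace (data frame or vector).
#' @param t_range `c(start, end)` fit window (s); needs >= 20 points.
#' @param time_s Time grid for a bare vector.
#' @return An object of class `"exp_fit"` with `k_per_s`, `amplitude`,
#'   `offset`, standard errors, and residual RMS.
#' @export
fit_monoexponential <- function(trace, t_range = NULL, time_s = NULL) {
  tv <- .as_tv(trace, time_s)
  if (is.null(t_range)) t_range <- range(tv$time_s)
  idx <- .window_idx(tv$time_s, t_range)
  if (length(idx) < 20L) stop("fit range must contain >= 20 points", call. = FALSE)
  t <- tv$time_s[idx] - t_range[1]
  y <- tv$value[idx]

  # initializer: offset from the tail, rate from log-linear decay
  ntail <- max(5L, round(length(y) * 0.1))
  off0 <- mean(utils::tail(y, ntail))
  d <- y - off0
  amp_sign <- sign(mean(utils::head(d, max(5L, round(length(d) * 0.1)))))
  if (amp_sign == 0) amp_sign <- 1
  mag <- abs(d)
  use <- which(mag > max(mag) * 0.05)
  if (length(use) < 5L || max(mag) == 0) {
    stop("degenerate amplitude: trace has no resolvable exponential component",
         call. = FALSE)
  }
  ll <- stats::lm(log(mag[use]) ~ t[use])
  k0 <- max(1e-6, -unname(stats::coef(ll)[2]))
  a0 <- amp_sign * exp(unname(stats::coef(ll)[1]))

  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ offset + amplitude * exp(-k * t),
                      start = list(offset = off0, amplitude = a0, k = k0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop(sprintf("monoexponential fit did not converge (initializer k = %.4g /s): %s",
                   k0, conditionMessage(e)), call. = FALSE)
    })
  co <- summary(fit)$coefficients
  res <- stats::residuals(fit)
  structure(list(k_per_s = co["k", "Estimate"],
                 amplitude = co["amplitude", "Estimate"],
                 offset = co["offset", "Estimate"],
                 k_se = co["k", "Std. Error"],
                 amplitude_se = co["amplitude", "Std. Error"],
                 offset_se = co["offset", "Std. Error"],
                 residual_rms = sqrt(mean(res^2)),
                 t_range = t_range, n_points = length(idx)),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<monoexponential fit> k = %.4g +/- %.2g /s, amplitude %.4g, offset %.4g (n = %d)\n",
              x$k_per_s, x$k_se, x$amplitude, x$offset, x$n_points))
  invisible(x)
}

#' Potassium Nernst potential
#'
#' `E_K = (R T / F) ln([K+]_out / [K+]_in)` in mV. Defaults: intracellular
#' K+ 423 mM and 18 degrees C (291.15 K), the standard values for sea
#' urchin sperm calibrations.
#'
#' @param K_out_mM Extracellular K+ (mM, > 0).
#' @param K_in_mM Intracellular K+ (mM, > 0; default 423).
#' @param temp_K Temperature (K; default 291.15).
#' @return Potential in mV.
#' @export
nernst_potential <- function(K_out_mM, K_in_mM = 423, temp_K = 291.15) {
  if (any(K_out_mM <= 0) || K_in_mM <= 0 || temp_K <= 0) {
    stop("concentrations and temperature must be positive", call. = FALSE)
  }
  R <- 8.3145; Fd <- 96485
  1000 * (R * temp_K / Fd) * log(K_out_mM / K_in_mM)
}

#' Calibrate a voltage dye against K+ Nernst potentials
#'
#' OLS fit of peak dF/F0 amplitudes against the Nernst potentials of the
#' corresponding external K+ concentrations. The slope is the voltage
#' sensitivity (% dF/F0 per mV); the x-intercept is the resting potential
#' (the potential at which the stimulus no longer changes Vm).
#'
#' @param peak_dff_pct Peak dF/F0 amplitudes (%).
#' @param E_K_mV Matching Nernst potentials (mV); >= 3 distinct values.
#' @return An object of class `"vm_calibration"` with
#'   `sensitivity_pct_per_mV`, `V_rest_mV`, standard errors, and the
#'   E_K values used.
#' @export
calibrate_vm <- function(peak_dff_pct, E_K_mV) {
  if (length(peak_dff_pct) != length(E_K_mV) || length(E_K_mV) < 3L) {
    stop("need >= 3 matched (peak, E_K) pairs", call. = FALSE)
  }
  if (length(unique(E_K_mV)) < 3L) {
    stop("E_K values must be distinct", call. = FALSE)
  }
  fit <- stats::lm(peak_dff_pct ~ E_K_mV)
  s <- unname(stats::coef(fit)[2]); b <- unname(stats::coef(fit)[1])
  if (abs(s) < 1e-12) {
    stop("slope is zero within tolerance; V_rest undefined", call. = FALSE)
  }
  co <- summary(fit)$coefficients
  V <- stats::vcov(fit)
  # delta method for V_rest = -b/s
  grad <- c(-1 / s, b / s^2)
  vr_se <- sqrt(drop(t(grad) %*% V %*% grad))
  structure(list(sensitivity_pct_per_mV = s, V_rest_mV = -b / s,
                 sensitivity_se = co[2, 2], intercept = b,
                 intercept_se = co[1, 2], V_rest_se = vr_se,
                 E_K_mV = E_K_mV),
            class = "vm_calibration")
}

#' @export
print.vm_calibration <- function(x, ...) {
  cat(sprintf("<Vm calibration> sensitivity %.4g %%/mV (SE %.2g), V_rest %.4g mV (SE %.2g)\n",
              x$sensitivity_pct_per_mV, x$sensitivity_se,
              x$V_rest_mV, x$V_rest_se))
  invisible(x)
}

#' Convert a dF/F0 trace to membrane voltage
#'
#' `V(t) = V_rest + dF/F0(t) / sensitivity`. A dF/F0 of 0 maps to the
#' resting potential; with positive sensitivity a negative deflection is a
#' hyperpolarization.
#'
#' @param trace A dF/F0 `"processed_trace"` (percent).
#' @param cal A [calibrate_vm()] result.
#' @return A `"processed_trace"` in mV.
#' @export
vm_from_dff <- function(trace, cal) {
  stopifnot(inherits(cal, "vm_calibration"))
  tv <- .as_tv(trace)
  processed_trace(tv$time_s,
                  cal$V_rest_mV + tv$value / cal$sensitivity_pct_per_mV,
                  baseline_window = attr(trace, "baseline_window"),
                  units = "mV",
                  provenance = c(attr(trace, "provenance"), "vm_from_dff"))
}

#' Detect signal onset by debounced threshold crossing
#'
#' First time at which at least `min_consecutive` successive samples
#' deviate from the baseline mean by more than `k_sd` baseline SDs, in the
#' direction of the trace's extremum (auto-detected). Returns the latency
#' relative to `stimulus_time_s`, or `NA` when no onset is found.
#'
#' @param trace Trace (data frame or vector).
#' @param baseline_window `c(start, end)` in s, preceding any response.
#' @param k_sd Threshold in baseline SDs (default 3).
#' @param min_consecutive Debounce length (default 5 samples).
#' @param stimulus_time_s Stimulus time the latency is referenced to.
#' @param time_s Time grid for a bare vector.
#' @return Latency in s, or `NA_real_` if no onset.
#' @export
detect_onset <- function(trace, baseline_window, k_sd = 3,
                         min_consecutive = 5L, stimulus_time_s = 0,
                         time_s = NULL) {
  tv <- .as_tv(trace, time_s)
  idx <- .window_idx(tv$time_s, baseline_window)
  if (length(idx) < 3L) stop("baseline window must contain >= 3 samples", call. = FALSE)
  mu <- mean(tv$value[idx]); s <- stats::sd(tv$value[idx])
  if (s == 0) s <- .Machine$double.eps
  after <- which(tv$time_s > baseline_window[2])
  if (!length(after)) return(NA_real_)
  v <- tv$value[after]
  direction <- sign(v[which.max(abs(v - mu))] - mu)
  if (direction == 0) return(NA_real_)
  exceeded <- if (direction > 0) v > mu + k_sd * s else v < mu - k_sd * s
  r <- rle(exceeded)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= min_consecutive)
  if (!length(hit)) return(NA_real_)
  first <- ends[hit[1]] - r$lengths[hit[1]] + 1L
  tv$time_s[after[first]] - stimulus_time_s
}

#' Membrane voltage at a signal's onset
#'
#' Value of a calibrated Vm trace at the onset time of another signal
#' (linear interpolation between samples).
#'
#' @param vm_trace A Vm `"processed_trace"` (mV) or `time_s`/`value` frame.
#' @param latency_s Onset time (s), inside the trace.
#' @return Vm in mV.
#' @export
vm_at_onset <- function(vm_trace, latency_s) {
  tv <- .as_tv(vm_trace)
  if (latency_s < min(tv$time_s) || latency_s > max(tv$time_s)) {
    stop("latency outside the trace", call. = FALSE)
  }
  stats::approx(tv$time_s, tv$value, xout = latency_s)$y
}

#' Rescale demodulated channels to a common baseline
#'
#' Divides channels by a baseline fluorescence so that crosstalk
#' regressions are performed on the scale used for the published analysis:
#' with a `reference` channel, every channel is divided by the reference
#' channel's baseline mean (one common scale, which preserves the relative
#' amplitudes between channels -- the loaded probe's channel is set to 1 at
#' baseline); without one, each channel is divided by its own baseline
#' mean.
#'
#' @param demod A `"demod_traces"` object.
#' @param baseline_window `c(start, end)` in s.
#' @param reference Reference channel label, or `NULL` for per-channel
#'   normalization.
#' @return The `"demod_traces"` with rescaled values.
#' @export
normalize_to_baseline <- function(demod, baseline_window, reference = NULL) {
  stopifnot(inherits(demod, "demod_traces"))
  idx <- .window_idx(demod$time_s, baseline_window)
  if (length(idx) < 3L) stop("baseline window must contain >= 3 samples", call. = FALSE)
  if (!is.null(reference)) {
    f0 <- mean(demod$x[idx, reference])
    if (f0 <= 0) stop("reference baseline is not positive", call. = FALSE)
    demod$x <- demod$x / f0
  } else {
    for (ch in colnames(demod$x)) {
      f0 <- mean(demod$x[idx, ch])
      if (f0 <= 0) stop("baseline of channel '", ch, "' is not positive", call. = FALSE)
      demod$x[, ch] <- demod$x[, ch] / f0
    }
  }
  demod
}
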