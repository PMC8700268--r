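#' Lock-in amplifier configuration
#'
#' Output-filter and phase settings of the software lock-in. `tau` is the
#' per-stage time constant of each of the `order` identical single-pole
#' stages (the commercial convention: a "third-order, 18 dB/octave" filter
#' with a stated time constant is three such stages).
#'
#' @param time_constant_s Per-stage time constant (s, > 0).
#' @param order Number of stages (integer >= 1, default 3).
#' @param output_interval_s Decimated output interval (s); the filtered
#'   stream is subsampled, the cascade acting as the anti-alias filter.
#' @param phase_mode `"auto"` (reference phase estimated from the data) or
#'   a fixed numeric phase in rad.
#' @param output_mode `"in_phase"` (signed X after phasing; default) or
#'   `"magnitude"` (R = sqrt(X^2 + Y^2), which rectifies noise at low
#'   signal).
#' @param settle_factor The first `settle_factor * order * tau` seconds of
#'   every demodulated trace are marked unreliable (default 10).
#' @return An object of class `"lockin_config"`.
#' @export
lockin_config <- function(time_constant_s, order = 3L,
                          output_interval_s = time_constant_s,
                          phase_mode = "auto",
                          output_mode = c("in_phase", "magnitude"),
                          settle_factor = 10) {
  if (time_constant_s <= 0) stop("time_constant_s must be positive", call. = FALSE)
  if (order < 1) stop("order must be >= 1", call. = FALSE)
  if (output_interval_s <= 0) stop("output_interval_s must be positive", call. = FALSE)
  output_mode <- match.arg(output_mode)
  if (!(identical(phase_mode, "auto") || is.numeric(phase_mode))) {
    stop("phase_mode must be \"auto\" or a numeric phase (rad)", call. = FALSE)
  }
  structure(list(time_constant_s = time_constant_s, order = as.integer(order),
                 output_interval_s = output_interval_s,
                 phase_mode = phase_mode, output_mode = output_mode,
                 settle_factor = settle_factor),
            class = "lockin_config")
}

#' Cascaded single-pole lowpass filter
#'
#' Applies `order` identical recursive stages
#' `y[n] = y[n-1] + (dt/(tau+dt)) (u[n] - y[n-1])` (DC gain exactly 1).
#' The cascade rolls off asymptotically at `6 * order` dB/octave
#' (18 dB/octave for the default third order); its closed-form gain is
#' [lockin_gain()].
#'
#' @param x Input signal (numeric).
#' @param tau_s Per-stage time constant (s, > 0).
#' @param order Number of stages (>= 1).
#' @param dt Sample interval (s).
#' @return Filtered signal, same length.
#' @export
cascaded_lowpass <- function(x, tau_s, order = 3L, dt) {
  if (tau_s <= 0) stop("tau_s must be positive", call. = FALSE)
  if (order < 1) stop("order must be >= 1", call. = FALSE)
  if (tau_s <= dt / 10) {
    warning("time constant close to the sample interval; filter is nearly transparent")
  }
  a <- dt / (tau_s + dt)
  for (i in seq_len(order)) {
    x <- as.numeric(stats::filter(a * x, 1 - a, method = "recursive"))
  }
  x
}

#' Time after which the demodulated output is considered settled
#' @param cfg A [lockin_config()].
#' @return Seconds.
#' @export
settle_time <- function(cfg) {
  cfg$settle_factor * cfg$order * cfg$time_constant_s
}

#' Settling mask
#'
#' Marks the initial transient of a demodulated trace: `TRUE` for samples
#' with `t < settle_factor * order * tau`, which analysis operations
#' exclude by default.
#'
#' @param cfg A [lockin_config()].
#' @param time_s Time grid (s).
#' @return Logical vector, `TRUE` = unreliable (still settling).
#' @export
settle_mask <- function(cfg, time_s) {
  time_s < settle_time(cfg)
}

#' Define the logical demodulation channels
#'
#' A logical channel is a (detector, reference frequency) pair, labeled by
#' the probe it isolates.
#'
#' @param label Channel labels (probe names).
#' @param detector Detector name per channel.
#' @param freq_hz Reference frequency per channel (Hz).
#' @param phase_rad Optional fixed reference phase per channel.
#' @return A data frame with one row per logical channel.
#' @export
demod_channels <- function(label, detector, freq_hz, phase_rad = 0) {
  d <- data.frame(label = label, detector = detector, freq_hz = freq_hz,
                  phase_rad = rep_len(phase_rad, length(label)),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(d$label)) stop("duplicate channel labels", call. = FALSE)
  d
}

#' Phase-sensitive demodulation of the raw detector traces
#'
#' Software lock-in amplifier. Per logical channel the raw trace is mixed
#' with quadrature references at the channel frequency,
#' `X = 2 LPF[y cos(2 pi f t)]`, `Y = -2 LPF[y sin(2 pi f t)]`, filtered by
#' the cascaded lowpass of `cfg`, phased (auto-phase maximizes the mean
#' in-phase component over the settled calibration window) and decimated
#' to the output interval by subsampling the filtered stream. The
#' amplitude convention: an input `A cos(2 pi f t)` returns a steady-state
#' in-phase output `A`.
#'
#' @param raw A `"raw_traces"` object from [simulate_acquisition()] (or
#'   [read_traces()]).
#' @param channels Logical channels from [demod_channels()].
#' @param cfg A [lockin_config()].
#' @param phase_window_s Optional `c(start, end)` window (s) for
#'   auto-phase calibration; default: all settled samples.
#' @return An object of class `"demod_traces"`: `time_s` (decimated),
#'   `x` (matrix samples x channels), `settled` (logical), `channels`,
#'   `lockin` (the config), `meta` (inherited from the raw traces, plus
#'   the recovered phases).
#' @export
demodulate <- function(raw, channels, cfg, phase_window_s = NULL) {
  stopifnot(inherits(raw, "raw_traces"), inherits(cfg, "lockin_config"),
            is.data.frame(channels))
  dt <- raw$dt
  n <- nrow(raw$y)
  t <- raw$time_s
  nyq <- 1 / (2 * dt)
  if (any(channels$freq_hz >= nyq)) {
    stop("reference frequency at or above Nyquist of the raw trace", call. = FALSE)
  }

  ratio <- cfg$output_interval_s / dt
  m <- max(1L, as.integer(round(ratio)))
  if (abs(ratio - m) > 1e-9) {
    warning(sprintf("output interval snapped to %d samples (%.6g s)", m, m * dt))
  }
  idx <- seq.int(1L, n, by = m)
  tout <- t[idx]
  settled_full <- !settle_mask(cfg, t)

  phw <- phase_window_s
  X <- matrix(0, length(idx), nrow(channels),
              dimnames = list(NULL, channels$label))
  phases <- numeric(nrow(channels))
  for (i in seq_len(nrow(channels))) {
    ch <- channels[i, ]
    y <- raw$y[, ch$detector]
    theta <- 2 * pi * ch$freq_hz * t
    C <- cascaded_lowpass(2 * y * cos(theta), cfg$time_constant_s, cfg$order, dt)
    S <- cascaded_lowpass(2 * y * sin(theta), cfg$time_constant_s, cfg$order, dt)
    xi <- C          # in-phase at reference phase 0
    yi <- -S         # quadrature
    if (identical(cfg$phase_mode, "auto")) {
      sel <- if (is.null(phw)) settled_full else (t >= phw[1] & t <= phw[2])
      if (!any(sel)) sel <- rep(TRUE, n)
      phi <- atan2(mean(yi[sel]), mean(xi[sel]))
    } else {
      phi <- cfg$phase_mode + ch$phase_rad
    }
    phases[i] <- phi
    out <- if (cfg$output_mode == "magnitude") {
      sqrt(xi^2 + yi^2)
    } else {
      xi * cos(phi) + yi * sin(phi)
    }
    X[, i] <- out[idx]
  }

  meta <- raw$meta
  meta$phases_rad <- stats::setNames(phases, channels$label)
  structure(list(time_s = tout, x = X, settled = settled_full[idx],
                 channels = channels, lockin = cfg, meta = meta),
            class = "demod_traces")
}

#' @export
print.demod_traces <- function(x, ...) {
  cat(sprintf("<demodulated traces> %d samples x %d channels (%s), interval %.4g s\n",
              nrow(x$x), ncol(x$x), paste(colnames(x$x), collapse = ", "),
              x$lockin$output_interval_s))
  invisible(x)
}

#' Extract one demodulated channel
#'
#' @param demod A `"demod_traces"` object.
#' @param label Channel label.
#' @param settled_only Drop samples inside the settling transient.
#' @return Data frame with `time_s` and `value`.
#' @export
channel_trace <- function(demod, label, settled_only = FALSE) {
  stopifnot(inherits(demod, "demod_traces"))
  if (!label %in% colnames(demod$x)) {
    stop("unknown channel '", label, "'", call. = FALSE)
  }
  keep <- if (settled_only) demod$settled else rep(TRUE, nrow(demod$x))
  data.frame(time_s = demod$time_s[keep], value = demod$x[keep, label])
}

#' Estimate the reference phase of a modulated component
#'
#' Phase of the component at frequency `f` in a raw trace, from quadrature
#' means over a calibration window of at least 20 modulation periods:
#' `phi = atan2(mean Y, mean X)`. Applying `phi` as the reference phase
#' zeroes the mean quadrature output.
#'
#' @param raw A `"raw_traces"` object.
#' @param f_hz Modulation frequency (Hz).
#' @param window `c(start, end)` calibration window (s).
#' @param detector Detector name or index (default first).
#' @return Phase in rad (of a `cos(2 pi f t + phi)` component).
#' @export
auto_phase <- function(raw, f_hz, window, detector = 1L) {
  stopifnot(inherits(raw, "raw_traces"), length(window) == 2L)
  if (diff(window) < 20 / f_hz) {
    stop("calibration window must span at least 20 modulation periods",
         call. = FALSE)
  }
  sel <- raw$time_s >= window[1] & raw$time_s <= window[2]
  y <- raw$y[sel, detector]
  theta <- 2 * pi * f_hz * raw$time_s[sel]
  X <- 2 * mean(y * cos(theta))
  Y <- -2 * mean(y * sin(theta))
  atan2(Y, X)
}
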