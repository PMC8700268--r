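#' Detector noise specification
#'
#' Gaussian noise model of a photomultiplier current in the high-flux
#' regime: a signal-independent dark term plus a shot-noise term whose
#' variance is proportional to the instantaneous signal. The same seed and
#' configuration reproduce the traces bit-identically.
#'
#' @param shot_scale Variance per unit instantaneous signal (>= 0).
#' @param dark_sd Additive, signal-independent SD (>= 0).
#' @param seed Integer seed for the trace generator.
#' @return An object of class `"noise_spec"`.
#' @export
noise_spec <- function(shot_scale = 0, dark_sd = 0, seed = 1L) {
  if (shot_scale < 0 || dark_sd < 0) {
    stop("noise parameters must be >= 0", call. = FALSE)
  }
  structure(list(shot_scale = shot_scale, dark_sd = dark_sd,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Acquisition configuration
#'
#' The high-rate sampling context of a simulated recording. The simulation
#' rate must be at least 2.5x the largest modulation frequency.
#'
#' @param excitation_channels List of [excitation_channel()] objects.
#' @param detection_channels List of [detection_channel()] objects.
#' @param duration_s Recording length (s).
#' @param sim_rate_hz Internal sampling rate (Hz, default 1 MHz).
#' @param multiplex_enabled With `TRUE` every excitation channel keeps its own
#'   modulation frequency (frequency-tagged multiplexing); with `FALSE`
#'   all channels are driven at `common_freq_hz` (the optical-filtering
#'   control condition).
#' @param common_freq_hz Common frequency for the control condition
#'   (default: the first channel's frequency).
#' @param background Per-detector additive background (recycled).
#' @param saturation_level Optional detector soft-saturation level: the
#'   noiseless signal is compressed as `L * tanh(y / L)`, which generates
#'   intermodulation between channels. Default `Inf` (linear response).
#' @return An object of class `"acquisition_config"`.
#' @export
acquisition_config <- function(excitation_channels, detection_channels,
                               duration_s, sim_rate_hz = 1e6,
                               multiplex_enabled = TRUE, common_freq_hz = NULL,
                               background = 0, saturation_level = Inf) {
  stopifnot(length(excitation_channels) >= 1L, length(detection_channels) >= 1L,
            duration_s > 0, sim_rate_hz > 0)
  freqs <- vapply(excitation_channels, function(e) e$mod_freq_hz, numeric(1))
  if (sim_rate_hz < 2.5 * max(freqs)) {
    stop(sprintf("sim_rate_hz (%.4g) must be >= 2.5x the maximum modulation frequency (%.4g)",
                 sim_rate_hz, max(freqs)), call. = FALSE)
  }
  if (multiplex_enabled && anyDuplicated(freqs)) {
    stop("multiplexed channels must carry distinct modulation frequencies",
         call. = FALSE)
  }
  if (is.null(common_freq_hz)) common_freq_hz <- freqs[1]
  nk <- length(detection_channels)
  structure(list(excitation_channels = excitation_channels,
                 detection_channels = detection_channels,
                 duration_s = duration_s, sim_rate_hz = sim_rate_hz,
                 multiplex_enabled = isTRUE(multiplex_enabled),
                 common_freq_hz = common_freq_hz,
                 background = rep_len(background, nk),
                 saturation_level = saturation_level),
            class = "acquisition_config")
}

#' Instantaneous LED intensity
#'
#' Sinusoidal drive `I(t) = intensity (1 + mod_depth cos(2 pi f t + phi))/2`.
#' With multiplexing disabled the channel's own frequency is replaced by
#' the common control frequency.
#'
#' @param exch An [excitation_channel()].
#' @param time_s Time grid (s).
#' @param multiplex_enabled Use the channel's own frequency (`TRUE`) or the
#'   common one (`FALSE`).
#' @param common_freq_hz Control frequency used when `multiplex_enabled` is
#'   `FALSE`.
#' @param sim_rate_hz If supplied, the frequency is validated against its
#'   Nyquist limit.
#' @return Numeric intensity trace (>= 0).
#' @export
led_intensity <- function(exch, time_s, multiplex_enabled = TRUE,
                          common_freq_hz = exch$mod_freq_hz,
                          sim_rate_hz = NULL) {
  f <- if (multiplex_enabled) exch$mod_freq_hz else common_freq_hz
  if (!is.null(sim_rate_hz) && f >= sim_rate_hz / 2) {
    stop(sprintf("modulation frequency %.6g Hz at or above Nyquist (%.6g Hz)",
                 f, sim_rate_hz / 2), call. = FALSE)
  }
  carrier <- cos(2 * pi * f * time_s + exch$phase_rad)
  if (identical(exch$waveform, "square")) carrier <- sign(carrier)
  exch$intensity * (1 + exch$mod_depth * carrier) / 2
}

# run expr with a private, seeded RNG stream, restoring global state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Forward-simulate the multiplexed detector signals
#'
#' For every detector `k` the instantaneous signal is
#' `y_k(t) = sum_j I_j(t) sum_s S[k,j,s] c_s(t) + background_k + noise`,
#' i.e. modulated excitation times the spectral coupling tensor times the
#' species kinetics, plus background and Gaussian dark/shot noise drawn
#' from the seeded generator. The kinetics grid is resampled to the
#' simulation grid by linear interpolation (constant extrapolation at the
#' ends).
#'
#' @param cfg An [acquisition_config()].
#' @param S Coupling tensor from [build_coupling_tensor()]; its species
#'   axis must match the kinetics.
#' @param kin A [concentration_traces()] of species concentrations.
#' @param noise A [noise_spec()] (default: noiseless).
#' @return An object of class `"raw_traces"`: list with `time_s`, `y`
#'   (matrix samples x detectors), `dt`, and `meta`.
#' @export
simulate_acquisition <- function(cfg, S, kin, noise = noise_spec()) {
  stopifnot(inherits(cfg, "acquisition_config"),
            inherits(kin, "concentration_traces"))
  snames <- dimnames(S)$species
  if (!setequal(snames, colnames(kin$conc))) {
    stop("species of the coupling tensor and the kinetics do not match",
         call. = FALSE)
  }
  dt <- 1 / cfg$sim_rate_hz
  n <- round(cfg$duration_s * cfg$sim_rate_hz)
  t <- (seq_len(n) - 1) * dt

  # resample kinetics onto the simulation grid
  conc <- matrix(0, n, length(snames), dimnames = list(NULL, snames))
  for (s in snames) {
    conc[, s] <- stats::approx(kin$time_s, kin$conc[, s], xout = t,
                               rule = 2)$y
  }

  knames <- dimnames(S)$detector
  y <- matrix(0, n, length(knames), dimnames = list(NULL, knames))
  for (j in seq_along(cfg$excitation_channels)) {
    exch <- cfg$excitation_channels[[j]]
    Ij <- led_intensity(exch, t, cfg$multiplex_enabled, cfg$common_freq_hz,
                        sim_rate_hz = cfg$sim_rate_hz)
    for (k in seq_along(knames)) {
      w <- S[k, j, ]           # per-species weights for this (k, j)
      nz <- which(w != 0)
      if (length(nz)) {
        y[, k] <- y[, k] + Ij * as.numeric(conc[, nz, drop = FALSE] %*% w[nz])
      }
    }
  }
  for (k in seq_along(knames)) y[, k] <- y[, k] + cfg$background[k]

  if (is.finite(cfg$saturation_level)) {
    L <- cfg$saturation_level
    y <- L * tanh(y / L)
  }

  if (noise$shot_scale > 0 || noise$dark_sd > 0) {
    y <- .with_seed(noise$seed, {
      sd <- sqrt(noise$dark_sd^2 + noise$shot_scale * pmax(y, 0))
      y + matrix(stats::rnorm(length(y)), nrow(y), ncol(y)) * sd
    })
  }

  structure(list(time_s = t, y = y, dt = dt,
                 meta = list(seed = noise$seed,
                             multiplex_enabled = cfg$multiplex_enabled,
                             common_freq_hz = cfg$common_freq_hz,
                             sim_rate_hz = cfg$sim_rate_hz,
                             flash_windows = list(), mixing = list())),
            class = "raw_traces")
}

#' @export
print.raw_traces <- function(x, ...) {
  cat(sprintf("<raw traces> %d samples x %d detectors (%s) at %.4g Hz\n",
              nrow(x$y), ncol(x$y), paste(colnames(x$y), collapse = ", "),
              1 / x$dt))
  invisible(x)
}

# smoothed rectangular window, raised-cosine edges of width edge_s
.smooth_window <- function(time_s, window, edge_s) {
  if (edge_s <= 0) {
    return(as.numeric(time_s >= window[1] & time_s <= window[2]))
  }
  up <- .rc_edge(time_s, window[1], edge_s)
  down <- 1 - .rc_edge(time_s, window[2], edge_s)
  up * down
}

#' Inject a flash (uncaging) artifact
#'
#' Adds an unmodulated additive transient -- a rectangular pulse with
#' raised-cosine edge smoothing -- to the selected detectors during the
#' window, emulating the broadband photodetector response to an uncaging
#' light pulse. Because the transient carries no modulation, the lock-in
#' demodulator suppresses it.
#'
#' @param raw A `"raw_traces"` object.
#' @param window `c(start, end)` in s, inside the trace.
#' @param amplitude Artifact amplitude (same units as the raw signal).
#' @param detectors Detector names or indices (default: all).
#' @param edge_s Edge smoothing width (s).
#' @return The modified `"raw_traces"`; the window is recorded in `meta`.
#' @export
inject_flash_artifact <- function(raw, window, amplitude,
                                  detectors = colnames(raw$y),
                                  edge_s = 1e-3) {
  stopifnot(inherits(raw, "raw_traces"), length(window) == 2L)
  tmax <- raw$time_s[length(raw$time_s)]
  if (window[1] < 0 || window[2] > tmax || window[1] >= window[2]) {
    stop("flash window outside the trace", call. = FALSE)
  }
  if (amplitude != 0) {
    w <- amplitude * .smooth_window(raw$time_s, window, edge_s)
    for (k in detectors) raw$y[, k] <- raw$y[, k] + w
  }
  raw$meta$flash_windows <- c(raw$meta$flash_windows,
                              list(list(window = window, amplitude = amplitude,
                                        detectors = detectors)))
  raw
}

#' Inject a stopped-flow mixing artifact
#'
#' Multiplies all detector traces by `1 + amplitude exp(-(t - stop)/decay)`
#' from the stop of the flow onward: a short multiplicative disturbance
#' that affects all detectors proportionally. The window is recorded in
#' the metadata so the analysis layer can crop it.
#'
#' @param raw A `"raw_traces"` object.
#' @param stop_time_s Time of the flow stop (s).
#' @param amplitude Relative disturbance amplitude.
#' @param decay_s Exponential decay constant (s, > 0).
#' @return The modified `"raw_traces"`.
#' @export
inject_mixing_artifact <- function(raw, stop_time_s, amplitude, decay_s) {
  stopifnot(inherits(raw, "raw_traces"), decay_s > 0)
  if (amplitude != 0) {
    td <- raw$time_s - stop_time_s
    g <- 1 + amplitude * ifelse(td >= 0, exp(-td / decay_s), 0)
    raw$y <- raw$y * g
  }
  raw$meta$mixing <- c(raw$meta$mixing,
                       list(list(stop_time_s = stop_time_s,
                                 amplitude = amplitude, decay_s = decay_s)))
  raw
}

#' Stopped-flow dead time
#'
#' The earliest observable reaction age: dead volume divided by flow rate.
#' With the 36.6 ul dead volume of the standard cuvette, flow rates of 1,
#' 2 and 4 ml/s give 36.6, 18.3 and 9.1 ms.
#'
#' @param dead_volume_ul Dead volume (microliters, > 0).
#' @param flow_rate_ml_per_s Flow rate (ml/s, > 0).
#' @return Dead time in seconds.
#' @examples
#' dead_time(36.6, 2) # 0.0183 s
#' @export
dead_time <- function(dead_volume_ul, flow_rate_ml_per_s) {
  if (dead_volume_ul <= 0 || flow_rate_ml_per_s <= 0) {
    stop("dead volume and flow rate must be positive", call. = FALSE)
  }
  (dead_volume_ul * 1e-3) / flow_rate_ml_per_s
}
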