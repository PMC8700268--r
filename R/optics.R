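#' Define a fluorescent species
#'
#' A species is one spectroscopic state of a probe (a ratiometric probe
#' contributes two species, e.g. Ca2+-bound and free forms). Brightness is
#' a relative quantum-yield-times-extinction factor; the coupling tensor is
#' linear in it.
#'
#' @param name Species label.
#' @param excitation,emission [spectrum_nm()] curves (arbitrary units).
#' @param brightness Positive relative brightness.
#' @param allow_negative_stokes Skip the Stokes-shift sanity check
#'   (emission peak >= excitation peak).
#' @return An object of class `"fl_species"`.
#' @export
species <- function(name, excitation, emission, brightness = 1,
                    allow_negative_stokes = FALSE) {
  stopifnot(inherits(excitation, "spectrum_nm"), inherits(emission, "spectrum_nm"))
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("species name must be a nonempty string", call. = FALSE)
  }
  if (!is.numeric(brightness) || brightness <= 0) {
    stop("brightness must be positive", call. = FALSE)
  }
  ex_peak <- excitation$wavelengths_nm[which.max(excitation$values)]
  em_peak <- emission$wavelengths_nm[which.max(emission$values)]
  if (!allow_negative_stokes && em_peak < ex_peak) {
    stop(sprintf("species '%s': emission peak (%g nm) below excitation peak (%g nm); %s",
                 name, em_peak, ex_peak,
                 "set allow_negative_stokes = TRUE to override"), call. = FALSE)
  }
  structure(list(name = name, excitation = excitation, emission = emission,
                 brightness = brightness),
            class = "fl_species")
}

#' Define a modulated excitation channel
#'
#' An LED plus excitation filter, sinusoidally modulated at `mod_freq_hz`.
#' With multiplexing enabled every channel in an experiment carries a
#' distinct frequency; the optical-filtering-only control drives all
#' channels at one common frequency.
#'
#' @param name Channel label (conventionally the probe it targets).
#' @param led_spectrum LED emission [spectrum_nm()].
#' @param ex_filter Excitation [filter_spec()] or vendor notation.
#' @param mod_freq_hz Modulation frequency (Hz, positive).
#' @param mod_depth Modulation depth in (0, 1].
#' @param intensity Peak drive intensity (arbitrary units, positive).
#' @param phase_rad Modulation phase (rad).
#' @param waveform `"sine"` (default) or `"square"`; square-wave drive
#'   carries odd harmonics and is provided to study harmonic crosstalk.
#' @return An object of class `"ex_channel"`.
#' @export
excitation_channel <- function(name, led_spectrum, ex_filter, mod_freq_hz,
                               mod_depth = 1, intensity = 1, phase_rad = 0,
                               waveform = c("sine", "square")) {
  stopifnot(inherits(led_spectrum, "spectrum_nm"))
  if (!is.numeric(mod_freq_hz) || mod_freq_hz <= 0) {
    stop("mod_freq_hz must be positive", call. = FALSE)
  }
  if (!is.numeric(mod_depth) || mod_depth <= 0 || mod_depth > 1) {
    stop("mod_depth must be in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(intensity) || intensity <= 0) {
    stop("intensity must be positive", call. = FALSE)
  }
  waveform <- match.arg(waveform)
  structure(list(name = name, led_spectrum = led_spectrum,
                 ex_filter = parse_filter(ex_filter),
                 mod_freq_hz = mod_freq_hz, mod_depth = mod_depth,
                 intensity = intensity, phase_rad = phase_rad,
                 waveform = waveform),
            class = "ex_channel")
}

#' Define a detection channel (photodetector)
#'
#' A photomultiplier behind one or more emission filters. The default
#' sensitivity is flat over the grid.
#'
#' @param name Detector label.
#' @param em_filters List of [filter_spec()] objects or vendor notations.
#' @param sensitivity Optional sensitivity [spectrum_nm()] (flat default).
#' @param gain Positive multiplicative gain.
#' @return An object of class `"det_channel"`.
#' @export
detection_channel <- function(name, em_filters, sensitivity = NULL, gain = 1) {
  if (!is.list(em_filters)) em_filters <- list(em_filters)
  em_filters <- lapply(em_filters, parse_filter)
  if (!is.null(sensitivity)) stopifnot(inherits(sensitivity, "spectrum_nm"))
  if (!is.numeric(gain) || gain <= 0) stop("gain must be positive", call. = FALSE)
  structure(list(name = name, em_filters = em_filters,
                 sensitivity = sensitivity, gain = gain),
            class = "det_channel")
}

#' Effective brightness of a species on a (detector, excitation) pair
#'
#' The overlap-integral reduction of the optical train: the product of the
#' excitation-side integral (LED spectrum x excitation filter x species
#' excitation) and the emission-side integral (species emission x emission
#' filters x detector sensitivity), scaled by species brightness, channel
#' intensity and detector gain. Trapezoid integration on a common grid;
#' disjoint spectral supports yield 0.
#'
#' @param sp An [species()].
#' @param exch An [excitation_channel()].
#' @param det A [detection_channel()].
#' @param wavelengths_nm Common integration grid.
#' @return Nonnegative scalar.
#' @export
coupling_coefficient <- function(sp, exch, det,
                                 wavelengths_nm = default_wavelengths()) {
  stopifnot(inherits(sp, "fl_species"), inherits(exch, "ex_channel"),
            inherits(det, "det_channel"))
  wl <- wavelengths_nm
  ex_side <- eval_spectrum(exch$led_spectrum, wl) *
    filter_transmission(exch$ex_filter, wl)$values *
    eval_spectrum(sp$excitation, wl)
  em_side <- eval_spectrum(sp$emission, wl)
  for (f in det$em_filters) {
    em_side <- em_side * filter_transmission(f, wl)$values
  }
  if (!is.null(det$sensitivity)) {
    em_side <- em_side * eval_spectrum(det$sensitivity, wl)
  }
  sp$brightness * exch$intensity * det$gain * .trapz(wl, ex_side) * .trapz(wl, em_side)
}

#' Build the coupling tensor
#'
#' The linear map from species concentrations to detector signals:
#' `S[detector, excitation channel, species]` holds the effective
#' brightness of each triple, computed by [coupling_coefficient()].
#'
#' @param probes List of [species()] objects.
#' @param excitation_channels List of [excitation_channel()] objects.
#' @param detection_channels List of [detection_channel()] objects.
#' @param wavelengths_nm Common integration grid.
#' @return A 3-d array with dimnames `(detector, excitation, species)`.
#' @export
build_coupling_tensor <- function(probes, excitation_channels,
                                  detection_channels,
                                  wavelengths_nm = default_wavelengths()) {
  stopifnot(length(probes) >= 1L, length(excitation_channels) >= 1L,
            length(detection_channels) >= 1L)
  snames <- vapply(probes, function(p) p$name, character(1))
  jnames <- vapply(excitation_channels, function(e) e$name, character(1))
  knames <- vapply(detection_channels, function(d) d$name, character(1))
  for (nm in list(snames, jnames, knames)) {
    if (anyDuplicated(nm)) {
      stop("duplicate channel/species names: ",
           paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
    }
  }
  S <- array(0, dim = c(length(knames), length(jnames), length(snames)),
             dimnames = list(detector = knames, excitation = jnames,
                             species = snames))
  for (k in seq_along(detection_channels)) {
    for (j in seq_along(excitation_channels)) {
      for (s in seq_along(probes)) {
        S[k, j, s] <- coupling_coefficient(probes[[s]],
                                           excitation_channels[[j]],
                                           detection_channels[[k]],
                                           wavelengths_nm)
      }
    }
  }
  S
}

#' Equivalent noise bandwidth of the lock-in output filter
#'
#' For a cascade of `order` identical single-pole stages of time constant
#' `tau`, the two-sided equivalent noise bandwidth is
#' `(1/(2 pi tau)) * (pi/2) * (2n-3)!! / (2n-2)!!`. For order 3, tau = 1 ms
#' this is 93.75 Hz.
#'
#' @param tau_s Per-stage time constant (s).
#' @param order Number of stages (>= 1).
#' @return Bandwidth in Hz.
#' @export
lockin_noise_bandwidth <- function(tau_s, order = 3) {
  stopifnot(tau_s > 0, order >= 1)
  int <- pi / 2
  if (order >= 2) {
    k <- 2:order
    int <- int * prod((2 * k - 3) / (2 * k - 2))
  }
  int / (2 * pi * tau_s)
}

#' Closed-form gain of the cascaded lowpass
#'
#' `|H(f)| = (1 + (2 pi f tau)^2)^(-order/2)` for `order` identical RC
#' stages with per-stage time constant `tau`.
#'
#' @param f_hz Frequency offset from the reference (Hz).
#' @inheritParams lockin_noise_bandwidth
#' @return Amplitude gain (1 at DC).
#' @export
lockin_gain <- function(f_hz, tau_s, order = 3) {
  (1 + (2 * pi * f_hz * tau_s)^2)^(-order / 2)
}

#' Check a modulation-frequency plan
#'
#' Report-only feasibility check of a set of modulation frequencies under a
#' lock-in configuration and simulation rate. Flags (i) channel pairs closer
#' than `min_separation_factor` times the filter's equivalent noise
#' bandwidth, (ii) second/third harmonics of one channel aliasing onto
#' another under the simulation rate, and (iii) frequencies at or above
#' Nyquist. Also reports the worst-case inter-channel leakage predicted by
#' the closed-form filter response.
#'
#' @param freqs_hz Positive modulation frequencies (Hz).
#' @param tau_s,order Lock-in filter parameters.
#' @param sim_rate_hz Simulation/sampling rate (Hz).
#' @param min_separation_factor Required pair separation in units of the
#'   noise bandwidth (default 10).
#' @param harmonics Harmonic orders checked for aliasing (default 2:3).
#' @param harmonic_guard_factor Guard band around folded harmonics, in
#'   units of the noise bandwidth (default 2; narrower than the pair
#'   separation because sinusoidal drive carries no harmonic power and
#'   square-wave drive only weak odd harmonics).
#' @return A list of class `"frequency_plan"` with elements `pass`,
#'   `issues` (character), `noise_bandwidth_hz`, and
#'   `worst_leakage_fraction` (amplitude fraction of the closest pair).
#' @export
plan_frequencies <- function(freqs_hz, tau_s = 1e-3, order = 3,
                             sim_rate_hz = 1e6,
                             min_separation_factor = 10, harmonics = 2:3,
                             harmonic_guard_factor = 2) {
  stopifnot(all(freqs_hz > 0))
  issues <- character(0)
  nyq <- sim_rate_hz / 2
  enbw <- lockin_noise_bandwidth(tau_s, order)

  above <- freqs_hz >= nyq
  if (any(above)) {
    issues <- c(issues, sprintf(
      "frequency %.6g Hz at or above Nyquist (%.6g Hz)", freqs_hz[above], nyq))
  }
  if (length(freqs_hz) >= 2L) {
    prs <- utils::combn(seq_along(freqs_hz), 2)
    for (i in seq_len(ncol(prs))) {
      df <- abs(freqs_hz[prs[1, i]] - freqs_hz[prs[2, i]])
      if (df < min_separation_factor * enbw) {
        issues <- c(issues, sprintf(
          "channels %.6g and %.6g Hz separated by %.4g Hz (< %g x noise bandwidth %.4g Hz)",
          freqs_hz[prs[1, i]], freqs_hz[prs[2, i]], df,
          min_separation_factor, enbw))
      }
    }
    # folded harmonic positions vs other channels
    for (a in seq_along(freqs_hz)) {
      for (m in harmonics) {
        fh <- (m * freqs_hz[a]) %% sim_rate_hz
        fh <- min(fh, sim_rate_hz - fh)  # alias into [0, Nyquist]
        for (b in seq_along(freqs_hz)) {
          if (b == a) next
          if (abs(fh - freqs_hz[b]) < harmonic_guard_factor * enbw) {
            issues <- c(issues, sprintf(
              "harmonic %d of %.6g Hz aliases to %.6g Hz, near channel %.6g Hz",
              m, freqs_hz[a], fh, freqs_hz[b]))
          }
        }
      }
    }
  }

  worst <- if (length(freqs_hz) >= 2L) {
    dmin <- min(stats::dist(freqs_hz))
    lockin_gain(dmin, tau_s, order)
  } else 0
  structure(list(pass = length(issues) == 0L, issues = issues,
                 freqs_hz = freqs_hz, tau_s = tau_s, order = order,
                 sim_rate_hz = sim_rate_hz,
                 noise_bandwidth_hz = enbw,
                 worst_leakage_fraction = worst),
            class = "frequency_plan")
}

#' @export
print.frequency_plan <- function(x, ...) {
  cat(sprintf("<frequency plan> %s; %d channels; noise bandwidth %.4g Hz; worst leakage %.3g%%\n",
              if (x$pass) "PASS" else "FAIL", length(x$freqs_hz),
              x$noise_bandwidth_hz, 100 * x$worst_leakage_fraction))
  for (i in x$issues) cat(" - ", i, "\n", sep = "")
  invisible(x)
}
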