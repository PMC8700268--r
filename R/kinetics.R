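#' Container for per-species concentration time courses
#'
#' Relative, baseline-normalized concentration (or activity) traces on a
#' uniform time grid: the ground truth each probe reports.
#'
#' @param time_s Strictly increasing, uniform time grid (s).
#' @param conc Numeric matrix, one column per species (nonnegative).
#' @param signed Allow signed values (used for analyte waveforms around 0,
#'   which become nonnegative only after composition with a probe's
#'   baseline in [probe_state_traces()]).
#' @return An object of class `"concentration_traces"`.
#' @export
concentration_traces <- function(time_s, conc, signed = FALSE) {
  conc <- as.matrix(conc)
  if (is.null(colnames(conc))) {
    stop("conc must have species column names", call. = FALSE)
  }
  if (length(time_s) != nrow(conc)) {
    stop("time and concentration lengths differ", call. = FALSE)
  }
  dt <- diff(time_s)
  if (any(dt <= 0) || (length(dt) > 1 && max(abs(dt - dt[1])) > 1e-9 * dt[1])) {
    stop("time grid must be strictly increasing and uniform", call. = FALSE)
  }
  if (any(!is.finite(conc)) || (!signed && any(conc < 0))) {
    stop("concentrations must be finite and nonnegative", call. = FALSE)
  }
  structure(list(time_s = as.numeric(time_s), conc = conc,
                 signed = isTRUE(signed)),
            class = "concentration_traces")
}

#' @export
print.concentration_traces <- function(x, ...) {
  cat(sprintf("<concentration traces> %d samples x %d species (%s), %g-%g s\n",
              nrow(x$conc), ncol(x$conc),
              paste(colnames(x$conc), collapse = ", "),
              min(x$time_s), max(x$time_s)))
  invisible(x)
}

#' Pulse waveform (transient deflection with full recovery)
#'
#' `w(t) = A (1 - exp(-(t-t0)/tau_r)) exp(-(t-t0)/tau_d)` for `t >= t0`,
#' 0 before. Used for the pulse-like membrane-voltage hyperpolarization of
#' the chemoattractant cascade (negative amplitude).
#'
#' @param time_s Time grid (s).
#' @param t0 Latency (s).
#' @param rise_tau_s,decay_tau_s Rise and decay time constants (s, > 0).
#' @param amplitude Signed amplitude.
#' @return Numeric trace.
#' @export
pulse_waveform <- function(time_s, t0, rise_tau_s, decay_tau_s, amplitude) {
  if (rise_tau_s <= 0 || decay_tau_s <= 0) {
    stop("time constants must be positive", call. = FALSE)
  }
  td <- time_s - t0
  w <- ifelse(td >= 0,
              amplitude * (1 - exp(-td / rise_tau_s)) * exp(-td / decay_tau_s),
              0)
  as.numeric(w)
}

#' Saturating exponential rise
#'
#' `w(t) = A (1 - exp(-(t-t0)/tau))` for `t >= t0`, 0 before; monotone and
#' saturating at `A`. Used for sustained pH and Na+ rises.
#'
#' @param time_s Time grid (s).
#' @param t0 Latency (s).
#' @param tau_s Time constant (s, > 0).
#' @param amplitude Signed plateau.
#' @return Numeric trace.
#' @export
saturating_rise <- function(time_s, t0, tau_s, amplitude) {
  if (tau_s <= 0) stop("tau_s must be positive", call. = FALSE)
  td <- time_s - t0
  as.numeric(ifelse(td >= 0, amplitude * (1 - exp(-td / tau_s)), 0))
}

#' Default cascade parameters
#'
#' Latencies and shapes of the chemoattractant-response cascade fixture:
#' a membrane-voltage hyperpolarization pulse followed by sustained pH and
#' Na+ rises and a later Ca2+ rise. The ordering Vm < pH <= Na < Ca is the
#' physiological one; the numeric values are fixture choices.
#'
#' @return Named list of waveform parameters.
#' @export
cascade_defaults <- function() {
  list(
    Vm = list(t0 = 0.050, rise_tau_s = 0.020, decay_tau_s = 0.200, amplitude = -1),
    pH = list(t0 = 0.150, tau_s = 0.300, amplitude = 1),
    Na = list(t0 = 0.150, tau_s = 0.300, amplitude = 1),
    Ca = list(t0 = 0.400, tau_s = 0.500, amplitude = 1)
  )
}

# monotone dose -> latency map: latency(1)/(1 + log10 dose), clipped
.dose_latency <- function(latency1, dose_scale) {
  latency1 / max(0.1, 1 + log10(dose_scale))
}

#' Chemoattractant-cascade fixture
#'
#' Analyte waveforms of the resact-type signaling cascade: a pulse-like
#' membrane-voltage (Vm) hyperpolarization, saturating pH and Na+ rises,
#' and a delayed Ca2+ rise. Latencies must keep the order
#' Vm < pH <= Na < Ca. Larger `dose_scale` shortens all latencies (via
#' `latency / (1 + log10 dose)`, clipped) and deepens the Vm pulse;
#' `dose_scale = 0` returns flat baselines.
#'
#' @param time_s Time grid (s).
#' @param dose_scale Relative stimulus dose (>= 0, 1 = reference dose).
#' @param params Waveform parameters as in [cascade_defaults()].
#' @param stimulus_time_s Time at which the stimulus arrives (s); all
#'   latencies are referenced to it.
#' @return A [concentration_traces()] with species `Vm`, `pH`, `Na`, `Ca`
#'   (signed waveforms around 0).
#' @export
resact_cascade <- function(time_s, dose_scale = 1, params = cascade_defaults(),
                           stimulus_time_s = 0) {
  stopifnot(dose_scale >= 0)
  p <- params
  if (!(p$Vm$t0 < p$pH$t0 && p$pH$t0 <= p$Na$t0 && p$Na$t0 < p$Ca$t0)) {
    stop("cascade latencies must satisfy Vm < pH <= Na < Ca", call. = FALSE)
  }
  n <- length(time_s)
  if (dose_scale == 0) {
    conc <- matrix(0, n, 4, dimnames = list(NULL, c("Vm", "pH", "Na", "Ca")))
    return(concentration_traces(time_s, conc))
  }
  depth <- 2 * dose_scale / (1 + dose_scale)  # 1 at reference dose, saturating
  lat <- function(l) stimulus_time_s + .dose_latency(l, dose_scale)
  conc <- cbind(
    Vm = pulse_waveform(time_s, lat(p$Vm$t0), p$Vm$rise_tau_s,
                        p$Vm$decay_tau_s, p$Vm$amplitude * depth),
    pH = saturating_rise(time_s, lat(p$pH$t0), p$pH$tau_s, p$pH$amplitude),
    Na = saturating_rise(time_s, lat(p$Na$t0), p$Na$tau_s, p$Na$amplitude),
    Ca = saturating_rise(time_s, lat(p$Ca$t0), p$Ca$tau_s, p$Ca$amplitude)
  )
  concentration_traces(time_s, conc, signed = TRUE)
}

#' Chelator-quench dissociation traces
#'
#' Excess-chelator regime: the bound indicator decays as
#' `c_bound(t) = b0 exp(-k_off (t - start))` (1 before `start`, scaled by
#' `b0`), the free form is its complement, and rebinding is neglected.
#'
#' @param time_s Time grid (s).
#' @param k_off_per_s Dissociation rate constant (1/s, > 0).
#' @param bound_fraction_initial Initial bound fraction `b0` in (0, 1].
#' @param start_s Time at which mixing starts the reaction (s).
#' @param species_names Names for the bound and free columns.
#' @return A [concentration_traces()] with the two species.
#' @export
dissociation_traces <- function(time_s, k_off_per_s,
                                bound_fraction_initial = 1, start_s = 0,
                                species_names = c("bound", "free")) {
  if (k_off_per_s <= 0) stop("k_off_per_s must be positive", call. = FALSE)
  if (bound_fraction_initial <= 0 || bound_fraction_initial > 1) {
    stop("bound_fraction_initial must be in (0, 1]", call. = FALSE)
  }
  td <- pmax(time_s - start_s, 0)
  cb <- bound_fraction_initial * exp(-k_off_per_s * td)
  conc <- cbind(cb, 1 - cb)
  colnames(conc) <- species_names
  concentration_traces(time_s, conc)
}

#' Flash-uncaging step fixture
#'
#' Cascade traces with all latencies referenced to the onset of a light
#' flash that releases the caged messenger; the flash window is returned so
#' the simulator can inject the corresponding broadband artifact.
#'
#' @param time_s Time grid (s).
#' @param flash_start_s Flash onset (s), inside the grid.
#' @param flash_dur_s Flash duration (s; 0.050 for the standard 50 ms UV
#'   pulse).
#' @param dose_scale,params Forwarded to [resact_cascade()].
#' @return List with `traces` ([concentration_traces()]) and
#'   `flash_window` (`c(start, end)` in s).
#' @export
uncaging_step <- function(time_s, flash_start_s, flash_dur_s = 0.050,
                          dose_scale = 1, params = cascade_defaults()) {
  if (flash_start_s < min(time_s) || flash_start_s + flash_dur_s > max(time_s)) {
    stop("flash window must lie inside the time grid", call. = FALSE)
  }
  tr <- resact_cascade(time_s, dose_scale = dose_scale, params = params,
                       stimulus_time_s = flash_start_s)
  list(traces = tr, flash_window = c(flash_start_s, flash_start_s + flash_dur_s))
}

#' cAMP-buffering toy fixture
#'
#' Rapid-equilibrium model of messenger buffering by a binding sensor:
#' total cAMP accumulates at a constant production rate; free cAMP follows
#' from the closed-form quadratic of the equilibrium
#' `bound = sensor_total * free / (Kd + free)`; a downstream channel
#' activates as a Hill function of free cAMP. A high-affinity sensor
#' delays channel activation relative to a low-affinity or absent sensor.
#'
#' Concentration units are arbitrary but must be consistent (the shipped
#' fixtures use micromolar).
#'
#' @param time_s Time grid (s).
#' @param sensor_Kd Sensor dissociation constant (> 0; `Inf` for a
#'   non-binding sensor).
#' @param sensor_total Total sensor concentration (>= 0).
#' @param channel_K12 Channel half-activation concentration (> 0).
#' @param production_rate Constant cAMP production rate (conc/s, > 0).
#' @param hill Hill coefficient of channel activation (default 1.5).
#' @return A [concentration_traces()] with species `cAMP_free`,
#'   `cAMP_total`, `sensor_bound`, `channel_activation`.
#' @export
buffered_messenger <- function(time_s, sensor_Kd, sensor_total, channel_K12,
                               production_rate, hill = 1.5) {
  stopifnot(sensor_Kd > 0, sensor_total >= 0, channel_K12 > 0,
            production_rate > 0, hill > 0)
  total <- production_rate * pmax(time_s - time_s[1], 0)
  if (is.infinite(sensor_Kd) || sensor_total == 0) {
    free <- total
  } else {
    # free^2 + (Kd + St - T) free - Kd T = 0; positive root, evaluated in
    # the cancellation-free form for either sign of the linear coefficient
    b <- sensor_Kd + sensor_total - total
    disc <- sqrt(b^2 + 4 * sensor_Kd * total)
    free <- ifelse(b > 0,
                   2 * sensor_Kd * total / (b + disc),
                   (-b + disc) / 2)
  }
  free <- pmax(free, 0)
  bound <- total - free
  stopifnot(all(bound >= -1e-9 * max(1, max(total))))  # must be impossible
  bound <- pmax(bound, 0)
  act <- free^hill / (free^hill + channel_K12^hill)
  act[free == 0] <- 0
  conc <- cbind(cAMP_free = free, cAMP_total = total,
                sensor_bound = bound, channel_activation = act)
  concentration_traces(time_s, conc)
}

#' Compose probe-state concentrations from analyte waveforms
#'
#' Maps the signed analyte waveforms of a scenario onto the loaded probes'
#' spectroscopic states: each state follows
#' `c_s(t) = max(0, 1 + gain_s * w_analyte(t))`, i.e. a unit baseline
#' modulated by the analyte it reports.
#'
#' @param analytes A [concentration_traces()] of signed analyte waveforms
#'   (e.g. from [resact_cascade()]).
#' @param probes Character vector of probe names from [probe_names()].
#' @return A [concentration_traces()] with one column per probe state.
#' @export
probe_state_traces <- function(analytes, probes) {
  stopifnot(inherits(analytes, "concentration_traces"))
  w <- analytes$conc
  out <- list()
  for (p in probes) {
    entry <- get_probe(p)
    for (i in seq_len(nrow(entry$response))) {
      sp <- entry$response$species[i]
      an <- entry$response$analyte[i]
      gain <- entry$response$gain[i]
      if (!an %in% colnames(w)) {
        stop(sprintf("probe '%s' responds to analyte '%s' absent from scenario (%s)",
                     p, an, paste(colnames(w), collapse = ", ")), call. = FALSE)
      }
      out[[sp]] <- pmax(0, 1 + gain * w[, an])
    }
  }
  concentration_traces(analytes$time_s, do.call(cbind, out))
}
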