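.config_keys <- c("name", "seed", "probes", "loaded", "excitation",
                  "detectors", "channels", "acquisition", "kinetics",
                  "lockin", "analysis")

#' Validate an experiment configuration
#'
#' Checks a config list referentially (every probe, LED, filter, detector
#' and channel named anywhere must exist) and structurally, and runs the
#' modulation-frequency plan. All problems are collected, not just the
#' first.
#'
#' @param cfg Config list (see [fixture_config()] for the schema).
#' @param strict Treat frequency-plan issues as errors (`TRUE`) or
#'   warnings (`FALSE`, default).
#' @return Invisibly, a character vector of problems (empty when valid).
#' @export
validate_config <- function(cfg, strict = FALSE) {
  errs <- character(0)
  push <- function(...) errs <<- c(errs, sprintf(...))

  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown)) push("unknown config keys: %s", paste(unknown, collapse = ", "))

  lib <- probe_names()
  for (p in cfg$probes) if (!p %in% lib) push("unknown probe '%s'", p)
  loaded <- cfg$loaded %||% cfg$probes
  for (p in loaded) if (!p %in% cfg$probes) {
    push("loaded probe '%s' is not in the probe list", p)
  }

  dnames <- vapply(cfg$detectors, function(d) d$name %||% "", character(1))
  if (anyDuplicated(dnames)) push("duplicate detector names")
  enames <- character(0)
  for (e in cfg$excitation) {
    for (f in c("name", "led", "ex_filter", "freq_khz", "detector")) {
      if (is.null(e[[f]])) push("excitation entry missing field '%s'", f)
    }
    if (!is.null(e$detector) && !e$detector %in% dnames) {
      push("excitation '%s' references unknown detector '%s'",
           e$name %||% "?", e$detector)
    }
    if (!is.null(e$led)) {
      tryCatch(led_spectrum(e$led), error = function(m) push("%s", conditionMessage(m)))
    }
    if (!is.null(e$ex_filter)) {
      tryCatch(parse_filter(e$ex_filter),
               error = function(m) push("%s", conditionMessage(m)))
    }
    enames <- c(enames, e$name %||% "?")
  }
  if (anyDuplicated(enames)) push("duplicate excitation channel names")

  for (ch in cfg$channels) {
    if (!is.null(ch$detector) && !ch$detector %in% dnames) {
      push("channel '%s' references unknown detector '%s'",
           ch$label %||% "?", ch$detector)
    }
    if (!is.null(ch$excitation) && !ch$excitation %in% enames) {
      push("channel '%s' references unknown excitation '%s'",
           ch$label %||% "?", ch$excitation)
    }
  }

  acq <- cfg$acquisition
  freqs <- vapply(cfg$excitation, function(e) (e$freq_khz %||% NA_real_) * 1e3,
                  numeric(1))
  if (!is.null(acq)) {
    if (isTRUE(acq$multiplex) && anyDuplicated(stats::na.omit(freqs))) {
      push("multiplexed channels must have distinct frequencies")
    }
    if (!is.null(acq$sim_rate_hz) && any(freqs >= acq$sim_rate_hz / 2, na.rm = TRUE)) {
      push("modulation frequency at or above Nyquist of the simulation rate")
    }
  }

  kin <- cfg$kinetics
  scenarios <- c("cascade", "uncaging", "dissociation", "buffered")
  if (is.null(kin$scenario) || !kin$scenario %in% scenarios) {
    push("kinetics scenario must be one of: %s", paste(scenarios, collapse = ", "))
  } else if (kin$scenario == "dissociation") {
    for (p in loaded) {
      if (is.null(kin$k_off_per_s[[p]])) push("no k_off for loaded probe '%s'", p)
    }
  }

  if (length(errs) == 0L && !is.null(acq$sim_rate_hz) &&
      length(stats::na.omit(freqs)) >= 1L && !is.null(cfg$lockin)) {
    plan <- plan_frequencies(stats::na.omit(freqs),
                             tau_s = cfg$lockin$time_constant_s %||% 1e-3,
                             order = cfg$lockin$order %||% 3,
                             sim_rate_hz = acq$sim_rate_hz)
    if (!plan$pass) {
      if (strict) {
        errs <- c(errs, paste("frequency plan:", plan$issues))
      } else {
        warning("frequency plan issues: ",
                paste(plan$issues, collapse = "; "), call. = FALSE)
      }
    }
  }
  invisible(errs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load an experiment configuration from YAML
#'
#' Reads and fully validates a config file; all validation problems are
#' reported together.
#'
#' @param path YAML file.
#' @param strict Forwarded to [validate_config()].
#' @return The validated config list.
#' @export
load_config <- function(path, strict = FALSE) {
  cfg <- yaml::read_yaml(path)
  errs <- validate_config(cfg, strict = strict)
  if (length(errs)) {
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  cfg
}

#' Write a configuration to YAML
#' @param cfg Config list.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
dump_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# canonical representation for hashing: names sorted, atomic vectors and
# one-element unnamed lists normalized so a YAML round trip is invariant
.canonicalize <- function(x) {
  if (is.list(x)) {
    if (!is.null(names(x)) && any(nzchar(names(x)))) {
      x <- x[order(names(x))]
    }
    out <- lapply(x, .canonicalize)
    if (is.null(names(out)) && length(out) == 1L && !is.list(out[[1]])) {
      return(out[[1]])
    }
    out
  } else if (is.atomic(x) && length(x) > 1L) {
    .canonicalize(as.list(x))
  } else x
}

#' Stable hash of a configuration
#'
#' MD5 of the canonical (name-sorted) JSON dump; invariant under key
#' order, so a load/dump/load round trip hashes identically.
#'
#' @param cfg Config list.
#' @return Hex string.
#' @export
config_hash <- function(cfg) {
  j <- jsonlite::toJSON(.canonicalize(cfg), auto_unbox = TRUE, digits = NA)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(j, tf)
  unname(tools::md5sum(tf))
}

# ---- experiment assembly ---------------------------------------------------

.build_experiment <- function(cfg) {
  loaded <- cfg$loaded %||% cfg$probes
  sp <- unlist(lapply(loaded, function(p) get_probe(p)$states),
               recursive = FALSE)
  exch <- lapply(cfg$excitation, function(e) {
    excitation_channel(e$name, led_spectrum(e$led), e$ex_filter,
                       mod_freq_hz = e$freq_khz * 1e3,
                       mod_depth = e$mod_depth %||% 1,
                       intensity = e$intensity %||% 1,
                       phase_rad = e$phase_rad %||% 0)
  })
  det <- lapply(cfg$detectors, function(d) {
    detection_channel(d$name, d$em_filters, gain = d$gain %||% 1)
  })
  background <- vapply(cfg$detectors, function(d) d$background %||% 0,
                       numeric(1))
  enames <- vapply(exch, function(e) e$name, character(1))
  edet <- vapply(cfg$excitation, function(e) e$detector, character(1))
  efreq <- vapply(exch, function(e) e$mod_freq_hz, numeric(1))
  channels <- if (!is.null(cfg$channels)) {
    demod_channels(
      label = vapply(cfg$channels, function(c) c$label, character(1)),
      detector = vapply(cfg$channels, function(c) c$detector, character(1)),
      freq_hz = vapply(cfg$channels, function(c) {
        efreq[match(c$excitation, enames)]
      }, numeric(1)))
  } else {
    demod_channels(label = enames, detector = edet, freq_hz = efreq)
  }
  acq <- acquisition_config(exch, det,
                            duration_s = cfg$acquisition$duration_s,
                            sim_rate_hz = cfg$acquisition$sim_rate_hz %||% 1e6,
                            multiplex_enabled = cfg$acquisition$multiplex %||% TRUE,
                            common_freq_hz = cfg$acquisition$common_freq_hz %||% NULL,
                            background = background)
  lock <- lockin_config(cfg$lockin$time_constant_s,
                        order = cfg$lockin$order %||% 3L,
                        output_interval_s = cfg$lockin$output_interval_s %||%
                          cfg$lockin$time_constant_s,
                        settle_factor = cfg$lockin$settle_factor %||% 10)
  # in the common-frequency control all references collapse onto one
  if (!acq$multiplex_enabled) channels$freq_hz <- acq$common_freq_hz
  list(species = sp, exch = exch, det = det, channels = channels,
       acq = acq, lock = lock, loaded = loaded)
}

.make_kinetics <- function(cfg, time_s, loaded) {
  kin <- cfg$kinetics
  switch(
    kin$scenario,
    cascade = {
      analytes <- resact_cascade(time_s, dose_scale = kin$dose_scale %||% 1,
                                 stimulus_time_s = kin$stimulus_time_s %||% 0)
      list(traces = probe_state_traces(analytes, loaded), flash_window = NULL)
    },
    uncaging = {
      u <- uncaging_step(time_s, flash_start_s = kin$flash_start_s,
                         flash_dur_s = kin$flash_dur_s %||% 0.050,
                         dose_scale = kin$dose_scale %||% 1)
      list(traces = probe_state_traces(u$traces, loaded),
           flash_window = u$flash_window)
    },
    dissociation = {
      mix <- kin$mix_time_s %||% 0
      cols <- list()
      for (p in loaded) {
        k <- kin$k_off_per_s[[p]]
        d <- dissociation_traces(time_s, k_off_per_s = k,
                                 bound_fraction_initial = kin$bound_fraction_initial %||% 1,
                                 start_s = mix,
                                 species_names = paste0(p, c(" (Ca)", " (free)")))
        cols[[p]] <- d$conc
      }
      conc <- do.call(cbind, unname(cols))
      keep <- intersect(colnames(conc),
                        unlist(lapply(loaded, function(p)
                          vapply(get_probe(p)$states, function(s) s$name,
                                 character(1)))))
      list(traces = concentration_traces(time_s, conc[, keep, drop = FALSE]),
           flash_window = NULL)
    },
    buffered = {
      stim <- kin$stimulus_time_s %||% 0
      idx <- time_s >= stim
      bm <- buffered_messenger(time_s[idx] - stim,
                               sensor_Kd = kin$sensor_Kd,
                               sensor_total = kin$sensor_total,
                               channel_K12 = kin$channel_K12,
                               production_rate = kin$production_rate,
                               hill = kin$hill %||% 1.5)
      occ <- rep(0, length(time_s))
      act <- rep(0, length(time_s))
      if (kin$sensor_total > 0) {
        occ[idx] <- bm$conc[, "sensor_bound"] / kin$sensor_total
      }
      act[idx] <- bm$conc[, "channel_activation"]
      analytes <- concentration_traces(
        time_s, cbind(cAMP_sensor = occ, Ca = act), signed = TRUE)
      list(traces = probe_state_traces(analytes, loaded), flash_window = NULL)
    },
    stop("unknown kinetics scenario '", kin$scenario, "'", call. = FALSE)
  )
}

# ---- end-to-end pipeline ---------------------------------------------------

#' Run a full in-silico experiment
#'
#' Executes the complete workflow on a configuration: build the optical
#' model and coupling tensor, generate the ground-truth kinetics, simulate
#' the modulated high-rate detector traces (with artifacts where the
#' scenario injects them), demodulate with the software lock-in, and run
#' the scenario's analysis recipe. Identical config and seed reproduce the
#' bundle bit-identically.
#'
#' @param cfg Config list (from [fixture_config()] or [load_config()]).
#' @param seed Overrides `cfg$seed`.
#' @param keep_raw Keep the high-rate raw traces in the bundle (large).
#' @return A result bundle: list with `name`, `config_hash`, `seed`,
#'   `version`, `plan` (frequency plan), `demod` (demodulated traces),
#'   `processed` (per-channel dF/F0 and ratio traces), `stats`
#'   (crosstalk, fits, latencies, flash rejection as applicable), and
#'   optionally `raw`.
#' @export
run_pipeline <- function(cfg, seed = NULL, keep_raw = FALSE) {
  errs <- validate_config(cfg)
  if (length(errs)) {
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  seed <- as.integer(seed %||% cfg$seed %||% 1L)
  ex <- .build_experiment(cfg)

  dt <- 1 / ex$acq$sim_rate_hz
  n <- round(ex$acq$duration_s * ex$acq$sim_rate_hz)
  tsim <- (seq_len(n) - 1) * dt
  kin <- .make_kinetics(cfg, tsim, ex$loaded)

  S <- build_coupling_tensor(ex$species, ex$exch, ex$det)
  plan <- plan_frequencies(unique(ex$channels$freq_hz),
                           tau_s = ex$lock$time_constant_s,
                           order = ex$lock$order,
                           sim_rate_hz = ex$acq$sim_rate_hz)

  # each reported signal is the average of n_average repeated recordings
  # (stopped-flow convention), each with its own noise realization
  n_avg <- cfg$acquisition$n_average %||% 1L
  demod <- NULL
  raw <- NULL
  for (r in seq_len(n_avg)) {
    noise <- noise_spec(shot_scale = cfg$acquisition$shot_scale %||% 0,
                        dark_sd = cfg$acquisition$dark_sd %||% 0,
                        seed = (seed + (r - 1L) * 1009L) %% .Machine$integer.max)
    raw_r <- simulate_acquisition(ex$acq, S, kin$traces, noise)
    if (!is.null(kin$flash_window)) {
      raw_r <- inject_flash_artifact(raw_r, kin$flash_window,
                                     amplitude = cfg$kinetics$flash_amplitude %||% 0)
    }
    if (!is.null(cfg$kinetics$mixing_amplitude)) {
      raw_r <- inject_mixing_artifact(raw_r,
                                      stop_time_s = cfg$kinetics$mix_time_s %||% 0,
                                      amplitude = cfg$kinetics$mixing_amplitude,
                                      decay_s = cfg$kinetics$mixing_decay_s %||% 5e-3)
    }
    demod_r <- demodulate(raw_r, ex$channels, ex$lock)
    if (is.null(demod)) {
      demod <- demod_r
      raw <- raw_r
    } else {
      demod$x <- demod$x + demod_r$x
    }
  }
  demod$x <- demod$x / n_avg
  an <- .analyze(cfg, demod, ex)

  bundle <- list(name = cfg$name %||% "experiment",
                 config_hash = config_hash(cfg), seed = seed,
                 version = as.character(utils::packageVersion("fdmfluor")),
                 plan = plan, demod = demod,
                 processed = an$processed, stats = an$stats)
  if (keep_raw) bundle$raw <- raw
  bundle
}

.analyze <- function(cfg, demod, ex) {
  a <- cfg$analysis %||% list()
  lock <- ex$lock
  valid_start <- settle_time(lock)
  dt_out <- lock$output_interval_s
  baseline <- a$baseline_window_s %||%
    c(valid_start, valid_start + 10 * dt_out)   # first 10 valid samples
  scenario <- cfg$kinetics$scenario
  stats_out <- list()
  processed <- list()

  # per-channel dF/F0 (own baseline) on settled samples only
  for (ch in colnames(demod$x)) {
    tr <- channel_trace(demod, ch, settled_only = TRUE)
    processed[[ch]] <- tryCatch(dff0(tr, baseline),
                                error = function(e) NULL)
  }

  if (!is.null(a$ratios)) {
    for (r in a$ratios) {
      processed[[r$label]] <- ratio_trace(
        channel_trace(demod, r$num, settled_only = TRUE),
        channel_trace(demod, r$den, settled_only = TRUE),
        baseline)
    }
  }

  src <- a$crosstalk_source %||%
    (if (length(ex$loaded) == 1L) {
      # a single loaded probe: its channel is the crosstalk source
      hit <- which(colnames(demod$x) %in% ex$loaded |
                     grepl(ex$loaded, colnames(demod$x), fixed = TRUE))
      if (length(hit)) colnames(demod$x)[hit[1]] else NULL
    } else NULL)
  if (!is.null(src) && src %in% colnames(demod$x)) {
    win <- c(valid_start,
             valid_start + (a$crosstalk_window_s %||% 2))
    win[2] <- min(win[2], max(demod$time_s))
    norm <- normalize_to_baseline(demod, baseline, reference = src)
    targets <- setdiff(colnames(demod$x), src)
    ct <- lapply(targets, function(tg) {
      crosstalk(channel_trace(norm, src), channel_trace(norm, tg),
                window_s = win)
    })
    stats_out$crosstalk <- data.frame(
      source = src, target = targets,
      percent = vapply(ct, function(x) x$percent, numeric(1)))
  }

  if (scenario == "dissociation") {
    mix <- cfg$kinetics$mix_time_s %||% 0
    delay <- a$fit_delay_s %||% 1.5e-3
    chans <- a$fit_channels %||% colnames(demod$x)
    fits <- lapply(chans, function(ch) {
      fit_monoexponential(channel_trace(demod, ch),
                          t_range = c(mix + delay, max(demod$time_s)))
    })
    stats_out$k_off <- data.frame(
      channel = chans,
      k_per_s = vapply(fits, function(f) f$k_per_s, numeric(1)),
      k_se = vapply(fits, function(f) f$k_se, numeric(1)))
    stats_out$fits <- fits
  }

  if (scenario %in% c("cascade", "uncaging", "buffered")) {
    stim <- if (scenario == "uncaging") cfg$kinetics$flash_start_s else
      cfg$kinetics$stimulus_time_s %||% 0
    # latencies are read from smoothed signals (80 ms sliding average by
    # default, the display convention for these recordings)
    smooth_s <- a$smooth_s %||% 0.080
    lat <- vapply(names(processed), function(ch) {
      p <- processed[[ch]]
      if (is.null(p)) return(NA_real_)
      ps <- tryCatch(sliding_average(p, smooth_s), error = function(e) p)
      detect_onset(ps, baseline, stimulus_time_s = stim)
    }, numeric(1))
    stats_out$latency_s <- lat
  }

  if (scenario == "uncaging") {
    fw <- c(cfg$kinetics$flash_start_s,
            cfg$kinetics$flash_start_s + (cfg$kinetics$flash_dur_s %||% 0.050))
    amp <- cfg$kinetics$flash_amplitude %||% 0
    if (amp > 0) {
      pre <- c(max(valid_start, fw[1] - 0.2), fw[1] - 0.01)
      dev <- vapply(colnames(demod$x), function(ch) {
        tr <- channel_trace(demod, ch)
        b <- mean(tr$value[tr$time_s >= pre[1] & tr$time_s <= pre[2]])
        inw <- tr$time_s >= fw[1] & tr$time_s <= fw[2]
        max(abs(tr$value[inw] - b))
      }, numeric(1))
      stats_out$flash_rejection_fraction <- dev / amp
    }
  }

  list(processed = processed, stats = stats_out)
}
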