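#' Shipped experiment fixtures
#'
#' Ready-made experiment configurations mirroring the acquisition
#' geometries the package is designed around. Each returns a plain nested
#' list in the same schema accepted by [load_config()]; pass it to
#' [run_pipeline()].
#'
#' * `"triple_probe"` -- three-probe stopped-flow recording of a
#'   chemoattractant cascade (Ca2+/pH/voltage probes Fura-2, BCECF, RhoVR
#'   at 30.4/37.3/50 kHz, two detectors).
#' * `"triple_probe_na"` -- variant with the Na+/pH/voltage set ANG-2,
#'   pHrodo, BeRST at 37/50/23 kHz.
#' * `"ratiometric"` -- dual-excitation ratiometric recording of Fura-FF
#'   (340/370 nm) and BCECF (445/485 nm) on one detector, four
#'   frequencies.
#' * `"uncaging"` -- flash-uncaging experiment with a 50 ms light-pulse
#'   artifact (Fluo-4, pHrodo, BeRST).
#' * `"dissociation"` -- chelator-quench kinetics of Fura-2 (dual
#'   excitation), Fluo-4 and Calbryte 630 at the 87.31/103.7/59.51/47.1
#'   kHz plan, lock-in time constant 100 us.
#' * `"single_cell"` -- FRET cAMP sensor (cerulean/citrine, one
#'   frequency, two detectors) plus Calbryte 630 on the acceptor-side
#'   detector.
#'
#' @param name Fixture name.
#' @param loaded Probes actually loaded (defaults to all probes of the
#'   fixture); unloaded probes keep their logical channels, which is how
#'   single-probe crosstalk runs are configured.
#' @param multiplex Use distinct modulation frequencies (`TRUE`) or the
#'   common-frequency optical-filtering control (`FALSE`).
#' @param seed Seed recorded in the config.
#' @param ... Overrides merged into the config (top-level names).
#' @return A config list.
#' @export
fixture_config <- function(name = c("triple_probe", "triple_probe_na",
                                    "ratiometric", "uncaging",
                                    "dissociation", "single_cell"),
                           loaded = NULL, multiplex = TRUE, seed = 1L, ...) {
  name <- match.arg(name)
  cfg <- switch(
    name,
    triple_probe = list(
      name = "triple_probe",
      probes = c("Fura-2", "BCECF", "RhoVR"),
      excitation = list(
        list(name = "Fura-2", led = "M375L4", ex_filter = "379/34",
             freq_khz = 30.4, detector = "D1"),
        list(name = "BCECF", led = "M490L4", ex_filter = "485/20",
             freq_khz = 50, detector = "D1"),
        list(name = "RhoVR", led = "M455L4", ex_filter = "438/24",
             freq_khz = 37.3, detector = "D2")),
      detectors = list(
        list(name = "D1", em_filters = list("524/24"), background = 0.5),
        list(name = "D2", em_filters = list("607/36"), background = 0.5)),
      acquisition = list(sim_rate_hz = 4e5, duration_s = 3.2, multiplex = multiplex,
                         shot_scale = 10, dark_sd = 5),
      kinetics = list(scenario = "cascade", dose_scale = 1),
      lockin = list(time_constant_s = 1e-3, order = 3,
                    output_interval_s = 1e-3),
      analysis = list(crosstalk_window_s = 2)),
    triple_probe_na = list(
      name = "triple_probe_na",
      probes = c("ANG-2", "pHrodo", "BeRST"),
      excitation = list(
        list(name = "ANG-2", led = "M490L4", ex_filter = "485/20",
             freq_khz = 37, detector = "D1"),
        list(name = "pHrodo", led = "M565L3", ex_filter = "575/19",
             freq_khz = 50, detector = "D2"),
        list(name = "BeRST", led = "M455L4", ex_filter = "438/24",
             freq_khz = 23, detector = "D2")),
      detectors = list(
        list(name = "D1", em_filters = list("542/20"), background = 0.5),
        list(name = "D2", em_filters = list("593LP"), background = 0.5)),
      acquisition = list(sim_rate_hz = 4e5, duration_s = 3.2, multiplex = multiplex,
                         shot_scale = 10, dark_sd = 5),
      kinetics = list(scenario = "cascade", dose_scale = 1),
      lockin = list(time_constant_s = 1e-3, order = 3,
                    output_interval_s = 1e-3),
      analysis = list(crosstalk_window_s = 2)),
    ratiometric = list(
      name = "ratiometric",
      probes = c("Fura-FF", "BCECF"),
      excitation = list(
        list(name = "Fura-FF 340", led = "M340L4", ex_filter = "340/22",
             freq_khz = 87.3, detector = "D1"),
        list(name = "Fura-FF 370", led = "M375L4", ex_filter = "370/10",
             freq_khz = 73.51, detector = "D1"),
        list(name = "BCECF 445", led = "M455L4", ex_filter = "445/20",
             freq_khz = 61.7, detector = "D1"),
        list(name = "BCECF 485", led = "M490L4", ex_filter = "485/20",
             freq_khz = 103.7, detector = "D1")),
      detectors = list(
        list(name = "D1", em_filters = list("524/24"), background = 0.5)),
      acquisition = list(sim_rate_hz = 5e5, duration_s = 2.0, multiplex = multiplex,
                         shot_scale = 10, dark_sd = 5),
      kinetics = list(scenario = "cascade", dose_scale = 1),
      lockin = list(time_constant_s = 1e-3, order = 3,
                    output_interval_s = 5e-3),
      analysis = list(ratios = list(
        list(label = "Fura-FF 340/370", num = "Fura-FF 340", den = "Fura-FF 370"),
        list(label = "BCECF 485/445", num = "BCECF 485", den = "BCECF 445")))),
    uncaging = list(
      name = "uncaging",
      probes = c("Fluo-4", "pHrodo", "BeRST"),
      excitation = list(
        list(name = "Fluo-4", led = "M490L4", ex_filter = "494/20",
             freq_khz = 37.3, detector = "D1"),
        list(name = "pHrodo", led = "M565L3", ex_filter = "575/19",
             freq_khz = 30.1, detector = "D2"),
        list(name = "BeRST", led = "M455L4", ex_filter = "438/24",
             freq_khz = 50.3, detector = "D2")),
      detectors = list(
        list(name = "D1", em_filters = list("542/20"), background = 0.5),
        list(name = "D2", em_filters = list("593LP"), background = 0.5)),
      acquisition = list(sim_rate_hz = 4e5, duration_s = 3.5, multiplex = multiplex,
                         shot_scale = 10, dark_sd = 5),
      kinetics = list(scenario = "uncaging", flash_start_s = 1.0,
                      flash_dur_s = 0.050, dose_scale = 1,
                      flash_amplitude = 500),
      lockin = list(time_constant_s = 1e-3, order = 3,
                    output_interval_s = 1e-3),
      analysis = list()),
    dissociation = list(
      name = "dissociation",
      probes = c("Fura-2", "Fluo-4", "Calbryte 630"),
      excitation = list(
        list(name = "Fura-2 340ex", led = "M340L4", ex_filter = "340/22",
             freq_khz = 87.31, detector = "D1"),
        list(name = "Fura-2 370ex", led = "M375L4", ex_filter = "370/10",
             freq_khz = 103.7, detector = "D1"),
        list(name = "Fluo-4", led = "M490L4", ex_filter = "485/20",
             freq_khz = 59.51, detector = "D1"),
        list(name = "Calbryte 630", led = "M565L3", ex_filter = "586/20",
             freq_khz = 47.1, detector = "D2")),
      detectors = list(
        list(name = "D1", em_filters = list("524/24"), background = 0.5),
        list(name = "D2", em_filters = list("647/57"), background = 0.5)),
      acquisition = list(sim_rate_hz = 1e6, duration_s = 0.12, multiplex = multiplex,
                         shot_scale = 10, dark_sd = 5, n_average = 5),
      kinetics = list(scenario = "dissociation", mix_time_s = 0.02,
                      k_off_per_s = list("Fura-2" = 115, "Fluo-4" = 354,
                                         "Calbryte 630" = 178)),
      lockin = list(time_constant_s = 1e-4, order = 3,
                    output_interval_s = 1e-4),
      analysis = list(fit_channels = c("Fura-2 340ex", "Fluo-4",
                                       "Calbryte 630"),
                      fit_delay_s = 1.5e-3)),
    single_cell = list(
      name = "single_cell",
      probes = c("cerulean", "citrine", "Calbryte 630"),
      excitation = list(
        list(name = "blue", led = "M455L4", ex_filter = "438/24",
             freq_khz = 36.1, detector = "Ddon"),
        list(name = "green", led = "M565L3", ex_filter = "565/24",
             freq_khz = 49.5, detector = "Dacc")),
      detectors = list(
        list(name = "Ddon", em_filters = list("475/28"), background = 0.5),
        list(name = "Dacc", em_filters = list("578/105"), background = 0.5)),
      channels = list(
        list(label = "donor", detector = "Ddon", excitation = "blue"),
        list(label = "acceptor", detector = "Dacc", excitation = "blue"),
        list(label = "Ca", detector = "Dacc", excitation = "green")),
      acquisition = list(sim_rate_hz = 1.25e5, duration_s = 16, multiplex = multiplex,
                         shot_scale = 10, dark_sd = 5),
      kinetics = list(scenario = "buffered", stimulus_time_s = 2,
                      sensor_Kd = 0.07, sensor_total = 10,
                      channel_K12 = 10, production_rate = 2, hill = 1.5),
      lockin = list(time_constant_s = 1e-2, order = 3,
                    output_interval_s = 5e-3),
      analysis = list(baseline_window_s = c(0.5, 1.5),
                      ratios = list(
                        list(label = "FRET", num = "donor", den = "acceptor"))))
  )
  if (!is.null(loaded)) cfg$loaded <- loaded
  cfg$seed <- as.integer(seed)
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  cfg
}

#' Names of the shipped fixtures
#' @return Character vector.
#' @export
fixture_names <- function() {
  c("triple_probe", "triple_probe_na", "ratiometric", "uncaging",
    "dissociation", "single_cell")
}
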