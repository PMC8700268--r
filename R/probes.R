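#' Built-in probe library
#'
#' Parametric (sum-of-Gaussians) approximations of the excitation and
#' emission spectra of the fluorescent probes used in the shipped
#' experiment fixtures, together with the wiring that links each
#' spectroscopic state to an analyte (Ca2+, pH, Na+, membrane voltage, or
#' cAMP-pathway readouts). These are plausible textbook-shaped
#' approximations, not measured spectra: peak positions follow vendor
#' values, widths are representative. Consequences for what the fixtures
#' can and cannot reproduce are discussed in the methods vignette.
#'
#' Ratiometric indicators contribute two species: `"<probe> (Ca)"` /
#' `"<probe> (free)"` for the Fura family and Ca2+ dyes, `"<probe> (base)"`
#' / `"<probe> (acid)"` for BCECF. The voltage dyes carry a secondary
#' excitation component near 400 nm, as photoinduced-electron-transfer
#' probes do.
#'
#' @return Named list; each entry has `states` (list of [species()]) and
#'   `response` (data frame with columns `species`, `analyte`, `gain`
#'   giving the relative fluorescence change per unit analyte waveform).
#' @export
probe_library <- function() {
  g <- gaussian_band
  mk <- function(states, response) list(states = states, response = response)
  resp <- function(...) {
    d <- data.frame(..., stringsAsFactors = FALSE)
    names(d) <- c("species", "analyte", "gain")
    d
  }

  lib <- list(
    "Fura-2" = mk(
      list(species("Fura-2 (Ca)",   g(335, 60), g(505, 70)),
           species("Fura-2 (free)", g(368, 65), g(512, 75))),
      resp(c("Fura-2 (Ca)", "Fura-2 (free)"), c("Ca", "Ca"), c(0.35, -0.35))),
    "Fura-FF" = mk(
      list(species("Fura-FF (Ca)",   g(335, 60), g(505, 70)),
           species("Fura-FF (free)", g(365, 65), g(510, 75))),
      resp(c("Fura-FF (Ca)", "Fura-FF (free)"), c("Ca", "Ca"), c(0.35, -0.35))),
    "BCECF" = mk(
      list(species("BCECF (base)", g(503, 55), g(528, 60)),
           species("BCECF (acid)", g(482, 60), g(522, 60), brightness = 0.4)),
      resp(c("BCECF (base)", "BCECF (acid)"), c("pH", "pH"), c(0.30, -0.30))),
    "Fluo-4" = mk(
      list(species("Fluo-4 (Ca)",   g(494, 45), g(516, 50)),
           species("Fluo-4 (free)", g(494, 45), g(516, 50), brightness = 0.01)),
      resp(c("Fluo-4 (Ca)", "Fluo-4 (free)"), c("Ca", "Ca"), c(0.40, 0))),
    "Calbryte 630" = mk(
      list(species("Calbryte 630 (Ca)",   g(607, 50), g(626, 55)),
           species("Calbryte 630 (free)", g(607, 50), g(626, 55), brightness = 0.02)),
      resp(c("Calbryte 630 (Ca)", "Calbryte 630 (free)"), c("Ca", "Ca"), c(0.40, 0))),
    "pHrodo" = mk(
      list(species("pHrodo", g(560, 55), g(585, 60))),
      resp("pHrodo", "pH", -0.30)),
    "ANG-2" = mk(
      list(species("ANG-2", g(517, 45), g(540, 50))),
      resp("ANG-2", "Na", 0.30)),
    "VF2.1.Cl" = mk(
      list(species("VF2.1.Cl", g(c(522, 405), c(50, 70), c(1, 0.35)),
                   g(535, 55))),
      resp("VF2.1.Cl", "Vm", 0.40)),
    "RhoVR" = mk(
      list(species("RhoVR", g(c(572, 405), c(50, 70), c(1, 0.35)),
                   g(595, 55))),
      resp("RhoVR", "Vm", 0.40)),
    "BeRST" = mk(
      list(species("BeRST", g(c(658, 405), c(55, 70), c(1, 0.35)),
                   g(683, 60))),
      resp("BeRST", "Vm", 0.40)),
    "cerulean" = mk(
      list(species("cerulean", g(433, 45), g(475, 55))),
      resp("cerulean", "cAMP_sensor", 0.30)),
    "citrine" = mk(
      list(species("citrine", g(516, 45), g(529, 50))),
      resp("citrine", "cAMP_sensor", -0.25))
  )
  lib
}

#' Names of the built-in probes
#' @return Character vector.
#' @export
probe_names <- function() names(probe_library())

#' Look up a probe definition
#' @param name Probe name, one of [probe_names()].
#' @return The library entry (`states`, `response`).
#' @export
get_probe <- function(name) {
  lib <- probe_library()
  if (!name %in% names(lib)) {
    stop("unknown probe '", name, "'; available: ",
         paste(names(lib), collapse = ", "), call. = FALSE)
  }
  lib[[name]]
}

#' Built-in LED spectra
#'
#' Gaussian approximations of the LED lines used in the shipped fixtures,
#' keyed by the vendor part name.
#'
#' @param name LED part name, e.g. `"M375L4"`.
#' @return A [spectrum_nm()].
#' @export
led_spectrum <- function(name) {
  tab <- list(
    M340L4 = c(340, 12), M375L4 = c(375, 12), M455L4 = c(455, 20),
    M490L4 = c(490, 25), M505L3 = c(505, 30), M565L3 = c(565, 80)
  )
  if (!name %in% names(tab)) {
    stop("unknown LED '", name, "'; available: ",
         paste(names(tab), collapse = ", "), call. = FALSE)
  }
  p <- tab[[name]]
  gaussian_band(p[1], p[2])
}
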