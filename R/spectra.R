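#' Default wavelength grid (nm)
#'
#' The working grid for all spectral calculations: 300--750 nm in 1 nm
#' steps. The 1 nm step resolves the narrowest excitation filter in the
#' shipped configurations (370/10) with more than 10 grid points.
#'
#' @return Numeric vector of wavelengths in nm.
#' @export
default_wavelengths <- function() seq(300, 750, by = 1)

#' Construct a spectrum
#'
#' A spectrum is a nonnegative curve indexed by a strictly increasing
#' wavelength grid. It is the shared currency of probes (excitation and
#' emission), LEDs, optical filters and detector sensitivities. Emission
#' and excitation curves are in arbitrary units; transmission curves are
#' bounded by 1.
#'
#' @param wavelengths_nm Strictly increasing numeric grid (nm).
#' @param values Nonnegative values, same length as `wavelengths_nm`.
#' @param transmission If `TRUE` the values are checked against the
#'   \[0, 1\] bound of a transmission curve.
#' @return An object of class `"spectrum_nm"`.
#' @export
spectrum_nm <- function(wavelengths_nm, values, transmission = FALSE) {
  wavelengths_nm <- as.numeric(wavelengths_nm)
  values <- as.numeric(values)
  if (length(wavelengths_nm) != length(values)) {
    stop("wavelengths and values must have the same length", call. = FALSE)
  }
  if (length(wavelengths_nm) < 2L) {
    stop("a spectrum needs at least two grid points", call. = FALSE)
  }
  if (any(diff(wavelengths_nm) <= 0)) {
    stop("wavelength grid must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("spectrum values must be finite and nonnegative", call. = FALSE)
  }
  if (transmission && any(values > 1 + 1e-12)) {
    stop("transmission values must not exceed 1", call. = FALSE)
  }
  structure(
    list(wavelengths_nm = wavelengths_nm, values = values,
         transmission = isTRUE(transmission)),
    class = "spectrum_nm"
  )
}

#' @export
print.spectrum_nm <- function(x, ...) {
  cat(sprintf("<spectrum> %g-%g nm, %d points, peak %.3g at %g nm\n",
              min(x$wavelengths_nm), max(x$wavelengths_nm),
              length(x$values), max(x$values),
              x$wavelengths_nm[which.max(x$values)]))
  invisible(x)
}

#' Evaluate a spectrum on arbitrary wavelengths
#'
#' Linear interpolation inside the grid; 0 outside the grid (a spectrum
#' carries no information beyond its support).
#'
#' @param spectrum A [spectrum_nm()] object.
#' @param wavelengths_nm Wavelengths (nm) at which to evaluate.
#' @return Numeric vector of values.
#' @export
eval_spectrum <- function(spectrum, wavelengths_nm) {
  stopifnot(inherits(spectrum, "spectrum_nm"))
  stats::approx(spectrum$wavelengths_nm, spectrum$values,
                xout = wavelengths_nm, rule = 1)$y -> v
  v[is.na(v)] <- 0
  v
}

#' Resample a spectrum onto a new grid
#'
#' @inheritParams eval_spectrum
#' @return A [spectrum_nm()] on the new grid.
#' @export
resample_spectrum <- function(spectrum, wavelengths_nm = default_wavelengths()) {
  spectrum_nm(wavelengths_nm, eval_spectrum(spectrum, wavelengths_nm),
              transmission = spectrum$transmission)
}

#' Gaussian spectral band
#'
#' Convenience constructor for parametric probe and LED spectra: a sum of
#' Gaussian components on the default grid. Widths are given as FWHM, the
#' quantity usually quoted for LEDs and dye bands.
#'
#' @param center_nm Peak wavelength(s), nm.
#' @param fwhm_nm Full width at half maximum per component, nm.
#' @param amplitude Relative amplitude per component (default 1).
#' @param wavelengths_nm Grid on which to tabulate.
#' @return A [spectrum_nm()].
#' @export
gaussian_band <- function(center_nm, fwhm_nm, amplitude = 1,
                          wavelengths_nm = default_wavelengths()) {
  stopifnot(length(center_nm) == length(fwhm_nm))
  amplitude <- rep_len(amplitude, length(center_nm))
  sigma <- fwhm_nm / (2 * sqrt(2 * log(2)))
  v <- rep(0, length(wavelengths_nm))
  for (i in seq_along(center_nm)) {
    v <- v + amplitude[i] * exp(-((wavelengths_nm - center_nm[i])^2) /
                                  (2 * sigma[i]^2))
  }
  spectrum_nm(wavelengths_nm, v)
}

#' Read a spectrum from a two-column CSV
#'
#' Expects columns `wavelength_nm, value` (header optional extra columns
#' are rejected).
#'
#' @param path CSV file path.
#' @param transmission Is this a transmission curve (bounded by 1)?
#' @return A [spectrum_nm()].
#' @export
read_spectrum_csv <- function(path, transmission = FALSE) {
  d <- utils::read.csv(path)
  if (ncol(d) != 2L) {
    stop("expected a two-column CSV (wavelength_nm, value): ", path,
         call. = FALSE)
  }
  spectrum_nm(d[[1]], d[[2]], transmission = transmission)
}

# ---- optical filters -------------------------------------------------------

#' Specify an optical filter
#'
#' Bandpass filters follow the vendor "center/FWHM" notation (a `"485/20"`
#' string is accepted directly); longpass filters are given by their cutoff.
#' Edges are raised cosines of configurable softness so that integrals over
#' the passband behave smoothly; the transmission crosses 0.5 exactly at the
#' nominal edge, making the FWHM exact.
#'
#' @param kind `"bandpass"` or `"longpass"`.
#' @param center_nm,fwhm_nm Bandpass center and full width at half maximum (nm).
#' @param cutoff_nm Longpass cutoff (nm).
#' @param edge_softness_nm Width of the raised-cosine transition (nm, >= 0).
#' @return An object of class `"filter_spec"`.
#' @examples
#' filter_spec("bandpass", center_nm = 485, fwhm_nm = 20)
#' parse_filter("593LP")
#' @export
filter_spec <- function(kind = c("bandpass", "longpass"),
                        center_nm = NULL, fwhm_nm = NULL,
                        cutoff_nm = NULL, edge_softness_nm = 2) {
  kind <- match.arg(kind)
  if (!is.numeric(edge_softness_nm) || edge_softness_nm < 0) {
    stop("edge_softness_nm must be >= 0", call. = FALSE)
  }
  if (kind == "bandpass") {
    if (is.null(center_nm) || is.null(fwhm_nm)) {
      stop("bandpass filters need center_nm and fwhm_nm", call. = FALSE)
    }
    if (fwhm_nm <= 0) stop("fwhm_nm must be positive", call. = FALSE)
    if (center_nm <= 0) stop("center_nm must be positive", call. = FALSE)
  } else {
    if (is.null(cutoff_nm) || cutoff_nm <= 0) {
      stop("longpass filters need a positive cutoff_nm", call. = FALSE)
    }
  }
  structure(
    list(kind = kind, center_nm = center_nm, fwhm_nm = fwhm_nm,
         cutoff_nm = cutoff_nm, edge_softness_nm = edge_softness_nm),
    class = "filter_spec"
  )
}

#' Parse vendor filter notation
#'
#' `"485/20"` is a bandpass with center 485 nm and FWHM 20 nm; `"593LP"` a
#' longpass with cutoff 593 nm. A `filter_spec` passes through unchanged.
#'
#' @param x Character notation or a [filter_spec()].
#' @param edge_softness_nm Edge softness forwarded to [filter_spec()].
#' @return A [filter_spec()].
#' @export
parse_filter <- function(x, edge_softness_nm = 2) {
  if (inherits(x, "filter_spec")) return(x)
  x <- trimws(as.character(x))
  if (grepl("^[0-9.]+/[0-9.]+$", x)) {
    parts <- as.numeric(strsplit(x, "/", fixed = TRUE)[[1]])
    return(filter_spec("bandpass", center_nm = parts[1], fwhm_nm = parts[2],
                       edge_softness_nm = edge_softness_nm))
  }
  if (grepl("^[0-9.]+ ?LP$", x, ignore.case = TRUE)) {
    cutoff <- as.numeric(sub("(?i) ?LP$", "", x, perl = TRUE))
    return(filter_spec("longpass", cutoff_nm = cutoff,
                       edge_softness_nm = edge_softness_nm))
  }
  stop("cannot parse filter notation: '", x,
       "' (expected 'center/fwhm' or 'cutoffLP')", call. = FALSE)
}

# raised-cosine step from 0 to 1 over [edge - s/2, edge + s/2]; 0.5 at edge
.rc_edge <- function(wl, edge, softness) {
  if (softness <= 0) return(as.numeric(wl >= edge))
  x <- (wl - edge) / softness + 0.5
  x <- pmin(pmax(x, 0), 1)
  0.5 * (1 - cos(pi * x))
}

#' Filter transmission curve
#'
#' Tabulates the transmission of a filter on a wavelength grid. Bandpass:
#' approximately 1 inside `center +/- fwhm/2`, falling to 0 outside through a
#' raised-cosine edge; longpass: rising to 1 above the cutoff. Transmission
#' is always in \[0, 1\].
#'
#' @param filter A [filter_spec()] or vendor notation accepted by
#'   [parse_filter()].
#' @param wavelengths_nm Grid (nm).
#' @return A transmission [spectrum_nm()].
#' @export
filter_transmission <- function(filter, wavelengths_nm = default_wavelengths()) {
  f <- parse_filter(filter)
  s <- f$edge_softness_nm
  if (f$kind == "bandpass") {
    lo <- f$center_nm - f$fwhm_nm / 2
    hi <- f$center_nm + f$fwhm_nm / 2
    v <- .rc_edge(wavelengths_nm, lo, s) * (1 - .rc_edge(wavelengths_nm, hi, s))
  } else {
    v <- .rc_edge(wavelengths_nm, f$cutoff_nm, s)
  }
  spectrum_nm(wavelengths_nm, pmin(pmax(v, 0), 1), transmission = TRUE)
}

# trapezoid rule on a (possibly nonuniform) grid
.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}
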