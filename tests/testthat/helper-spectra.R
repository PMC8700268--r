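# rectangular ("boxcar") spectrum: value `height` on [lo, hi], 0 outside
boxcar_spectrum <- function(lo, hi, height = 1,
                            wl = default_wavelengths()) {
  spectrum_nm(wl, ifelse(wl >= lo & wl <= hi, height, 0))
}

# independent trapezoid rule used as the oracle for overlap integrals
trapz_oracle <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2)
}

# small two-detector, three-channel optical bench resembling the standard
# Ca/pH/voltage stopped-flow geometry
bench_triple <- function() {
  list(
    exch = list(
      excitation_channel("Fura-2", led_spectrum("M375L4"), "379/34", 30.4e3),
      excitation_channel("BCECF", led_spectrum("M490L4"), "485/20", 50e3),
      excitation_channel("RhoVR", led_spectrum("M455L4"), "438/24", 37.3e3)),
    det = list(detection_channel("D1", list("524/24")),
               detection_channel("D2", list("607/36")))
  )
}
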