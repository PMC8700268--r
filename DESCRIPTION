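Package: fdmfluor
Title: Frequency-Division Multiplexed Fluorescence: Forward Simulation
    and Software Lock-In Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation and analysis of frequency-tagged,
    spectrally overlapping fluorescence recordings, as used in stopped-flow
    photometry of sperm signaling and rapid indicator kinetics. Parametric
    probe, LED and filter spectra are reduced to a linear coupling tensor;
    a high-rate simulator generates modulated photodetector traces with
    shot noise and flash or mixing artifacts; a software lock-in amplifier
    (phase-sensitive demodulation with a cascaded single-pole lowpass)
    separates the probe channels; and an analysis layer provides dF/F0 and
    dR/R0 measures, slope-based crosstalk quantification, signal-to-noise
    ratios, onset latencies, monoexponential dissociation-rate fits, and
    Nernst-potential calibration of membrane-voltage dyes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
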