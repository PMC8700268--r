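# fdmfluor

Frequency-division multiplexed fluorescence, in silico: a forward
simulator of frequency-tagged, spectrally overlapping fluorescence
recordings, a software lock-in amplifier that separates the probe
channels, and the analysis layer used with such recordings.

## The problem

Rapid cellular signaling — a millisecond-scale membrane-voltage
hyperpolarization followed by pH and Ca²⁺ changes, or the dissociation
kinetics of Ca²⁺ indicators in a stopped-flow mixer — demands *truly
simultaneous* recording of several fluorescent probes in one sample.
Their emission spectra overlap, so optical filtering alone cannot keep
the channels apart. Frequency tagging can: each excitation LED is
modulated sinusoidally at its own kHz frequency, every emitted photon
inherits the frequency of the LED that excited it, and a phase-sensitive
(lock-in) demodulator referenced to each frequency recovers each probe's
signal from a shared photomultiplier.

`fdmfluor` is for people who design, teach, or analyze such experiments:
it simulates the full measurement chain (parametric probe/LED/filter
spectra → coupling tensor → modulated detector currents with shot noise
and flash/mixing artifacts → cascaded-lowpass lock-in demodulation) and
implements the standard quantitative layer on top.

## The core quantities

* **Coupling tensor** `S[k, j, s]` — effective brightness of species *s*
  on detector *k* under excitation channel *j*, from the overlap
  integrals of the optical train. The detector current is
  `y_k(t) = Σ_j I_j(t) Σ_s S[k,j,s] c_s(t) + background + noise` with
  `I_j(t) = ½(1 + m cos 2πf_j t)`.
* **Lock-in output** — `X = 2·LPF[y cos 2πft]`, `Y = −2·LPF[y sin 2πft]`
  through `order` identical single-pole stages of time constant τ
  (gain `|H(f)| = (1+(2πfτ)²)^(−order/2)`, 18 dB/octave at order 3); an
  input `A cos 2πft` reads back as `X = A`.
* **Crosstalk** — 100 × the OLS slope of the target channel regressed on
  the source (loaded-probe) channel; 100 % for perfectly correlated
  channels, ~0 % for independent ones.
* **ΔF/F₀, ΔR/R₀** — percent change versus a baseline-window mean;
  gain-invariant.
* **k_off** — unconstrained monoexponential fit
  `y = offset + A·e^(−kt)` to chelator-quench traces.
* **V_m calibration** — peak ΔF/F₀ vs. K⁺ Nernst potential
  `E_K = (RT/F)·ln([K⁺]_o/423 mM)`; slope = sensitivity (%/mV),
  x-intercept = resting potential.

See `vignettes/methods.Rmd` for the model, assumptions, and design
choices.

## Worked example

Simulate the stopped-flow chelator-quench experiment — three Ca²⁺
indicators premixed with Ca²⁺, rapidly mixed with excess chelator, four
frequency-tagged channels on two detectors, lock-in at τ = 100 µs — and
fit the dissociation rates:

```r
library(fdmfluor)
cfg <- fixture_config("dissociation", seed = 42)
bundle <- run_pipeline(cfg)
bundle$plan
#> <frequency plan> PASS; 4 channels; noise bandwidth 937.5 Hz; worst leakage 0.206%
bundle$stats$k_off
#>        channel  k_per_s      k_se
#> 1 Fura-2 340ex 114.6907 1.3540023
#> 2       Fluo-4 353.6231 2.2489323
#> 3 Calbryte 630 178.3978 0.1473948
```

The fitted `k_per_s` are the dissociation rate constants (s⁻¹) recovered
from the simulated recordings; the fixture's ground-truth rates are
115, 354 and 178 s⁻¹, so the end-to-end chain (spectral coupling →
modulation → shot noise → demodulation → fit) recovers them to well
within 1 %.

The benefit of frequency tagging, on a single pH-probe recording whose
channels share a detector:

```r
run_pipeline(fixture_config("triple_probe", loaded = "BCECF",
                            multiplex = FALSE, seed = 42))$stats$crosstalk
#>   source target    percent
#> 1  BCECF Fura-2 100.000000
#> 2  BCECF  RhoVR   3.613103
run_pipeline(fixture_config("triple_probe", loaded = "BCECF",
                            multiplex = TRUE, seed = 42))$stats$crosstalk
#>   source target     percent
#> 1  BCECF Fura-2  0.08756128
#> 2  BCECF  RhoVR -0.09803647
```

With all LEDs on one common frequency (optical filtering alone) the pH
probe floods its same-detector sibling channel completely (100 %); with
distinct frequencies the crosstalk collapses to below 0.1 %.

A thin command-line front end is installed with the package
(`system.file("cli", "fdmfluor", package = "fdmfluor")`) with
subcommands `fixtures`, `plan-check`, `simulate`, `demodulate` and
`pipeline`; configurations are YAML (see
`inst/extdata/triple_probe.yaml`).

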