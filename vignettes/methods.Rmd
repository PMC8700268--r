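---
title: "Frequency-tagged fluorescence multiplexing: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-tagged fluorescence multiplexing: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdmfluor)
```

## The measurement problem

Rapid cellular signaling events — a membrane-voltage (V~m~)
hyperpolarization, a pH~i~ rise, a Ca^2+^ influx — unfold within tens to
hundreds of milliseconds of each other. Following them simultaneously
requires several fluorescent probes in the same sample, but the probes'
emission spectra overlap, so optical filtering alone cannot separate
them: light from one probe leaks into another probe's detection channel
(*crosstalk*).

Frequency-division multiplexing solves this by tagging each probe with a
modulation frequency. Each excitation LED is driven sinusoidally at its
own kHz-range frequency; every photon a probe emits inherits the
frequency of the LED that excited it. A phase-sensitive (lock-in)
demodulator referenced to each frequency then recovers each probe's
signal from a shared photomultiplier, in real time, regardless of the
spectral overlap on the emission side. Emission-side optical filtering
still routes broad spectral bands onto one of a small number of
detectors; the frequency tags separate channels *within* a detector.

`fdmfluor` implements this measurement end to end, in silico: a forward
simulator of the modulated acquisition, a software lock-in amplifier,
and the downstream analysis layer used with such recordings
(ΔF/F₀, ratiometrics, crosstalk quantification, dissociation-rate fits,
Nernst-potential voltage calibration).

## Optical model

All spectra live on a 300–750 nm grid with 1 nm steps; the narrowest
shipped filter (370/10) is resolved with more than 10 points. Filters
have raised-cosine edges of configurable softness (default 2 nm) whose
transmission crosses 0.5 exactly at the nominal band edge; the soft edge
avoids the integration artifacts of hard boxcars while staying
near-ideal. Detector sensitivity is flat by default, as no
quantum-efficiency curves are assumed.

The optical train reduces to a *coupling tensor*
`S[detector, excitation channel, species]`, the effective brightness of
each species on each (detector, excitation) pair:

$$
S_{kjs} = B_s \, I_j \, G_k
  \int \! L_j(\lambda)\,T^{ex}_j(\lambda)\,E^{ex}_s(\lambda)\,d\lambda
  \int \! E^{em}_s(\lambda)\,T^{em}_k(\lambda)\,d\lambda
$$

with brightness $B_s$, drive intensity $I_j$, detector gain $G_k$, LED
spectrum $L$, filter transmissions $T$, and species excitation/emission
curves $E$ (trapezoid integration). The detector signal is then linear
in the species concentrations:

$$
y_k(t) = \sum_j I_j(t) \sum_s S_{kjs}\, c_s(t) + \text{background}_k + \varepsilon(t),
\qquad
I_j(t) = \tfrac{1}{2}\big(1 + m \cos(2\pi f_j t + \varphi_j)\big).
$$

**Probe spectra are parametric approximations.** The library ships
sum-of-Gaussians excitation/emission curves for the Fura family, BCECF,
Fluo-4, Calbryte 630, pHrodo, ANG-2, the VoltageFluor dyes (VF2.1.Cl,
RhoVR, BeRST — with a broad secondary excitation band near 405 nm, as
photoinduced-electron-transfer dyes have), cerulean and citrine. Peak
positions follow vendor values; widths are representative. This is the
main idealization of the package: crosstalk magnitudes that depend on
the exact in-situ spectra (e.g. how much a pH dye's emission tail leaks
into a red detector) are reproduced only qualitatively. Quantities that
do *not* depend on exact spectra — the definitional 100 % crosstalk of a
channel against itself, the same-detector/same-frequency control, the
sub-percent crosstalk achieved by frequency separation, filter rolloff,
rate-constant recovery — are quantitative.

## Kinetic scenarios

The generator produces per-species relative concentration traces
$c_s(t)$, a unit baseline modulated by signed analyte waveforms:

* **Chemoattractant cascade** — a pulse-like V~m~ hyperpolarization
  $A(1-e^{-t/\tau_r})e^{-t/\tau_d}$ (onset 50 ms, $\tau_r$ = 20 ms,
  $\tau_d$ = 200 ms, amplitude −1), saturating pH and Na^+^ rises (onset
  150 ms, $\tau$ = 300 ms) and a delayed Ca^2+^ rise (onset 400 ms,
  $\tau$ = 500 ms). The latency ordering V~m~ < pH ≤ Na < Ca is the
  physiological one; the numeric latencies and time constants are
  fixture choices — the acceptance of the package rests on
  signal-processing fidelity, not on biological parameter estimates.
  Dose dependence uses the monotone map
  $\text{latency}(d) = \text{latency}(1)/(1+\log_{10} d)$ (clipped
  positive) with a saturating depth factor $2d/(1+d)$ for the V~m~
  pulse.
* **Chelator quench** — excess-chelator dissociation:
  $c_\text{bound}(t) = b_0 e^{-k_\text{off} t}$ from the mixing time,
  free form complementary, rebinding neglected. Ground-truth rates for
  the shipped fixture: 354 s⁻¹ (Fluo-4), 178 s⁻¹ (Calbryte 630),
  115 s⁻¹ (Fura-2).
* **Flash uncaging** — the cascade referenced to a 50 ms light flash,
  which also injects an unmodulated broadband artifact into the raw
  traces.
* **cAMP buffering toy** — total messenger accumulates at a constant
  production rate; free messenger follows from the closed-form quadratic
  of rapid-equilibrium sensor binding; a downstream channel activates as
  a Hill function of free messenger. Because production is constant the
  total-cAMP ODE has the exact solution (rate × t), so the fixture uses
  it directly rather than a numerical integrator; conservation
  (free + bound = total) holds to machine precision by construction.
  With equal sensor amounts, activation latency orders as
  none < low-affinity (K~d~ ≈ 1 µM) < high-affinity (K~d~ ≈ 70 nM)
  sensor, the signature of messenger buffering. The low-affinity K~d~ of
  1 µM is a toy choice for the mutant sensor; only the ordering is
  asserted.

Note on sign conventions: the quench fixture uses conventional Fura-2
state spectra (Ca^2+^-bound excitation peaking near 335 nm, free near
368 nm), which makes the 340 nm-excited channel *decrease* on
dissociation. Published quench traces can show the opposite sign,
depending on the probe's in-situ state spectra; the monoexponential rate
fit is sign-agnostic, so recovered rate constants are unaffected.

## Acquisition model

The simulator samples at a configurable internal rate (default 1 MHz;
the rate must be ≥ 2.5× the largest modulation frequency). Modulation is
sinusoidal: the modulation waveform of the hardware is not specified in
the literature this models, and sinusoids avoid harmonic collisions and
match lock-in practice. Noise is Gaussian with variance
$\sigma^2_\text{dark} + s\,\cdot\,\text{signal}(t)$ — shot noise in the
high-flux regime of an analog PMT current — drawn from a seeded
generator; identical configuration and seed reproduce traces
bit-identically. Flash artifacts are additive smoothed rectangles;
mixing artifacts are multiplicative exponentially decaying disturbances
recorded in the metadata so analysis can crop them. Detector response is
linear (no saturation model).

The fixtures use 400 kHz (three-probe cascade, 8× the 50 kHz maximum
frequency), 500 kHz (four-frequency ratiometric), 1 MHz (quench, max
103.7 kHz) and 125 kHz (single-cell); the noise scale (shot variance 10
per unit signal, dark SD 5, against baseline signals of order a few
hundred) gives demodulated baseline noise of roughly 1 % — a realistic
stopped-flow regime. The quench fixture averages 5 repeated recordings
per signal and the reported stopped-flow convention is the average of
at least 3–5 recordings.

## The software lock-in

Per logical channel (detector × reference frequency) the demodulator
computes

$$
X = 2\,\mathrm{LPF}[y \cos 2\pi f t], \qquad
Y = -2\,\mathrm{LPF}[y \sin 2\pi f t],
$$

so that an input $A\cos(2\pi f t + \varphi_0)$ yields the phasor
$X + iY = A e^{i\varphi_0}$ in steady state. The lowpass is a cascade of
`order` identical single-pole recursive stages
$y[n] = y[n-1] + \frac{\Delta t}{\tau + \Delta t}(u[n]-y[n-1])$, with
$\tau$ the *per-stage* time constant — the commercial convention, so a
"third-order, 18 dB/octave" filter with τ = 1 ms is three such stages.
Its closed-form gain is $|H(f)| = (1 + (2\pi f \tau)^2)^{-\text{order}/2}$
and its equivalent noise bandwidth
$\frac{1}{2\pi\tau}\cdot\frac{\pi}{2}\cdot\frac{(2n-3)!!}{(2n-2)!!}$
(93.75 Hz at order 3, τ = 1 ms).

Auto-phasing estimates $\varphi = \operatorname{atan2}(\bar Y, \bar X)$
over the settled samples (or an explicit calibration window of at least
20 modulation periods) and outputs the in-phase component
$X' = \operatorname{Re}[(X+iY)e^{-i\varphi}]$. In-phase output is the
default rather than the magnitude $R=\sqrt{X^2+Y^2}$ because $R$
rectifies noise at low signal and destroys the sign of downward
deflections; magnitude mode is available. Output is decimated by
subsampling the filtered stream (the cascade is the anti-alias filter),
and the first `settle_factor × order × τ` seconds (default factor 10)
are masked as settling transient; analysis operations exclude masked
samples.

Numerical choices: references are generated in double precision directly
from $2\pi f t$; the recursive stages run in compiled code
(`stats::filter`); a non-integer decimation ratio is snapped to the
nearest integer with a warning.

## Analysis layer

* **ΔF/F₀** — percent change relative to the mean of a baseline window
  (default: the first 10 valid samples after the settling mask,
  configurable down to 3, matching the "first 5–10 points" convention);
  invariant under any positive gain.
* **ΔR/R₀** — percent change of an excitation ratio; invariant under
  independent per-channel gains.
* **Control subtraction** — pointwise subtraction of the plain-medium
  response on a common grid.
* **Sliding average** — centered moving mean (display convention 80 ms)
  with symmetrically shrinking edges.
* **Crosstalk** — 100 × the OLS slope of target vs. source channel over
  a stated window (first 2 s by convention). The regression is
  deliberately asymmetric (loaded probe on the abscissa) and the
  intercept absorbs offsets. For the pipeline's crosstalk statistics all
  channels are first divided by the *source channel's* baseline mean:
  a single common scale that preserves relative amplitudes between
  channels. Normalizing each channel to its own baseline would force the
  slope of any purely proportional leak to 1 and could never show the
  sub-percent crosstalk that frequency separation achieves; the common
  scale keeps the self-case at exactly 100 % while making the slope
  equal the physical coupling ratio.
* **S/N** — mean over SD across a 200-point stationary window.
* **Monoexponential fit** — unconstrained least squares of
  $y = \text{offset} + A e^{-k t}$ (Levenberg–Marquardt via
  `minpack.lm`), initialized by log-linear regression; the quench
  recipe starts the fit window 1.5 ms (15 filter time constants) after
  mixing, by which time the lowpass transient has decayed to below
  10⁻⁶ while the filtered trace is again a pure exponential with the
  *same* rate (filtering an exponential through RC stages rescales its
  amplitude by $(1-k\tau)^{-\text{order}}$ but leaves $k$ intact).
* **Voltage calibration** — OLS of peak ΔF/F₀ against K^+^ Nernst
  potentials $E_K = \frac{RT}{F}\ln([K^+]_o/[K^+]_i)$ (defaults
  [K^+^]~i~ = 423 mM, 291.15 K); the slope is the sensitivity
  (%ΔF/F₀ per mV), the x-intercept the resting potential, with
  delta-method SEs. `vm_from_dff()` inverts the line to calibrate a
  trace into mV.
* **Onset detection** — first run of ≥ 5 consecutive samples beyond
  baseline mean ± 3 SD, direction auto-detected from the extremum; the
  exact latency rule behind published figures is not specified, so this
  debounced threshold is a documented stand-in with exposed parameters.
  The pipeline reads latencies from 80 ms-smoothed traces, the same
  smoothing used for display of such signals; threshold crossing on a
  noisy slow rise biases latencies late, which is inherent to any
  threshold rule at finite S/N.

## Frequency planning

`plan_frequencies()` is a report-only feasibility check: channel pairs
closer than 10× the filter's noise bandwidth are flagged (100 Hz apart
at τ = 1 ms, order 3 — noise bandwidth ≈ 94 Hz — fails); second and
third harmonics folded by the simulation rate are checked against a
narrower 2× guard (sinusoidal drive carries no harmonic power, so this
only guards the optional square-wave mode); frequencies at or above
Nyquist fail. The worst-case inter-channel leakage from the closed-form
filter response is reported — for the standard 30.4/37.3/50 kHz set at
τ = 1 ms it is ≈ 1.2 × 10⁻⁵, i.e. ≈ 0.001 %.

## What the tests do and do not show

The test suite validates the signal-processing chain against closed
forms (filter gain, 18 dB/octave rolloff, amplitude conventions,
two-tone rejection), algebraic invariances (gain invariance of ΔF/F₀
and ΔR/R₀, linearity of the forward map and the demodulator), and
end-to-end parameter recovery at the shipped study conditions
(dissociation rates within 3 %, crosstalk bounds, cascade onset
ordering). Because probe spectra are approximations and the kinetic
waveforms are fixtures, passing tests demonstrate fidelity of the
*measurement pipeline*, not of any biological parameter; in-vivo
crosstalk percentages between specific dye pairs (e.g. a pH dye into a
red voltage-dye channel) are matched only qualitatively.

Problem sizes were chosen to keep every fixture comfortably within a
desk-scale run: simulations of 0.12–16 s at 0.125–1 MHz, i.e. 10⁵–10⁶
samples per detector, each completing in seconds.

## Known limitations

* No photobleaching, inner-filter effects, absolute radiometric units,
  PMT gain drift or saturation (an optional soft-saturation hook exists
  for studying intermodulation, off by default).
* Shot noise is Gaussian, not Poisson — appropriate for high photon
  flux, wrong for photon-counting regimes.
* Square-wave modulation is available but the default analysis assumes
  the sinusoidal spectrum.
* The buffering fixture is a qualitative toy: it reproduces the latency
  ordering under sensor buffering, not quantitative cAMP dynamics.
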