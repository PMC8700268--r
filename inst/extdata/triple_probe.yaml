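name: triple_probe
probes:
- Fura-2
- BCECF
- RhoVR
excitation:
- name: Fura-2
  led: M375L4
  ex_filter: 379/34
  freq_khz: 30.4
  detector: D1
- name: BCECF
  led: M490L4
  ex_filter: 485/20
  freq_khz: 50.0
  detector: D1
- name: RhoVR
  led: M455L4
  ex_filter: 438/24
  freq_khz: 37.3
  detector: D2
detectors:
- name: D1
  em_filters:
  - 524/24
  background: 0.5
- name: D2
  em_filters:
  - 607/36
  background: 0.5
acquisition:
  sim_rate_hz: 400000.0
  duration_s: 3.2
  multiplex: yes
  shot_scale: 10.0
  dark_sd: 5.0
kinetics:
  scenario: cascade
  dose_scale: 1.0
lockin:
  time_constant_s: 0.001
  order: 3.0
  output_interval_s: 0.001
analysis:
  crosstalk_window_s: 2.0
seed: 1
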