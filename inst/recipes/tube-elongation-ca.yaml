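name: tube-elongation-ca
description: >
  Control versus constitutively-active-like cohorts (20 phantoms each); the
  mutant tortuosity is reduced 3% relative to a mildly curved control
  (ratio 1.10), and the percent reduction of group means is recovered from
  auto-traced centerlines.
mirrors: mild dorsal-trunk shortening under receptor overactivation
type: tube_elongation
seed: 20170706
params:
  n_per_group: 20
  control_tortuosity: 1.10
  mutant_tortuosity: 1.067
  tortuosity_sd: 0.03
  length_um: 40
  diameter_um: 3
  control_label: control
  mutant_label: EGFR_CA
  trace: true
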