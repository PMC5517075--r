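name: tube-elongation-dn
description: >
  Two cohorts of 20 tube phantoms: a mildly curved control (mean ratio 1.05,
  a ratio of exactly 1 with nonzero spread is geometrically impossible) and a
  receptor-downregulated-like cohort elevated 22.6% over control (1.2873);
  centerlines are auto-traced and the percent difference of mean arc/chord
  ratios is recovered.
mirrors: dorsal trunk elongation under receptor downregulation
type: tube_elongation
seed: 20170705
params:
  n_per_group: 20
  control_tortuosity: 1.05
  mutant_tortuosity: 1.2873
  tortuosity_sd: 0.03
  length_um: 40
  diameter_um: 3
  control_label: control
  mutant_label: EGFR_DN
  trace: true
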