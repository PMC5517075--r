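name: vesicle-census
description: >
  A 194-vesicle two-channel field at cargo-class probabilities 0.67 / 0.15 /
  0.18 (the reported 66/15/18 census with the rounding remainder assigned to
  the dual class); detection, cargo classification and census recover the
  planted proportions.
mirrors: dual-cargo sorting-endosome census at stage 14
type: vesicle_census
seed: 20170707
params:
  n_vesicles: 194
  p_both: 0.67
  p_ch1_only: 0.15
  p_ch2_only: 0.18
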