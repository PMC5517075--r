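name: crb-intensity
description: >
  Ten replicates of a two-band phantom (tube band at 1.5x the reference-band
  intensity, widths 60 and 10 px); the normalized band-mean ratio recovers
  the planted 1.5.
mirrors: apical-determinant level normalization to an internal reference
type: intensity_ratio
seed: 20170713
params:
  n_replicates: 10
  dt_intensity: 1500
  mt_intensity: 1000
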