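name: junction-orientation
description: >
  A junction lattice with axial edges of 2 um and circumferential edges of
  1 um, 5 degrees orientation jitter; classification and per-class mean
  lengths are recovered.
mirrors: axial versus circumferential junction lengths
type: junction_orientation
seed: 20170712
params:
  n_cells: 25
  axial_length_um: 2
  circumferential_length_um: 1
  orientation_jitter_deg: 5
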