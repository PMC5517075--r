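name: endosome-diameter
description: >
  Enlarged sorting endosomes planted at 1.3 um mean diameter; detection and
  equivalent-diameter measurement recover the planted mean within 10%.
mirrors: enlarged endosome diameter under receptor downregulation
type: diameter_recovery
seed: 20170709
params:
  n_vesicles: 27
  diameter_um_mean: 1.3
  diameter_um_sd: 0.1
  min_separation_um: 3.5
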