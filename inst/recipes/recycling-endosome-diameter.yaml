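name: recycling-endosome-diameter
description: >
  Small recycling endosomes planted at 0.28 um, imaged at 0.05 um/px with a high-NA
  confocal PSF (sigma 0.085 um), near the resolution limit; mean measured diameter recovered within 20%.
mirrors: small junction-proximal recycling endosomes
type: diameter_recovery
seed: 20170710
imaging:
  pixel_size_um: 0.05
  psf_sigma_um: 0.085
params:
  n_vesicles: 30
  diameter_um_mean: 0.28
  diameter_um_sd: 0.02
  min_separation_um: 1.2
  field_um: 12
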