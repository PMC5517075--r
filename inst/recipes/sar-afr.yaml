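name: sar-afr
description: >
  A square apical cell with a 0.3 um contour band at twice the interior
  intensity, rendered diffraction-free with shot noise so the measured band
  shares the generator's pixel masks; the sum-intensity SAR/AFR ratio
  recovers the pixel-enumeration ground truth.
mirrors: subapical versus apical-free-region accumulation ratio
type: sar_afr
seed: 20170714
imaging:
  psf_sigma_um: 0
params:
  cell_side_um: 5
  sar_band_width_um: 0.3
  sar_intensity: 2000
  afr_intensity: 1000
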