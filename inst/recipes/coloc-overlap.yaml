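name: coloc-overlap
description: >
  118 dual-cargo endosomes generated with a 0.60 within-endosome signal
  overlap; the mean per-endosome colocalized integrated-density fraction at
  ratio cutoff 0.5 recovers the planted overlap. Imaged at the lateral resolution of a high-NA confocal
  (PSF sigma 0.085 um, i.e. 0.2 um FWHM) with low noise, since sub-endosome
  domain structure is only measurable when the optics resolve it.
mirrors: colocalized signal fraction in common sorting endosomes
type: coloc_overlap
seed: 20170708
imaging:
  psf_sigma_um: 0.085
  poisson_noise: false
  read_noise_sigma: 2
params:
  n_vesicles: 118
  within_vesicle_overlap: 0.60
  ratio_cutoff: 0.5
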