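# tubemorph

Morphometric and cargo-trafficking quantification for tubular epithelia
imaged by fluorescence microscopy — with a synthetic phantom generator so
every measurement is validated by parameter recovery against exact ground
truth.

## The problem

During the maturation of a branched tubular organ (the motivating system is
the embryonic *Drosophila* tracheal dorsal trunk), tube length is set by a
balance between apical membrane growth and restraint by the luminal
extracellular matrix. The readouts that make this tractable are image
measurements:

- **Tube tortuosity.** Trace the lumen path between two anchor landmarks and
  compute the arc-to-chord ratio
  `ratio = L_arc / ‖P_end − P_start‖`. A straight tube gives exactly 1; an
  overelongated tube buckles inside the fixed body segment and the ratio
  rises (e.g. +22.6% when receptor signalling is downregulated, −3% when it
  is overactivated).
- **Junction orientation.** Each cell junction's chord angle to the tube
  axis, folded into [0°, 90°]: axial (≤ 30°), circumferential (≥ 60°), or
  unclassified, with per-class length statistics.
- **Intensity ratios.** A tube-band mean normalized to an internal reference
  band (60 px and 10 px line widths), and the subapical-region over
  apical-free-region sum-intensity ratio within single cells.
- **Colocalization.** A pixel colocalizes when both channels pass their
  thresholds and `min(i1,i2)/max(i1,i2) ≥ 0.5`; per channel (and per
  endosome) the colocalized fraction is integrated density over the mask
  divided by integrated density over that channel's above-threshold pixels.
- **Endosome census and sizes.** Blob detection, equivalent-circle diameter
  `2·sqrt(area/π)·pixel_size` (with optional PSF-inversion correction near
  the resolution limit), cargo presence classification, and the
  both / channel-1-only / channel-2-only census; plus nuclei counts.
- **Statistics.** Unpaired two-tailed pooled-variance Student's *t*,
  standard errors, percent difference vs control, and the star code
  (\* p<0.05, \*\* 0.001<p<0.01, \*\*\* p<0.001).

Because the quantities are measurements on images, the package ships a
generator of fluorescence phantoms (Gaussian PSF, Poisson shot noise,
Gaussian read noise, quantization) that plants each quantity as ground
truth, making the whole pipeline testable without any microscopy data.

## Worked example

Generate a two-channel endosome field, detect and classify the vesicles,
and take the cargo census:

```r
library(tubemorph)

ph  <- vesicle_phantom(n_vesicles = 60, imaging = imaging_params(seed = 7))
det <- detect_vesicles(ph$image)
vesicle_census(det)
#> # A tibble: 1 × 7
#>   n_total n_both n_ch1_only n_ch2_only p_both p_ch1_only p_ch2_only
#>     <int>  <int>      <int>      <int>  <dbl>      <dbl>      <dbl>
#> 1      60     36          9         15    0.6       0.15       0.25
```

All 60 planted vesicles are found; 60% carry both cargoes — the realized
draw of the generator's class probabilities, which the census recovers
exactly. Tortuosity, end to end from pixels:

```r
tube   <- tube_phantom(length_um = 30, diameter_um = 3, tortuosity = 1.226,
                       imaging = imaging_params(seed = 1))
traced <- trace_centerline(tube$image, anchors = tube$truth$anchors_px)
dt_ratio(traced, pixel_size_um = 0.1)
#> # A tibble: 1 × 3
#>   arc_length_um chord_length_um ratio
#>           <dbl>           <dbl> <dbl>
#> 1          36.6              30  1.22
```

The auto-traced path measures 36.6 µm along a 30 µm chord — ratio 1.22
against a planted 1.226 (0.4% off). Group comparison, reported the way the
field prints it:

```r
group_compare(c(1.04, 1.08, 1.05, 1.10, 1.06),
              c(1.27, 1.31, 1.25, 1.30, 1.33),
              labels = c("control", "EGFR_DN"))
#> <group_comparison> control (n=5, mean 1.066 +/- 0.0108 s.e.) vs EGFR_DN (n=5, mean 1.292 +/- 0.0143 s.e.)
#>   t = -12.6338, df = 8, p = 1.447e-06 ***; percent difference 21.2%
```

`tidy()`, `glance()` and `autoplot()` methods turn comparisons, censuses and
reports into tibbles and ggplots. Whole experiments — simulate, measure,
report, with provenance — run from YAML recipes:

```r
run_experiment(bundled_recipes()[["vesicle-census"]], out_dir = "out")
```

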