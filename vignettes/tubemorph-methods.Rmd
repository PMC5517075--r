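---
title: "Models and methods behind tubemorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tubemorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tubemorph)
```

## What the package measures

tubemorph quantifies five fluorescence-microscopy readouts used to study how
an epithelial tube attains its length and how apical cargo proteins traffic
through sorting endosomes:

1. **Tube tortuosity** — the arc-to-chord ratio of a traced lumen path. For a
   path $P$ between two anchor landmarks, the statistic is
   $\mathrm{ratio} = L_{\mathrm{arc}}(P) / \lVert P_{\mathrm{end}} -
   P_{\mathrm{start}}\rVert$. A perfectly straight tube gives exactly 1; an
   overelongated, convoluted tube gives a larger value. The ratio is
   dimensionless and invariant to rotation, translation and uniform scaling,
   including the pixel-size calibration.
2. **Junction orientation morphometrics** — each cell junction's chord angle
   relative to the tube axis, folded into $[0^\circ, 90^\circ]$, classified
   as *axial* ($\le 30^\circ$), *circumferential* ($\ge 60^\circ$) or
   unclassified, with per-class length summaries.
3. **Normalized intensity ratios** — a tube-band mean over a reference-band
   mean (cancels embryo-wide staining differences), and the subapical (SAR)
   over apical-free-region (AFR) *sum*-intensity ratio within one cell.
4. **Thresholded-ratio colocalization** — a pixel colocalizes when both
   channels pass their thresholds and $\min(i_1,i_2)/\max(i_1,i_2) \ge 0.5$;
   per channel, the colocalized-signal fraction is the integrated density
   over the mask divided by the integrated density over that channel's
   above-threshold pixels, optionally restricted per endosome.
5. **Vesicle census and sizes** — blob detection, equivalent-circle diameter
   $d = 2\sqrt{A/\pi}\cdot s$ (area $A$ in px, pixel size $s$), cargo
   presence classification and the dual-cargo / channel-1-only /
   channel-2-only census; plus nuclei counting.

Group differences are assessed exactly as the mirrored laboratory workflow
reports them:
an unpaired two-tailed pooled-variance Student's *t*-test, standard errors
$s/\sqrt{n}$, percent differences relative to control, and the star code
(* p<0.05, ** 0.001<p<0.01, *** p<0.001).

## Why a phantom generator is first-class

No microscopy data ships with the package. Instead, every measurement has a
synthetic counterpart with exact ground truth, so each operation is validated
by *parameter recovery*: the generator plants a known quantity (a tortuosity,
class proportions, an overlap fraction, a diameter, a count), the pipeline
measures the rendered image, and tests compare measurement to truth at a
stated tolerance. Ground-truth geometry is always computed from the planted
coordinates, never from rendered pixels, so the truth cannot inherit the
pipeline's own biases.

### Acquisition model

All phantoms pass through one acquisition model (`imaging_params()`):
isotropic Gaussian PSF of s.d. `psf_sigma_um`, Poisson shot noise on the
blurred signal (pixel values read as expected photon counts), additive
Gaussian read noise, then clipping and rounding to the detector bit depth.
Defaults: 0.1 µm/px (the smallest quantified object, a 0.28 µm recycling
endosome, spans ~3 px), PSF σ = 0.2 µm, 16 bit, read noise s.d. 5. One
integer seed drives everything; per-stage sub-streams are derived
deterministically so adding a stage never perturbs another, and identical
parameters plus seed give bit-identical images and truth.

Two experiment recipes use σ = 0.085 µm instead (≈ 0.2 µm FWHM, the lateral
resolution of a 63×/1.4 NA confocal): the within-endosome colocalization
recovery and the 0.28 µm diameter recovery. Sub-domain structure inside a
0.55 µm endosome simply does not survive a σ = 0.2 µm PSF — the choice
mirrors the fact that such measurements are only made on high-NA,
Nyquist-sampled acquisitions.

### Generators

- **Tube** (`tube_phantom()`): a single-period sinusoid centerline between
  two anchors; the amplitude is solved by bisection (tolerance $10^{-4}$ on
  the ratio) to hit the requested tortuosity. The shape is a modelling
  choice — only the statistic is specified by the problem — and the recorded
  truth is the exact polyline ratio.
- **Junction lattice** (`junction_phantom()`): a rectangular grid of axial
  and circumferential edges (an unrolled tube surface), each segment rotated
  about its midpoint by a normal jitter, then the whole lattice rotated to
  the tube axis. Truth lists every segment's endpoints, folded angle and
  length. Note that folding makes planted deviations half-normal: the RMS
  deviation, not the s.d., estimates the jitter parameter.
- **Vesicle field** (`vesicle_phantom()`): non-overlapping discs with
  normal diameters; cargo class drawn from (p_both, p_ch1, p_ch2). Dual
  cargo vesicles are split into a central shared band and two private
  flanks: a fraction *v* (`within_vesicle_overlap`) of each channel's
  integrated signal is placed uniformly in the shared band (where the two
  channels match exactly, hence pass the 0.5 ratio criterion) and $1-v$ in
  that channel's private flank. The per-endosome colocalized-signal
  fraction of the planted pattern is therefore *v* by construction.
  Defaults are the study conditions the generator emulates: diameters
  0.55 ± 0.05 µm, class probabilities (0.67, 0.15, 0.18) — the reported
  66/15/18 census renormalized by assigning the 1% rounding remainder to
  the dual class — and v = 0.60.
- **Apical cell** (`apical_cell_phantom()`): a contour band (SAR) and
  interior (AFR) at distinct intensities; the generating SAR/AFR ratio is
  enumerated pixel-by-pixel from the two disjoint planted masks.
- **Nuclei field** (`nuclei_phantom()`): non-overlapping bright discs,
  default 3 µm across at ≥ 4.5 µm separation.
- **Intensity bands** (`intensity_band_phantom()`): a wide tube band and a
  narrow reference band. Under a PSF the mean over a width-$W$ band centered
  on a width-$W$ structure falls below the painted intensity by an edge
  coverage factor $\frac{1}{W}\int_{-W/2}^{W/2}
  \left[\Phi\!\big(\tfrac{W/2-x}{\sigma}\big) +
  \Phi\!\big(\tfrac{W/2+x}{\sigma}\big) - 1\right] dx$, which hits the
  narrow band harder; the recorded `dt_mt_true_ratio` is the analytic
  band-mean ratio under this 1-d model, not the nominal painted ratio.

## Numerical choices in the measurements

**Centerline tracing.** `trace_centerline()` binarizes the lumen channel
(Otsu unless given a threshold), closes small gaps, and finds the minimum
cost 8-connected path between the mask pixels nearest the two anchors, with
step costs weighted by the inverse distance transform so the path rides the
medial ridge of the tube. The raw pixel chain is then smoothed with an
endpoint-anchored moving average over about one tube radius — an 8-connected
chain otherwise overestimates arc length by its staircase geometry. On
default phantoms the traced ratio lands within 0.5% of truth; the module
contract asks for 2%. Anchors not connected within the mask, or a blank
image, raise errors rather than returning a guess.

**Blob detection and sizing.** `detect_vesicles()` enhances the per-pixel
maximum of the detection channels with a difference-of-Gaussians band-pass
tuned to the size window, thresholds it (Otsu), splits touching blobs by
watershed on the distance transform, then re-segments each blob at its local
half-max (background plus half the peak prominence) for measurement. When
the PSF is known, measured half-max diameters are corrected by inverting the
exact forward model of a uniform disc convolved with a Gaussian — the radial
profile $I(r) = \int_0^R \frac{\rho}{\sigma^2}
e^{-(\rho-r)^2/2\sigma^2}\,[I_0(r\rho/\sigma^2)e^{-r\rho/\sigma^2}]\,d\rho$
is tabulated over true radii and inverted by interpolation. Naive quadrature
subtraction of the FWHM is wrong at both extremes: for objects much larger
than the PSF the half-max contour already sits on the true edge (no
correction needed), while near the resolution limit the blur dominates.
Below a point source's half-max footprint the inversion clamps rather than
extrapolates.

**Cargo presence.** A channel is present in a vesicle when its mean
intensity inside the mask exceeds twice the channel's background median
(pixels outside all detections). The visual judgement this replaces has no
stated intensity rule; the 2× factor is a conventional
signal-over-background margin, and the rule is invariant under common
rescaling of both channels.

**Colocalization.** The conventional statement of the criterion — a "ratio
between red and green channels above 0.5" — does not fix a direction; the symmetric min/max form is the default
so results cannot depend on channel order, and a directional variant exists
behind a flag. "Number of pixels (integrated density)" conflates two
quantities; both are computed, integrated density being the primary one.
Per-channel Otsu thresholds are used when none are supplied. Boundary
behaviour is inclusive (`ratio >= cutoff`), making the mask monotonically
shrinking in the cutoff.

**Junction conventions.** Angles come from the endpoint chord (matching how
a freehand-traced junction's overall orientation reads); a total-least
squares direction is available via `method = "tls"`. The printed bands
"0°±30°" and "90°±30°" are taken as closed, so 30° is axial and 60° is
circumferential; the open interval between them is reported separately and
excluded from the two-class comparison.

**Statistics.** Classic pooled-variance Student's *t* (df $= n_a+n_b-2$),
because that is the named procedure being mirrored; Welch is available via
`var_equal = FALSE`. No multiple-testing correction is applied (none is
applied in the workflow being reproduced); reports carry a note when more
than 5 comparisons run together. Star thresholds are read with strict
inequalities as printed, so p exactly 0.001 or 0.01 falls into the `*` band.

## Study conditions in the bundled recipes

Each recipe under `inst/recipes/` fixes one desk-scale experiment, with a
mandatory seed:

- **tube-elongation-dn / -ca**: cohorts of 20 phantoms per group,
  between-embryo tortuosity s.d. 0.03. A control with mean ratio exactly 1
  and nonzero spread is geometrically impossible (the ratio is bounded below
  by 1), so the control baselines are mildly curved — 1.05 (DN experiment)
  and 1.10 (CA) — and the mutant is planted at the reported percentage
  relative to control (+22.6% → 1.2873; −3% → 1.067). With n = 20 + 20 and
  s.d. 0.03 the sampling s.e. of the recovered percent difference is about
  0.9 percentage points, which dominates the tracing bias (< 0.1 pp).
- **vesicle-census**: 194 vesicles at (0.67, 0.15, 0.18); the recovered and
  planted censuses are compared within three binomial standard errors.
- **coloc-overlap**: 118 dual-cargo endosomes at overlap 0.60, σ = 0.085 µm,
  shot noise off and read noise 2 ("low noise"): the per-endosome mean
  colocalized fraction recovers 60% within 5 points.
- **endosome-diameter / recycling-endosome-diameter**: 27 endosomes at
  1.3 µm (default optics) and 30 at 0.28 µm (0.05 µm/px, σ = 0.085 µm),
  recovered within 10% and 20% respectively.
- **nuclei-count**: planted counts 25, 26, 25, 26 (mean 25.5); counting must
  be exact per field.
- **junction-orientation**: axial 2 µm vs circumferential 1 µm edges, 5°
  jitter; per-class means recovered within 5%.
- **crb-intensity**: ten replicates of the two-band phantom at nominal ratio
  1.5, compared to the analytic generating ratio.
- **sar-afr**: a 5 µm square cell with a 0.3 µm contour band at twice the
  interior intensity, rendered diffraction-free (the 3 px band is narrower
  than the default PSF, and this operation's contract is pixel-mask
  accounting, not deblurring).

The test suite runs the same experiments at these sizes; the whole suite
completes in a few minutes on one core.

## What passing tests do and do not show

The phantoms emulate geometry, optics at first order, and counting
statistics. They do **not** emulate: textured or filamentous luminal matrix
(tubes are uniform cylinders), anisotropic axial blur or true z-stacks
(projection is tested on synthetic stacks only), autofluorescent or
structured background, touching or partially out-of-focus vesicles beyond
the planted separation, chromatic misregistration between channels, or
embryo-to-embryo correlation beyond a single variance term. Recovery on
phantoms therefore demonstrates the correctness of the measurement
operations and their stated invariances — not that any particular biological
image will be segmented correctly. The statistics module pools objects
across embryos exactly as the mirrored workflow does; treating the embryo as
the experimental unit would require a nested model that is deliberately out
of scope, and both groupings can be computed from the tidy measurement
tables.

Degenerate inputs are contracts, not crashes with stack traces: coincident
path endpoints, an interior region with zero summed intensity, a channel
with no above-threshold pixels, an empty census, overcrowded placement and
unknown recipe keys all raise (or flag) informative conditions, and the
tests pin each of these behaviours.
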