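---
title: "Confidence-interval classification of HRME images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confidence-interval classification of HRME images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

High-resolution microendoscopy (HRME) images the superficial oral epithelium
through a 790-micrometre fiber-optic probe: nuclei appear as bright oval
structures on a darker cytoplasm background inside a circular field of view
(FOV) of roughly 960 pixels across, i.e. about 0.82 micrometres per pixel.
Neoplastic epithelium carries crowded, enlarged, eccentric nuclei, so the
*number of abnormal nuclei per square millimetre* is a discriminative feature:
densities above a decision boundary of 189 abnormal nuclei per mm^2 indicate
neoplasia (the "ND" rule, `nd_classify()`).

Real images routinely contain regions where nuclei are not visible —
sensor saturation, poor probe contact (dim regions), surface keratin,
whole-image contrast loss. Pooling such regions into the density estimate
corrupts it. This package implements the full remedy pipeline:

1. a U-Net labels every pixel *visible nuclei* / *no visible nuclei* /
   *background* (`unet_fit()`, `predict()`);
2. nuclei are segmented and scored only inside the visible regions
   (`segment_nuclei()`, `classify_nuclei()`);
3. the abnormal density over the *full* FOV is treated as an estimand, with an
   exact binomial confidence interval (`density_ci()`);
4. a three-way decision with a reject option: *neoplastic* if the whole
   interval is above the boundary, *benign* if below, and *cannot classify*
   if the interval spans it (`ndci_decide()`).

## The density confidence interval

Within the visible regions, `p_hat` is the abnormal fraction among the
`n_hat` segmented nuclei and `A_hat` the region area in mm^2; the observed
abnormal density is `p_hat * (n_hat / A_hat)`. The full-FOV density is
`p * (n / A)`. The interval assumes the nuclear density is spatially
homogeneous (`n / A = n_hat / A_hat`) and models the abnormal count as
binomial, so the only uncertain factor is `p`. Its Clopper–Pearson exact
interval (`clopper_pearson()`, two-sided equal-tailed, via beta quantiles) is
scaled by `n_hat / A_hat` to give the density interval. With no nuclei
available the interval is undefined and the image is always rejected.

Numerical choices: all boundary comparisons are strict, so an interval
endpoint exactly at 189/mm^2 yields *cannot classify*, and a density exactly
at the boundary is benign under the no-reject rule; interval bounds are
compared unrounded. The default confidence level is 0.90.

## Coverage validation

`run_coverage()` reproduces the validation experiment: full-FOV images of
known density, circular regions of interest (ROIs) with radii on a linear
grid from 41 px to the FOV radius (25 values), centres drawn uniformly *by
area* over the concentric disc of radius `R_FOV - R_ROI` so each ROI fits in
the FOV, an interval per ROI, and the fraction of intervals containing the
image's true density per (radius, level). ROI draws are shared across
confidence levels. A nucleus belongs to an ROI iff its centroid does, the
same membership rule used for region masks. The FOV "true" density and ROI
areas both use the analytic disc area `pi r^2`, keeping the degenerate
full-FOV ROI exactly covered.

The stand-in panel (`phantom_panel()`) is 48 homogeneous phantoms — 24
benign-like and 24 neoplastic-like — with abnormal densities spanning roughly
60–120 and 230–350 per mm^2 (bracketing typical clinical values of ~70–290)
and total nucleation of 900–2200 nuclei per mm^2, typical of oral epithelium
at this magnification. These values were fixed once, from the densities the
study prints, before any coverage measurement.

**What a homogeneous panel can and cannot show.** On such a panel the
empirical coverage *exceeds* the nominal level everywhere, most visibly at
low confidence levels. Two mechanisms guarantee this: the Clopper–Pearson
interval is intrinsically conservative (its exact coverage of `p` is
`>= level` for every `n`, and markedly so at level 0.50 for any realistic
nucleus count), and an ROI samples a finite nucleus population, so the
abnormal count is hypergeometric-like with variance a factor `(1 - f)` below
binomial (`f` = ROI area fraction). A normal-approximation argument gives
limiting coverage `2*Phi(z_level / sqrt(1 - f)) - 1`, above the level for
every `f > 0`. Clinical images escape this because within-image
heterogeneity (clustered abnormal nuclei, segmentation noise) adds variance
the interval does not model, pulling mid-range coverage back down to near
nominal. The package therefore asserts the qualitative structure — coverage
monotone in level, above nominal for large ROIs, exactly 1 at the full-FOV
ROI — and reports the measured coverage curves; near-nominal mid-band
calibration should not be expected from homogeneous phantoms, and the test
suite's strict mid-band calibration check documents this gap rather than
papering over it.

## The segmentation network

The U-Net is implemented in vectorized base R: feature maps are
`(H, W, batch, channel)` arrays, every 3x3 zero-padded convolution is one
BLAS matrix product on an im2col matrix, and all backward passes are
hand-derived (they are verified against finite differences in the test
suite). The encoder is five six-layer groups — twice (3x3 convolution, batch
normalization, ReLU) — with 2x2 maxpools between, channel plan
`base * {1, 2, 4, 8, 16}`; the decoder mirrors it with 2x2 stride-2
transposed convolutions that halve the channels, skip concatenations, and
four more six-layer groups; a final 1x1 convolution produces three class
scores. Zero padding preserves spatial size, so the score map is at the
network input size and the postprocessing bilinear upsample only restores
the original image resolution before the two-class softmax over the nucleus
channels, binarized at 0.5 (ties go to *no visible nuclei*); pixels outside
the FOV are forced to background.

Training uses the reference protocol: Adam (`alpha = 1e-4`,
`beta1 = 0.9`, `beta2 = 0.999`), L2 penalty `1e-4` on convolution kernels,
learning rate decayed by 0.9 every 10 epochs, batches of five images,
horizontal/vertical reflections and random crop-with-resize (crop scale
uniform on [0.7, 1]; the range is this package's choice). The loss is
pixel-wise cross-entropy averaged over FOV pixels with class weights
*inversely* proportional to training-set prevalence (normalized to mean 1);
weighting *toward* the ~79%-prevalent visible class would defeat the stated
purpose of the weighting, so the inverse reading is implemented. Background
pixels carry weight zero. The checkpoint with the highest validation IoU is
selected (the earliest epoch on ties; selecting for the *highest* validation
IoU is the only reading consistent with IoU being a quality score, and is
what is implemented). Ground truth for
training composites three rater masks: a pixel is *no visible nuclei* iff at
least two raters marked it so.

**Desk-scale profile.** The architecture is size-parametric. Tests and the
acceptance script use input 128x128 with base 8 channels (486,307 parameters
versus 7,762,051 at full scale) on 20 synthetic phantoms — sizes chosen so a
complete overfitting run finishes in minutes on one CPU while exercising the
identical topology. One deviation from the full-scale protocol: the sanity
run uses a learning rate of `1e-3` and no augmentation. With 20 images in
batches of five, an epoch is only 4 gradient steps (the full-scale study had
~80), so the full-scale rate of `1e-4` leaves the run far from convergence
within the 30-epoch budget; scaling the rate to the step count is the
standard adjustment, and the run's purpose is a capacity/correctness check,
not protocol replication.

## The phantom generator

`generate_phantom()` emulates HRME imagery: nuclei are placed by a hard-core
point process (minimum separation 0.8x the mean nuclear diameter — nuclei do
not interpenetrate) at a requested density, each rendered as a bright ellipse
with Gaussian edge blur on a darker cytoplasm background, plus additive
Gaussian noise. Default morphology: normal nuclei 35 +/- 10 um^2 area,
eccentricity 0.40 +/- 0.15; abnormal 90 +/- 30 um^2, 0.75 +/- 0.10 —
consistent with the qualitative description of neoplastic nuclei as larger,
more eccentric and more variable; no quantitative distributions are
published, so these are configurable stand-ins and every test that uses them
is property-based rather than value-matched. Degradations: saturated and dim
blobs (unions of 1–4 discs), keratinized horizontal bands (which physically
remove the underlying nuclei), and whole-FOV contrast compression; degraded
pixels are marked *no visible nuclei* in the ground-truth mask.
`simulate_raters()` derives noisy rater masks by jittering region boundaries
morphologically and flipping whole regions with a configured probability.
`generate_dataset()` groups images into biopsies (1–3 images sharing a spec)
and patients, and partitions *patients* into train/validation/test by
largest-remainder rounding of the 50/20/30 fractions, so no patient spans
splits.

What the phantoms do **not** model: fiber-bundle honeycomb structure, optical
point-spread functions, spatially clustered abnormal nuclei, nucleus
intensity variation with depth, and rater biases beyond boundary jitter and
region flips. Passing tests on phantoms therefore demonstrate algorithmic
correctness and calibration mechanics, not clinical performance; the
segmentation metrics attainable on clinical image sets are not reproducible
from synthetic data and are not asserted anywhere.

## Nucleus segmentation stand-in

The density feature as deployed clinically relies on instrument-specific
nucleus segmentation whose internals are not public, so this package
implements a conventional, fully documented pipeline: white top-hat background flattening (structuring
element 3x the expected mean nuclear radius), Otsu threshold within the
analyzed region, distance-transform watershed to split touching nuclei, and
removal of components under 8 um^2 or touching the FOV border. A nucleus is
abnormal iff its area exceeds 65 um^2 **or** its eccentricity exceeds 0.65
(strict comparisons; the clinically used rule form and thresholds are not
public, so both live in `nd_config()`). Morphological primitives come from
EBImage. Matching any particular clinical per-image density is explicitly
out of scope; what is asserted is recovery of generator truth (detection
recall/precision, ranking of abnormal vs normal nuclei, density accuracy).

## Problem sizes used by tests and the acceptance script

Phantoms for module tests use 128x128 canvases at 2 um/px; the coverage
panel uses the full 960x960 geometry (generated as point processes only,
never rendered, which is what the experiment needs); the network sanity run
uses the desk-scale profile above with 50 ROI draws per radius in the
coverage experiment (the full 200 per radius is used for the ROI-count
accounting). These sizes are the package's own choices to keep a complete
run reproducible in minutes on a single core.

## Known limitations

- The interval models only binomial uncertainty in the abnormal proportion;
  nuclear-density fluctuation between the visible regions and the full FOV
  is assumed away by construction. Hypergeometric or
  finite-population-corrected intervals are a documented extension point,
  not implemented.
- Coverage calibration claims transfer to clinical images only qualitatively
  (see the coverage section).
- The pure-R network trains desk-scale models comfortably; full-scale
  (512x512, base 32) training is possible but slow and is not exercised by
  the tests.
- `detect_fov()` assumes the active area is a single bright disc; it is a
  fallback for images shipped without a sidecar mask.
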