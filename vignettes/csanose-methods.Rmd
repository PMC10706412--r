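---
title: "Methods: colorimetric sensor array analysis for oil adulteration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: colorimetric sensor array analysis for oil adulteration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csanose)
```

## The measurement principle

A colorimetric sensor array (CSA) is a 2 × 3 grid of chemo-responsive dye
spots — pH and redox indicators such as methyl violet, chlorophenol red,
Nile blue, methyl orange, alizarin and cresol red — deposited on a TLC
silica plate. Volatile organic compounds (VOCs) released by an oil sample
protonate, deprotonate or oxidize the indicators, shifting their colors.
Photographing the array before and after exposure and subtracting the two
images yields a *difference map*: a spatial fingerprint of the sample's
VOC profile. Because adulterant oils (sunflower, sesame) release different
VOC mixtures than quince seed oil, the fingerprint changes smoothly with
the blending ratio, and a classifier can grade the adulteration level.

`csanose` implements the full chain: spot segmentation, difference-map
fingerprinting, exposure-time optimization, and PCA + SVM chemometrics,
plus a synthetic array generator that stands in for laboratory images.

## Image processing

Segmentation runs on the pre-exposure photograph:

1. **Luminance.** RGB is collapsed with the conventional 4-digit BT.601
   weights `0.2989 R + 0.5870 G + 0.1140 B`. (These sum to 0.9999, so a
   uniform gray image is reproduced to within that truncation.)
2. **Otsu thresholding** over the 256-bin integer histogram; ties go to
   the smallest threshold. The foreground polarity is decided by which
   class's mean luminance lies farther from the border pixels' mean —
   the image border is reliably plate background, so this works whether
   dyes are darker or lighter than the plate.
3. **Area opening** removes 8-connected components strictly smaller
   than 1000 px (residual background speckle).
4. **Erosion** with a Euclidean disk (radius 3 px by default) trims the
   halo of mixed plate/dye pixels at each spot boundary, and **area
   closing** fills interior holes smaller than 1000 px (pixels lost to
   suboptimal thresholding). Both thresholds are configurable; the
   closing default simply mirrors the opening threshold since no
   separate value is conventional.
5. **Reading-order labeling.** Components are grouped into rows when
   the centroid-row gap exceeds half the median component height (a
   rule that is robust to slight plate rotation), rows are ordered top
   to bottom, and labels run left to right within a row.

All connectivity is 8-connected, for both foreground components and
holes, and all coordinates are 1-based `(row, col)` matrix indices.

The difference map is `|post − pre|` per pixel per channel inside the
labeled spots and zero elsewhere. The absolute value guarantees
non-negative fingerprints whether a dye darkens or lightens; it also
makes the map symmetric under swapping the two captures, which is
covered by a property test. Correspondence between captures is by label
index — the array is assumed untouched between captures — with an
optional guard that paired centroids move at most 5 px.

The fingerprint is the 18-vector of per-spot, per-channel means of the
difference map (6 spots × R, G, B), in gray levels. Features are always
computed on raw deltas; the 6-bit → 8-bit display rescale
(`round((clip(v, 3, 62) − 3) · 255/59)`, half-away-from-zero) exists
only to make difference-map figures legible.

## Exposure-time optimization

During a time-lapse exposure the fingerprint's Euclidean norm traces a
saturating curve. `steady_state_time()` makes the usual visual judgment
algorithmic: the earliest sampled time whose next `window_min = 10`
minutes stay within `epsilon = 2%` of the maximum norm. A time point is
eligible only when its full window lies inside the sampled range;
otherwise a never-flattening profile would vacuously "stabilize" at its
last sample. Between candidate conditions, `optimal_exposure()` picks
the maximal final-time norm (the curves saturate monotonically, so final
and peak norm coincide), breaking ties by earlier steady state, then by
input order.

## Chemometrics

**PCA** centers the 18 columns but does not scale them — standardization
is a separate, searched classifier hyperparameter, and applying it twice
would silently change the search space. Components are selected as the
smallest number explaining ≥ 95% of variance. A deterministic sign
convention (largest-magnitude loading entry positive) makes fits
reproducible across platforms.

**SVM.** Soft-margin SVM with one-vs-one multiclass reduction (libsvm
via e1071 stands behind this surface). Kernels: linear `u·v`,
polynomial `(1 + u·v)^d` with `d ∈ {2, 3, 4}`, gaussian
`exp(−‖u−v‖²/s²)`. Vote counting over the pairwise decision values is
done in-package so that ties break by the largest aggregate decision
value and then the lowest class index — a stated, testable rule rather
than a library internal. With standardization on, predictors are
centered/scaled by calibration-set statistics only; a zero-variance
predictor gets scale 1 instead of failing.

**Random search** draws kernel and standardization uniformly, the
polynomial order uniformly from {2, 3, 4}, and kernel scale and box
constraint log-uniformly on `[1e-3, 1e3]` — the range spans six orders
of magnitude, and a linear draw would almost never propose small
values. Each draw is scored by stratified 10-fold cross-validated
misclassification; the same fold partition (derived from the seed) is
reused across draws so configurations compete on identical splits. The
minimum-observed trace is non-increasing by construction and is
reported alongside the winner (first-found on ties).

**Outer validation** uses ten stratified Monte-Carlo 70/30 splits
(calibration size = round-half-up of `0.7 n`; 104 samples split
73/31). PCA, standardization and the SVM are all refitted on each
calibration subset — nothing from the prediction subset leaks into the
fit. Per-class allocation is proportional with largest-remainder
rounding and always keeps at least one sample of every class in
calibration; when rounding requires it, a class may be absent from a
particular prediction subset, which matches the unequal per-class
counts seen in practice. The inner 10-fold objective and the outer
70/30 repeats play different roles deliberately: the former tunes, the
latter reports.

## The synthetic array generator

No laboratory images are deposited, so `synthetic_spec()` +
`render_pair()` emulate them with known ground truth:

* **Geometry.** 480 × 640 px, spot radius 40 px (area ≈ 5000 px,
  comfortably above the 1000 px opening threshold), 2 × 3 grid at
  160 px spacing — a 2 cm plate with 5 mm spot spacing imaged at about
  80 px/cm. Spots are antialiased with a one-pixel coverage ramp; the
  ground-truth mask contains only fully covered pixels, so noise-free
  masked means equal the true shift exactly.
* **Color model.** Each pure oil has a 6 × 3 matrix of true post−pre
  shifts. A mixture with adulterant fraction *f* shifts by
  `(1−f)·Q + f·A` — a linear stand-in for VOC blending consistent with
  fingerprints varying smoothly with the volume ratio. The default
  matrices share one sign per (spot, channel), so the absolute
  fingerprints interpolate linearly and the distance from pure quince
  grows strictly with *f* (a tested invariant). The three pure-oil
  fingerprints are mutually ≥ 40 gray levels apart, and spots 1, 4, 6
  respond most to sesame, echoing which indicators discriminate that
  adulterant. Base dye colors leave enough headroom that no shift can
  clip at 0 or 255.
* **Nuisance effects.** I.i.d. Gaussian pixel noise (default SD 3 gray
  levels) independently per capture, and a per-sample linear
  illumination field of random direction with slope up to 3%, shared by
  the pre and post captures of a sample (the lighting, not the noise,
  is what persists between the two photographs). The illumination field
  is the main source of *within-class* feature scatter; pixel noise
  averages out over ~4500-pixel spots.
* **Kinetics.** Time-lapse frames scale the shift by
  `1 − exp(−t/τ)` with τ = 20 min, which places ~95% of the response at
  60 min — the steady-state exposure time used in practice. With the
  2%/10-min criterion the analytic onset is ≈ 59.8 min, so detection at
  the 60-min sample is the designed behavior, not a coincidence of
  seeds.
* **Design.** 8 samples per class × 13 classes = 104 samples (pure
  quince; 10–50% sunflower; pure sunflower; 10–50% sesame; pure
  sesame).

What the generator does *not* emulate: spatially correlated sensor
noise, color-channel crosstalk, plate texture, lens distortion,
misregistration between captures, and nonlinear (chemistry-dependent)
mixing of VOC responses. Passing tests on synthetic data therefore
demonstrate the correctness of the pipeline's computations and its
robustness to pixel noise and smooth illumination changes — not
field performance on real arrays.

A consequence of the linear mixing model is that the 13 class means
span essentially two directions in feature space, so two principal
components already carry > 99% of the variance and the 95% rule selects
2 PCs; laboratory data, with six semi-independent dyes, needs more.
The classifier layer is exercised identically either way.

## Numerical choices and degenerate inputs

* Otsu on a constant raster is an error ("degenerate histogram"), as is
  a segmentation that does not find exactly the expected spot count.
* `round_half_up()` (half away from zero) is used wherever a rounding
  convention is observable: display rescaling and calibration sizes.
  Base R's banker's rounding would map 72.8 identically but halves
  differently.
* All stochastic operations take explicit integer seeds; derived seeds
  are drawn below 2³¹. Rendering, search and evaluation are bit-for-bit
  reproducible given (spec, seed), which the tests assert.
* Problem sizes used by the default test/acceptance runs: 104-sample
  datasets at full 480 × 640 geometry for the end-to-end checks, a
  240 × 320 / radius-20 variant of the same generator for unit tests,
  50 random-search evaluations, and 91-frame time-lapses at 1-minute
  sampling over 0–90 min.

## Known limitations

* Segmentation assumes all six spots survive thresholding and cleanup
  as separate components; merged or missing spots are reported as
  errors rather than repaired.
* The polarity rule assumes the image border is background; an array
  photographed edge-to-edge would need an explicit mask.
* The SVM layer inherits libsvm's working-set behavior for extreme
  hyperparameters (e.g. C = 10³ with a near-singular kernel), where
  optimization may be slow; the search range caps both scales at 10³.
* `parse_confusion_table()` trusts row labels over a printed header —
  headers in published tables occasionally carry typos (a duplicated
  column label), and row labels are the less error-prone source.
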