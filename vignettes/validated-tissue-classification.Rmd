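---
title: "Validated tissue classification: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validated tissue classification: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

histodap implements a fully prespecified evaluation pipeline for
tissue-of-origin classification on whole-slide histology images (WSIs):
tissue detection and tile sampling, feature extraction behind a pluggable
interface, a Data Analysis Plan (DAP) built on repeated stratified
cross-validation, and slide-level vote aggregation. This vignette explains
the models and procedures, the tunable parameters and their defaults, and
the design decisions taken where more than one reasonable choice existed.

```{r setup}
library(histodap)
```

## Tissue detection and tiling

H&E-stained tissue is dark on a light scanner background, so the tissue
region of a slide thumbnail is found by a classical four-step pipeline:

1. **Grayscale conversion** with the Rec. 601 luminance weights
   (0.299, 0.587, 0.114). Idempotent on grayscale input.
2. **Otsu binarization**: pixels are binned to integer levels 0–255 and
   the threshold $t \in \{0,\dots,254\}$ maximizes the between-class
   variance of the histogram; the dark side ($\le t$) is foreground.
   Ties go to the lowest threshold so runs are bit-reproducible. A
   constant image has no threshold and is an error.
3. **Morphological refinement**: dilation by a disk structuring element
   (pixels within Euclidean distance $r$ of the center; default radius 5
   thumbnail pixels) followed by filling of all enclosed holes. The
   operation is extensive — the output mask always contains the input —
   and the hole fill is idempotent.
4. **Largest-region selection**: connected components (8-connectivity by
   default; 4 available) are compared by pixel count, ties broken by the
   component whose first pixel comes first in row-major raster order, and
   the winner's tight axis-aligned bounding box is reported.

Detection runs on a thumbnail: the `downsample` factor (default 32×)
trades precision for speed, and the resulting mask and box are mapped back
to full resolution by the stored scale factor. Coordinates throughout are
1-based inclusive `(row, col)` boxes, the native R convention.

### Tile sampling and the tissue-fraction filter

Candidate tile origins (default 512×512 px at full resolution, at most 100
tiles) are drawn uniformly at random inside the tissue bounding box. Each
candidate is re-examined by the same detection criterion and kept only if
its tissue fraction is at least `min_tissue_fraction` (default 0.85).
Sampling stops at `max_tiles` accepted tiles or after an attempt budget of
`attempt_factor * max_tiles` draws (default 50×), which bounds runtime on
slides with sparse tissue.

Whether the per-tile fraction should come from a tile-local threshold or
from the slide-level one is genuinely ambiguous. A pure tile-local Otsu is
wrong in the limit: on a tile that is *entirely* tissue, Otsu happily
splits the tissue texture itself and reports a fraction near 0.5. We
therefore use the tile-local threshold only when the tile histogram is
convincingly bimodal, as measured by Otsu's effectiveness metric
$\eta = \sigma_B^2 / \sigma_T^2 \in [0,1]$, and fall back to classifying
the tile's pixels with the slide-level threshold otherwise. The cutoff
default is $\eta \ge 0.8$: for a unimodal Gaussian-like texture the best
split yields $\eta \approx 2/\pi \approx 0.64$, while two well-separated
gray modes give $\eta > 0.85$ even when one mode holds only a few percent
of the pixels, so the two regimes are cleanly separable.

## Feature extraction

Tiles are turned into fixed-width vectors in three stages.

**Augmentation** (training-time loading only) draws independent
horizontal/vertical flips, a uniform scale from `scale_range`, and a
center or random crop. Inference is augmentation-free by default.

**Extractor.** Deep convolutional backbones plug in through the
`feature_extractor` interface (a name, a constant output width, and an
`extract` function). The package ships a deterministic, hand-computable
reference descriptor of width 38 — 16 intensity-histogram proportions, 6
gradient-magnitude statistics, 16 block means over a 4×4 grid — so every
downstream stage is testable without pretrained weights, GPUs, or
downloads. It is documented component by component so tests can recompute
it independently.

**Adapter.** Extractors emit different widths, so an affine map
normalizes the width to 1,000 (configurable). For the SVM and forest heads
the adapter is a fixed seeded random projection with
$N(0, 1/\sqrt{d_{in}})$ entries — a standard norm-preserving choice when
no gradient signal is available to train it; for the neural head the first
dense layer plays the adapter's role and is trained jointly with the rest
of the head. An identity/zero-padding variant is available for debugging
and exact-identity tests. Features serialize to CSV at 9 significant
digits (single-precision fidelity), and the writer/reader round-trips
bit-stably at that precision.

## The Data Analysis Plan

The DAP guards against selection bias by separating model selection from
model assessment:

1. **External split.** A stratified 80/20 split; each class contributes
   `round(0.2 * n_class)` samples to the external set. External rows are
   locked away and touched exactly once, at the very end; the report's
   audit block records the access count.
2. **Internal cross-validation.** The training part undergoes 5-fold CV
   repeated 10 times (50 internal validation sets), stratified the same
   way; per-fold class counts are within one sample of proportionality.
3. **Ranking and fits.** Within each of the 50 splits, features are
   ranked on the split's training part only by the one-way ANOVA F
   statistic; the classifier is fitted on the top 10%, 25%, 50% and 100%
   of the ranked features and scored on the internal validation part with
   multiclass MCC and accuracy.
4. **Aggregation.** Per-fraction means with 95% studentized bootstrap
   confidence intervals, a Borda consensus of the 50 ranked lists, and a
   Canberra stability score.
5. **Final evaluation.** The fraction with the best mean internal MCC is
   selected (ties to the smaller fraction, preferring parsimony); the head
   is refitted on the whole training part and scored once on the external
   set.

The feature list used for the final refit is the Borda consensus truncated
at the selected fraction. The consensus is computed entirely from
training-side rankings, so this choice leaks nothing; we prefer it over
re-ranking the full training set because it is the list the stability
analysis actually certifies.

Class imbalance is handled by weighting the loss with
$w_i = n_{\max} / n_i$ (largest class weight exactly 1), computed from the
training counts and applied to all three heads.

### Classifier heads

* `linear_max_margin`: linear-kernel SVM, $C = 1$, class weights.
* `randomized_tree_ensemble`: random forest, 500 trees, seeded, class
  weights.
* `feed_forward_head`: dense layers (default 1000–1000–256–$K$) with ReLU
  activations and a softmax output, trained with Adam at a fixed learning
  rate of $10^{-5}$ on the class-weighted cross-entropy, 50 epochs,
  batch size 32. All sizes and the optimization budget are configurable so
  tests can run narrow nets for a few epochs.

### Metrics

Accuracy is the confusion-matrix trace over the total. The multiclass MCC
is computed directly from the confusion matrix $C$:

$$\mathrm{MCC} = \frac{c\,s - \sum_k p_k t_k}
  {\sqrt{\left(s^2 - \sum_k p_k^2\right)\left(s^2 - \sum_k t_k^2\right)}}$$

with $c$ the trace, $s$ the total, $t_k$/$p_k$ the true/predicted
marginals. It equals the per-class indicator-covariance correlation
between truth and prediction, which is how the tests cross-check it. When
a marginal is degenerate (a zero factor under the root) the MCC is defined
as 0 — such a classifier is no better than chance, and the convention
keeps the random-labels diagnostic well-defined. The product of the two
factors is formed before the square root so that error-free and fully
misclassified matrices evaluate to exactly ±1 in floating point.

ANOVA F ties are always broken by ascending feature index; a feature with
zero within-class variance but separated means ranks first ($F = \infty$),
and a globally constant feature (the 0/0 case) ranks last — it carries no
signal.

### Confidence intervals

The bootstrap-t (studentized) interval is applied to the 50 split-level
metric values: resample, form the pivot
$(\bar x^*_b - \bar x)/\widehat{se}^*_b$ with the analytic standard error
of the mean inside each resample, and invert the pivot quantiles. Applying
it to split-level values (rather than per-sample statistics) matches the
protocol's "evaluated across all the iterations" framing; we flag this as
an interpretation since the alternative is not ruled out. Defaults:
$B = 1000$ outer resamples, analytic inner standard error, degenerate
constant input collapses to $[v, v]$ with a warning. A coverage simulation
in the test suite confirms ~95% coverage for Gaussian samples of size 50.

### Ranked-list stability

The Canberra stability of the 50 per-split rankings is the mean pairwise
Canberra distance between rank-position vectors,
$d(a,b) = \sum_i |a_i - b_i| / (a_i + b_i)$, normalized by the *exact*
expected distance between two independent uniform random permutations,
$E_n = \frac{1}{n}\sum_{s,t=1}^{n} |s-t|/(s+t)$ (positions are marginally
independent uniform across two independent permutations). 0 means
identical lists; ≈1 means as unstable as random; lower is better. Several
indicator variants exist in the literature; we expose both this complete
form and a top-$k$ variant (all ranks capped at $k+1$, with the
correspondingly capped normalizer) without claiming either is canonical,
and always report the raw mean distance alongside.

### Bias diagnostics

`random_labels` mode scrambles the training labels once, after the
external split and before the CV; the external labels are untouched. An
unbiased pipeline must then average an internal MCC near 0 — any
systematic excess means information from validation folds is leaking into
ranking or fitting. `random_ranking` mode replaces the per-split ANOVA
ranking with a fresh seeded random permutation; because informative
features are then scattered uniformly, performance should reach its
maximum only when all features are used. Both behaviours are asserted in
the test suite on planted-signal tables.

### Slide-grouped splitting

Real WSI datasets have many tiles per slide, and tiles of one slide are
correlated. The default stratification treats tiles as exchangeable
(matching per-class tile stratification protocols); setting
`group_by_slide = TRUE` in `dap_config()` assigns whole slides to one side
of the external split and to single CV folds (and, in `random_labels`
mode, permutes labels between slides rather than tiles). Grouped splitting
requires one class per slide, which the synthetic generator guarantees by
construction.

### Seeding

One master seed drives everything. Stage $i$ receives
`child_seed(seed, i)` $= (48271\,\mathrm{seed} + i) \bmod 2147483629$;
per-split fits use counters offset by the split index. Identical config
and seed reproduce the entire report bit-for-bit, and all seeding is done
without disturbing the caller's RNG state.

## Slide-level aggregation

Tile predictions are aggregated per slide by plurality vote; ties go to
the lexicographically smallest class label and are flagged rather than
hidden. `tiles_per_wsi_curve()` subsamples $n$ tiles per slide (default
$n \in \{3, 5, 7, 10\}$), aggregates, and scores slide-level MCC/ACC;
slides with fewer than $\max n$ tiles are excluded with a reported count
so every point of the curve uses the same slides. With any per-tile
accuracy above chance, majority voting amplifies accuracy and the curve is
non-decreasing in $n$ on average — both properties are exercised by the
vote simulator in the tests.

## What the synthetic fixtures do and do not emulate

The slide phantoms place dark tissue blobs (with optional carved holes)
on a light background and add band-limited texture — white noise on a
coarse grid, bilinearly upsampled — so that thresholding faces a
realistic two-mode histogram rather than a degenerate two-level image.
The exact blob geometry is recorded, giving pixel-exact ground truth for
masks, largest regions and bounding boxes.

The feature-table generator plants `n_informative` features whose class
means are drawn once per seed as `class_separation` × N(0,1) (so the
effect size is expressed in noise-s.d. units and scaling the separation
up never weakens the planted signal at a fixed seed); all other features
are unit-variance noise. Consecutive tiles are grouped into slides that
share one class.

Deliberately *not* emulated: stain variation and artefacts (pen marks,
blur, folds), spatial correlation between neighbouring tiles, correlated
or heavy-tailed feature noise, and any resemblance between the reference
descriptor and deep-network features. Passing tests therefore certify the
*protocol* — leakage-freedom, calibration of the diagnostics, correctness
of the arithmetic — not performance on real H&E images.

## Problem sizes

The test suite and the endpoint script run at desk scale, chosen so the
full suite completes in minutes on one core: planted tables of 500
samples × 100 (or 1,000) features over 5 balanced classes for the DAP
endpoints, 100,000 draws for the chance-level MCC simulation, 1,000
repetitions of size-50 samples for bootstrap coverage, and phantoms of a
few hundred pixels. All of these scale up through the same spec objects.

## Known limitations

* Tissue detection assumes dark-on-light contrast; it would need
  inversion for fluorescence imagery.
* The attempt-budget rule means sparse-tissue slides can legitimately
  return fewer than `max_tiles` tiles; callers should consult the
  manifest rather than assume the maximum.
* The feed-forward head is plain R matrix arithmetic: correct and
  reproducible, but not fast at the paper-scale widths; at desk scale use
  narrow hidden layers.
* MCC's zero-denominator convention (return 0) is one of several in use;
  comparisons with software using NaN conventions should normalize first.
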