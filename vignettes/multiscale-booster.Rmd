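---
title: "Attention-guided multi-scale boosting: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-guided multi-scale boosting: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roiboost)
```

## The problem and the method

Dermoscopy classifiers must separate lesion classes whose diagnostic signal
is concentrated in a compact image region — fine pigment texture, border
irregularity — while most of the image is uninformative skin. `roiboost`
implements a pipeline built on that premise:

1. **Saliency from self-attention.** A vision transformer's attention
   weights for one head are `softmax(Q Kᵀ / sqrt(D/H))`, a row-stochastic
   token-to-token relevance matrix (`scaled_dot_attention()`). Per layer the
   head matrices are summed, and the per-layer sums are averaged across
   layers; the class-token row, reshaped to the patch grid and bilinearly
   upsampled, is the saliency map (`aggregate_attention()`,
   `upsample_to_image()`).
2. **ROI extraction.** The map is thresholded at its own arithmetic mean
   (pixels strictly above the mean become 1), the largest connected
   component of the binary mask is kept, and the minimal enclosing rectangle
   of that component is cropped from the original image (`extract_roi()`).
3. **Dual-branch fusion.** The full image (global context) and the ROI crop
   (fine detail) pass through two parallel identical feature extractors;
   the branch features are concatenated at a flatten layer and classified by
   an MLP ending in softmax (`build_dual_branch()`).
4. **Majority voting.** Several trained classifiers are combined per
   instance by the statistical mode of their predicted labels
   (`majority_vote()`), and evaluated with per-class precision, recall, F1
   and one-vs-rest ROC-AUC (`classification_report()`).

## Attention aggregation: two readings, one default

Summing heads within a layer is unambiguous; how to combine layers is not
uniquely determined by the head-sum formula alone. The package exposes both
natural readings and defaults to the more literal one:

* `sum_heads_mean_layers` (default): sum the `H` head matrices per layer,
  take the arithmetic mean of the per-layer sums, read off the class-token
  row. This is the most direct composition of "sum over heads" with
  "aggregate across layers".
* `rollout`: average heads per layer, add the identity for the residual
  path, renormalize rows, and multiply the layer matrices in order. This is
  the standard relevance-propagation alternative; it reduces to the
  normalized single-layer attention when `L = 1` (a property the tests
  check).

The class-token row is used as the map source because that token is the
designated aggregator for classification; a mean over all token rows is
available (`source_token = "mean_rows"`). The aggregated map is thresholded
on raw values without per-image normalization: the mean-threshold rule is
invariant to positive rescaling, so normalization would change nothing.

## ROI numerical choices

* **Strict threshold.** A pixel is kept iff its value is *strictly* greater
  than the map mean. A constant map therefore yields an empty mask, which is
  handled by an explicit fallback (use the full image, flag
  `fallback = TRUE`) rather than by weakening the rule to `>=`.
* **Connectivity.** Diagonally touching high-attention patches plausibly
  form one region, so 8-connectivity is the default; 4-connectivity is
  selectable.
* **Ties.** Equal-size components are broken toward the component containing
  the lexicographically smallest `(row, col)` pixel — arbitrary, but
  deterministic and auditable.
* **Degenerate boxes.** Boxes smaller than `min_box_fraction` (default 1%)
  of the image area trigger the same full-image fallback; a sliver crop
  upsampled to the backbone input would be pure interpolation noise.
* **Conventions.** All coordinates are 0-based, half-open, row-major.
  Bilinear resampling uses half-pixel centers, so output values are convex
  combinations of inputs and global bounds are preserved.

## The classifier at desk scale

The package targets CPU-scale experiments, so the "backbone" is a frozen
spectral feature extractor rather than a deep network: images are resized to
`input_size` (default 48 px), converted to luminance, and summarized by the
radial power spectrum of the 2-D FFT (12 log band energies over concentric
frequency annuli) plus per-channel mean and standard deviation. Radial
pooling gives orientation invariance; band position encodes texture
frequency — exactly the kind of fine-grained signal an ROI crop amplifies.
Each branch adds a trainable linear adapter with ReLU; adapter outputs are
concatenated and classified by a one-hidden-layer MLP with softmax. The two
branches are architecturally identical; their adapters are independent by
default (`weight_sharing = "independent"`), with a tied variant available.

Training follows the conventional protocol for this task family: Adam with
an initial learning rate annealed by a cosine schedule, categorical
cross-entropy, a stratified 10% validation split, and early stopping on
validation accuracy with patience 10, returning the best-validation
checkpoint. The `train_config()` defaults (200 epochs, learning rate 1e-4,
batch size 8) mirror that protocol for full-size backbones; the tiny
spectral model is much smaller, so the examples, tests and acceptance runs
use 20 epochs at learning rate 0.01 — the setting at which the trivially
separable two-class sanity problem reaches training accuracy 1.0.
Determinism is promised per fixed device: identical seeds give identical
histories and weights on the same machine.

## What the synthetic generator emulates — and what it does not

`generate_record()` renders an elliptical blob (~15% of image area,
eccentricity 1.2–2.0, random position/orientation) on a skin-toned
background, darkened by a factor drawn identically across classes, with
additive Gaussian pixel noise (sd 0.05). The class signal is **only** the
spatial frequency of a sinusoidal texture confined to the blob
(0.06/0.12/0.18 cycles per pixel for the 3-class default, evenly spaced
below the Nyquist limit of the 48-px backbone input; amplitude 0.15, chosen
so the in-blob texture variance exceeds the background noise variance about
five-fold). Because tone carries no class information, global color
statistics cannot solve the task, which makes the dual-branch advantage
property falsifiable rather than vacuous.

The generator emulates the structural premise of the method — discriminative
signal concentrated in a compact region with known ground truth — but not
real dermoscopy: no hair or ruler artifacts, no multi-modal lesion shapes,
no inter-class tone differences, no label noise. Passing tests therefore
demonstrate the pipeline's correctness and its behavior under the planted
assumption, not clinical performance. On these clean conditions the
frequency classes are in fact easy: both single- and dual-branch models
typically reach perfect test accuracy, and the booster ablation shows ties
(dual ≥ single) rather than strict gains.

The oracle saliency map (`oracle_saliency()`) is the raw blob indicator plus
low-amplitude uniform background noise. Smoothing defaults to 0 so that
mean-thresholding recovers the blob support exactly and box recovery is
pixel-exact; a Gaussian smoothing parameter is available to emulate blurrier
attention maps.

## Data preparation rules

* **Lesion-group deduplication** keeps one row per `group_id` — the
  lexicographically smallest `image_id`, a deterministic stand-in for an
  unspecified "representative" — and runs *before* splitting, so one lesion
  can never leak across the train/test boundary.
* **Stratified splitting** draws `round(test_fraction × class count)` test
  rows per class. Round-half-up is used (not banker's rounding) so that
  counts are stable and predictable.
* **Rebalancing** oversamples each minority class to exactly the target via
  augmented copies of uniformly re-sampled originals of the same class;
  augmented images are generated once and fixed, not regenerated per epoch.
* **Augmentation** combines geometric transforms (rotation up to 180°,
  shifts and zoom up to 10%, random flips) with photometric jitter
  (saturation/contrast/brightness, ±10% — matching the spirit of the
  geometric ranges). Rotations and shifts use reflect padding: constant
  black fill would plant spurious dark corners that a saliency method could
  latch onto. Flip options are probabilities (a deterministic flip is
  probability 1).

## Voting and metrics conventions

The mode of an even panel can tie. The default tie policy uses the highest
mean predicted probability among tied classes when probabilities are
available and falls back to the lowest class index otherwise; both policies
are explicit options, and requesting the probability policy without
probabilities is a configuration error. Precision or recall with a zero
denominator is reported as 0 with a warning. ROC-AUC is one-vs-rest with
trapezoidal integration, reported per class; macro/weighted ROC-AUC rows are
not emitted.

## Problem sizes

The test-suite and acceptance workloads are sized for a single CPU: the
`tiny` preset (15 images) drives the end-to-end smoke run; the `smoke`
preset (300 images, 3 classes) drives the booster ablation (three seeds,
20 epochs, 45 test images per seed) and the three-member ensemble; oracle
cross-checks use 100–1,000 random instances each. A full run of the
acceptance script takes well under a minute.

## Known limitations

* The spectral backbone is not a learned deep feature extractor; it is the
  right size for CPU experiments and for texture-frequency signals, but it
  will not capture the shape/border semantics a pretrained ViT or CNN would.
* Saliency for the end-to-end pipeline comes from the generator's oracle (or
  a simple tone/texture-contrast map); plugging in a real pretrained
  transformer requires exporting its attention stack into
  `attention_stack()`.
* Single-region extraction only: lesions with two disjoint salient areas
  lose the smaller one by construction.
* Mean thresholding is global; percentile or morphology-adaptive thresholds
  are deliberately out of scope.
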