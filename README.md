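# roiboost

Attention-guided region-of-interest boosting for image classification, built
for dermoscopy-style problems where the diagnostic signal lives in a compact
region of an otherwise uninformative image.

The toolkit implements four pieces and wires them into one pipeline:

1. **Attention saliency.** Per-head attention weights
   `AW = softmax(Q Kᵀ / √(D/H))` are summed over heads within each layer,
   averaged across layers (attention rollout available as an alternative),
   and the class-token row is reshaped to the patch grid and bilinearly
   upsampled into a pixel-level saliency map.
2. **ROI extraction.** The saliency map is binarized at its arithmetic mean,
   the largest connected above-threshold component is isolated, and its
   minimal enclosing rectangle is cropped from the original image (with a
   full-image fallback for degenerate masks).
3. **Multi-scale dual-branch classifier.** The full image and the ROI crop
   pass through two parallel identical feature extractors; features are
   concatenated at a flatten layer and classified by an MLP with softmax.
   Training uses Adam with cosine annealing, categorical cross-entropy, a
   stratified validation split and early stopping on validation accuracy.
4. **Majority-voting ensemble.** `Y = mode(y₁, …, y_k)` over k trained
   models, with explicit tie policies, plus the full evaluation suite:
   per-class precision `TP/(TP+FP)`, recall `TP/(TP+FN)`,
   `F1 = 2PR/(P+R)`, one-vs-rest ROC-AUC, accuracy, macro/weighted
   averages and the confusion matrix.

Data preparation covers lesion-group deduplication (one image per lesion id,
before splitting, so no lesion spans train and test), stratified train/test
splitting, and class rebalancing by augmentation-based oversampling
(rotation up to 180°, 10% shifts/zoom, flips, saturation/contrast/brightness
jitter, reflect padding).

A synthetic generator produces dermoscopy-like images — a textured
elliptical blob on a skin-toned background — whose class signal is purely
the spatial frequency of the blob texture, with ground-truth masks and
boxes, so the whole pipeline is testable offline.

## Worked example

Train three dual-branch members on the 300-image synthetic preset and
combine them by majority vote:

```r
library(roiboost)

ds   <- synth_preset("smoke", seed = 1)                 # 3 classes x 100 images
sp   <- stratified_split(ds$manifest, test_fraction = 0.15, seed = 1)
spec <- backbone_spec()                                 # frozen spectral backbone
prov <- make_oracle_roi_provider(ds)                    # ground-truth saliency -> crops
cfg  <- train_config(epochs = 20, learning_rate = 0.01, seed = 1)

members <- lapply(1:3, function(j)
  train(build_dual_branch(spec, num_classes = 3, init_seed = j),
        sp$train, cfg, images = ds$images, roi_provider = prov))

res <- ensemble_predict(members, sp$test, images = ds$images, roi_provider = prov)
print(res$report)
```

```
class         precision     recall         f1    roc_auc  support
C1               1.0000     1.0000     1.0000     1.0000       15
C2               1.0000     1.0000     1.0000     1.0000       15
C3               1.0000     1.0000     1.0000     1.0000       15
accuracy         1.0000  (n = 45)
macro avg        1.0000     1.0000     1.0000
weighted avg     1.0000     1.0000     1.0000
```

Each row is one lesion class; `support` counts test images of that class,
and the ensemble classifies all 45 held-out images correctly — the
synthetic frequency classes are clean and well separated, so perfect
accuracy is the expected outcome at these settings. ROI extraction itself is
pixel-exact on this data:

```r
rec <- generate_record(synth_params(), label = 2, seed = 42)
roi <- extract_roi(rec$image, oracle_saliency(rec, synth_params(), seed = 7))
unlist(rec$truth_box)   # 24 31 56 88
unlist(roi$box)         # 24 31 56 88
```

The end-to-end pipeline (synth → prepare → extract-roi → train → predict →
ensemble → report) runs from a single YAML config:

```r
run_pipeline(list(output_dir = "run1", seed = 3))
```

or from the shell via the thin wrapper `inst/cli/roiboost.R`:

```sh
Rscript inst/cli/roiboost.R run --config cfg.yaml --seed 3
```

Every stage writes its artifacts plus a provenance record (config hash,
seed, timestamp) and is skipped on re-run with an identical config.

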