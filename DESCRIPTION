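Package: roiboost
Title: Attention-Guided Region-of-Interest Boosting for Dermoscopy Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for attention-guided multi-scale image classification:
    derives saliency maps from transformer self-attention weights, extracts the
    largest connected high-attention region and crops its minimal enclosing
    rectangle, classifies with a dual-branch (global + region-of-interest)
    model whose features are fused at a flatten layer, and combines several
    classifiers by majority vote. Includes manifest-level data preparation
    (lesion-group deduplication, stratified splitting, augmentation-based class
    rebalancing), a full classification report (per-class precision, recall,
    F1, one-vs-rest ROC-AUC, confusion matrix), and a synthetic dermoscopy-like
    image generator with known ground-truth regions for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC
Config/testthat/edition: 3
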