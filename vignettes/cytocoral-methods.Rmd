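---
title: "cytocoral: models, synthetic data and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cytocoral: models, synthetic data and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Liquid-based cervical cytology slides (SurePath, ThinPrep and related
preparations) are screened for precancerous change and classified under the
Bethesda system; this package works with the four categories NILM, LSIL,
HSIL and SCC, in that severity order. Two practical obstacles dominate
automated multi-cell image classification in this setting: public datasets
are small and class-imbalanced, and models trained on one preparation
protocol degrade on slides prepared with another, because staining, contrast
and cell density differ systematically between protocols.

`cytocoral` packages the complete workflow around these two obstacles:
duplicate-free augmentation and class balancing, stratified 65:15:20
splitting, compact convolutional classifiers with exact parameter
accounting, an autoencoder-compressed classifier, majority-vote ensembling,
CORAL (correlation alignment) unsupervised domain adaptation, and a full
evaluation suite. Because the clinical images are not redistributable, the
package includes a synthetic image simulator that reproduces the *structure*
of the problem — class-dependent nuclear morphology plus a controllable
cross-preparation appearance shift — so that every component is exercised
and tested end to end on data generated in code.

## Models

### Layer primitives

All network primitives are implemented in vectorized base R and tested
against naive loop oracles:

* **Convolution** computes each output map as
  `A_j = f(sum_i I_i * K_{i,j} + B_j)`, where `*` is cross-correlation (the
  deep-learning convention — no kernel flip), one `k x k` kernel per
  (input, output) channel pair and one bias per output map. Internally an
  im2col gather turns convolution into a single BLAS matrix product.
* **ReLU** is `f(x) = max(0, x)`; the final classifier layer is linear
  (scores), and the autoencoder output is sigmoid so reconstructions live in
  `[0, 1]`.
* **Max pooling** takes the maximum over disjoint 2x2 blocks, halving each
  spatial dimension; odd trailing rows/columns are dropped (floor
  division). In backpropagation, ties route the gradient to the first block
  element in a fixed scan order, making training deterministic.
* Training uses Adam with categorical cross-entropy (classifiers) or mean
  squared error (autoencoder). The optimizer is Adam everywhere; the source
  protocol states Adam explicitly only for transfer fine-tuning, and
  reusing it for the compact models is the minimal assumption.

### Reference architectures and parameter budgets

The published architecture figures leave channel widths partially
unspecified, but the parameter totals are printed exactly: 60,772 for the
compact CNN, 20,355 for the autoencoder, 10,292 for the downstream
classifier (30,647 for the AE-CNN pair). The package therefore pins
reference configurations found by `solve_cnn_widths()`, a brute-force
search over channel widths under the stated structural constraints
(alternating conv/pool blocks; dense-64 then dense-4 head for the CNN;
mirrored encoder/decoder; 20% dropout in the AE-CNN head), such that the
closed-form counts hit the budgets exactly:

* `cnn_reference_spec()` — 64x64 RGB, conv widths 40, 48, 40, 40 (3x3,
  valid) each followed by 2x2 pooling, flatten (160), dense-64, dense-4:
  exactly 60,772 parameters.
* `ae_reference_spec()` — 32x32 RGB, mirrored conv stack
  3 → 5 → 30 → 32 → 30 → 5 → 3 with three poolings/upsamplings: exactly
  20,355 parameters; the 4x4x32 bottleneck (512 values, a 6x compression)
  is the representation handed to the classifier.
* `ae_cnn_classifier_spec()` — conv-24, conv-12 (each pooled), dense-44,
  dropout 0.20, dense-4: exactly 10,292 parameters. No width assignment
  with a dense-64 head meets this budget under the searched structural
  space, so the head uses dense-44; the dense-64-then-dense-4 pattern is a
  constraint on the *main* CNN only.

These budgets imply the headline size reductions relative to the mean of
the five transfer backbones (27,140,781.4 parameters):
`transfer_reduction_pct(60772)` = 99.78% and
`transfer_reduction_pct(30647)` = 99.89%. The abstract-level figure of
"99.80% smaller" circulating for the AE-CNN is inconsistent with the
printed per-model counts; the 99.89% figure is the arithmetically
consistent one and is what the package reproduces.

Training presets (`training_config()`): transfer = 25 epochs, learning rate
0.001, batch 16; CNN = 230 epochs at 0.0005; AE = 100 epochs at 0.00005;
AE-CNN classifier = 350 epochs at 0.00005. Tests and examples use far
fewer epochs at smaller resolutions purely for runtime; the presets encode
the published protocol.

### Transfer heads

Pretrained ImageNet backbones are out of scope (no network access, no
bundled weights). `stub_backbone()` provides a small random-weight model
with the same *interface* — a feature layer followed by a final dense
layer — and `adapt_transfer_head()` performs the protocol's head surgery:
the final fully-connected layer is replaced by a fresh 4-output dense
layer. `head_only` (default) freezes everything else, because the protocol
describes re-training the replaced layer; `full` fine-tunes end to end,
since "continuing backpropagation" can be read either way. Real backbones
are pluggable through the same contract.

### Majority voting

`majority_vote()` implements plurality voting over one-hot classifier
votes: the winning class maximizes the column sum of the vote indicator
matrix. The published index notation for this rule swaps the roles of the
number-of-classifiers and number-of-classes symbols between prose and
formula; standard plurality voting is what is described and what is
implemented. Tie-breaking is not specified at all in the source protocol,
so the package uses a deterministic documented rule: among tied classes,
highest summed softmax confidence wins; if confidences are unavailable or
equal, the lowest class index in severity order wins (equivalent to
preferring the less severe call, and reproducible).

### CORAL domain adaptation

CORAL aligns second-order statistics of source and target features. For an
`n x d` activation batch `D`, the batch covariance is

    C = (D'D - (1/n) (1'D)'(1'D)) / (n - 1)

and the CORAL loss between source and target batches is
`||C_S - C_T||_F^2 / (4 d^2)`, combined with the classification loss as
`l = l_CLASS + lambda * l_CORAL`. `adapt_train()` runs the two-stream
protocol: each step draws one labelled source batch and one unlabelled
target batch (the target loader cycles when shorter — unequal stream sizes
are fine because the covariances normalize independently), computes the
classification loss on the source stream only and the CORAL loss on both
streams' adapted-layer activations, and backpropagates the joint loss
through the shared weights. Target labels are never read.

Design choices where the protocol is open:

* **Adapted layer**: the final dense layer's pre-softmax activations
  (d = 4), the usual Deep CORAL placement.
* **lambda**: unreported per model in the source material. The default grid
  is {0.1, 0.5, 1, 5, 10}; `tune_lambda()` selects by source-validation
  accuracy subject to the target features remaining non-degenerate
  (finite, non-constant). Tuning never sees target labels.
* **Degenerate batches**: a stream batch with fewer than 2 examples skips
  the CORAL term for that step (its covariance is undefined).
* **Reduction**: with `lambda = 0` the loop skips the target stream
  entirely and consumes the identical RNG sequence as plain training, so
  plain training is reproduced bit for bit — this is tested.
* **Warm start**: the recommended (and tested) adaptation workflow first
  trains the classifier on source data alone and then *continues* training
  with the joint loss. This mirrors both the usual Deep CORAL practice of
  starting from a pretrained network and the evaluation design the package
  emulates, in which the same source-trained models are assessed before
  and after adding adaptation to the workflow. In our synthetic world this
  choice matters: joint training from scratch lets the covariance penalty
  act on meaningless random features and measurably hurts target accuracy,
  while warm-started adaptation improves it across the lambda grid. The
  comparison baseline in tests continues training identically with
  `lambda = 0`, so the measured difference isolates the CORAL term.

## The synthetic data generator

`synth_cell_image()` renders multi-cell microscopy-style images: a pale
textured background and 6-12 cells, each a cytoplasm ellipse with a darker
nucleus. The class signal mirrors what matters diagnostically — nuclear
size relative to the cell, boundary irregularity and chromatin darkness all
increase with severity:

| class | nuclear area fraction (mean) | irregularity | clustering |
|-------|------------------------------|--------------|------------|
| NILM  | 0.10                         | 0.04         | 0.10       |
| LSIL  | 0.20                         | 0.12         | 0.20       |
| HSIL  | 0.32                         | 0.25         | 0.35       |
| SCC   | 0.45                         | 0.40         | 0.50       |

The per-class standard deviation of the area fraction is 0.03, chosen once
so that neighbouring classes overlap (the task is learnable but not
trivial) while NILM and SCC are essentially separable by a single
threshold — the generator's ground-truth masks let tests verify both. The
default resolution is 96x96 (configurable); the clinical originals are
2048x1536, far beyond desk-scale training, and most tests run at 16-32
pixels.

The cross-preparation shift (`preparation_style("target")`) emulates a
different staining/preparation protocol: stain hue rotated +20 degrees,
contrast x1.3 about mid-grey, cell density x0.7, and doubled background
noise. Geometry is drawn from per-cell substreams of the seed, so reducing
density truncates the cell list without altering the shared cells — the
same seed yields the same geometry across domains, with only appearance
changed. The shift was fixed a priori so that raw-pixel covariances differ
measurably between domains (tested via `coral_loss()` on pooled pixel
features) and unadapted classifiers degrade directionally.

What the generator does **not** model: real chromatin texture,
overlapping translucent cytoplasm, mucus/debris, uneven illumination,
magnification variation, or the segmentation step by which clinical images
were cropped. A green test on synthetic data therefore establishes that
the *algorithms* behave as specified — not that any accuracy number
transfers to clinical slides.

## Data protocol

* **Balancing** (`balance_classes()`): minority classes are augmented up to
  the majority size by rotation/flip duplicates. Rotations are integer
  degrees in ±25 by default (the protocol names "randomized rotation" with
  a stated quality concern about excessive rotation; 25 is conservative and
  the cap is 45). Discretizing rotations makes the duplicate-avoidance
  budget countable: each source image admits
  `(2*25+1) * 4 - 1 = 203` distinct non-identity transforms, and the
  sampler rejects repeats per source image, so requesting more copies than
  the budget raises a capacity error. Rotation fills borders by reflection,
  avoiding black corners that a classifier could exploit as a shortcut.
  Applied to the published class counts 613/113/163/74 this yields
  613 per class, 2452 total.
* **Splitting** (`stratified_split()`): per class of size m,
  `round(0.20 m)` test and `round(0.15 m)` validation images
  (half-away-from-zero), train takes the remainder: for 4x613 balanced
  classes that is 123/92/398 per class and a 492-image test partition —
  the unique simple rounding rule consistent with the published test-set
  size (plain truncation would give 490).
* **Model selection**: weights from the epoch with the best validation
  accuracy (the protocol reports validation curves but no selection rule).
  Epoch-level training metrics are running averages over batches, the
  convention of mainstream frameworks.

## Numerical choices

* He-normal weight initialization; single-threaded BLAS assumed for exact
  reproducibility; every stochastic step (initialization, shuffling,
  dropout, augmentation sampling) draws from a stream seeded by the
  user-supplied seed, and library calls restore the caller's RNG state.
* Per-image seeds are derived from the master seed by integer hashing, so
  datasets are reproducible element-wise regardless of generation order.
* Images are resized with bilinear interpolation when a model's input
  resolution differs from the data (the source protocol never states a
  resize; synthetic data is generated at the requested resolution so this
  is usually the identity).
* AUC uses average ranks, i.e. tied score pairs earn 0.5; metric averaging
  is support-weighted by default (macro variants are also returned), and
  multiclass FPR/FNR are macro-averaged one-vs-rest rates — the published
  tables print single FPR/FNR values without defining them. Consistency
  summaries use the sample (n-1) standard deviation.
* Reports with zero-support classes warn and report 0 rather than NaN.

## Known limitations

* The synthetic world is far easier and smaller than clinical data; the
  published accuracy tables are not reproducible without the clinical
  datasets and pretrained backbones, and the package does not attempt
  them. Acceptance is structural (exact parameter budgets, protocol
  counts) and property-based (oracle equivalences, directional adaptation
  behaviour).
* CORAL aligns covariances only; a shift that mostly translates the
  feature means is invisible to it. On the synthetic shift its benefit is
  directional and modest, consistent with its role as a regularizer
  rather than a fix-all.
* Pure-R training is CPU-bound; the reference 230/350-epoch presets are
  impractical at full resolution on a laptop and are provided as protocol
  documentation, with tests running scaled-down configurations.
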