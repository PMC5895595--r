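---
title: "Patch-based convolutional diagnosis of facial acne: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patch-based convolutional diagnosis of facial acne: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Clinical assessment of acne vulgaris asks two questions about a face
photograph: *where is the skin*, and *what lesions does it carry, in what
proportions*. `acnescan` answers both with a two-stage, patch-based
pipeline:

1. A 500×500 face image is tiled by a non-overlapping sliding window into
   100 patches of 50×50 pixels — the atomic classification unit.
2. A **binary skin/non-skin classifier** scores every tile; tiles below the
   decision threshold are masked out (blacked) as hair, eyes, background.
3. A **seven-class classifier** labels each remaining skin tile as papule
   (c0), cyst (c1), blackhead (c2), normal skin (c3), pustule (c4),
   whitehead (c5) or nodule (c6).
4. The per-tile decisions are aggregated: component $c$ of the report is
   the fraction of skin tiles whose argmax class is $c$. A symptom set is
   derived from these proportions.

Both classifiers are convolutional networks over raw RGB patches. Two
architectures are provided:

* `build_small_cnn()` — a self-contained CNN: Conv64, Conv64, maxpool,
  Conv64, maxpool, dropout, flatten, Dense-128, dropout, Dense-$k$ with a
  softmax output. With 3×3 same-padded convolutions and ceil-mode 2×2
  pooling, a 50×50 input collapses 50 → 25 → 13, so the flatten width is
  exactly $13^2 \times 64 = 10816$. That printed width is what pins the
  pooling geometry; no other conventional choice reproduces it.
* `build_extractor("vgg16_headless")` — the 13-layer VGG16 body without
  its classification head. Floor-mode pooling takes a 50×50 input through
  spatial sizes 25, 12, 6, 3, 1, ending in a 1×1×512 map: the
  512-dimensional feature vector consumed by `build_head()`
  (Flatten-512 → Dense-256/ReLU → Dropout → Dense-$k$ → softmax).

The two pooling-rounding modes differ on purpose: each is forced by the
architecture's printed widths (10816 and 512 respectively).

## Training protocol

`train_config()` defaults encode the reference protocol: Adam with learning
rate 0.001, $\beta_1 = 0.9$, $\beta_2 = 0.999$, batch size 64, 50 epochs,
seed 1337. The loss is binary cross entropy
$L = -t\log p - (1-t)\log(1-p)$ for the two-class task and categorical
cross entropy $L = -\sum_i t_i \log y_i$ for the seven-class task, natural
logs, probabilities clipped at $10^{-7}$. After every epoch the model is
scored on the validation split; the snapshot with the highest validation
accuracy is kept, ties resolved to the earliest epoch (the simplest reading
of "choose the best model on the validation set"). Adam's $\epsilon$ is
$10^{-7}$, the default of the framework family whose other constants the
protocol matches.

Data are split 80/10/10 (train/validation/test), stratified by class with
largest-remainder rounding, so a 6000-patch class yields exactly
4800/600/600. Preprocessing is per-classifier: the binary task rescales
intensities to 0–1 (divide by 255); the seven-class task standardizes all
pixels by a single global mean and standard deviation computed on the
training split (one scalar each, not per-channel, matching how the
reference constants 183.643/38.210 are quoted).

When a classifier has a frozen extractor, `train_classifier()` computes the
features of the train and validation splits once and trains only the dense
head — the transfer-learning fast path. `fine_tune()` unfreezes the last
$n$ convolution layers and trains them jointly with the head using plain
SGD (momentum 0, learning rate restricted to the quoted 0.001–0.01 range);
activations below the unfreezing point are precomputed, and `n = 0` leaves
the extractor byte-identical.

## Augmentation

Patch sets are enlarged by random affine transforms: rotation, shift,
shear, zoom and horizontal flip. The elementary 3×3 homogeneous matrices
are anchored at the image center $((h+1)/2, (w+1)/2)$, which is a fixed
point of rotation, shear and zoom for every parameter value. Two of the
printed shear/zoom offset entries in the source material are not
center-preserving (one references a zoom symbol inside the shear matrix);
we treat both as typographical slips and construct the offsets from the
fixed-point condition, consistent with how the rotation matrix is built.
This is a judgment call, recorded here, not a claim about the authors'
exact pixels.

Parameter ranges are not specified upstream, so the defaults are common
augmentation practice and fully configurable: rotation ±40°, shift ±5 px,
shear ±0.2 rad, zoom 0.8–1.2, flip probability 0.5. One composed matrix
(rotation · shift · shear · zoom, a fixed documented order; the upstream
order is unstated) is applied per draw by inverse-mapped resampling,
bilinear interpolation, edge-replicate fill. `augment_to_target()` treats
augmentation as producing a fixed enlarged data set (the reading implied by
the quoted per-class counts), keeps the originals untouched, and pads each
class round-robin.

## Evaluation

`roc_curve()` builds the empirical ROC over the distinct observed scores
(descending, with an infinite sentinel), predicting positive at
score ≥ threshold; `roc_auc()` integrates it by trapezoid, which equals the
tie-corrected Mann–Whitney pair count — a property the tests verify against
an exhaustive pair-counting oracle and against an independent ROC library.
`youden_best()` maximizes $J = \mathrm{TPR} - \mathrm{FPR}$; ties are
resolved toward the *smallest* maximizing threshold, favoring sensitivity
(no upstream tie rule is stated). `threshold_metrics()` reports ACC/SEN/SPE
at a threshold, and `normalize_rows()` turns confusion counts into
per-class recall. Multiclass ROC extensions are deliberately out of scope;
the seven-class task is evaluated by its normalized confusion matrix.

## The symptom rule

`determine_symptoms()` converts a proportion vector into a symptom set:
ignore normal skin (c3), keep classes at or above a threshold of 0.10, and
cap the set at the 3 largest (boundary ties to the lower class index). The
threshold and cap are reconstructed, not quoted: across the six worked
probability→class examples the rule must include a 0.11 (forcing
threshold ≤ 0.11), exclude a 0.07 (forcing threshold > 0.07), and drop a
qualifying 0.11 in a row that already has three larger entries (forcing the
cap). Threshold 0.10 with cap 3 is the unique simple rule consistent with
all six rows; both are configurable arguments.

Aggregation uses argmax fractions rather than mean softmax: "statistics of
all classification results" reads as counting per-tile decisions, and
two-decimal reports over ~100 tiles are consistent with fractions. This
choice is open upstream and is recorded here.

## Synthetic data: what it emulates and what it does not

Clinical acne photographs are private, so the package generates its own
fixtures. Recipes are deliberately separable by low-order color/shape
statistics so that small CPU-trained networks can learn them:

* normal skin (c3): beige base, RGB ≈ (200, 160, 140), per-pixel noise
  sd 10;
* non-skin: dark high-frequency hair stripes (all channels < 80) or a
  saturated uniform background, 50/50;
* lesions: red discs of radius 5–8 (papule), dark-red discs of radius
  15–20 (cyst), 1–3 dark dots of radius 2–3 (blackhead), a red disc with a
  white center (pustule), a small white dot (whitehead), and a large
  low-contrast dark-red region covering over 40% of the patch (nodule);
* the binary task's skin class mixes plain and lesioned skin 50/50,
  because diseased skin is part of that class's definition — a detector
  trained only on clear skin would mask lesion tiles out of the face.

Faces are assembled from a 10×10 grid of such patches with per-tile seeds
`seed + row*10 + col`, so fixtures are reproducible tile by tile and carry
exact ground truth.

What passing tests on these fixtures shows: the pipeline's plumbing,
training loop, threshold selection and aggregation behave correctly, and
the architectures can learn color/shape-separable classes end to end. What
it does not show: performance on real clinical images, where lesions vary
continuously, lighting and skin tone shift, and class boundaries blur.
Numbers obtained on synthetic fixtures are not comparable to clinically
reported accuracies.

## Desk-scale study conditions

The self-tests train at desk scale on one CPU: 200 patches per class. The
binary classifier is the small CNN trained for 20 epochs (seed 1337); it
reaches held-out AUC ≥ 0.95 comfortably. The seven-class classifier is the
small CNN with a 7-way output trained end to end for 12 epochs on
standardized pixels (it converges by roughly epoch 10 on these fixtures).
The transfer-learning route — frozen VGG16 features plus a trained head —
is implemented and unit-tested, but with *randomly initialized* VGG16
weights (the pre-trained ImageNet checkpoint is an optional asset the test
suite never requires) its frozen features under-represent small dark dots:
measured min per-class recall ≈ 0.65, with blackhead as the weakest class,
versus ≥ 0.9 for the end-to-end small CNN. Plain-SGD fine-tuning from a
random initialization is unstable and does not rescue it. The end-to-end
small CNN is therefore the package's default seven-class route at desk
scale; attach real pre-trained weights via `load_weights()` to use the
transfer route as intended.

The binary decision threshold defaults to the Youden optimum of the
validation ROC (`calibrate_threshold()`), mirroring how best thresholds
are reported per class; a fixed 0.5 can be passed instead.

## Numerical choices and degenerate inputs

* Probabilities are clipped at $10^{-7}$ before logarithms.
* Convolution kernels initialize He-uniform (variance-preserving for deep
  ReLU stacks, which matters when the VGG16 body runs with random
  weights); dense layers Glorot-uniform; biases zero. Dropout rate 0.5
  everywhere (the cited default), inverted-dropout scaling.
* Resampled pixels are clipped to [0, 255] and rounded; coordinates are
  (row, col) with 1-based pixel centers.
* Images whose dimensions are not multiples of 50 are padded bottom/right
  with black; padded tiles are forced non-skin and a warning is raised.
* A face with zero detected skin tiles yields a flagged empty report
  (proportions undefined) rather than an error.
* Argmax ties in classification resolve to the lower class index.
* All seeded entry points restore the caller's RNG state.

## Known limitations

* No lesion localization or counting within a tile, no severity grading,
  no overlapping-stride tiling: one label per 50×50 tile.
* The synthetic generator does not model lesion age, severity, skin-tone
  diversity or illumination; class separability is by construction.
* Exact reproduction of any externally reported seeded run is not promised
  — determinism holds within one installation.
* The seven-class transfer route needs genuine pre-trained weights to
  reach its intended accuracy, as discussed above.
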