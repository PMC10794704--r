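---
title: "NeuroNet19: models, preprocessing and protocol choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NeuroNet19: models, preprocessing and protocol choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(neuronet19)
```

This vignette documents the scientific content of the package: the
preprocessing model and its assumptions, the network architecture, the
training and evaluation protocol, the explanation protocol, what the
synthetic phantoms do and do not emulate, and the numerical and design
choices that were genuinely open.

## The problem

Four-class classification of brain MRI slices: glioma, meningioma,
pituitary tumor, and no tumor. Gliomas present as irregularly shaped
masses with heterogeneous intensity; meningiomas as well-defined rounded
masses; pituitary tumors as small masses near the base of the brain. The
pipeline has five stages: brain extraction, training-set augmentation, a
convolutional classifier with multi-scale feature refinement,
cross-validated training, and post-hoc LIME explanations.

## Brain extraction

Every image is resized to the working resolution (128 x 128, bilinear,
aspect not preserved) and converted to gray. The extraction chain is:

1. **Gaussian blur** of a working copy with an `n x n` kernel, `n = 11`,
   and standard deviation tied to the kernel size as
   `sigma = (n - 1) / 6` (about 1.67 for the default). Borders are
   edge-replicated. Blurring stabilizes the threshold; the blurred copy is
   used only for mask construction.
2. **Otsu's threshold**: the gray level `T` maximizing the inter-class
   variance `w1 w2 (mu1 - mu2)^2` of the split at `T`. Candidates are the
   gray levels present in the image except the maximum (thresholds inside
   runs of empty histogram bins produce the same split, so each distinct
   split is evaluated once); equal-variance ties go to the smallest `T`.
   Foreground is the bright side, matching the MRI-on-black convention
   (a config flag flips this for inverted material). A constant image has
   no valid split; the pipeline then warns and falls back to the
   full-image region.
3. **Contour filter**: connected foreground components are labelled,
   their holes filled, and components with filled area below 1000 px (at
   the 128 x 128 working resolution) are discarded — this removes bright
   specks and annotations. The largest surviving component is the brain;
   equal-area ties go to the component seen first in row-major scan
   order, for determinism.
4. **Mask and crop**: pixels outside the selected filled component are
   zeroed on the *un-blurred* standardized image — the blur exists for
   mask construction only, and the unblurred image preserves the detail
   the classifier needs — and the image is cropped to the component's
   bounding rectangle `(x, y, w, h)`.
5. **Power-law transform**: intensities are scaled to `[0, 1]`,
   transformed as `P = k Q^beta` with `k = 1`, `beta = 1.5`, clipped, and
   mapped back to `[0, 255]`. `beta > 1` darkens the mid-range and
   emphasizes bright structure. `k` is exposed but defaults to 1: on
   normalized values any other gain only clips or rescales.
6. **Final resize** back to 128 x 128. Crops vary in size and the network
   input is fixed, so a final resize is required; bilinear interpolation
   without aspect preservation matches the initial standardization.

"Contour area" here means the filled connected-component pixel count
rather than a polygon-enclosed area; the two differ negligibly at this
scale and the pixel count has an exact oracle (component labelling plus
counting), which keeps the stage testable.

## Augmentation

Training images — never validation or test images — are augmented with
one affine warp per image per epoch, parameters drawn uniformly from:
rotation 0–25 degrees, shear 0–0.2, per-axis zoom 1–1.2, width/height
shifts up to ±0.2 of the image dimension, plus a Bernoulli(1/2)
horizontal flip. Rotation, shear, zoom and shift compose into a single
matrix about the image center and are applied in one bilinear resampling
pass (repeated resampling would compound interpolation blur); the flip is
a lossless column reversal applied last. Out-of-frame coordinates clamp
to the nearest edge pixel, avoiding black borders that would otherwise
imprint spurious contour features. Rotation is sampled from `[0, 25]` as
stated rather than symmetrically; the warp engine accepts any angle, so a
symmetric range is a one-line config change.

## Architecture

The classifier is a VGG19 convolutional backbone followed by an inverted
pyramid pooling module (iPPM) and a small convolutional head:

- **Backbone**: sixteen 3 x 3 convolutions (ReLU) in five blocks of
  64/128/256/512/512 filters, each block ending in a 2 x 2 stride-2 max
  pool. The stack is truncated after the fifth pool: the pyramid module
  consumes a spatial feature map, so VGG19's fully-connected layers have
  no place in the data path. A 128 x 128 input yields a 4 x 4 x 512 map.
- **iPPM**: for each pool size `s` in {2, 3, 4, 6}, nearest-neighbor
  upsample by `s`, max-pool with window and stride `s` (restoring the
  original spatial size), and a 1 x 1 convolution to 128 channels; the
  four level outputs concatenate channel-wise back to 512. No identity
  branch is included by default (`include_identity` adds one).

  A structural remark that the tests pin down: nearest-neighbor
  upsampling by `s` followed by aligned `s x s` max pooling is exactly
  the identity map — every pooling window contains `s^2` copies of one
  source pixel. Each pyramid level therefore equals a 1 x 1 convolution
  of its input, and the module as a whole is a learned 4-way channel
  re-compression. The module is implemented as literally specified and
  this identity is asserted numerically; whether offset windows or
  unequal strides were intended is unknowable from the published
  description, and the literal reading is the only defensible one.
- **Head**: 3 x 3 convolutions with 256 then 128 filters (ReLU), global
  average pooling (giving the 128-vector used as the embedding for
  downstream projections), and a softmax dense layer over the 4 classes.

### The network engine

No deep-learning framework is available to this package, so the layers
and their gradients are implemented directly on R's BLAS-backed matrix
algebra: convolutions are an im2col gather followed by one matrix
multiplication (whole mini-batches are stacked so each layer costs one
BLAS call); the backward pass is the transposed multiplication plus a
`rowsum` scatter-add; max-pool gradients are split equally among tied
maxima, which makes the upsample-then-pool composition's gradient an
exact identity, consistent with its forward behavior. Because that
composition is an exact identity in both directions, the engine computes
each pyramid level as its equivalent 1 x 1 convolution directly — the
literal composition stays available in `ippm_level()` and the tests
assert the two paths agree numerically. Correctness is
established by hand-computed convolution cases and central-difference
gradient checks over every parameter tensor. (The ReLU subgradient at
exactly zero is taken as 0; gradient tests perturb biases away from zero
so no unit sits on the kink.)

### Input normalization

Inputs are resized to the model resolution, scaled to `[0, 1]`, and then
standardized per image to zero mean and unit variance. The scaling
matches the stated `[0, 1]` convention; the additional standardization is
an optimization conditioning choice made after observing (and it is
reproducible in the engine) that all-positive inputs with zero-initialized
biases produce strongly correlated first-layer gradients and stall
desk-scale training near the uniform-prediction plateau (`ln 4`).

### The tiny variant

CPU-scale runs use a reduced preset with the same layer grammar and
contracts: 32 x 32 input, two conv blocks, 32-filter iPPM levels and a
64/32 head. Its sizing was settled during development so that the scaled
sanity protocol (below) trains to well above chance within minutes on one
CPU; the full-size model is built and shape-checked but not trained at
desk scale.

## Training protocol

Full-scale settings: Adam (learning rate 1e-5, beta1 0.9, beta2 0.999),
sparse categorical cross-entropy on integer labels, batch size 32, 50
epochs, no early stopping, 3-fold cross-validation. Folds are stratified
by class — the protocol only says "3-fold", but per-class metrics are
reported and stratification keeps their supports stable. Each fold trains
a freshly initialized model with seed `base_seed + fold`. After each
epoch the checkpoint is overwritten iff validation accuracy strictly
improved (ties keep the earlier epoch). The scaled sanity protocol used
by the tests is the same harness at desk scale: 400 phantoms
(300 train / 100 validation), 10 epochs, batch 32, Adam 1e-3, tiny
variant — chosen to fit in minutes of CPU time while leaving a wide
margin over the 0.25 chance level.

## Evaluation

Predictions are the argmax of the softmax probabilities, ties broken by
the lowest class index. From the K x K confusion matrix (rows true,
columns predicted) the suite computes accuracy (trace/total), one-vs-rest
precision/recall/F1 per class, their unweighted macro means — the
published aggregates do not state the averaging; macro is neutral to
class imbalance, and a weighted variant is a config flag away — Cohen's
kappa `(p_o - p_e) / (1 - p_e)`, and the micro-averaged ROC: all `N x K`
one-vs-rest (indicator, score) pairs are flattened into one binary
problem, the threshold sweeps the unique scores, and AUC is the
trapezoidal integral (ties produce the usual diagonal segments, matching
the pair-counting definition `P(s+ > s-) + P(tie)/2` exactly).
Zero-denominator precision/recall are reported as 0 with a warning.

## Explanations

LIME explanations follow a stability protocol: the algorithm runs 20
times and the per-superpixel weights are averaged. Within a run, 3000
random on/off superpixel masks are drawn, masked-out regions are filled
with the image mean, the model is queried, and a ridge-regularized linear
surrogate (exponential kernel on the fraction of superpixels removed,
weighted least squares with an unpenalized intercept) is fitted to the
predicted-class probability. Two protocol choices deserve note:

- The segmentation is computed once per image (a deterministic grid,
  8 x 8 = 64 superpixels by default) and held fixed across the 20 runs;
  only the perturbation seeds vary (`base_seed + run - 1`). Averaging
  per-superpixel weights across runs is only meaningful when the
  superpixels are the same objects in every run.
- The stated "superpixel level of 3000" is read as the perturbation
  sample count — the standard LIME sample-size knob. A 3000-segment
  partition of a 128 x 128 image would leave about 5 pixels per segment,
  too fine to be an interpretable region; both knobs are exposed in
  `explain_config()` so either reading is runnable.

A constant-output model yields exactly zero surrogate slopes (the
weighted centering absorbs any constant response), which the tests
assert; the averaged explanation's standard error shrinks as `1/sqrt(n)`
in the number of runs on a stochastic model, which the tests assert as a
trend over 1/5/20 runs.

## Synthetic phantoms

The phantom generator exists so that every stage is testable without the
external dataset: a bright ellipse ("brain") with jittered center, random
semi-axes (0.30–0.42 of the image side) and orientation on a dark noisy
background (tissue 140, background 8, additive Gaussian noise sd 6,
clipped), plus a class-conditional lesion strictly inside the ellipse —
glioma: 3–5 lobes placed at jittered angles around the lesion center
with stratified per-lobe intensities spanning 90–220, so every draw is
visibly multi-lobed and internally heterogeneous;
meningioma: a uniform disk of intensity 200; pituitary: a small disk
(radius 4–8 px at 128) of intensity 210 placed in the lower-middle part
of the ellipse; no-tumor: none. Bright sub-threshold specks are placed in
the background so the area filter has something to reject. Class
morphology is deliberately separable — distinct shape, intensity and
position — so that scaled-down training has a learnable signal.

What passing phantom tests shows: the preprocessing chain isolates a
bright, roughly elliptical object and never selects sub-threshold
distractors; the training harness extracts a learnable signal; the
protocol plumbing (splits, augmentation scoping, checkpointing, metrics)
is correct. What it does not show: performance on real MRI. Phantoms
have none of the anatomy, bias fields, partial-volume effects, k-space
artifacts, scanner variation or class overlap of clinical data, and the
published full-scale accuracies cannot be reproduced from them.

## Numerical and degenerate-input choices

- Otsu on a constant image: degenerate flag, full-image fallback region,
  warning; downstream stages are total functions of it.
- Components tied on filled area: row-major first occurrence wins.
- Argmax ties in prediction: lowest class index.
- Power-law output and all image stages round half away from zero to
  integers in `[0, 255]`; the affine warp and resizes use bilinear
  interpolation with nearest-edge fill.
- The engine requires pooled dimensions to divide evenly (true for every
  shipped configuration); it stops otherwise rather than silently pad.
- All stochastic steps (phantoms, fold assignment, augmentation, weight
  init, LIME masks) draw from explicitly seeded streams; the package
  never mutates the caller's RNG state.

## Problem sizes used by the test suite

Oracle-equivalence tests run 1000 random 16 x 16 images (Otsu), 1000
random confusion matrices, and 200 random score sets (ROC); the
preprocessing end-to-end property uses 200 phantoms; the training sanity
check uses 400 phantoms for 10 epochs; LIME protocol tests use reduced
sample counts (tens to hundreds) against the same code paths as the
full 20 x 3000 defaults. These sizes are the package's chosen balance
between statistical force and a test suite that runs in minutes.

## Known limitations

- The engine is CPU-bound R; full-scale 50-epoch VGG19 training is out
  of its intended use. The full model builds, runs forward, and is
  gradient-correct, but training it belongs on GPU hardware with a
  framework.
- ImageNet-pretrained VGG19 weights are not bundled; requesting
  `pretrained_backbone = TRUE` errors, naming the missing resource.
  Random initialization is the supported mode, which is also the honest
  scaled-down analogue of the published "without pre-trained weights"
  configuration.
- No DICOM/NIfTI ingestion, no 3-D volumes, no atlas-based skull
  stripping; inputs are 2-D PNG/JPEG slices in a class-per-directory
  layout.
- The LIME surrogate uses binary masks over a grid segmentation;
  gradient-based saliency and SHAP are out of scope.
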