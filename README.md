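# neuronet19

Four-class brain-tumor classification from MRI slices — glioma,
meningioma, pituitary tumor, no tumor — with the NeuroNet19 architecture:
a VGG19 convolutional backbone whose feature maps are refined by an
**inverted pyramid pooling module (iPPM)** before a compact convolutional
head and softmax. Around the model the package implements the full
protocol: deterministic brain-extraction preprocessing, affine
training-set augmentation, stratified k-fold training with
best-validation checkpointing, a multi-metric evaluation suite, and a
repeated-run LIME explanation protocol. A synthetic phantom generator
emulates the statistical structure of brain MRI slices so every stage is
testable at desk scale with no downloads.

The package is aimed at researchers who want a transparent, fully tested
reference implementation of this pipeline in R — every numerical claim in
it is backed by an oracle test — rather than a GPU training harness.

## The method

**Brain extraction.** Each slice is standardized to 128 x 128 gray, a
working copy is blurred with an 11 x 11 Gaussian kernel
(sigma = (n-1)/6), and Otsu's method picks the threshold T maximizing the
inter-class variance

    sigma_b^2(T) = w1(T) w2(T) [mu1(T) - mu2(T)]^2 .

Connected foreground components are filled; those with area below
1000 px are rejected; the largest survivor is the brain. Its filled mask
zeroes the background of the *un-blurred* image, the bounding rectangle
(x, y, w, h) crops it, and the power-law transform P = k Q^beta
(k = 1, beta = 1.5, on [0, 1]-normalized intensities) emphasizes bright
structure before the final resize.

**iPPM.** For each pool size s in {2, 3, 4, 6}: nearest-neighbor upsample
by s (U(i,j) = I(floor(i/s), floor(j/s))), max-pool with window and
stride s, then a 1 x 1 convolution to 128 channels; outputs concatenate
channel-wise. Upsample-then-aligned-pool is an exact identity — each
level is a learned 1 x 1 re-compression — and the package documents and
*tests* that identity rather than hiding it.

**Evaluation.** Accuracy, one-vs-rest precision/recall/F1 with macro
averages, Cohen's kappa = (p_o - p_e)/(1 - p_e), and the micro-averaged
ROC/AUC built by flattening all one-vs-rest (indicator, score) pairs.

**Explanations.** LIME run 20 times with 3000 perturbation samples per
run over a fixed superpixel partition; per-superpixel surrogate weights
are averaged across runs.

The network layers and their gradients are implemented on R's
BLAS-backed matrix algebra (im2col convolutions, exact pooling
gradients); correctness is established by hand-computed cases and
central-difference gradient checks. See `vignette("neuronet19-methods")`
for the full account.

## Worked example

```r
library(neuronet19)

# a synthetic dataset: 400 phantoms, class-per-directory PNG tree
idx <- generate_dataset(phantom_spec(), n_per_class = 100,
                        seed = 1, out_dir = "phantoms")
loaded <- load_dataset_images(idx)
images <- lapply(loaded$images, preprocess_pipeline)

# stratified 300/100 split, tiny CPU preset, scaled training
folds <- make_folds(loaded$labels, k = 4, seed = 1)
model <- build_neuronet19(tiny_model_config(seed = 1))
fit <- train_fold(model, folds[[1]]$train, folds[[1]]$val,
                  images, loaded$labels,
                  train_config(epochs = 10, learning_rate = 1e-3,
                               batch_size = 32, base_seed = 1),
                  seed = 1, verbose = TRUE)

ev <- evaluate_model(fit$model, images[folds[[1]]$val],
                     loaded$labels[folds[[1]]$val])
round(c(accuracy = ev$metrics$accuracy, kappa = ev$metrics$kappa,
        auc = ev$roc$auc), 3)
```

```
#> accuracy    kappa      auc
#>    0.830    0.773    0.979
```

The three numbers are the held-out validation accuracy (fraction of the
100 validation phantoms classified correctly; chance is 0.25), Cohen's
kappa (chance-corrected agreement, 0 = chance, 1 = perfect), and the
micro-averaged ROC AUC (1 = every one-vs-rest decision ranked
perfectly). An explanation for one validation image:

```r
ex <- explain_image(fit$model, images[[folds[[1]]$val[1]]],
                    explain_config(n_runs = 20, n_samples = 150,
                                   base_seed = 1, n_segments_side = 4))
png::writePNG(render_overlay(images[[folds[[1]]$val[1]]], ex, top_k = 3),
              "overlay.png")
```

A command-line wrapper over the same functions ships in
`inst/cli/nn19.R` (subcommands `phantoms`, `preprocess`, `train`,
`evaluate`, `explain`, `run`).

## Scope

Full-scale training of VGG19 (50 epochs, 3 folds, the published
dataset) is GPU-scale and outside what this package executes at desk
scale; the full model builds, runs forward, and is gradient-checked.
ImageNet-pretrained weights are not bundled; requesting them raises an
explicit error. Inputs are 2-D PNG/JPEG slices; DICOM/NIfTI, 3-D
volumes, and the web/federated deployment surface are out of scope.
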