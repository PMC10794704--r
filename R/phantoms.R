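#' Phantom generation specification
#'
#' Parameters controlling the synthetic brain-MRI phantom generator. Each
#' phantom is a bright elliptical "brain" on a dark noisy background, with a
#' class-conditional lesion: gliomas are irregular multi-lobe blobs with
#' heterogeneous intensity, meningiomas are well-defined uniform disks,
#' pituitary tumors are small disks near the brain base, and the no-tumor
#' class carries no lesion. Small bright background specks ("distractors")
#' exercise the minimum-area contour filter of the preprocessing stage.
#'
#' @param image_size Side length of the square phantom, in pixels.
#' @param brain_axes_range Range of the ellipse semi-axes as a fraction of
#'   `image_size`.
#' @param brain_intensity Mean gray level of brain tissue, in \[0, 255\].
#' @param background_intensity Mean gray level outside the brain.
#' @param noise_sd Standard deviation of the additive Gaussian pixel noise,
#'   in gray levels. Noise is added last and clipped to \[0, 255\].
#' @param distractor_count Number of small bright background specks; each has
#'   pixel area far below the preprocessing minimum-contour-area threshold.
#' @param lesion_params Per-class lesion descriptors; see defaults.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 128L,
                         brain_axes_range = c(0.30, 0.42),
                         brain_intensity = 140,
                         background_intensity = 8,
                         noise_sd = 6,
                         distractor_count = 3L,
                         lesion_params = NULL) {
  stopifnot(image_size >= 32, length(brain_axes_range) == 2L,
            brain_axes_range[1] > 0, brain_axes_range[2] < 0.5,
            noise_sd >= 0, distractor_count >= 0)
  if (is.null(lesion_params)) {
    s <- image_size / 128
    lesion_params <- list(
      glioma = list(n_lobes = c(3L, 5L), lobe_radius = c(6, 14) * s,
                    intensity = c(90, 220)),
      meningioma = list(radius = c(10, 16) * s, intensity = 200),
      pituitary = list(radius = c(4, 8) * s, intensity = 210)
    )
  }
  structure(list(
    image_size = as.integer(image_size),
    brain_axes_range = brain_axes_range,
    brain_intensity = brain_intensity,
    background_intensity = background_intensity,
    noise_sd = noise_sd,
    distractor_count = as.integer(distractor_count),
    lesion_params = lesion_params
  ), class = "phantom_spec")
}

#' Canonical tumor class names
#'
#' Class names in the lexicographic order that defines the integer label
#' encoding used throughout the package: glioma = 0, meningioma = 1,
#' notumor = 2, pituitary = 3.
#' @return Character vector of length 4.
#' @export
tumor_classes <- function() c("glioma", "meningioma", "notumor", "pituitary")

# Logical mask of an axis-rotated ellipse, optionally shrunk by `shrink`
# (multiplies both semi-axes) to test strict interiority.
ellipse_mask <- function(size, cx, cy, a, b, phi, shrink = 1) {
  x <- matrix(rep(seq_len(size), each = size), size)   # column index
  y <- matrix(rep(seq_len(size), times = size), size)  # row index
  dx <- x - cx; dy <- y - cy
  u <- dx * cos(phi) + dy * sin(phi)
  v <- -dx * sin(phi) + dy * cos(phi)
  (u / (a * shrink))^2 + (v / (b * shrink))^2 <= 1
}

disk_mask <- function(size, cx, cy, r) {
  x <- matrix(rep(seq_len(size), each = size), size)
  y <- matrix(rep(seq_len(size), times = size), size)
  (x - cx)^2 + (y - cy)^2 <= r^2
}

#' Generate one synthetic brain phantom
#'
#' Deterministically renders a synthetic MRI-like slice for the requested
#' class. The same `(label, spec, seed)` triple always yields bit-identical
#' pixels. Lesions are constrained to lie strictly inside the brain ellipse;
#' the returned bounding boxes are measured from the rendered masks.
#'
#' @param label Integer class index in 0..3 (see [tumor_classes()]) or a
#'   class name.
#' @param spec A [phantom_spec()].
#' @param seed Integer seed.
#' @return An object of class `phantom_image`: a list with `pixels`
#'   (H x W integer matrix in \[0, 255\]), `label`, `class_name`,
#'   `brain_bbox`, `lesion_bbox` (NULL for the no-tumor class), and the
#'   rendered ground-truth `brain_mask` / `lesion_mask` logical matrices.
#'   Bounding boxes are 0-based `(x, y, w, h)` lists.
#' @export
generate_phantom <- function(label, spec = phantom_spec(), seed = 1L) {
  classes <- tumor_classes()
  if (is.character(label)) label <- match(label, classes) - 1L
  if (is.na(label) || !label %in% 0:3)
    stop("label must be an integer in 0..3 or one of: ",
         paste(classes, collapse = ", "))
  label <- as.integer(label)
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$image_size

  local_seed(as.integer(seed) %% 536870000L * 4L + label, {
    # brain ellipse: jittered center, random semi-axes and orientation
    cx <- n / 2 + runif(1, -0.04, 0.04) * n
    cy <- n / 2 + runif(1, -0.04, 0.04) * n
    a <- runif(1, spec$brain_axes_range[1], spec$brain_axes_range[2]) * n
    b <- runif(1, spec$brain_axes_range[1], spec$brain_axes_range[2]) * n
    phi <- runif(1, 0, pi)
    brain <- ellipse_mask(n, cx, cy, a, b, phi)
    inner <- ellipse_mask(n, cx, cy, a, b, phi, shrink = 0.88)

    px <- matrix(spec$background_intensity, n, n)
    px[brain] <- spec$brain_intensity

    # class-conditional lesion, clipped to the strict interior of the brain
    lesion <- NULL
    lp <- spec$lesion_params
    if (label == 0L) {                      # glioma: irregular multi-lobe
      nl <- sample(lp$glioma$n_lobes[1]:lp$glioma$n_lobes[2], 1)
      ccx <- cx + runif(1, -0.25, 0.25) * a
      ccy <- cy + runif(1, -0.25, 0.25) * b
      lesion <- matrix(FALSE, n, n)
      # heterogeneity and irregularity are guaranteed per draw, not just in
      # expectation: lobe intensities are a stratified sample spanning the
      # whole range (every glioma has strong internal contrast, unlike the
      # uniform meningioma disk) and lobe centers sit at jittered angles
      # around the lesion center so the outline is always multi-lobed
      ints <- lp$glioma$intensity[1] +
        (sample(nl) - runif(nl)) / nl *
          diff(lp$glioma$intensity)
      ang0 <- runif(1, 0, 2 * pi)
      for (i in seq_len(nl)) {
        r <- runif(1, lp$glioma$lobe_radius[1], lp$glioma$lobe_radius[2])
        ang <- ang0 + 2 * pi * (i - 1 + runif(1, -0.2, 0.2)) / nl
        off <- r * runif(1, 0.7, 1.1)
        lobe <- disk_mask(n, ccx + off * cos(ang), ccy + off * sin(ang),
                          r) & inner
        px[lobe] <- ints[i]
        lesion <- lesion | lobe
      }
    } else if (label == 1L) {               # meningioma: uniform disk
      r <- runif(1, lp$meningioma$radius[1], lp$meningioma$radius[2])
      lx <- cx + runif(1, -0.3, 0.3) * a
      ly <- cy + runif(1, -0.3, 0.3) * b
      lesion <- disk_mask(n, lx, ly, r) & inner
      px[lesion] <- lp$meningioma$intensity
    } else if (label == 3L) {               # pituitary: small disk, brain base
      r <- runif(1, lp$pituitary$radius[1], lp$pituitary$radius[2])
      # lower-middle fifth of the brain ellipse (image rows grow downward)
      lx <- cx + runif(1, -0.1, 0.1) * a
      ly <- cy + runif(1, 0.60, 0.72) * b
      lesion <- disk_mask(n, lx, ly, r) & inner
      px[lesion] <- lp$pituitary$intensity
    }
    if (!is.null(lesion) && !any(lesion)) lesion <- NULL

    # bright distractor specks in the background, each far below the
    # minimum-contour-area threshold
    for (i in seq_len(spec$distractor_count)) {
      repeat {
        dx0 <- runif(1, 4, n - 4); dy0 <- runif(1, 4, n - 4)
        r <- runif(1, 1, 3)
        speck <- disk_mask(n, dx0, dy0, r)
        if (!any(speck & brain)) { px[speck] <- 180; break }
      }
    }

    px <- px + rnorm(n * n, 0, spec$noise_sd)
    structure(list(
      pixels = quantize_gray(px),
      label = label,
      class_name = classes[label + 1L],
      brain_bbox = mask_bbox(brain),
      lesion_bbox = if (is.null(lesion)) NULL else mask_bbox(lesion),
      brain_mask = brain,
      lesion_mask = lesion
    ), class = "phantom_image")
  })
}

#' Generate a phantom dataset on disk
#'
#' Writes a balanced class-per-directory PNG tree mirroring the layout of
#' public brain-tumor MRI collections:
#' `<out_dir>/<class_name>/<index>.png` with class directories `glioma`,
#' `meningioma`, `notumor`, `pituitary`.
#'
#' @param spec A [phantom_spec()].
#' @param n_per_class Number of images per class.
#' @param seed Integer seed; image `i` of class `c` uses a seed derived
#'   deterministically from it, so reruns reproduce identical files.
#' @param out_dir Output directory (created if needed).
#' @return A `dataset_index` (see [load_image_folder()]) over the files
#'   written, with `4 * n_per_class` entries.
#' @export
generate_dataset <- function(spec = phantom_spec(), n_per_class = 25L,
                             seed = 1L, out_dir) {
  stopifnot(n_per_class >= 1)
  classes <- tumor_classes()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  for (ci in seq_along(classes)) {
    cdir <- file.path(out_dir, classes[ci])
    dir.create(cdir, showWarnings = FALSE)
    for (i in seq_len(n_per_class)) {
      ph <- generate_phantom(ci - 1L, spec, seed = seed + 131L * i)
      write_gray_png(ph$pixels, file.path(cdir, sprintf("%04d.png", i)))
    }
  }
  load_image_folder(out_dir)
}
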