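#' Explanation configuration
#'
#' Protocol for repeated-run LIME explanations: the segmentation is fixed
#' once per image, each run perturbs superpixels with its own derived seed
#' (`base_seed + run - 1`), and the per-superpixel surrogate weights are
#' averaged over runs. Defaults follow the stability protocol of running
#' LIME 20 times with 3000 perturbation samples per run.
#'
#' @param n_runs Number of repeated LIME runs averaged together.
#' @param n_samples Perturbation samples per run.
#' @param base_seed Base seed; run `r` uses `base_seed + r - 1`.
#' @param n_segments_side Side count of the deterministic grid
#'   segmentation (`n_segments_side^2` superpixels).
#' @param kernel_width Width of the exponential similarity kernel on the
#'   mask distance (fraction of superpixels turned off).
#' @param ridge_lambda Ridge penalty of the weighted linear surrogate.
#' @param fill How masked-out superpixels are filled: `"mean"` (image mean
#'   gray) or `"black"`.
#' @return An object of class `explain_config`.
#' @export
explain_config <- function(n_runs = 20L, n_samples = 3000L, base_seed = 0L,
                           n_segments_side = 8L, kernel_width = 0.25,
                           ridge_lambda = 1, fill = c("mean", "black")) {
  fill <- match.arg(fill)
  stopifnot(n_runs >= 1, n_samples >= 10, n_segments_side >= 2,
            kernel_width > 0, ridge_lambda >= 0)
  structure(list(n_runs = as.integer(n_runs),
                 n_samples = as.integer(n_samples),
                 base_seed = as.integer(base_seed),
                 n_segments_side = as.integer(n_segments_side),
                 kernel_width = kernel_width, ridge_lambda = ridge_lambda,
                 fill = fill), class = "explain_config")
}

# Deterministic grid superpixel partition; ids contiguous from 0,
# row-major over grid cells.
grid_segments <- function(H, W, n_side) {
  ri <- pmin(floor((seq_len(H) - 1L) * n_side / H), n_side - 1L)
  ci <- pmin(floor((seq_len(W) - 1L) * n_side / W), n_side - 1L)
  outer(ri, ci, function(r, c) r * n_side + c)
}

# Weighted ridge regression with unpenalized intercept; returns slopes.
# Centering X and y by their weighted means absorbs the intercept, so a
# constant response yields exactly zero slopes.
weighted_ridge <- function(X, y, w, lambda) {
  sw <- sum(w)
  xm <- colSums(X * w) / sw
  ym <- sum(y * w) / sw
  Xc <- sweep(X, 2L, xm)
  yc <- y - ym
  A <- crossprod(Xc, Xc * w) + diag(lambda, ncol(X))
  as.vector(solve(A, crossprod(Xc, yc * w)))
}

#' Repeated-run LIME explanation of one prediction
#'
#' Computes a superpixel-level importance map for the model's predicted
#' class on one image. The image is partitioned once into a deterministic
#' grid of superpixels; in each of `n_runs` runs, `n_samples` random
#' on/off superpixel masks are drawn (run seed `base_seed + run - 1`), the
#' model is queried on the masked images, and a ridge-regularized linear
#' surrogate weighted by an exponential kernel on mask distance is fitted
#' to the predicted-class probability. The per-run coefficient vectors are
#' averaged into `mean_weight`.
#'
#' @param model An `nn19_model` (or any function `f(image) -> probability
#'   vector`, accepted for testing).
#' @param image Gray matrix in \[0, 255\] at the model input size.
#' @param config An [explain_config()].
#' @return An object of class `nn19_explanation`: `segment_map` (H x W
#'   integer ids from 0), `mean_weight`, `per_run_weights`
#'   (n_runs x n_segments), `predicted_class`, `class_probs`.
#' @export
explain_image <- function(model, image, config = explain_config()) {
  stopifnot(inherits(config, "explain_config"))
  px <- as_gray_matrix(image)
  H <- nrow(px); W <- ncol(px)
  predict_fn <- if (inherits(model, "nn19_model")) {
    function(im) nn_forward(model, model_input(model, im))$probs
  } else model
  seg <- grid_segments(H, W, config$n_segments_side)
  n_seg <- config$n_segments_side^2
  class_probs <- predict_fn(px)
  predicted <- which.max(class_probs) - 1L
  fill_val <- if (config$fill == "mean") mean(px) else 0
  seg_cells <- lapply(seq_len(n_seg) - 1L, function(s) which(seg == s))

  per_run <- matrix(0, config$n_runs, n_seg)
  for (r in seq_len(config$n_runs)) {
    local_seed(config$base_seed + r - 1L, {
      Z <- matrix(stats::rbinom(config$n_samples * n_seg, 1L, 0.5),
                  config$n_samples, n_seg)
      Z[1L, ] <- 1L                      # anchor on the unperturbed image
      y <- numeric(config$n_samples)
      for (i in seq_len(config$n_samples)) {
        xi <- px
        off <- which(Z[i, ] == 0L)
        for (s in off) xi[seg_cells[[s]]] <- fill_val
        y[i] <- predict_fn(xi)[predicted + 1L]
      }
      d <- 1 - rowMeans(Z)               # fraction of superpixels removed
      w <- exp(-(d / config$kernel_width)^2)
      per_run[r, ] <- weighted_ridge(Z, y, w, config$ridge_lambda)
    })
  }
  structure(list(segment_map = seg, mean_weight = colMeans(per_run),
                 per_run_weights = per_run, predicted_class = predicted,
                 class_probs = class_probs),
            class = "nn19_explanation")
}

#' Render an explanation overlay
#'
#' Tints the `top_k` superpixels by absolute mean weight over the source
#' image: red for positive evidence toward the predicted class, blue for
#' negative. A small two-swatch legend is embedded in the top-left corner.
#' Output dimensions equal the input's.
#'
#' @param image Gray matrix in \[0, 255\].
#' @param expl An `nn19_explanation`.
#' @param top_k Number of superpixels to highlight (clamped with a warning
#'   if it exceeds the segment count).
#' @return H x W x 3 numeric array in \[0, 1\].
#' @export
render_overlay <- function(image, expl, top_k = 5L) {
  px <- as_gray_matrix(image) / 255
  stopifnot(identical(dim(px), dim(expl$segment_map)))
  n_seg <- length(expl$mean_weight)
  if (top_k > n_seg) {
    warning("top_k exceeds the number of superpixels; clamping to ", n_seg)
    top_k <- n_seg
  }
  rgb <- array(px, c(dim(px), 3L))
  if (top_k > 0) {
    sel <- order(abs(expl$mean_weight), decreasing = TRUE)[seq_len(top_k)]
    for (s in sel) {
      cells <- which(expl$segment_map == s - 1L)
      ch <- if (expl$mean_weight[s] >= 0) 1L else 3L   # red / blue
      plane <- rgb[, , ch]
      plane[cells] <- pmin(plane[cells] + 0.35, 1)
      rgb[, , ch] <- plane
    }
    # embedded legend: red (positive) and blue (negative) swatches
    rgb[1:4, 1:4, ] <- 0; rgb[1:4, 1:4, 1] <- 1
    rgb[1:4, 6:9, ] <- 0; rgb[1:4, 6:9, 3] <- 1
  }
  rgb
}

#' Write explanation weights as CSV
#'
#' @param expl An `nn19_explanation`.
#' @param path Output CSV path (segment id, mean weight, per-run weights).
#' @return Invisibly, the path.
#' @export
write_explanation <- function(expl, path) {
  df <- data.frame(segment = seq_along(expl$mean_weight) - 1L,
                   mean_weight = expl$mean_weight,
                   t(expl$per_run_weights))
  names(df)[-(1:2)] <- paste0("run_", seq_len(nrow(expl$per_run_weights)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
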