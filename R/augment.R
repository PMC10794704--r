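#' Augmentation configuration
#'
#' Ranges of the affine training-set augmentation operators. Defaults match
#' the standard recipe for this task: rotation 0-25 degrees, horizontal
#' flip enabled, shear 0-0.2, zoom 0-0.2, and width/height shifts of up to
#' 0.2 of the image dimension in either direction.
#'
#' @param rotation_max_deg Maximum rotation angle in degrees (sampled
#'   uniformly from `[0, rotation_max_deg]`).
#' @param horizontal_flip Whether to flip horizontally with probability 1/2.
#' @param shear_max Maximum shear factor.
#' @param zoom_max Maximum extra zoom; scale factors are drawn from
#'   `[1, 1 + zoom_max]` independently per axis.
#' @param width_shift_max,height_shift_max Maximum shift as a fraction of
#'   the image width/height; shifts are drawn from `[-max, +max]`.
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(rotation_max_deg = 25, horizontal_flip = TRUE,
                           shear_max = 0.2, zoom_max = 0.2,
                           width_shift_max = 0.2, height_shift_max = 0.2) {
  stopifnot(rotation_max_deg >= 0, shear_max >= 0, zoom_max >= 0,
            width_shift_max >= 0, height_shift_max >= 0)
  structure(list(rotation_max_deg = rotation_max_deg,
                 horizontal_flip = isTRUE(horizontal_flip),
                 shear_max = shear_max, zoom_max = zoom_max,
                 width_shift_max = width_shift_max,
                 height_shift_max = height_shift_max),
            class = "augment_config")
}

#' Sample one set of affine parameters
#'
#' Draws each parameter uniformly from its configured range using the
#' caller's RNG stream: rotation angle theta, shear factor lambda, zoom
#' scales (zx, zy), pixel shifts (dx, dy), and a Bernoulli(1/2) horizontal
#' flip when enabled.
#'
#' @param config An [augment_config()].
#' @param width,height Image dimensions, used to convert the fractional
#'   shift ranges into pixels.
#' @return An object of class `affine_params`.
#' @export
sample_affine_params <- function(config = augment_config(),
                                 width = 128L, height = 128L) {
  stopifnot(inherits(config, "augment_config"))
  structure(list(
    theta = runif(1, 0, config$rotation_max_deg),
    flip = config$horizontal_flip && runif(1) < 0.5,
    lam = runif(1, 0, config$shear_max),
    zx = runif(1, 1, 1 + config$zoom_max),
    zy = runif(1, 1, 1 + config$zoom_max),
    dx = runif(1, -config$width_shift_max, config$width_shift_max) * width,
    dy = runif(1, -config$height_shift_max, config$height_shift_max) * height
  ), class = "affine_params")
}

identity_affine_params <- function() {
  structure(list(theta = 0, flip = FALSE, lam = 0, zx = 1, zy = 1,
                 dx = 0, dy = 0), class = "affine_params")
}

# 2x2 linear part of the composed transform zoom %*% shear %*% rotation,
# acting on (x, y) coordinates. Exposed internally so the individual
# operator matrices can be checked against their closed forms.
rotation_matrix <- function(theta_deg) {
  t <- theta_deg * pi / 180
  matrix(c(cos(t), sin(t), -sin(t), cos(t)), 2, 2)
}
shear_matrix <- function(lam) matrix(c(1, 0, lam, 1), 2, 2)
zoom_matrix <- function(zx, zy) diag(c(zx, zy))
affine_linear_part <- function(params) {
  zoom_matrix(params$zx, params$zy) %*% shear_matrix(params$lam) %*%
    rotation_matrix(params$theta)
}

#' Apply an affine warp to a gray image
#'
#' Applies rotation, shear, zoom and shift about the image center as a
#' single combined warp (one bilinear resampling pass), then the optional
#' horizontal flip. Coordinates falling outside the frame are filled with
#' the nearest edge value. The output has the same shape as the input.
#'
#' @param image Gray matrix in \[0, 255\].
#' @param params An `affine_params` (see [sample_affine_params()]).
#' @return Integer gray matrix of the same shape.
#' @export
apply_affine <- function(image, params) {
  stopifnot(inherits(params, "affine_params"))
  px <- as_gray_matrix(image)
  H <- nrow(px); W <- ncol(px)
  is_ident <- params$theta == 0 && params$lam == 0 && params$zx == 1 &&
    params$zy == 1 && params$dx == 0 && params$dy == 0
  out <- px
  if (!is_ident) {
    cx <- (W + 1) / 2; cy <- (H + 1) / 2
    M <- affine_linear_part(params)
    Minv <- solve(M)
    xo <- rep(seq_len(W), each = H) - cx - params$dx
    yo <- rep(seq_len(H), times = W) - cy - params$dy
    xs <- Minv[1, 1] * xo + Minv[1, 2] * yo + cx
    ys <- Minv[2, 1] * xo + Minv[2, 2] * yo + cy
    # nearest-edge fill: clamp source coordinates into the frame
    xs <- clamp(xs, 1, W); ys <- clamp(ys, 1, H)
    x0 <- pmin(floor(xs), W - 1L); y0 <- pmin(floor(ys), H - 1L)
    fx <- xs - x0; fy <- ys - y0
    i00 <- (x0 - 1) * H + y0
    v <- px[i00] * (1 - fx) * (1 - fy) + px[i00 + H] * fx * (1 - fy) +
      px[i00 + 1] * (1 - fx) * fy + px[i00 + H + 1] * fx * fy
    out <- matrix(v, H, W)
  }
  if (params$flip) out <- out[, rev(seq_len(W)), drop = FALSE]
  quantize_gray(out)
}

#' Augmented copies of a training set for one epoch
#'
#' Yields one randomly augmented copy of each image, labels unchanged.
#' Intended for the training stream only; validation and test images must
#' never pass through this function (the training harness enforces that).
#'
#' @param images List of gray matrices.
#' @param labels Integer labels, same length.
#' @param config An [augment_config()]; with all ranges zero and flip
#'   disabled the stream is bitwise-identical to its input.
#' @param seed Integer seed; the same seed reproduces the same stream.
#' @param hook Optional function called as `hook(i)` for every image that
#'   passes through augmentation (used to assert the train-only contract).
#' @return List with `images` (augmented copies) and `labels` (unchanged).
#' @export
augment_stream <- function(images, labels, config = augment_config(),
                           seed = 1L, hook = NULL) {
  stopifnot(length(images) == length(labels), length(images) >= 1)
  local_seed(seed, {
    out <- vector("list", length(images))
    for (i in seq_along(images)) {
      p <- sample_affine_params(config, ncol(images[[i]]), nrow(images[[i]]))
      out[[i]] <- apply_affine(images[[i]], p)
      if (!is.null(hook)) hook(i)
    }
    list(images = out, labels = labels)
  })
}
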