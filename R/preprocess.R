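#' Preprocessing configuration
#'
#' Parameters of the brain-extraction chain: standardize, Gaussian blur,
#' Otsu threshold, minimum-area contour filter, filled-mask overlay, crop,
#' power-law intensity transform, final standardize.
#'
#' @param target_size Working (and output) resolution in pixels; images are
#'   resized to `target_size x target_size` before anything else.
#' @param blur_kernel_n Odd Gaussian kernel dimension `n`; the kernel
#'   standard deviation is tied to it as `sigma = (n - 1) / 6`.
#' @param min_contour_area Minimum filled connected-component pixel area for
#'   a contour to be considered the brain, interpreted at the working
#'   resolution.
#' @param gamma_beta Exponent `beta` of the power-law transform
#'   `P = k * Q^beta` on \[0, 1\]-normalized intensities.
#' @param gamma_gain Gain `k` of the power-law transform.
#' @param foreground Either `"bright"` (brain brighter than background; the
#'   MRI-on-black convention) or `"dark"` for inverted inputs.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_size = 128L, blur_kernel_n = 11L,
                              min_contour_area = 1000L, gamma_beta = 1.5,
                              gamma_gain = 1, foreground = c("bright", "dark")) {
  foreground <- match.arg(foreground)
  if (blur_kernel_n %% 2 == 0 || blur_kernel_n < 3)
    stop("blur_kernel_n must be odd and >= 3")
  stopifnot(target_size >= 32, min_contour_area >= 1, gamma_beta > 0,
            gamma_gain > 0)
  structure(list(
    target_size = as.integer(target_size),
    blur_kernel_n = as.integer(blur_kernel_n),
    min_contour_area = as.integer(min_contour_area),
    gamma_beta = gamma_beta,
    gamma_gain = gamma_gain,
    foreground = foreground
  ), class = "preprocess_config")
}

#' Standardize a raster to a fixed-size gray image
#'
#' Decodes (if given a path), converts color inputs to gray by Rec. 601
#' luminance, and bilinearly resizes to `size x size` without preserving
#' aspect ratio. An image already at the target size passes through with
#' values unchanged.
#'
#' @param image File path, gray matrix, or H x W x C array.
#' @param size Output side length in pixels.
#' @return Integer gray matrix `size x size` in \[0, 255\].
#' @export
standardize <- function(image, size = 128L) {
  px <- as_gray_matrix(image)
  quantize_gray(resize_gray(px, size, size))
}

# Normalized n x n Gaussian kernel with sigma = (n - 1) / 6.
gaussian_kernel <- function(n) {
  stopifnot(n %% 2 == 1, n >= 3)
  sigma <- (n - 1) / 6
  r <- (n - 1) / 2
  a <- outer((-r):r, (-r):r, function(a, b) exp(-(a^2 + b^2) / (2 * sigma^2)))
  a / sum(a)
}

#' Gaussian blur with a size-tied standard deviation
#'
#' Convolves a gray image with the normalized `n x n` Gaussian kernel whose
#' standard deviation is `sigma = (n - 1) / 6`. Borders are handled by edge
#' replication.
#'
#' @param image Gray matrix in \[0, 255\].
#' @param n Odd kernel dimension (default 11, giving sigma = 10/6).
#' @return Integer gray matrix of the same shape.
#' @export
gaussian_blur <- function(image, n = 11L) {
  if (n %% 2 == 0) stop("kernel dimension n must be odd")
  px <- as_gray_matrix(image)
  r <- (n - 1) / 2
  # replicate-pad, then FFT convolution; the pad is wide enough that the
  # circular wrap-around of filter2 never reaches the region of interest
  padded <- px[c(rep(1, r), seq_len(nrow(px)), rep(nrow(px), r)),
               c(rep(1, r), seq_len(ncol(px)), rep(ncol(px), r))]
  out <- EBImage::filter2(padded, gaussian_kernel(n))
  quantize_gray(out[r + seq_len(nrow(px)), r + seq_len(ncol(px))])
}

#' Otsu's threshold by inter-class variance maximization
#'
#' Selects the gray level `T` maximizing the inter-class variance
#' `w1(T) * w2(T) * (mu1(T) - mu2(T))^2` of the two pixel populations split
#' at `T` (class 1: values <= T; class 2: values > T). Candidate thresholds
#' are the gray levels present in the image (excluding the maximum, which
#' would leave class 2 empty); among equal-variance candidates the smallest
#' `T` wins. Foreground is the bright side (`pixels > T`) under the default
#' MRI-on-black polarity.
#'
#' @param image Gray matrix in \[0, 255\].
#' @param foreground `"bright"` or `"dark"`.
#' @return An object of class `binary_mask`: list with `pixels` (logical
#'   matrix), `threshold_used`, and `degenerate` (TRUE for constant images,
#'   where no split exists and the mask is all-foreground).
#' @export
otsu_threshold <- function(image, foreground = "bright") {
  px <- quantize_gray(as_gray_matrix(image))
  h <- tabulate(as.vector(px) + 1L, nbins = 256L)  # counts for levels 0..255
  total <- sum(h)
  levs <- which(h > 0L) - 1L
  if (length(levs) < 2L) {
    return(structure(list(pixels = matrix(TRUE, nrow(px), ncol(px)),
                          threshold_used = NA_integer_, degenerate = TRUE),
                     class = "binary_mask"))
  }
  cand <- levs[-length(levs)]
  cw <- cumsum(h)                       # pixels <= T
  cs <- cumsum(h * (0:255))             # intensity sum over pixels <= T
  s <- cs[256L]
  w1 <- cw[cand + 1L]; w2 <- total - w1
  m1 <- cs[cand + 1L] / w1; m2 <- (s - cs[cand + 1L]) / w2
  sigma_b <- (w1 / total) * (w2 / total) * (m1 - m2)^2
  t_star <- cand[which.max(sigma_b)]    # first maximizer: smallest T
  fg <- if (identical(foreground, "dark")) px <= t_star else px > t_star
  structure(list(pixels = fg, threshold_used = as.integer(t_star),
                 degenerate = FALSE), class = "binary_mask")
}

#' Brain region of interest from a binary mask
#'
#' Labels the connected foreground components, fills their holes, and among
#' components whose filled pixel area reaches `min_area` selects the
#' largest. Equal-area ties go to the component whose first pixel comes
#' first in row-major scan order. If no component qualifies, the full-image
#' ROI is returned with `fallback = TRUE`.
#'
#' @param mask A `binary_mask` or logical matrix.
#' @param min_area Minimum filled component pixel area.
#' @return An object of class `roi`: 0-based top-left `(x, y)`, `w`, `h`,
#'   filled pixel `area`, a `fallback` flag, and `component`, the logical
#'   mask of the selected filled component (all-TRUE on fallback).
#' @export
brain_roi <- function(mask, min_area = 1000L) {
  m <- if (inherits(mask, "binary_mask")) mask$pixels else mask
  stopifnot(is.matrix(m))
  H <- nrow(m); W <- ncol(m)
  full <- function() structure(list(x = 0L, y = 0L, w = W, h = H,
                                    area = sum(m), fallback = TRUE,
                                    component = matrix(TRUE, H, W)),
                               class = "roi")
  if (!any(m)) return(full())
  lab <- EBImage::bwlabel(m * 1)
  filled <- EBImage::fillHull(lab)
  areas <- tabulate(filled[filled > 0])
  ok <- which(areas >= min_area)
  if (length(ok) == 0L) return(full())
  best <- ok[areas[ok] == max(areas[ok])]
  if (length(best) > 1L) {
    # row-major scan order: row-first index (y * W + x), smallest wins
    scan_first <- vapply(best, function(l) {
      idx <- which(filled == l, arr.ind = TRUE)
      min((idx[, 1L] - 1L) * W + (idx[, 2L] - 1L))
    }, numeric(1))
    best <- best[which.min(scan_first)]
  }
  comp <- filled == best
  bb <- mask_bbox(comp)
  structure(list(x = bb$x, y = bb$y, w = bb$w, h = bb$h,
                 area = as.integer(areas[best]), fallback = FALSE,
                 component = comp), class = "roi")
}

#' Mask the background and crop to the ROI
#'
#' Sets pixels outside the selected filled component to 0 and crops the
#' image to the ROI rectangle.
#'
#' @param image Gray matrix.
#' @param mask Logical matrix of the filled component (or a `roi`'s
#'   `component`, or a `binary_mask`).
#' @param roi A `roi`.
#' @return Gray matrix of dimensions `(h, w)`.
#' @export
apply_mask_and_crop <- function(image, mask, roi) {
  px <- as_gray_matrix(image)
  m <- if (inherits(mask, "binary_mask")) mask$pixels
       else if (inherits(mask, "roi")) mask$component else mask
  stopifnot(identical(dim(px), dim(m)))
  if (roi$x < 0 || roi$y < 0 || roi$x + roi$w > ncol(px) ||
      roi$y + roi$h > nrow(px))
    stop("internal error: ROI exceeds image bounds")
  px[!m] <- 0
  quantize_gray(px[roi$y + seq_len(roi$h), roi$x + seq_len(roi$w),
                   drop = FALSE])
}

#' Power-law (gamma) intensity transform
#'
#' Normalizes gray levels to \[0, 1\], applies `P = k * Q^beta` (clipped to
#' \[0, 1\]), and maps back to \[0, 255\]. With `beta > 1` bright structures
#' are emphasized relative to the dark background.
#'
#' @param image Gray matrix in \[0, 255\].
#' @param k Gain (default 1).
#' @param beta Exponent (default 1.5).
#' @return Integer gray matrix of the same shape.
#' @export
power_law <- function(image, k = 1, beta = 1.5) {
  stopifnot(k > 0, beta > 0)
  px <- as_gray_matrix(image)
  quantize_gray(clamp(k * (px / 255)^beta, 0, 1) * 255)
}

#' Full brain-extraction preprocessing pipeline
#'
#' Runs the complete chain on one raster: standardize to the working
#' resolution, Gaussian blur a working copy, Otsu-threshold the blurred
#' copy, select the largest filled contour above the area threshold, apply
#' the component mask to the *un-blurred* standardized image, crop to the
#' ROI, power-law transform, and resize back to `target_size` for the
#' fixed-shape network input. On a degenerate threshold (constant image)
#' the full-image fallback ROI is used and a warning is emitted.
#'
#' @param image File path, gray matrix, or color array.
#' @param config A [preprocess_config()].
#' @param debug_dir Optional directory; when given, one PNG per stage is
#'   written there.
#' @return Integer gray matrix `target_size x target_size`, with attributes
#'   `roi` (the `roi` used, minus its component mask), `threshold`
#'   (Otsu gray level) and `fallback`.
#' @export
preprocess_pipeline <- function(image, config = preprocess_config(),
                                debug_dir = NULL) {
  stopifnot(inherits(config, "preprocess_config"))
  std <- standardize(image, config$target_size)
  blurred <- gaussian_blur(std, config$blur_kernel_n)
  mask <- otsu_threshold(blurred, config$foreground)
  if (mask$degenerate) {
    warning("degenerate Otsu threshold (constant image); using full-image ROI")
    n <- config$target_size
    roi <- structure(list(x = 0L, y = 0L, w = n, h = n, area = n * n,
                          fallback = TRUE, component = matrix(TRUE, n, n)),
                     class = "roi")
  } else {
    roi <- brain_roi(mask, config$min_contour_area)
  }
  cropped <- apply_mask_and_crop(std, roi$component, roi)
  transformed <- power_law(cropped, config$gamma_gain, config$gamma_beta)
  out <- quantize_gray(resize_gray(transformed, config$target_size))
  if (!is.null(debug_dir)) {
    dir.create(debug_dir, recursive = TRUE, showWarnings = FALSE)
    write_gray_png(std, file.path(debug_dir, "1_standardized.png"))
    write_gray_png(blurred, file.path(debug_dir, "2_blurred.png"))
    write_gray_png(mask$pixels * 255, file.path(debug_dir, "3_otsu_mask.png"))
    write_gray_png(roi$component * 255, file.path(debug_dir, "4_component.png"))
    write_gray_png(cropped, file.path(debug_dir, "5_cropped.png"))
    write_gray_png(transformed, file.path(debug_dir, "6_power_law.png"))
    write_gray_png(out, file.path(debug_dir, "7_final.png"))
  }
  attr(out, "roi") <- roi[c("x", "y", "w", "h", "area", "fallback")]
  attr(out, "threshold") <- mask$threshold_used
  attr(out, "fallback") <- roi$fallback
  out
}

#' Preprocess every image of a dataset index
#'
#' @param index A `dataset_index`.
#' @param config A [preprocess_config()].
#' @param out_dir Optional directory mirroring the class layout with
#'   preprocessed PNGs.
#' @return List of preprocessed gray matrices, in index order.
#' @export
preprocess_dataset <- function(index, config = preprocess_config(),
                               out_dir = NULL) {
  stopifnot(inherits(index, "dataset_index"))
  lapply(seq_len(nrow(index$entries)), function(i) {
    e <- index$entries[i, ]
    out <- preprocess_pipeline(e$path, config)
    if (!is.null(out_dir)) {
      d <- file.path(out_dir, e$class_name)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      write_gray_png(out, file.path(d, basename(e$path)))
    }
    out
  })
}
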