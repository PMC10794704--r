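# Internal helpers shared across modules.

# Run code with a temporarily fixed RNG state, restoring the caller's state.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Coerce raster input to a numeric H x W gray matrix on the [0, 255] scale.
# Accepts a file path (PNG via the png package, anything else via EBImage),
# a matrix, or an H x W x C array (converted by Rec. 601 luminance).
as_gray_matrix <- function(image) {
  if (is.character(image)) {
    if (length(image) != 1L || !file.exists(image))
      stop("image file not found: ", paste(image, collapse = ", "))
    px <- if (grepl("\\.png$", image, ignore.case = TRUE)) {
      png::readPNG(image)
    } else {
      img <- EBImage::readImage(image)
      d <- EBImage::imageData(img)
      # EBImage stores (x, y[, c]); transpose to row/col convention
      if (length(dim(d)) == 2L) t(d) else aperm(d, c(2L, 1L, 3L))
    }
    return(as_gray_matrix(px * if (max(px) <= 1) 255 else 1))
  }
  if (is.array(image) && length(dim(image)) == 3L) {
    nc <- dim(image)[3L]
    image <- if (nc >= 3L) {
      0.299 * image[, , 1L] + 0.587 * image[, , 2L] + 0.114 * image[, , 3L]
    } else {
      image[, , 1L]
    }
  }
  if (!is.matrix(image)) stop("cannot interpret input as a gray image")
  if (length(image) == 0L) stop("empty image")
  storage.mode(image) <- "double"
  image
}

# Bilinear resize of a [0, 255] gray matrix to h x w, no aspect preservation.
resize_gray <- function(px, h, w = h) {
  if (nrow(px) == h && ncol(px) == w) return(px)
  out <- EBImage::resize(EBImage::Image(px / 255), w = h, h = w,
                         filter = "bilinear")
  clamp(EBImage::imageData(out) * 255, 0, 255)
}

# Integer-valued gray image in [0, 255]
quantize_gray <- function(px) {
  px <- round(clamp(px, 0, 255))
  storage.mode(px) <- "integer"
  px
}

# Bounding box of a logical mask, 0-based (x, y) top-left plus width/height.
mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  list(
    x = min(idx[, 2L]) - 1L,
    y = min(idx[, 1L]) - 1L,
    w = max(idx[, 2L]) - min(idx[, 2L]) + 1L,
    h = max(idx[, 1L]) - min(idx[, 1L]) + 1L
  )
}

bbox_contains <- function(outer, inner) {
  !is.null(outer) && !is.null(inner) &&
    inner$x >= outer$x && inner$y >= outer$y &&
    inner$x + inner$w <= outer$x + outer$w &&
    inner$y + inner$h <= outer$y + outer$h
}

write_gray_png <- function(px, path) {
  png::writePNG(clamp(px, 0, 255) / 255, path)
}
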