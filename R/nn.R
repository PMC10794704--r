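# Minimal convolutional-network engine.
#
# Tensors are base-R arrays with dim (H, W, C). Convolutions are computed
# by im2col gather + one BLAS matrix multiplication; gradients use the
# transposed multiplication and a rowsum scatter-add. Max pooling uses
# non-overlapping s x s windows (window == stride), with gradients split
# equally among tied maxima so that the upsample->pool composition has an
# exact identity gradient.

as_hwc <- function(x) {
  if (is.matrix(x)) array(x, c(dim(x), 1L)) else x
}

# Patch-gather index for 'same' zero-padded k x k convolution over an
# H x W plane padded to (H + 2P) x (W + 2P): an (H*W) x k^2 matrix of
# linear indices into the padded plane, output pixels in column-major order.
conv_patch_index <- function(H, W, k) {
  P <- (k - 1L) %/% 2L
  Hp <- H + 2L * P
  oi <- rep(seq_len(H), times = W)
  oj <- rep(seq_len(W), each = H)
  idx <- matrix(0L, H * W, k * k)
  col <- 0L
  for (dc in 0:(k - 1L)) for (dr in 0:(k - 1L)) {
    col <- col + 1L
    idx[, col] <- (oj + dc - 1L) * Hp + (oi + dr)
  }
  idx
}

pad_zero <- function(x, P) {
  if (P == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2L * P, d[2] + 2L * P, d[3]))
  out[P + seq_len(d[1]), P + seq_len(d[2]), ] <- x
  out
}

# x: (H, W, Cin); returns (H*W) x (k*k*Cin) with channel-major column blocks
im2col <- function(x, k, idx) {
  d <- dim(x)
  P <- (k - 1L) %/% 2L
  xp <- pad_zero(x, P)
  cols <- vector("list", d[3])
  for (c in seq_len(d[3])) {
    plane <- xp[, , c]
    cols[[c]] <- matrix(plane[idx], nrow = d[1] * d[2])
  }
  do.call(cbind, cols)
}

conv_init <- function(k, cin, cout) {
  # He initialization for ReLU stacks
  fan_in <- k * k * cin
  list(W = matrix(rnorm(fan_in * cout, 0, sqrt(2 / fan_in)), fan_in, cout),
       b = numeric(cout), k = as.integer(k), cin = as.integer(cin),
       cout = as.integer(cout))
}

conv_forward <- function(x, p, cache = FALSE) {
  d <- dim(x)
  idx <- conv_patch_index(d[1], d[2], p$k)
  X <- im2col(x, p$k, idx)
  out <- X %*% p$W
  out <- sweep(out, 2L, p$b, "+")
  res <- array(out, c(d[1], d[2], p$cout))
  if (cache) attr(res, "cache") <- list(X = X, idx = idx, din = d)
  res
}

conv_backward <- function(dout, p, cache) {
  d <- cache$din
  dmat <- matrix(dout, d[1] * d[2], p$cout)
  dW <- crossprod(cache$X, dmat)
  db <- colSums(dmat)
  dX <- dmat %*% t(p$W)                       # (H*W) x (k^2*Cin)
  P <- (p$k - 1L) %/% 2L
  Hp <- d[1] + 2L * P; Wp <- d[2] + 2L * P
  dx <- array(0, d)
  kk <- p$k * p$k
  gidx <- as.vector(cache$idx)
  for (c in seq_len(d[3])) {
    block <- dX[, (c - 1L) * kk + seq_len(kk)]
    acc <- rowsum(as.vector(block), gidx)
    plane <- numeric(Hp * Wp)
    plane[as.integer(rownames(acc))] <- acc
    dim(plane) <- c(Hp, Wp)
    dx[, , c] <- plane[P + seq_len(d[1]), P + seq_len(d[2])]
  }
  list(dx = dx, dW = dW, db = db)
}

relu_forward <- function(x) pmax(x, 0)
relu_backward <- function(dout, x) dout * (x > 0)

#' Nearest-neighbor upsampling
#'
#' Enlarges an H x W (x C) tensor by integer factor `s` by pixel
#' replication: output position `(i, j)` (0-based) takes the input value at
#' `(floor(i/s), floor(j/s))`.
#'
#' @param x Matrix or (H, W, C) array.
#' @param s Integer factor >= 1.
#' @return Upsampled array of dim (H*s, W*s, C) (matrix in, matrix out).
#' @export
upsample_nn <- function(x, s) {
  s <- as.integer(s)
  was_mat <- is.matrix(x)
  x <- as_hwc(x)
  d <- dim(x)
  out <- x[rep(seq_len(d[1]), each = s), rep(seq_len(d[2]), each = s), ,
           drop = FALSE]
  if (was_mat) out <- out[, , 1L]
  out
}

# reduce non-overlapping s x s blocks of (H, W, C) with binary op `f`
block_reduce <- function(x, s, f) {
  d <- dim(x)
  a <- array(x, c(s, d[1] %/% s, d[2], d[3]))
  m <- a[1, , , , drop = FALSE]
  if (s > 1) for (r in 2:s) m <- f(m, a[r, , , , drop = FALSE])
  m <- array(m, c(d[1] %/% s, d[2], d[3]))
  m <- aperm(m, c(2L, 1L, 3L))                 # (W, H/s, C)
  a <- array(m, c(s, d[2] %/% s, d[1] %/% s, d[3]))
  m <- a[1, , , , drop = FALSE]
  if (s > 1) for (r in 2:s) m <- f(m, a[r, , , , drop = FALSE])
  m <- array(m, c(d[2] %/% s, d[1] %/% s, d[3]))
  aperm(m, c(2L, 1L, 3L))
}

#' Max pooling with window equal to stride
#'
#' Partitions the spatial plane into non-overlapping `s x s` windows and
#' keeps each window's maximum. Spatial dimensions must be divisible by `s`.
#'
#' @param x Matrix or (H, W, C) array.
#' @param s Integer window/stride.
#' @return Pooled array of dim (H/s, W/s, C).
#' @export
maxpool <- function(x, s) {
  s <- as.integer(s)
  was_mat <- is.matrix(x)
  x <- as_hwc(x)
  d <- dim(x)
  if (d[1] %% s != 0 || d[2] %% s != 0)
    stop("spatial dimensions must be divisible by the pool size")
  out <- block_reduce(x, s, pmax)
  if (was_mat) out <- out[, , 1L]
  out
}

maxpool_backward <- function(dout, x, out, s) {
  up <- upsample_nn(out, s)
  mask <- (x == up) * 1
  counts <- block_reduce(mask, s, `+`)
  upsample_nn(dout / counts, s) * mask
}

upsample_backward <- function(dout, s) block_reduce(dout, s, `+`)

gap_forward <- function(x) {
  d <- dim(x)
  colMeans(matrix(x, d[1] * d[2], d[3]))
}
gap_backward <- function(dout, d) {
  array(rep(dout, each = d[1] * d[2]) / (d[1] * d[2]), d)
}

dense_init <- function(cin, cout) {
  list(W = matrix(rnorm(cin * cout, 0, sqrt(1 / cin)), cin, cout),
       b = numeric(cout))
}
dense_forward <- function(v, p) as.vector(v %*% p$W) + p$b
dense_backward <- function(dout, v, p) {
  list(dv = as.vector(p$W %*% dout), dW = outer(v, dout), db = dout)
}

#' Softmax probabilities
#'
#' `softmax(z)_i = exp(z_i) / sum_j exp(z_j)`, computed with the usual
#' max-shift for numerical stability.
#'
#' @param z Numeric vector of logits.
#' @return Probability vector summing to 1.
#' @export
softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

#' Sparse categorical cross-entropy
#'
#' Mean negative log-probability of the true integer class:
#' `-log p[label]`, averaged over samples. The loss of the uniform K-class
#' prediction is `log(K)` (about 1.3863 for K = 4), the plateau a diverged
#' classifier settles at.
#'
#' @param probs Numeric vector (one sample) or N x K matrix of class
#'   probabilities.
#' @param labels Integer labels in 0..K-1.
#' @return Mean cross-entropy (a single number).
#' @export
sparse_categorical_crossentropy <- function(probs, labels) {
  if (is.vector(probs)) probs <- matrix(probs, nrow = 1)
  stopifnot(nrow(probs) == length(labels))
  p <- probs[cbind(seq_len(nrow(probs)), as.integer(labels) + 1L)]
  mean(-log(pmax(p, 1e-12)))
}

## ---- batched paths -----------------------------------------------------
## A mini-batch is stored as an (H, W, C, B) array. Pointwise and pooling
## ops reuse the 3-D kernels by collapsing the trailing channel and batch
## dims (column-major layout makes that a free reshape); convolutions stack
## the per-image im2col blocks into one matrix so each layer costs one BLAS
## multiplication per batch.

stack_batch <- function(xs) {
  d <- dim(xs[[1]])
  array(unlist(xs, use.names = FALSE), c(d, length(xs)))
}

collapse_cb <- function(x) {
  d <- dim(x)
  array(x, c(d[1], d[2], d[3] * d[4]))
}
expand_cb <- function(x, C, B) {
  d <- dim(x)
  array(x, c(d[1], d[2], C, B))
}

conv_forward_b <- function(x, p, cache = FALSE) {
  d <- dim(x)                                  # H W C B
  HW <- d[1] * d[2]
  idx <- conv_patch_index(d[1], d[2], p$k)
  X <- matrix(0, d[4] * HW, p$k * p$k * d[3])
  for (b in seq_len(d[4])) {
    xb <- x[, , , b, drop = FALSE]
    dim(xb) <- d[1:3]
    X[(b - 1L) * HW + seq_len(HW), ] <- im2col(xb, p$k, idx)
  }
  out <- X %*% p$W
  out <- sweep(out, 2L, p$b, "+")
  # rows are ordered batch-major: reshape to (H, W, B, Cout) then put the
  # channel axis back before the batch axis
  res <- aperm(array(out, c(d[1], d[2], d[4], p$cout)), c(1L, 2L, 4L, 3L))
  if (cache) attr(res, "cache") <- list(X = X, idx = idx, din = d)
  res
}

conv_backward_b <- function(dout, p, cache) {
  d <- cache$din
  HW <- d[1] * d[2]
  dmat <- matrix(aperm(dout, c(1L, 2L, 4L, 3L)), d[4] * HW, p$cout)
  dW <- crossprod(cache$X, dmat)
  db <- colSums(dmat)
  dX <- dmat %*% t(p$W)
  P <- (p$k - 1L) %/% 2L
  Hp <- d[1] + 2L * P; Wp <- d[2] + 2L * P
  kk <- p$k * p$k
  # one scatter-add per input channel across the whole batch; element
  # order must match dX's batch-major rows flattened column by column
  gidx_arr <- vapply(seq_len(d[4]), function(b)
    cache$idx + (b - 1L) * Hp * Wp, cache$idx)   # (HW, kk, B)
  gidx <- as.vector(aperm(gidx_arr, c(1L, 3L, 2L)))
  dx <- array(0, d)
  for (c in seq_len(d[3])) {
    block <- dX[, (c - 1L) * kk + seq_len(kk)]
    # rows of dX are batch-major: expand idx accordingly
    vals <- rowsum(as.vector(block), gidx)
    planes <- numeric(Hp * Wp * d[4])
    planes[as.integer(rownames(vals))] <- vals
    dim(planes) <- c(Hp, Wp, d[4])
    dx[, , c, ] <- planes[P + seq_len(d[1]), P + seq_len(d[2]), ,
                          drop = FALSE]
  }
  list(dx = dx, dW = dW, db = db)
}

maxpool_b <- function(x, s) {
  d <- dim(x)
  expand_cb(maxpool(collapse_cb(x), s), d[3], d[4])
}
maxpool_backward_b <- function(dout, x, out, s) {
  d <- dim(x)
  expand_cb(maxpool_backward(collapse_cb(dout), collapse_cb(x),
                             collapse_cb(out), s), d[3], d[4])
}
upsample_b <- function(x, s) {
  d <- dim(x)
  expand_cb(upsample_nn(collapse_cb(x), s), d[3], d[4])
}
upsample_backward_b <- function(dout, s) {
  d <- dim(dout)
  expand_cb(upsample_backward(collapse_cb(dout), s), d[3], d[4])
}

# forward a whole mini-batch; returns probs (B x K), embeddings (B x E)
# and, when cache = TRUE, the per-layer caches for the backward pass
nn_forward_batch <- function(model, xs, cache = FALSE) {
  x <- if (is.list(xs)) stack_batch(xs) else xs
  caches <- if (cache) vector("list", length(model$layers))
  embedding <- NULL
  for (li in seq_along(model$layers)) {
    l <- model$layers[[li]]
    if (l$type == "conv") {
      pre <- conv_forward_b(x, l, cache = cache)
      if (cache) caches[[li]] <- list(x_cache = attr(pre, "cache"),
                                      pre = pre)
      x <- if (identical(l$act, "relu")) relu_forward(pre) else pre
    } else if (l$type == "maxpool") {
      out <- maxpool_b(x, l$s)
      if (cache) caches[[li]] <- list(xin = x, out = out)
      x <- out
    } else if (l$type == "ippm") {
      # identity shortcut: see the single-image ippm branch
      lvl <- vector("list", length(l$pool_sizes))
      lcache <- vector("list", length(l$pool_sizes))
      for (i in seq_along(l$pool_sizes)) {
        f <- conv_forward_b(x, l$convs[[i]], cache = cache)
        lvl[[i]] <- f
        if (cache) lcache[[i]] <- list(conv_cache = attr(f, "cache"))
      }
      if (l$include_identity) lvl[[length(lvl) + 1L]] <- x
      d <- dim(x)
      ctot <- sum(vapply(lvl, function(t) dim(t)[3], 0))
      out <- array(0, c(d[1], d[2], ctot, d[4]))
      off <- 0L
      for (t in lvl) {
        nf <- dim(t)[3]
        out[, , off + seq_len(nf), ] <- t
        off <- off + nf
      }
      if (cache) caches[[li]] <- list(xin = x, levels = lcache)
      x <- out
    } else if (l$type == "gap") {
      d <- dim(x)
      if (cache) caches[[li]] <- list(din = d)
      embedding <- t(matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])),
                            d[3], d[4]))          # B x C
      x <- embedding
    } else if (l$type == "dense") {
      if (cache) caches[[li]] <- list(vin = x)
      x <- sweep(x %*% l$W, 2L, l$b, "+")
    }
  }
  probs <- t(apply(x, 1L, softmax))
  list(logits = x, probs = probs, embedding = embedding, caches = caches)
}

# backward for a whole batch from the softmax cross-entropy gradients;
# grads are summed over the batch (caller divides)
nn_backward_batch <- function(model, fwd, labels) {
  B <- nrow(fwd$probs)
  grads <- vector("list", length(model$layers))
  d <- fwd$probs
  d[cbind(seq_len(B), labels + 1L)] <- d[cbind(seq_len(B), labels + 1L)] - 1
  for (li in rev(seq_along(model$layers))) {
    l <- model$layers[[li]]
    cc <- fwd$caches[[li]]
    if (l$type == "dense") {
      grads[[li]] <- list(dW = crossprod(cc$vin, d), db = colSums(d))
      d <- d %*% t(l$W)                          # B x cin
    } else if (l$type == "gap") {
      dd <- cc$din
      # expand each sample's vector over its spatial plane
      d <- aperm(array(rep(t(d), each = dd[1] * dd[2]) / (dd[1] * dd[2]),
                       c(dd[1], dd[2], dd[3], dd[4])), c(1L, 2L, 3L, 4L))
    } else if (l$type == "ippm") {
      dx_total <- array(0, dim(cc$xin))
      off <- 0L
      for (i in seq_along(l$pool_sizes)) {
        s <- l$pool_sizes[i]
        nf <- l$convs[[i]]$cout
        dslice <- d[, , off + seq_len(nf), , drop = FALSE]
        off <- off + nf
        g <- conv_backward_b(dslice, l$convs[[i]], cc$levels[[i]]$conv_cache)
        dx_total <- dx_total + g$dx
        grads[[li]]$convs[[i]] <- list(dW = g$dW, db = g$db)
      }
      if (l$include_identity) {
        nf <- dim(cc$xin)[3]
        dx_total <- dx_total + d[, , off + seq_len(nf), , drop = FALSE]
      }
      d <- dx_total
    } else if (l$type == "maxpool") {
      d <- maxpool_backward_b(d, cc$xin, cc$out, l$s)
    } else if (l$type == "conv") {
      if (identical(l$act, "relu")) d <- relu_backward(d, cc$pre)
      g <- conv_backward_b(d, l, cc$x_cache)
      grads[[li]] <- list(dW = g$dW, db = g$db)
      d <- g$dx
    }
  }
  grads
}
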