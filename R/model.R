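#' Inverted pyramid pooling module configuration
#'
#' The iPPM refines a backbone feature map at several scales: for each pool
#' size `s` it nearest-neighbor upsamples by `s`, max-pools with window and
#' stride `s` (restoring the original spatial size), applies a `k x k`
#' convolution that compresses the channels, and concatenates the per-level
#' outputs channel-wise.
#'
#' @param pool_sizes Integer upsampling/pooling factors (default 2, 3, 4, 6).
#' @param level_filters Output channels of each level's convolution
#'   (default 128, so the default four levels concatenate back to 512).
#' @param level_kernel Kernel size of the per-level convolution (default 1).
#' @param include_identity Optionally append the unprocessed input to the
#'   concatenation (off by default: the module concatenates the per-level
#'   outputs only).
#' @return An object of class `ippm_config`.
#' @export
ippm_config <- function(pool_sizes = c(2L, 3L, 4L, 6L), level_filters = 128L,
                        level_kernel = 1L, include_identity = FALSE) {
  stopifnot(length(pool_sizes) >= 1, all(pool_sizes >= 2), level_filters >= 1,
            level_kernel %% 2 == 1)
  structure(list(pool_sizes = as.integer(pool_sizes),
                 level_filters = as.integer(level_filters),
                 level_kernel = as.integer(level_kernel),
                 include_identity = isTRUE(include_identity)),
            class = "ippm_config")
}

#' Model configuration
#'
#' @param input_size Input image side length in pixels.
#' @param input_channels 1 for native grayscale input; 3 replicates the gray
#'   channel (the convention when a 3-channel pretrained backbone is used).
#' @param pretrained_backbone If TRUE, ImageNet-pretrained VGG19
#'   convolutional weights are required; this package does not bundle them,
#'   so requesting them raises an explicit error naming the missing
#'   resource. Random (He) initialization is the default.
#' @param backbone_variant `"vgg19"` for the full 16-convolution,
#'   5-max-pool stack, or `"tiny"` for a 2-block CPU-scale stack with the
#'   same head and iPPM contracts.
#' @param ippm An [ippm_config()].
#' @param head_filters Two filter counts for the 3x3 convolutions after the
#'   iPPM (default 256 and 128).
#' @param num_classes Number of output classes.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `model_config`.
#' @export
model_config <- function(input_size = 128L, input_channels = 1L,
                         pretrained_backbone = FALSE,
                         backbone_variant = c("vgg19", "tiny"),
                         ippm = ippm_config(), head_filters = c(256L, 128L),
                         num_classes = 4L, seed = 1L) {
  backbone_variant <- match.arg(backbone_variant)
  stopifnot(num_classes >= 2, length(head_filters) == 2,
            input_channels %in% c(1L, 3L), input_size >= 16)
  structure(list(input_size = as.integer(input_size),
                 input_channels = as.integer(input_channels),
                 pretrained_backbone = isTRUE(pretrained_backbone),
                 backbone_variant = backbone_variant, ippm = ippm,
                 head_filters = as.integer(head_filters),
                 num_classes = as.integer(num_classes),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Tiny CPU-scale model preset
#'
#' A reduced configuration for desk-scale runs: 32 x 32 input, a two-block
#' 32/64-filter backbone, 32-filter iPPM levels and a 64/32 head. Contracts (layer
#' order, iPPM structure, softmax head) are identical to the full model.
#'
#' @param seed Integer seed for weight initialization.
#' @param num_classes Number of classes.
#' @return A `model_config`.
#' @export
tiny_model_config <- function(seed = 1L, num_classes = 4L) {
  model_config(input_size = 32L, backbone_variant = "tiny",
               ippm = ippm_config(level_filters = 32L),
               head_filters = c(64L, 32L), num_classes = num_classes,
               seed = seed)
}

# Backbone layer plans: conv entries are filter counts, "P" is a 2x2/2 pool.
backbone_plan <- function(variant) {
  switch(variant,
    vgg19 = list(c(64, 64, "P"), c(128, 128, "P"), c(256, 256, 256, 256, "P"),
                 c(512, 512, 512, 512, "P"), c(512, 512, 512, 512, "P")),
    tiny = list(c(32, "P"), c(64, "P")),
    stop("unknown backbone variant: ", variant))
}

#' Build the convolutional backbone
#'
#' Constructs the VGG19 feature extractor: sixteen 3x3 convolutions with
#' ReLU activations interleaved with five 2x2 max-pooling layers, truncated
#' after the fifth pool; the fully-connected stack is discarded because the
#' pyramid pooling module consumes a spatial feature map. A 128 x 128 input
#' yields a 4 x 4 x 512 output. The `"tiny"` variant is a two-block stack
#' with the same layer grammar.
#'
#' @param config A [model_config()].
#' @return List with `layers` (layer descriptors with weights),
#'   `out_channels` and `out_size`.
#' @export
build_backbone <- function(config) {
  stopifnot(inherits(config, "model_config"))
  if (config$pretrained_backbone)
    stop("pretrained_backbone = TRUE requires the ImageNet-pretrained ",
         "VGG19 convolutional weights, which are not bundled with this ",
         "package; supply them or use random initialization")
  plan <- backbone_plan(config$backbone_variant)
  layers <- list()
  cin <- config$input_channels
  size <- config$input_size
  for (block in plan) {
    for (item in block) {
      if (item == "P") {
        layers[[length(layers) + 1L]] <- list(type = "maxpool", s = 2L)
        size <- size %/% 2L
      } else {
        cout <- as.integer(item)
        layers[[length(layers) + 1L]] <-
          c(list(type = "conv", act = "relu"), conv_init(3L, cin, cout))
        cin <- cout
      }
    }
  }
  list(layers = layers, out_channels = cin, out_size = size)
}

#' One iPPM pyramid level
#'
#' Nearest-neighbor upsample by `s`, max-pool with window and stride `s`
#' (restoring H x W), then a `k x k` convolution with `filters` outputs.
#' Because the pooling windows align exactly with the replicated blocks,
#' the upsample-pool composition is an identity map, so this level equals a
#' `k x k` convolution of its input; the module is implemented as literally
#' specified and that algebraic identity is part of its tested contract.
#'
#' @param fmap (H, W, C) array.
#' @param s Integer factor >= 2.
#' @param conv_params Convolution parameters from `conv_init()`.
#' @return (H, W, filters) array.
#' @export
ippm_level <- function(fmap, s, conv_params) {
  stopifnot(s >= 2)
  pooled <- maxpool(upsample_nn(as_hwc(fmap), s), s)
  conv_forward(pooled, conv_params)
}

#' Build the full NeuroNet19 classifier
#'
#' Backbone, iPPM, a 3x3/ReLU convolution pair (`head_filters`), global
#' average pooling and a softmax dense layer over `num_classes`. Weight
#' initialization is deterministic in `config$seed`.
#'
#' @param config A [model_config()].
#' @return An object of class `nn19_model`.
#' @export
build_neuronet19 <- function(config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  local_seed(config$seed, {
    bb <- build_backbone(config)
    layers <- bb$layers
    ip <- config$ippm
    level_convs <- lapply(ip$pool_sizes, function(s)
      conv_init(ip$level_kernel, bb$out_channels, ip$level_filters))
    layers[[length(layers) + 1L]] <-
      list(type = "ippm", pool_sizes = ip$pool_sizes, convs = level_convs,
           include_identity = ip$include_identity)
    cin <- length(ip$pool_sizes) * ip$level_filters +
      if (ip$include_identity) bb$out_channels else 0L
    for (f in config$head_filters) {
      layers[[length(layers) + 1L]] <-
        c(list(type = "conv", act = "relu"), conv_init(3L, cin, f))
      cin <- f
    }
    layers[[length(layers) + 1L]] <- list(type = "gap")
    layers[[length(layers) + 1L]] <-
      c(list(type = "dense"), dense_init(cin, config$num_classes))
    structure(list(config = config, layers = layers,
                   embedding_dim = cin), class = "nn19_model")
  })
}

# Forward pass; with cache = TRUE also returns per-layer caches for the
# backward pass. Input x: (H, W, C) array scaled to [0, 1].
nn_forward <- function(model, x, cache = FALSE) {
  caches <- if (cache) vector("list", length(model$layers))
  embedding <- NULL
  for (li in seq_along(model$layers)) {
    l <- model$layers[[li]]
    if (l$type == "conv") {
      pre <- conv_forward(x, l, cache = cache)
      if (cache) caches[[li]] <- list(x_cache = attr(pre, "cache"), pre = pre)
      x <- if (identical(l$act, "relu")) relu_forward(pre) else pre
    } else if (l$type == "maxpool") {
      out <- maxpool(x, l$s)
      if (cache) caches[[li]] <- list(xin = x, out = out)
      x <- out
    } else if (l$type == "ippm") {
      lvl <- vector("list", length(l$pool_sizes))
      lcache <- vector("list", length(l$pool_sizes))
      for (i in seq_along(l$pool_sizes)) {
        s <- l$pool_sizes[i]
        up <- upsample_nn(x, s)
        pooled <- maxpool(up, s)
        f <- conv_forward(pooled, l$convs[[i]], cache = cache)
        lvl[[i]] <- f
        if (cache) lcache[[i]] <- list(up = up, pooled = pooled,
                                       conv_cache = attr(f, "cache"))
      }
      if (l$include_identity) lvl[[length(lvl) + 1L]] <- x
      d <- dim(x)
      out <- array(unlist(lvl), c(d[1], d[2],
                                  sum(vapply(lvl, function(t) dim(t)[3], 0))))
      if (cache) caches[[li]] <- list(xin = x, levels = lcache)
      x <- out
    } else if (l$type == "gap") {
      if (cache) caches[[li]] <- list(din = dim(x))
      embedding <- gap_forward(x)
      x <- embedding
    } else if (l$type == "dense") {
      if (cache) caches[[li]] <- list(vin = x)
      x <- dense_forward(x, l)
    }
  }
  probs <- softmax(x)
  list(logits = x, probs = probs, embedding = embedding, caches = caches)
}

# Backward pass from the softmax cross-entropy gradient; returns grads as a
# list parallel to model$layers (NULL for parameter-free layers).
nn_backward <- function(model, fwd, label) {
  grads <- vector("list", length(model$layers))
  d <- fwd$probs
  d[label + 1L] <- d[label + 1L] - 1        # d loss / d logits
  for (li in rev(seq_along(model$layers))) {
    l <- model$layers[[li]]
    cc <- fwd$caches[[li]]
    if (l$type == "dense") {
      g <- dense_backward(d, cc$vin, l)
      grads[[li]] <- list(dW = g$dW, db = g$db)
      d <- g$dv
    } else if (l$type == "gap") {
      d <- gap_backward(d, cc$din)
    } else if (l$type == "ippm") {
      dx_total <- array(0, dim(cc$xin))
      off <- 0L
      for (i in seq_along(l$pool_sizes)) {
        s <- l$pool_sizes[i]
        nf <- l$convs[[i]]$cout
        dslice <- d[, , off + seq_len(nf), drop = FALSE]
        off <- off + nf
        g <- conv_backward(dslice, l$convs[[i]], cc$levels[[i]]$conv_cache)
        dpool <- maxpool_backward(g$dx, cc$levels[[i]]$up,
                                  cc$levels[[i]]$pooled, s)
        dx_total <- dx_total + upsample_backward(dpool, s)
        grads[[li]]$convs[[i]] <- list(dW = g$dW, db = g$db)
      }
      if (l$include_identity) {
        nf <- dim(cc$xin)[3]
        dx_total <- dx_total + d[, , off + seq_len(nf), drop = FALSE]
      }
      d <- dx_total
    } else if (l$type == "maxpool") {
      d <- maxpool_backward(d, cc$xin, cc$out, l$s)
    } else if (l$type == "conv") {
      if (identical(l$act, "relu")) d <- relu_backward(d, cc$pre)
      g <- conv_backward(d, l, cc$x_cache)
      grads[[li]] <- list(dW = g$dW, db = g$db)
      d <- g$dx
    }
  }
  grads
}

# Convert a [0, 255] gray matrix to the model's input tensor: resize to the
# input resolution, scale to [0, 1], then sample-wise standardize (zero
# mean, unit variance per image). Centering matters for optimization: with
# all-positive inputs and zero-init biases the first-layer gradients are
# strongly correlated and training stalls.
model_input <- function(model, image) {
  cfg <- model$config
  px <- resize_gray(as_gray_matrix(image), cfg$input_size) / 255
  px <- (px - mean(px)) / (stats::sd(px) + 1e-6)
  if (cfg$input_channels == 1L) array(px, c(dim(px), 1L))
  else array(rep(px, 3L), c(dim(px), 3L))
}

#' Class probabilities for a batch of images
#'
#' @param model An `nn19_model`.
#' @param images List of gray matrices in \[0, 255\] (any size; resized to
#'   the model input size).
#' @param chunk Mini-batch size used for the forward passes.
#' @return N x K matrix of softmax probabilities (rows sum to 1).
#' @export
predict_proba <- function(model, images, chunk = 32L) {
  stopifnot(inherits(model, "nn19_model"))
  if (!is.list(images)) images <- list(images)
  inputs <- lapply(images, function(im) model_input(model, im))
  n <- length(inputs)
  probs <- matrix(0, n, model$config$num_classes)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    probs[idx, ] <- nn_forward_batch(model, inputs[idx])$probs
  }
  probs
}

#' Penultimate-layer embeddings
#'
#' Global-average-pooled feature vectors (length `head_filters[2]`, 128 for
#' the default configuration), one row per image, row order preserved.
#' These are the vectors a downstream projection (e.g. t-SNE) would consume.
#'
#' @param model An `nn19_model`.
#' @param images List of gray matrices.
#' @param chunk Mini-batch size used for the forward passes.
#' @return N x `embedding_dim` matrix.
#' @export
extract_embeddings <- function(model, images, chunk = 32L) {
  stopifnot(inherits(model, "nn19_model"))
  if (!is.list(images)) images <- list(images)
  inputs <- lapply(images, function(im) model_input(model, im))
  n <- length(inputs)
  emb <- matrix(0, n, model$embedding_dim)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    emb[idx, ] <- nn_forward_batch(model, inputs[idx])$embedding
  }
  emb
}

#' Save / load model checkpoints
#'
#' Checkpoints are written with R's native serialization (`saveRDS`).
#'
#' @param model An `nn19_model`.
#' @param path File path.
#' @return `load_checkpoint` returns the model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

#' One-line-per-layer architecture summary
#'
#' @param object An `nn19_model`.
#' @param ... Unused.
#' @export
summary.nn19_model <- function(object, ...) {
  for (l in object$layers) {
    desc <- switch(l$type,
      conv = sprintf("conv %dx%d, %d -> %d filters, %s", l$k, l$k, l$cin,
                     l$cout, l$act %||% "linear"),
      maxpool = sprintf("maxpool %dx%d / stride %d", l$s, l$s, l$s),
      ippm = sprintf("iPPM levels s = {%s}, %d filters each",
                     paste(l$pool_sizes, collapse = ","),
                     l$convs[[1]]$cout),
      gap = "global average pooling",
      dense = sprintf("dense %d -> %d + softmax", nrow(l$W), ncol(l$W)))
    cat(desc, "\n")
  }
  invisible(object)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
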