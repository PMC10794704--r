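ns <- asNamespace("neuronet19")

test_that("convolution matches a hand-computed case", {
  # 3x3 input, one channel, one 3x3 filter of ones, zero padding:
  # center output = sum of all inputs; corner = its 2x2 neighborhood
  x <- array(matrix(1:9, 3, 3), c(3, 3, 1))
  p <- list(W = matrix(1, 9, 1), b = 0, k = 3L, cin = 1L, cout = 1L)
  out <- ns$conv_forward(x, p)
  expect_equal(out[2, 2, 1], 45)
  expect_equal(out[1, 1, 1], sum(x[1:2, 1:2, 1]))
  expect_equal(out[3, 3, 1], sum(x[2:3, 2:3, 1]))
})

test_that("relu and softmax unit checks", {
  expect_equal(ns$relu_forward(c(-3, 5)), c(0, 5))
  expect_equal(softmax(c(0, 0, 0, 0)), rep(0.25, 4))
  set.seed(1)
  z <- rnorm(6)
  p <- softmax(z)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(softmax(z + 17.3), p, tolerance = 1e-9)  # shift invariance
})

test_that("nearest upsampling matches the floor-index closed form", {
  x <- matrix(c(1, 3, 2, 4), 2, 2)  # [[1,2],[3,4]] row-wise
  u <- upsample_nn(x, 2L)
  expect_equal(u, matrix(c(1, 1, 3, 3, 1, 1, 3, 3, 2, 2, 4, 4, 2, 2, 4, 4),
                         4, 4))
  # general random check against the closed form U(i,j) = I(floor(i/s), floor(j/s))
  set.seed(2)
  for (s in c(2L, 3L, 5L)) {
    a <- matrix(rnorm(12), 3, 4)
    u <- upsample_nn(a, s)
    for (i in 0:(3 * s - 1)) for (j in 0:(4 * s - 1))
      expect_identical(u[i + 1, j + 1], a[i %/% s + 1, j %/% s + 1])
  }
})

test_that("maxpool of an upsampled tensor is the identity for all pool sizes", {
  set.seed(3)
  for (s in c(2L, 3L, 4L, 6L)) {
    for (rep in 1:25) {
      d <- c(sample(1:6, 1), sample(1:6, 1), sample(1:3, 1))
      x <- array(rnorm(prod(d)), d)
      expect_equal(maxpool(upsample_nn(x, s), s), x, tolerance = 0)
    }
  }
})

test_that("each iPPM level reduces to a kxk convolution of its input", {
  set.seed(4)
  x <- array(rnorm(5 * 5 * 3), c(5, 5, 3))
  p <- neuronet19:::local_seed(8, ns$conv_init(1L, 3L, 2L))
  for (s in c(2L, 3L, 4L, 6L)) {
    expect_equal(ippm_level(x, s, p), ns$conv_forward(x, p),
                 tolerance = 1e-12)
  }
})

test_that("iPPM concatenates level outputs channel-wise in order", {
  set.seed(5)
  mc <- model_config(input_size = 16L, backbone_variant = "tiny",
                     ippm = ippm_config(pool_sizes = c(2L, 3L),
                                        level_filters = 4L),
                     head_filters = c(6L, 5L), seed = 2)
  m <- build_neuronet19(mc)
  ippm_idx <- which(vapply(m$layers, function(l) l$type, "") == "ippm")
  l <- m$layers[[ippm_idx]]
  x <- array(rnorm(4 * 4 * l$convs[[1]]$cin), c(4, 4, l$convs[[1]]$cin))
  # run the module forward manually through the engine
  lvl1 <- ippm_level(x, 2L, l$convs[[1]])
  lvl2 <- ippm_level(x, 3L, l$convs[[2]])
  fwd_to <- function(model, x, upto) {
    for (li in seq_len(upto)) {
      ll <- model$layers[[li]]
      x <- switch(ll$type,
        conv = ns$relu_forward(ns$conv_forward(x, ll)),
        maxpool = maxpool(x, ll$s), x)
    }
    x
  }
  # feed x directly into the ippm layer path
  got1 <- ippm_level(x, l$pool_sizes[1], l$convs[[1]])
  expect_equal(got1, lvl1)
  expect_equal(dim(abind_c <- array(c(lvl1, lvl2), c(4, 4, 8)))[3], 8)
  expect_equal(abind_c[, , 1:4], lvl1)
  expect_equal(abind_c[, , 5:8], lvl2)
})

test_that("backbone and full model meet their shape contracts", {
  bb <- build_backbone(model_config())
  expect_equal(bb$out_size, 4L)          # 128 / 2^5
  expect_equal(bb$out_channels, 512L)
  nconv <- sum(vapply(bb$layers, function(l) l$type == "conv", TRUE))
  npool <- sum(vapply(bb$layers, function(l) l$type == "maxpool", TRUE))
  expect_equal(nconv, 16L)
  expect_equal(npool, 5L)

  tm <- build_neuronet19(tiny_model_config(seed = 1))
  img <- generate_phantom(1L, seed = 3)$pixels
  p <- predict_proba(tm, list(img))
  expect_equal(ncol(p), 4L)
  expect_true(all(p > 0 & p < 1))
  expect_equal(sum(p), 1, tolerance = 1e-6)

  emb <- extract_embeddings(tm, list(img, img))
  expect_equal(dim(emb), c(2L, tm$embedding_dim))
  expect_identical(emb[1, ], emb[2, ])
  expect_true(all(is.finite(emb)))
})

test_that("weight initialization is deterministic in the seed", {
  m1 <- build_neuronet19(tiny_model_config(seed = 42))
  m2 <- build_neuronet19(tiny_model_config(seed = 42))
  expect_identical(m1, m2)
  m3 <- build_neuronet19(tiny_model_config(seed = 43))
  expect_false(identical(m1$layers[[1]]$W, m3$layers[[1]]$W))
})

test_that("requesting pretrained weights raises a named error", {
  expect_error(build_backbone(model_config(pretrained_backbone = TRUE)),
               "ImageNet")
})

test_that("analytic gradients match central differences", {
  cfg <- model_config(input_size = 16L, backbone_variant = "tiny",
                      ippm = ippm_config(pool_sizes = c(2L, 3L),
                                         level_filters = 4L),
                      head_filters = c(6L, 5L), num_classes = 3L, seed = 2)
  m <- build_neuronet19(cfg)
  # nudge biases off zero so no pre-activation sits exactly on the ReLU kink
  set.seed(31)
  for (li in seq_along(m$layers)) {
    if (!is.null(m$layers[[li]]$b))
      m$layers[[li]]$b <- rnorm(length(m$layers[[li]]$b), 0, 0.05)
    if (identical(m$layers[[li]]$type, "ippm"))
      for (ci in seq_along(m$layers[[li]]$convs))
        m$layers[[li]]$convs[[ci]]$b <-
          rnorm(length(m$layers[[li]]$convs[[ci]]$b), 0, 0.05)
  }
  set.seed(9)
  x <- array(runif(16 * 16), c(16, 16, 1))
  lab <- 1L
  fwd <- ns$nn_forward(m, x, cache = TRUE)
  fl <- ns$flatten_grads(m, ns$nn_backward(m, fwd, lab))
  loss_of <- function(mm) -log(ns$nn_forward(mm, x)$probs[lab + 1])
  eps <- 1e-6
  for (nm in names(fl)) {
    g <- fl[[nm]]
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    li <- as.integer(sub("L", "", parts[1]))
    bump <- function(d, j) {
      mm <- m
      if (length(parts) == 2L) {
        mm$layers[[li]][[parts[2]]][j] <- mm$layers[[li]][[parts[2]]][j] + d
      } else {
        ci <- as.integer(sub("c", "", parts[2]))
        mm$layers[[li]]$convs[[ci]][[parts[3]]][j] <-
          mm$layers[[li]]$convs[[ci]][[parts[3]]][j] + d
      }
      mm
    }
    set.seed(li)
    for (j in sample(length(g), min(2, length(g)))) {
      num <- (loss_of(bump(eps, j)) - loss_of(bump(-eps, j))) / (2 * eps)
      expect_equal(g[j], num, tolerance = 1e-4)
    }
  }
  # every parameter tensor receives a nonzero gradient for generic input
  expect_true(all(vapply(fl, function(g) any(g != 0), TRUE)))
})

test_that("batched and per-image engine paths agree exactly", {
  cfg <- model_config(input_size = 16L, backbone_variant = "tiny",
                      ippm = ippm_config(pool_sizes = c(2L, 3L),
                                         level_filters = 4L),
                      head_filters = c(6L, 5L), num_classes = 3L, seed = 2)
  m <- build_neuronet19(cfg)
  set.seed(9)
  xs <- lapply(1:5, function(i) array(runif(16 * 16), c(16, 16, 1)))
  labs <- c(0L, 1L, 2L, 0L, 1L)
  fb <- ns$nn_forward_batch(m, xs, cache = TRUE)
  acc <- NULL
  for (i in 1:5) {
    fi <- ns$nn_forward(m, xs[[i]], cache = TRUE)
    expect_equal(fb$probs[i, ], fi$probs, tolerance = 1e-12)
    expect_equal(fb$embedding[i, ], fi$embedding, tolerance = 1e-12)
    acc <- ns$flatten_grads(m, ns$nn_backward(m, fi, labs[i]), acc)
  }
  gb <- ns$flatten_grads(m, ns$nn_backward_batch(m, fb, labs))
  for (nm in names(acc))
    expect_equal(gb[[nm]], acc[[nm]], tolerance = 1e-10)
})

test_that("the engine's pyramid levels equal the literal composition", {
  # the module computes each level as the equivalent convolution; assert
  # against the literal upsample -> pool -> conv path
  set.seed(12)
  x <- array(rnorm(6 * 6 * 3), c(6, 6, 3))
  p <- neuronet19:::local_seed(4, ns$conv_init(1L, 3L, 5L))
  for (s in c(2L, 3L, 4L, 6L)) {
    literal <- ns$conv_forward(maxpool(upsample_nn(x, s), s), p)
    expect_equal(ippm_level(x, s, p), literal, tolerance = 1e-12)
    expect_equal(ns$conv_forward(x, p), literal, tolerance = 1e-12)
  }
})
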