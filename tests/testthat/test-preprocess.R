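test_that("standardize enforces shape and identity contracts", {
  rgb <- array(runif(512 * 512 * 3), c(512, 512, 3))
  out <- standardize(rgb, 128L)
  expect_identical(dim(out), c(128L, 128L))
  expect_true(all(out >= 0L & out <= 255L))

  g <- matrix(sample(0:255, 128 * 128, TRUE), 128)
  expect_identical(standardize(g, 128L), neuronet19:::quantize_gray(g))

  wide <- matrix(runif(100 * 200) * 255, 100, 200)
  expect_identical(dim(standardize(wide, 128L)), c(128L, 128L))

  expect_error(standardize(matrix(numeric(0), 0, 0), 128L), "empty")
})

test_that("gaussian blur matches the closed-form kernel and a dense oracle", {
  # kernel: sigma = (n-1)/6, normalized
  kern <- neuronet19:::gaussian_kernel(11L)
  expect_equal(sum(kern), 1, tolerance = 1e-12)
  sigma <- 10 / 6
  expect_equal(kern[6, 6] / kern[6, 7], exp(1 / (2 * sigma^2)),
               tolerance = 1e-12)

  const <- matrix(200, 32, 32)
  expect_true(all(gaussian_blur(const, 11L) == 200L))

  # single bright pixel: response equals the kernel scaled by the value
  imp <- matrix(0, 21, 21); imp[11, 11] <- 255
  got <- gaussian_blur(imp, 5L)
  want <- round(oracle_conv2d_replicate(imp, neuronet19:::gaussian_kernel(5L)))
  expect_identical(as.integer(got), as.integer(want))

  # random image vs dense oracle
  set.seed(4)
  px <- matrix(sample(0:255, 30 * 30, TRUE), 30)
  got <- gaussian_blur(px, 7L)
  want <- round(oracle_conv2d_replicate(px, neuronet19:::gaussian_kernel(7L)))
  expect_lte(max(abs(got - want)), 1L)  # FFT vs direct rounding at .5 edges

  expect_error(gaussian_blur(px, 4L), "odd")
})

test_that("otsu threshold equals the brute-force maximizer", {
  px <- matrix(c(rep(0, 50), rep(255, 50)), 10)
  m <- otsu_threshold(px)
  expect_equal(sum(m$pixels), 50)
  expect_false(m$degenerate)
  expect_identical(m$threshold_used, oracle_otsu(px))

  px2 <- matrix(c(rep(10, 12), rep(200, 4)), 4)
  m2 <- otsu_threshold(px2)
  expect_equal(sum(m2$pixels), 4)

  expect_true(otsu_threshold(matrix(128, 5, 5))$degenerate)

  set.seed(99)
  for (i in 1:200) {
    px <- matrix(sample(0:255, 256, TRUE, prob = runif(256)^2), 16)
    expect_identical(otsu_threshold(px)$threshold_used, oracle_otsu(px))
  }
})

test_that("between-class plus within-class variance equals total variance", {
  set.seed(12)
  for (i in 1:20) {
    v <- sample(0:255, 256, TRUE)
    n <- length(v)
    tot <- mean((v - mean(v))^2)
    for (t in sample(unique(v)[-length(unique(v))], 5, replace = TRUE)) {
      lo <- v[v <= t]; hi <- v[v > t]
      if (!length(lo) || !length(hi)) next
      w1 <- length(lo) / n; w2 <- length(hi) / n
      between <- w1 * w2 * (mean(lo) - mean(hi))^2
      within <- w1 * mean((lo - mean(lo))^2) + w2 * mean((hi - mean(hi))^2)
      expect_equal(between + within, tot, tolerance = 1e-9)
    }
  }
})

test_that("brain_roi selects by filled area with deterministic tie-breaks", {
  m <- matrix(FALSE, 60, 80)
  m[5:34, 5:54] <- TRUE          # 30x50 = 1500
  m[50:54, 70:79] <- TRUE        # 50
  roi <- brain_roi(m, 1000L)
  expect_false(roi$fallback)
  expect_equal(c(roi$x, roi$y, roi$w, roi$h), c(4, 4, 50, 30))
  expect_equal(roi$area, 1500L)

  # holes count toward filled area
  mh <- matrix(FALSE, 64, 64)
  mh[10:49, 10:49] <- TRUE
  mh[20:39, 20:39] <- FALSE      # hole
  roi_h <- brain_roi(mh, 1200L)
  expect_equal(roi_h$area, 1600L)

  # nothing qualifies -> full-image fallback
  small <- matrix(FALSE, 20, 20); small[1:3, 1:3] <- TRUE
  rf <- brain_roi(small, 1000L)
  expect_true(rf$fallback)
  expect_equal(c(rf$w, rf$h), c(20, 20))

  # equal-area tie: row-major first occurrence wins
  tie <- matrix(FALSE, 30, 30)
  tie[20:24, 2:6] <- TRUE        # first pixel at row 20
  tie[2:6, 20:24] <- TRUE        # first pixel at row 2 -> wins row-major
  rt <- brain_roi(tie, 10L)
  expect_equal(c(rt$x, rt$y), c(19, 1))
})

test_that("apply_mask_and_crop zeroes background and crops to the ROI", {
  px <- matrix(sample(0:255, 40 * 40, TRUE), 40)
  full <- brain_roi(matrix(TRUE, 40, 40), 1L)
  expect_identical(apply_mask_and_crop(px, full$component, full),
                   neuronet19:::quantize_gray(px))

  m <- matrix(FALSE, 40, 40); m[11:30, 6:25] <- TRUE
  roi <- brain_roi(m, 10L)
  out <- apply_mask_and_crop(px, roi$component, roi)
  expect_identical(dim(out), c(roi$h, roi$w))
  # a pixel outside the component inside another call: mask zeroes it
  px2 <- px; px2[1, 1] <- 200
  out2 <- apply_mask_and_crop(px2, m, brain_roi(matrix(TRUE, 40, 40), 1L))
  expect_equal(out2[1, 1], 0L)
})

test_that("power law matches hand values and is monotone", {
  expect_equal(power_law(matrix(round(0.25 * 255)), 1, 1.5)[1, 1], 32L)
  px <- matrix(sample(0:255, 100, TRUE), 10)
  expect_true(all(abs(power_law(px, 1, 1) - px) <= 1))
  expect_equal(power_law(matrix(255), 1, 3.7)[1, 1], 255L)
  # monotone non-decreasing for random k, beta
  set.seed(5)
  for (i in 1:10) {
    k <- runif(1, 0.2, 2); b <- runif(1, 0.2, 3)
    y <- power_law(matrix(0:255, 1), k, b)
    expect_true(all(diff(as.vector(y)) >= 0))
  }
})

test_that("pipeline output is fixed-size, deterministic, and covers lesions", {
  cfg <- preprocess_config()
  ph <- generate_phantom("meningioma", seed = 5)
  out1 <- preprocess_pipeline(ph$pixels, cfg)
  out2 <- preprocess_pipeline(ph$pixels, cfg)
  expect_identical(out1, out2)
  expect_identical(dim(out1), c(128L, 128L))

  roi <- attr(out1, "roi")
  lb <- ph$lesion_bbox
  expect_true(lb$x >= roi$x && lb$y >= roi$y &&
              lb$x + lb$w <= roi$x + roi$w && lb$y + lb$h <= roi$y + roi$h)

  # constant image: degenerate threshold -> fallback ROI, defined output
  expect_warning(outc <- preprocess_pipeline(matrix(0, 64, 64), cfg),
                 "degenerate")
  expect_true(attr(outc, "fallback"))
  expect_true(all(outc == 0L))
})

test_that("debug dir writes one image per pipeline stage", {
  d <- withr::local_tempdir()
  ph <- generate_phantom("glioma", seed = 2)
  preprocess_pipeline(ph$pixels, preprocess_config(), debug_dir = d)
  expect_length(list.files(d, pattern = "\\.png$"), 7L)
})
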