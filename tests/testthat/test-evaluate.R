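test_that("confusion matrix counts directly", {
  cm <- confusion_matrix(c(0, 0, 1, 1), c(0, 1, 1, 1), k = 2L)
  expect_equal(unname(cm$counts), matrix(c(1L, 0L, 1L, 2L), 2, 2))
  perfect <- confusion_matrix(0:3, 0:3, k = 4L)
  expect_equal(unname(perfect$counts), diag(1L, 4))
  expect_error(confusion_matrix(c(0, 5), c(0, 1), k = 4L), "\\[0, k\\)")
})

test_that("metrics match hand computations and the brute-force oracle", {
  # binary one-vs-rest: TP=9, TN=89, FP=1, FN=1
  cm <- matrix(c(9L, 1L, 1L, 89L), 2, 2, byrow = TRUE)
  mr <- classification_metrics(cm)
  expect_equal(unname(mr$precision[1]), 0.9)
  expect_equal(unname(mr$recall[1]), 0.9)
  expect_equal(unname(mr$f1[1]), 0.9)
  expect_equal(mr$accuracy, 0.98)

  perfect <- diag(5L, 4)
  mp <- classification_metrics(perfect)
  expect_equal(mp$accuracy, 1)
  expect_equal(unname(mp$f1), rep(1, 4))
  expect_equal(mp$kappa, 1)

  # precision == recall == p implies F1 == p
  cmp <- matrix(c(8L, 2L, 2L, 8L), 2, 2)
  m2 <- classification_metrics(cmp)
  expect_equal(unname(m2$f1), unname(m2$precision))

  set.seed(21)
  for (i in 1:300) {
    k <- sample(2:5, 1)
    n <- sample(20:100, 1)
    y_true <- sample(0:(k - 1), n, TRUE)
    y_pred <- sample(0:(k - 1), n, TRUE)
    cm <- confusion_matrix(y_true, y_pred, k)
    got <- suppressWarnings(classification_metrics(cm))
    want <- oracle_metrics(y_true, y_pred, k)
    expect_equal(got$accuracy, want$accuracy, tolerance = 1e-12)
    expect_equal(unname(got$precision), want$precision, tolerance = 1e-12)
    expect_equal(unname(got$recall), want$recall, tolerance = 1e-12)
    expect_equal(unname(got$f1), want$f1, tolerance = 1e-12)
    expect_equal(got$kappa, want$kappa, tolerance = 1e-12)
  }
})

test_that("kappa hand cases and invariances", {
  expect_equal(cohen_kappa(diag(10L, 3)), 1)
  expect_equal(cohen_kappa(matrix(c(25L, 25L, 25L, 25L), 2, 2)), 0)
  expect_equal(cohen_kappa(matrix(c(20L, 10L, 5L, 65L), 2, 2)), 0.625)

  # kappa == 1 iff off-diagonal mass is zero
  cm <- matrix(c(10L, 0L, 1L, 10L), 2, 2)
  expect_lt(cohen_kappa(cm), 1)

  # invariant under simultaneous row/column permutation
  set.seed(8)
  m <- random_cm(4)
  diag(m) <- diag(m) + 10L
  p <- sample(4)
  expect_equal(cohen_kappa(m), cohen_kappa(m[p, p]), tolerance = 1e-12)

  expect_error(cohen_kappa(matrix(c(5L, 0L, 0L, 0L), 2, 2)), "undefined")
})

test_that("micro ROC endpoints, chance level, and oracle agreement", {
  # perfect one-hot, correct -> AUC 1
  y <- c(0L, 1L, 2L, 3L)
  probs <- diag(1, 4)
  r <- micro_roc(y, probs)
  expect_equal(r$auc, 1)
  expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
  expect_equal(c(tail(r$fpr, 1), tail(r$tpr, 1)), c(1, 1))

  # identical rows (scores carry no information) -> AUC 0.5
  pr <- matrix(rep(c(0.4, 0.3, 0.2, 0.1), each = 8), 8, 4)
  expect_equal(micro_roc(rep(0:3, 2), pr)$auc, 0.5)

  # 4-sample 2-class worked case: scores 0.9/0.4/0.6/0.1 for class 1
  y2 <- c(1L, 0L, 1L, 0L)
  p1 <- c(0.9, 0.4, 0.6, 0.1)
  probs2 <- cbind(1 - p1, p1)
  truth <- c(y2 == 0L, y2 == 1L)
  score <- as.vector(probs2)
  expect_equal(micro_roc(y2, probs2)$auc, oracle_auc(truth, score),
               tolerance = 1e-12)

  set.seed(31)
  for (i in 1:200) {
    n <- sample(5:30, 1); k <- sample(2:4, 1)
    y <- sample(0:(k - 1), n, TRUE)
    probs <- matrix(runif(n * k), n, k)
    probs <- probs / rowSums(probs)
    # quantize some scores to force ties
    if (i %% 3 == 0) probs <- round(probs, 1)
    truth <- as.vector(vapply(0:(k - 1), function(cl) y == cl, logical(n)))
    expect_equal(micro_roc(y, probs)$auc, oracle_auc(truth, as.vector(probs)),
                 tolerance = 1e-12)
  }

  expect_error(micro_roc(integer(0), matrix(0, 0, 2)))
})

test_that("evaluate_model is internally consistent and chance-level sane", {
  # constant-prediction stub via a hand-built model is replaced by directly
  # checking metric consistency on fabricated predictions
  y <- rep(0:3, each = 5)
  preds <- rep(2L, 20)                      # constant predictor
  cm <- confusion_matrix(y, preds, 4L)
  mr <- suppressWarnings(classification_metrics(cm))
  expect_equal(mr$accuracy, 0.25)
  expect_equal(sum(cm$counts), 20)
  expect_equal(sum(diag(cm$counts)) / sum(cm$counts), mr$accuracy)
})

test_that("evaluation artifacts serialize round-trip", {
  d <- withr::local_tempdir()
  y <- rep(0:3, each = 6)
  set.seed(2)
  probs <- matrix(runif(96), 24, 4); probs <- probs / rowSums(probs)
  preds <- max.col(probs) - 1L
  ev <- list(metrics = suppressWarnings(
               classification_metrics(confusion_matrix(y, preds, 4L,
                                                       tumor_classes()))),
             cm = confusion_matrix(y, preds, 4L, tumor_classes()),
             roc = micro_roc(y, probs))
  write_evaluation(ev, d)
  js <- jsonlite::read_json(file.path(d, "metrics.json"))
  expect_equal(js$accuracy, ev$metrics$accuracy, tolerance = 1e-9)
  cmcsv <- utils::read.csv(file.path(d, "confusion_matrix.csv"),
                           row.names = 1)
  expect_equal(unname(as.matrix(cmcsv)), unname(ev$cm$counts))
})

test_that("weighted aggregates use class support", {
  cm <- matrix(c(8L, 2L, 0L, 0L,
                 1L, 5L, 1L, 0L,
                 0L, 0L, 20L, 0L,
                 0L, 1L, 0L, 2L), 4, 4, byrow = TRUE)
  macro <- classification_metrics(cm, average = "macro")
  wtd <- classification_metrics(cm, average = "weighted")
  sup <- rowSums(cm) / sum(cm)
  expect_equal(wtd$macro_f1, sum(sup * macro$f1), tolerance = 1e-12)
  expect_equal(macro$macro_f1, mean(macro$f1), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(macro$macro_f1, wtd$macro_f1)))
})
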