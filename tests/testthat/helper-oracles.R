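# Independent oracles used across tests. These deliberately recompute
# quantities by a different route than the package implementation.

# Exhaustive Otsu: split the raw pixel vector at every candidate level and
# compute the inter-class variance from subset means directly.
oracle_otsu <- function(px) {
  v <- as.vector(px)
  levs <- sort(unique(v))
  if (length(levs) < 2) return(NA_integer_)
  cand <- levs[-length(levs)]
  best_t <- NA_integer_; best_s <- -Inf
  n <- length(v)
  for (t in cand) {
    lo <- v[v <= t]; hi <- v[v > t]
    s <- (length(lo) / n) * (length(hi) / n) * (mean(lo) - mean(hi))^2
    if (s > best_s) { best_s <- s; best_t <- t }
  }
  as.integer(best_t)
}

# Dense direct 2-D convolution with replicate borders (for blur checks).
oracle_conv2d_replicate <- function(px, kern) {
  k <- nrow(kern); r <- (k - 1) / 2
  H <- nrow(px); W <- ncol(px)
  pad <- px[c(rep(1, r), seq_len(H), rep(H, r)),
            c(rep(1, r), seq_len(W), rep(W, r))]
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W))
    out[i, j] <- sum(pad[i:(i + k - 1), j:(j + k - 1)] * kern)
  out
}

# Brute-force per-class metrics from label vectors (not from the matrix).
oracle_metrics <- function(y_true, y_pred, k) {
  acc <- mean(y_true == y_pred)
  prec <- rec <- f1 <- numeric(k)
  for (c in seq_len(k) - 1L) {
    tp <- sum(y_true == c & y_pred == c)
    fp <- sum(y_true != c & y_pred == c)
    fn <- sum(y_true == c & y_pred != c)
    prec[c + 1] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[c + 1] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[c + 1] <- if (prec[c + 1] + rec[c + 1] > 0)
      2 * prec[c + 1] * rec[c + 1] / (prec[c + 1] + rec[c + 1]) else 0
  }
  po <- acc
  pe <- sum(vapply(seq_len(k) - 1L, function(c)
    mean(y_true == c) * mean(y_pred == c), 0))
  list(accuracy = acc, precision = prec, recall = rec, f1 = f1,
       kappa = (po - pe) / (1 - pe))
}

# Pair-counting AUC: P(score+ > score-) + 0.5 P(tie).
oracle_auc <- function(truth, score) {
  pos <- score[truth]; neg <- score[!truth]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

random_cm <- function(k, max_count = 50) {
  matrix(sample(0:max_count, k * k, replace = TRUE), k, k)
}
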