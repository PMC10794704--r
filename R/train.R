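#' Training configuration
#'
#' Defaults are the optimized settings for the full-scale model: Adam with
#' learning rate 1e-5, sparse categorical cross-entropy over integer
#' labels, batch size 32, 50 epochs, 3-fold cross-validation.
#'
#' @param epochs Number of training epochs (no early stopping).
#' @param learning_rate Adam step size.
#' @param beta1,beta2 Adam moment decay rates (conventional defaults).
#' @param batch_size Mini-batch size.
#' @param n_folds Number of cross-validation folds.
#' @param base_seed Base seed; fold `f` derives its seed as
#'   `base_seed + f`.
#' @param augment An [augment_config()] applied to the training stream only.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 50L, learning_rate = 1e-5, beta1 = 0.9,
                         beta2 = 0.999, batch_size = 32L, n_folds = 3L,
                         base_seed = 42L, augment = augment_config()) {
  stopifnot(epochs >= 1, learning_rate > 0, n_folds >= 2, batch_size >= 1)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size),
                 n_folds = as.integer(n_folds),
                 base_seed = as.integer(base_seed), augment = augment),
            class = "train_config")
}

#' Stratified k-fold partition
#'
#' Splits indices into `k` validation folds that are pairwise disjoint,
#' cover the dataset, and preserve per-class proportions within one item.
#'
#' @param labels Integer class labels.
#' @param k Number of folds.
#' @param seed Integer seed (same seed, same folds).
#' @return List of `k` lists with `train` and `val` integer index vectors.
#' @export
make_folds <- function(labels, k = 3L, seed = 1L) {
  labels <- as.integer(labels)
  tab <- table(labels)
  if (any(tab < k))
    stop("every class must have at least k = ", k, " members; smallest has ",
         min(tab))
  local_seed(seed, {
    fold_of <- integer(length(labels))
    for (cl in as.integer(names(tab))) {
      idx <- sample(which(labels == cl))
      fold_of[idx] <- rep_len(seq_len(k), length(idx))
    }
    lapply(seq_len(k), function(f)
      list(train = which(fold_of != f), val = which(fold_of == f)))
  })
}

# flatten model parameters into a named list of tensors (by layer index)
collect_params <- function(model) {
  out <- list()
  for (li in seq_along(model$layers)) {
    l <- model$layers[[li]]
    if (l$type %in% c("conv", "dense")) {
      out[[paste0("L", li, ".W")]] <- l$W
      out[[paste0("L", li, ".b")]] <- l$b
    } else if (l$type == "ippm") {
      for (i in seq_along(l$convs)) {
        out[[paste0("L", li, ".c", i, ".W")]] <- l$convs[[i]]$W
        out[[paste0("L", li, ".c", i, ".b")]] <- l$convs[[i]]$b
      }
    }
  }
  out
}

adam_init <- function(model) {
  p <- collect_params(model)
  list(m = lapply(p, function(x) x * 0), v = lapply(p, function(x) x * 0),
       t = 0L)
}

# apply accumulated gradients (same structure as collect_params) in place
adam_step <- function(model, grads_flat, state, config) {
  state$t <- state$t + 1L
  lr <- config$learning_rate
  b1 <- config$beta1; b2 <- config$beta2
  corr1 <- 1 - b1^state$t; corr2 <- 1 - b2^state$t
  for (nm in names(grads_flat)) {
    g <- grads_flat[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    step <- lr * (state$m[[nm]] / corr1) /
      (sqrt(state$v[[nm]] / corr2) + 1e-8)
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    li <- as.integer(sub("L", "", parts[1]))
    if (length(parts) == 2L) {
      model$layers[[li]][[parts[2]]] <- model$layers[[li]][[parts[2]]] - step
    } else {
      ci <- as.integer(sub("c", "", parts[2]))
      model$layers[[li]]$convs[[ci]][[parts[3]]] <-
        model$layers[[li]]$convs[[ci]][[parts[3]]] - step
    }
  }
  list(model = model, state = state)
}

# accumulate per-sample grads into the flat structure
flatten_grads <- function(model, grads, acc = NULL) {
  out <- if (is.null(acc)) list() else acc
  add <- function(nm, g) out[[nm]] <<- if (is.null(out[[nm]])) g else out[[nm]] + g
  for (li in seq_along(model$layers)) {
    g <- grads[[li]]
    if (is.null(g)) next
    if (!is.null(g$dW)) {
      add(paste0("L", li, ".W"), g$dW)
      add(paste0("L", li, ".b"), g$db)
    } else if (!is.null(g$convs)) {
      for (i in seq_along(g$convs)) {
        add(paste0("L", li, ".c", i, ".W"), g$convs[[i]]$dW)
        add(paste0("L", li, ".c", i, ".b"), g$convs[[i]]$db)
      }
    }
  }
  out
}

eval_on <- function(model, inputs, labels, chunk = 32L) {
  n <- length(inputs)
  probs <- matrix(0, n, model$config$num_classes)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    probs[idx, ] <- nn_forward_batch(model, inputs[idx])$probs
  }
  preds <- max.col(probs, ties.method = "first") - 1L
  list(loss = sparse_categorical_crossentropy(probs, labels),
       acc = mean(preds == labels), probs = probs, preds = preds)
}

#' Train one cross-validation fold
#'
#' Trains with augmented copies of the training images only; validation
#' images are evaluated raw. After each epoch the checkpoint is overwritten
#' iff validation accuracy strictly improved (ties keep the earlier epoch).
#'
#' @param model An `nn19_model` (freshly built).
#' @param train_idx,val_idx Disjoint integer indices into `images`.
#' @param images List of preprocessed gray matrices in \[0, 255\].
#' @param labels Integer labels.
#' @param config A [train_config()].
#' @param seed Seed for shuffling/augmentation within this fold.
#' @param augment_hook Optional function `hook(i)` invoked with the (local)
#'   index of every image that passes through augmentation; used to assert
#'   that validation data never does.
#' @param verbose Print per-epoch INFO lines.
#' @return List with `model` (best checkpoint), `history` (data.frame with
#'   epoch, loss, acc, val_loss, val_acc) and `best_epoch`.
#' @export
train_fold <- function(model, train_idx, val_idx, images, labels,
                       config = train_config(), seed = config$base_seed,
                       augment_hook = NULL, verbose = FALSE) {
  stopifnot(length(intersect(train_idx, val_idx)) == 0)
  cfg <- model$config
  prep <- function(im) model_input(model, im)
  train_raw <- images[train_idx]
  train_lab <- as.integer(labels[train_idx])
  val_in <- lapply(images[val_idx], prep)
  val_lab <- as.integer(labels[val_idx])

  state <- adam_init(model)
  hist <- data.frame(epoch = integer(), loss = numeric(), acc = numeric(),
                     val_loss = numeric(), val_acc = numeric())
  best <- list(model = model, val_acc = -Inf, epoch = 0L)

  for (epoch in seq_len(config$epochs)) {
    aug <- augment_stream(train_raw, train_lab, config$augment,
                          seed = seed + 7919L * epoch, hook = augment_hook)
    inputs <- lapply(aug$images, prep)
    order_idx <- local_seed(seed + 104729L * epoch,
                            sample(length(inputs)))
    ep_loss <- 0; ep_correct <- 0L
    for (bstart in seq(1, length(order_idx), by = config$batch_size)) {
      bidx <- order_idx[bstart:min(bstart + config$batch_size - 1L,
                                   length(order_idx))]
      blab <- train_lab[bidx]
      fwd <- nn_forward_batch(model, inputs[bidx], cache = TRUE)
      pl <- fwd$probs[cbind(seq_along(bidx), blab + 1L)]
      li <- -log(pmax(pl, 1e-12))
      if (any(!is.finite(li)))
        stop("non-finite training loss at epoch ", epoch, "; aborting")
      ep_loss <- ep_loss + sum(li)
      ep_correct <- ep_correct +
        sum(max.col(fwd$probs, ties.method = "first") - 1L == blab)
      acc_grads <- flatten_grads(model, nn_backward_batch(model, fwd, blab))
      acc_grads <- lapply(acc_grads, function(g) g / length(bidx))
      upd <- adam_step(model, acc_grads, state, config)
      model <- upd$model; state <- upd$state
    }
    tr_loss <- ep_loss / length(order_idx)
    tr_acc <- ep_correct / length(order_idx)
    ev <- eval_on(model, val_in, val_lab)
    hist <- rbind(hist, data.frame(epoch = epoch, loss = tr_loss,
                                   acc = tr_acc, val_loss = ev$loss,
                                   val_acc = ev$acc))
    if (ev$acc > best$val_acc) {
      best <- list(model = model, val_acc = ev$acc, epoch = epoch)
    }
    if (verbose)
      message(sprintf(
        "epoch %d/%d loss %.4f acc %.3f val_loss %.4f val_acc %.3f",
        epoch, config$epochs, tr_loss, tr_acc, ev$loss, ev$acc))
  }
  list(model = best$model, history = hist, best_epoch = best$epoch)
}

#' Run stratified k-fold cross-validation
#'
#' Builds one fresh model per fold (seed `base_seed + fold`), trains it
#' with [train_fold()], and aggregates per-fold histories, best
#' checkpoints and validation accuracies.
#'
#' @param images List of preprocessed gray matrices.
#' @param labels Integer labels.
#' @param model_cfg A [model_config()].
#' @param config A [train_config()].
#' @param verbose Print progress.
#' @return List with `folds` (per-fold results), `fold_indices`, and
#'   `summary` data.frame (fold, best_epoch, best_val_acc).
#' @export
run_cv <- function(images, labels, model_cfg = model_config(),
                   config = train_config(), verbose = FALSE) {
  folds <- make_folds(labels, config$n_folds, config$base_seed)
  results <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    mc <- model_cfg
    mc$seed <- config$base_seed + f
    model <- build_neuronet19(mc)
    results[[f]] <- train_fold(model, folds[[f]]$train, folds[[f]]$val,
                               images, labels, config,
                               seed = config$base_seed + 1000L * f,
                               verbose = verbose)
  }
  summary <- data.frame(
    fold = seq_along(folds),
    best_epoch = vapply(results, function(r) r$best_epoch, 0L),
    best_val_acc = vapply(results, function(r) max(r$history$val_acc), 0))
  list(folds = results, fold_indices = folds, summary = summary)
}
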