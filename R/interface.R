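#' Load a class-per-directory image folder
#'
#' Indexes a directory tree `<root>/<class>/<image>` of PNG/JPEG files.
#' Class names are the child directory names in locale-independent byte
#' (lexicographic) order, and the integer label of a class is its 0-based
#' rank in that order — for the canonical layout: glioma = 0,
#' meningioma = 1, notumor = 2, pituitary = 3. Files within each class are
#' byte-order sorted too, so the index is deterministic across machines.
#'
#' @param root Directory with at least one class subdirectory.
#' @param split Optional split tag (`"train"`, `"val"`, `"test"`).
#' @return An object of class `dataset_index`: `entries` (data.frame with
#'   `path`, `class_name`, `label`), `class_names`, `split`.
#' @export
load_image_folder <- function(root, split = NA_character_) {
  if (!dir.exists(root)) stop("dataset root does not exist: ", root)
  dirs <- list.dirs(root, recursive = FALSE, full.names = TRUE)
  dirs <- dirs[order(basename(dirs), method = "radix")]
  if (length(dirs) == 0L)
    stop("dataset root contains no class directories: ", root)
  entries <- list()
  for (ci in seq_along(dirs)) {
    files <- list.files(dirs[ci], pattern = "\\.(png|jpg|jpeg)$",
                        ignore.case = TRUE, full.names = TRUE)
    files <- files[order(basename(files), method = "radix")]
    if (length(files) == 0L)
      stop("class directory contains no images: ", dirs[ci])
    entries[[ci]] <- data.frame(path = files,
                                class_name = basename(dirs[ci]),
                                label = ci - 1L)
  }
  structure(list(entries = do.call(rbind, entries),
                 class_names = basename(dirs), split = split),
            class = "dataset_index")
}

#' Load the images of a dataset index
#'
#' Reads every indexed file as a gray matrix. Undecodable files are
#' skipped with a warning and counted.
#'
#' @param index A `dataset_index`.
#' @return List with `images` (gray matrices), `labels`, and `skipped`
#'   (count of undecodable files).
#' @export
load_dataset_images <- function(index) {
  stopifnot(inherits(index, "dataset_index"))
  images <- list(); labels <- integer(); skipped <- 0L
  for (i in seq_len(nrow(index$entries))) {
    px <- tryCatch(as_gray_matrix(index$entries$path[i]), error = identity)
    if (inherits(px, "error")) {
      warning("skipping undecodable image: ", index$entries$path[i])
      skipped <- skipped + 1L
      next
    }
    images[[length(images) + 1L]] <- px
    labels <- c(labels, index$entries$label[i])
  }
  list(images = images, labels = labels, skipped = skipped)
}

#' Default experiment configuration
#'
#' Nested configuration covering every stage. The defaults are the
#' published full-scale settings (128 x 128 working resolution, kernel-11
#' blur, area-1000 contour filter, beta = 1.5 gamma transform, the
#' standard augmentation ranges, a VGG19 backbone with 2/3/4/6 iPPM
#' levels, Adam 1e-5 for 50 epochs with batch 32 and 3 folds, 20 x 3000
#' LIME), so an empty override reproduces that configuration.
#'
#' @param base_seed Base seed echoed into every stage default.
#' @return Nested list of stage configs, class `experiment_config`.
#' @export
default_experiment_config <- function(base_seed = 42L) {
  structure(list(
    base_seed = as.integer(base_seed),
    preprocess = preprocess_config(),
    augment = augment_config(),
    model = model_config(),
    train = train_config(base_seed = base_seed),
    explain = explain_config(base_seed = base_seed),
    phantom = phantom_spec()
  ), class = "experiment_config")
}

# shallow+recursive merge of a plain-list override into a config object
merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read an experiment configuration file
#'
#' Reads a YAML (or JSON) file whose keys override the defaults of
#' [default_experiment_config()]; unspecified keys keep their defaults.
#'
#' @param path YAML/JSON file path; `NULL` returns the defaults.
#' @param base_seed Base seed for the defaults.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path = NULL, base_seed = 42L) {
  cfg <- default_experiment_config(base_seed)
  if (is.null(path)) return(cfg)
  override <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  merge_config(cfg, override)
}

#' Run a phantom-backed experiment end-to-end
#'
#' Generates (or loads) a dataset, preprocesses it, holds out a stratified
#' test split that never enters any training or validation fold,
#' cross-validates the model on the remainder, evaluates the best fold's
#' checkpoint on the held-out test set, and writes config echo, histories,
#' checkpoints and evaluation artifacts under one run directory.
#'
#' @param config An `experiment_config`.
#' @param out_dir Run directory (created; a timestamped subdirectory of
#'   `tempdir()` by default).
#' @param data_dir Existing class-per-directory image tree; if `NULL`, a
#'   phantom dataset is generated with `config$phantom`.
#' @param n_per_class Phantom images per class when generating.
#' @param test_fraction Stratified held-out test fraction.
#' @param verbose Print stage progress.
#' @return List with `out_dir`, `cv` (per-fold results), `test`
#'   (evaluation on the held-out set) and `test_idx`.
#' @export
run_experiment <- function(config = default_experiment_config(),
                           out_dir = file.path(tempdir(),
                             format(Sys.time(), "run_%Y%m%d_%H%M%S")),
                           data_dir = NULL, n_per_class = 25L,
                           test_fraction = 0.2, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    if (verbose) message("[", name, "] ...")
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  yaml::write_yaml(rapply(unclass(config), identity, how = "list"),
                   file.path(out_dir, "config.yaml"))

  index <- stage("data", {
    if (is.null(data_dir)) {
      data_dir <- file.path(out_dir, "phantoms")
      generate_dataset(config$phantom, n_per_class, config$base_seed,
                       data_dir)
    } else load_image_folder(data_dir)
  })
  loaded <- stage("load", load_dataset_images(index))
  images <- stage("preprocess",
                  lapply(loaded$images, preprocess_pipeline,
                         config = config$preprocess))
  labels <- loaded$labels

  # stratified held-out test split, disjoint from all folds
  test_idx <- local_seed(config$base_seed + 7L, {
    unlist(lapply(unique(labels), function(cl) {
      idx <- which(labels == cl)
      sample(idx, max(1L, round(length(idx) * test_fraction)))
    }))
  })
  dev_idx <- setdiff(seq_along(labels), test_idx)

  config$train$augment <- config$augment
  cv <- stage("train",
              run_cv(images[dev_idx], labels[dev_idx], config$model,
                     config$train, verbose = verbose))
  for (f in seq_along(cv$folds)) {
    utils::write.csv(cv$folds[[f]]$history,
                     file.path(out_dir, sprintf("history_fold%d.csv", f)),
                     row.names = FALSE)
    save_checkpoint(cv$folds[[f]]$model,
                    file.path(out_dir, sprintf("checkpoint_fold%d.rds", f)))
  }
  best_fold <- which.max(cv$summary$best_val_acc)
  test <- stage("evaluate",
                evaluate_model(cv$folds[[best_fold]]$model,
                               images[test_idx], labels[test_idx],
                               class_names = index$class_names))
  write_evaluation(test, file.path(out_dir, "test_evaluation"))
  jsonlite::write_json(
    list(base_seed = config$base_seed, best_fold = best_fold,
         cv_summary = cv$summary, n_test = length(test_idx),
         timestamp = format(Sys.time())),
    file.path(out_dir, "run_meta.json"), auto_unbox = TRUE, digits = NA)
  list(out_dir = out_dir, cv = cv, test = test, test_idx = test_idx)
}
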