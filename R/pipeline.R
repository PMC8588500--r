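#' Build the per-window dataset the two-stage framework consumes
#'
#' Runs the shared preprocessing chain once: per-channel z-score, optional
#' Teager-energy relabeling, fixed-window segmentation without overlap,
#' time-domain feature extraction for stage 1, and per-window MVMD giving
#' the mode-stacked image (height = window samples, width = electrode
#' channels, depth = K modes sorted by ascending center frequency) for
#' stage 2.
#'
#' @param rec An [emg_recording()].
#' @param config An [emg_config()].
#' @param taxonomy A [gesture_taxonomy()]; `NULL` uses `config$superclass_map`.
#' @param relabel_first Replace the label stream with Teager-detected
#'   activity before segmenting.
#' @return A `window_dataset`: `windows`, `features` (data.frame), `images`
#'   (n x H x W x K array), `labels`, `superclass`, `taxonomy`, `fs`.
#' @export
build_window_dataset <- function(rec, config = emg_config(), taxonomy = NULL,
                                 relabel_first = TRUE) {
  if (is.null(taxonomy)) {
    if (is.null(config$superclass_map))
      stop("a gesture taxonomy (or config$superclass_map) is required",
           call. = FALSE)
    taxonomy <- gesture_taxonomy(config$superclass_map)
  }
  rec <- zscore(rec)
  if (relabel_first) rec <- teager_relabel(rec, config)$recording
  windows <- segment_windows(rec, config$window_ms, taxonomy)
  if (!length(windows))
    stop("no complete labeled windows in the recording", call. = FALSE)
  features <- extract_feature_table(windows, selected = config$stage1_features,
                                    T = config$feature_threshold)
  settings <- mvmd_settings(K = config$n_modes, alpha = config$alpha,
                            tau = config$tau, tol = config$tol,
                            max_iter = config$max_iter)
  H <- nrow(windows[[1L]]$data); W <- ncol(windows[[1L]]$data)
  images <- array(0, c(length(windows), H, W, config$n_modes))
  for (i in seq_along(windows)) {
    mt <- mvmd_decompose(windows[[i]]$data, settings, fs = rec$fs)
    images[i, , , ] <- aperm(mt$modes, c(2L, 3L, 1L))
  }
  structure(list(windows = windows, features = features, images = images,
                 labels = vapply(windows, `[[`, integer(1), "label"),
                 superclass = vapply(windows, `[[`, integer(1), "superclass"),
                 taxonomy = taxonomy, config = config, fs = rec$fs),
            class = "window_dataset")
}

#' @export
print.window_dataset <- function(x, ...) {
  cat(sprintf("<window_dataset> %d windows (%d x %d x %d images), %d gestures, %d superclasses\n",
              length(x$labels), dim(x$images)[2], dim(x$images)[3],
              dim(x$images)[4], length(unique(x$labels)),
              length(unique(x$superclass))))
  invisible(x)
}

subset_dataset <- function(ds, idx) {
  structure(list(windows = ds$windows[idx],
                 features = ds$features[idx, , drop = FALSE],
                 images = ds$images[idx, , , , drop = FALSE],
                 labels = ds$labels[idx], superclass = ds$superclass[idx],
                 taxonomy = ds$taxonomy, config = ds$config, fs = ds$fs),
            class = "window_dataset")
}

#' Train the full two-stage model
#'
#' Stage 1: a classical classifier over time-domain features predicting the
#' superclass. Stage 2: one separable-convolution network per superclass,
#' trained on the mode stacks of that superclass's windows, resolving the
#' exact gesture.
#'
#' @param ds A [build_window_dataset()] result.
#' @param config An [emg_config()].
#' @return A `two_stage_model`.
#' @export
train_two_stage <- function(ds, config = ds$config) {
  stopifnot(inherits(ds, "window_dataset"))
  stage1 <- train_stage1(ds$features, method = config$stage1_method,
                         seed = config$seed)
  stage2 <- list()
  for (s in ds$taxonomy$superclasses) {
    idx <- which(ds$superclass == s)
    if (length(unique(ds$labels[idx])) < 2L)
      stop("superclass ", s, " has fewer than 2 gestures in the training data",
           call. = FALSE)
    stage2[[as.character(s)]] <-
      train_stage2(ds$images[idx, , , , drop = FALSE], ds$labels[idx],
                   config = config)
  }
  structure(list(stage1 = stage1, stage2_models = stage2,
                 taxonomy = ds$taxonomy, config = config),
            class = "two_stage_model")
}

#' Predict gestures with a two-stage model
#'
#' Each window's features are routed by the stage-1 model to a superclass;
#' the window's mode stack is then classified by that superclass's stage-2
#' network. The final gesture id is always a member of the predicted
#' superclass, even when the routing is wrong (no rejection).
#'
#' @param object A `two_stage_model`.
#' @param ds A `window_dataset` (built with the same configuration).
#' @param ... Unused.
#' @return data.frame with `superclass_pred` and `gesture_pred` per window.
#' @export
predict.two_stage_model <- function(object, ds, ...) {
  stopifnot(inherits(ds, "window_dataset"))
  sc_pred <- predict(object$stage1, ds$features)
  gest <- integer(length(sc_pred))
  for (s in unique(sc_pred)) {
    m2 <- object$stage2_models[[as.character(s)]]
    if (is.null(m2))
      stop("no trained stage-2 model for predicted superclass ", s,
           call. = FALSE)
    idx <- which(sc_pred == s)
    gest[idx] <- predict(m2, ds$images[idx, , , , drop = FALSE])
  }
  data.frame(superclass_pred = sc_pred, gesture_pred = gest)
}

#' Confusion matrix over gesture classes
#'
#' @param true,predicted Equal-length integer label vectors in
#'   `1..n_classes`.
#' @param n_classes Number of classes.
#' @return List with `counts` (entry `(i, j)` = true class `i` predicted as
#'   `j`) and `proportions` (row-normalized; zero rows stay zero).
#' @export
confusion_matrix <- function(true, predicted, n_classes) {
  if (length(true) != length(predicted))
    stop("true and predicted must have equal length", call. = FALSE)
  if (any(c(true, predicted) < 1L) || any(c(true, predicted) > n_classes))
    stop("label error: labels must lie in [1, n_classes]", call. = FALSE)
  counts <- matrix(0L, n_classes, n_classes,
                   dimnames = list(true = seq_len(n_classes),
                                   predicted = seq_len(n_classes)))
  for (i in seq_along(true))
    counts[true[i], predicted[i]] <- counts[true[i], predicted[i]] + 1L
  rs <- rowSums(counts)
  proportions <- counts / ifelse(rs == 0, 1, rs)
  list(counts = counts, proportions = proportions)
}

#' Tenfold cross-validation of the two-stage framework
#'
#' Windows are shuffled with the configured seed and split into `folds`
#' parts, stratified by gesture so every class appears in every fold; per
#' fold the full two-stage model is retrained on the remaining windows and
#' evaluated on the held-out part.
#'
#' @param ds A [build_window_dataset()] result.
#' @param config An [emg_config()].
#' @param folds Number of folds (default 10).
#' @return An `eval_report`: `confusion` (+ `confusion_prop`),
#'   `per_fold_accuracy`, `stage1_accuracy`, `end_to_end_accuracy`,
#'   `classes`, `fold_of` (fold assignment per window).
#' @export
crossvalidate <- function(ds, config = ds$config, folds = 10L) {
  stopifnot(inherits(ds, "window_dataset"), folds >= 2L)
  classes <- sort(unique(ds$labels))
  tab <- table(ds$labels)
  short <- names(tab)[tab < folds]
  if (length(short))
    stop("stratification error: gesture class(es) with fewer windows than folds: ",
         paste(short, collapse = ", "), call. = FALSE)
  set.seed(config$seed)
  fold_of <- integer(length(ds$labels))
  for (cl in classes) {
    idx <- sample(which(ds$labels == cl))
    fold_of[idx] <- rep_len(seq_len(folds), length(idx))
  }
  true_all <- pred_all <- sc_true_all <- sc_pred_all <- integer(0)
  per_fold <- numeric(folds)
  for (f in seq_len(folds)) {
    test_idx <- which(fold_of == f)
    train_ds <- subset_dataset(ds, which(fold_of != f))
    test_ds <- subset_dataset(ds, test_idx)
    model <- train_two_stage(train_ds, config)
    pred <- predict(model, test_ds)
    per_fold[f] <- mean(pred$gesture_pred == test_ds$labels)
    true_all <- c(true_all, test_ds$labels)
    pred_all <- c(pred_all, pred$gesture_pred)
    sc_true_all <- c(sc_true_all, test_ds$superclass)
    sc_pred_all <- c(sc_pred_all, pred$superclass_pred)
  }
  ti <- match(true_all, classes)
  pi <- match(pred_all, classes)
  cm <- confusion_matrix(ti, pi, length(classes))
  dimnames(cm$counts) <- dimnames(cm$proportions) <-
    list(true = classes, predicted = classes)
  structure(list(confusion = cm$counts, confusion_prop = cm$proportions,
                 per_fold_accuracy = per_fold,
                 stage1_accuracy = mean(sc_pred_all == sc_true_all),
                 end_to_end_accuracy = mean(pred_all == true_all),
                 classes = classes, fold_of = fold_of, folds = folds),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d-fold CV over %d windows, %d gestures\n",
              x$folds, length(x$fold_of), length(x$classes)))
  cat(sprintf("  stage-1 (superclass) accuracy: %.4f\n", x$stage1_accuracy))
  cat(sprintf("  end-to-end gesture accuracy:   %.4f\n", x$end_to_end_accuracy))
  cat(sprintf("  per-fold: %s\n",
              paste(sprintf("%.3f", x$per_fold_accuracy), collapse = " ")))
  invisible(x)
}

#' Inter-repetition class-consistency correlation
#'
#' For every gesture class with at least two windows: the mean pairwise
#' Pearson correlation across the class's windows, computed channel-wise
#' and averaged — on the raw window signal, or on the lowest-frequency MVMD
#' mode ("modified EMG") when `use_modified` is `TRUE`. A higher value for
#' the modified signal means the low-frequency oscillation is the more
#' repeatable representation of the gesture.
#'
#' @param ds A [build_window_dataset()] result (its `images` depth-1 slice
#'   is the lowest-frequency mode).
#' @param use_modified Correlate the modified (lowest-mode) signal instead
#'   of the raw signal.
#' @return Named numeric vector: mean correlation per gesture class
#'   (classes with a single window are skipped with a warning).
#' @export
class_consistency_correlation <- function(ds, use_modified = TRUE) {
  stopifnot(inherits(ds, "window_dataset"))
  classes <- sort(unique(ds$labels))
  out <- numeric(0)
  for (cl in classes) {
    idx <- which(ds$labels == cl)
    if (length(idx) < 2L) {
      warning("class ", cl, " has a single window; skipped")
      next
    }
    mats <- lapply(idx, function(i) {
      if (use_modified) ds$images[i, , , 1L] else ds$windows[[i]]$data
    })
    pairs <- utils::combn(length(mats), 2L)
    vals <- apply(pairs, 2L, function(p) {
      a <- mats[[p[1]]]; b <- mats[[p[2]]]
      cc <- vapply(seq_len(ncol(a)), function(ch) {
        if (stats::sd(a[, ch]) == 0 || stats::sd(b[, ch]) == 0) NA_real_
        else stats::cor(a[, ch], b[, ch])
      }, numeric(1))
      mean(cc, na.rm = TRUE)
    })
    out[as.character(cl)] <- mean(vals)
  }
  out
}
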