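#' Participant-level hold-out split
#'
#' Implements the evaluation protocol for the cycling-task classifier: the
#' windows of the designated training participants are split 80/20 into train
#' and test, and every window of the remaining participants forms the
#' generalisation set, never seen in training. The 80/20 split is by
#' contiguous blocks of windows within each session (seeded random block
#' order) rather than window-level sampling, which would leak information
#' between temporally adjacent windows.
#'
#' @param sessions Named list (one element per participant), each a list with
#'   `features` (a [stft_magnitudes] feature matrix or plain matrix) and
#'   `labels` (character, one per window).
#' @param train_ids Character vector of participant names used for training.
#' @param train_fraction Fraction of training participants' windows used to
#'   fit (default 0.8; the rest are the test set).
#' @param seed RNG seed for the block order.
#' @param block_windows Windows per contiguous block (default 8, i.e. 20 s at
#'   the default window length).
#' @return List with elements `train`, `test`, `general`, each a list of
#'   `x` (matrix), `y` (labels) and `participant` (vector).
#' @export
split_holdout <- function(sessions, train_ids, train_fraction = 0.8,
                          seed = 1L, block_windows = 8L) {
  if (!length(train_ids)) stop_argument("train_ids is empty")
  if (!all(train_ids %in% names(sessions)))
    stop_argument("train_ids must name elements of sessions")
  set.seed(seed)
  get_x <- function(s) if (inherits(s$features, "feature_matrix"))
    s$features$values else s$features
  out <- list(train = NULL, test = NULL, general = NULL)
  add <- function(part, x, y, pid) {
    out[[part]] <<- list(x = rbind(out[[part]]$x, x),
                         y = c(out[[part]]$y, y),
                         participant = c(out[[part]]$participant,
                                         rep(pid, length(y))))
  }
  for (pid in names(sessions)) {
    x <- get_x(sessions[[pid]])
    y <- sessions[[pid]]$labels
    if (nrow(x) != length(y))
      stop_argument(sprintf("participant %s: %d windows but %d labels",
                            pid, nrow(x), length(y)))
    if (!pid %in% train_ids) {
      add("general", x, y, pid)
      next
    }
    n <- nrow(x)
    n_blocks <- ceiling(n / block_windows)
    block_of <- rep(seq_len(n_blocks), each = block_windows)[seq_len(n)]
    ord <- sample(n_blocks)
    n_train <- round(train_fraction * n)
    take <- integer()
    for (b in ord) {
      if (length(take) >= n_train) break
      take <- c(take, which(block_of == b))
    }
    # trim overshoot from the last block so the split is exactly 80/20
    if (length(take) > n_train) take <- take[seq_len(n_train)]
    is_train <- seq_len(n) %in% take
    add("train", x[is_train, , drop = FALSE], y[is_train], pid)
    add("test", x[!is_train, , drop = FALSE], y[!is_train], pid)
  }
  out
}

#' Fit the cycling-task classification model
#'
#' Trains a gradient-boosted decision-tree ensemble (XGBoost, softmax
#' objective) on standardized spectral window features. The standardizer is
#' fitted on the training windows only and travels with the model, so
#' prediction takes raw (unstandardized) feature matrices. Library-default
#' boosting parameters are used (no tuning): 100 rounds, maximum depth 6,
#' learning rate 0.3. `unlabelled` windows are dropped before fitting.
#'
#' @param x A [stft_magnitudes] feature matrix or plain windows-by-features
#'   matrix of raw spectral magnitudes.
#' @param y Character labels, one per window (subset of [TASK_LABELS], plus
#'   `unlabelled` rows which are ignored).
#' @param seed Integer seed making training deterministic.
#' @param nrounds Number of boosting rounds (default 100).
#' @param stft An [stft_config] recorded with the model (default standard
#'   2.5 s windows).
#' @param nthread Threads for xgboost (default 1, fully reproducible).
#' @return An object of class `task_model`.
#' @export
task_model <- function(x, y, seed = 1L, nrounds = 100L,
                       stft = stft_config(), nthread = 1L) {
  xm <- if (inherits(x, "feature_matrix")) x$values else x
  if (nrow(xm) != length(y))
    stop_argument("x and y disagree on the number of windows")
  keep <- y != UNLABELLED
  xm <- xm[keep, , drop = FALSE]
  y <- y[keep]
  classes <- intersect(TASK_LABELS, unique(y))
  if (length(classes) < 2L)
    stop_with("tricadence_training_error",
              "training data must contain at least two classes")
  std <- fit_standardizer(xm)
  z <- apply_standardizer(std, xm)
  ynum <- match(y, classes) - 1L
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(z, label = ynum)
  booster <- xgboost::xgb.train(
    params = list(objective = "multi:softmax", num_class = length(classes),
                  max_depth = 6, eta = 0.3, nthread = nthread, seed = seed),
    data = dtrain, nrounds = nrounds, verbose = 0)
  structure(list(booster = booster, standardizer = std, stft = stft,
                 classes = classes, seed = as.integer(seed),
                 nrounds = as.integer(nrounds), n_train = length(y)),
            class = "task_model")
}

#' @export
print.task_model <- function(x, ...) {
  cat(sprintf("<task_model> gradient-boosted trees: %d rounds, %d classes (%s)\n",
              x$nrounds, length(x$classes), paste(x$classes, collapse = ", ")))
  cat(sprintf("  trained on %d windows, %d features, seed %d\n",
              x$n_train, x$standardizer$n_features, x$seed))
  invisible(x)
}

#' @export
summary.task_model <- function(object, ...) {
  print(object)
  cat(sprintf("  stft: %d-sample windows, overlap %d\n",
              object$stft$window_samples, object$stft$overlap_samples))
  invisible(object)
}

#' Predict per-window task labels
#'
#' @param object A [task_model].
#' @param newdata A feature matrix ([stft_magnitudes] output or plain
#'   matrix) of raw spectral magnitudes; the model's standardizer is applied
#'   internally.
#' @param ... Unused.
#' @return Character vector of predicted labels, one per window.
#' @export
predict.task_model <- function(object, newdata, ...) {
  xm <- if (inherits(newdata, "feature_matrix")) newdata$values else newdata
  if (ncol(xm) != object$standardizer$n_features)
    stop_argument(sprintf("feature dimension %d does not match model (%d)",
                          ncol(xm), object$standardizer$n_features))
  z <- apply_standardizer(object$standardizer, xm)
  p <- predict(object$booster, xgboost::xgb.DMatrix(z))
  object$classes[p + 1L]
}

#' Save / load a trained task model as a single-file bundle
#'
#' The bundle holds the serialised booster together with the standardizer,
#' STFT configuration, class set and seed.
#'
#' @param model A [task_model].
#' @param path Bundle path.
#' @return `path` (save) or the restored `task_model` (load).
#' @export
save_task_model <- function(model, path) {
  raw <- xgboost::xgb.save.raw(model$booster)
  bundle <- model
  bundle$booster <- raw
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname save_task_model
#' @export
load_task_model <- function(path) {
  bundle <- readRDS(path)
  bundle$booster <- xgboost::xgb.load.raw(bundle$booster)
  class(bundle) <- "task_model"
  bundle
}

#' Merge per-window labels into a task interval track
#'
#' Run-length encodes consecutive identical window labels into half-open
#' intervals on the window grid; runs of `unlabelled` become gaps. Interval
#' durations are multiples of the window hop.
#'
#' @param labels Character window labels, ordered by window start.
#' @param cfg The [stft_config] that produced the windows.
#' @return A [label_track].
#' @export
merge_windows <- function(labels, cfg = stft_config()) {
  if (!length(labels)) return(label_track())
  hop_s <- stft_hop(cfg) / cfg$sample_rate_hz
  win_s <- cfg$window_samples / cfg$sample_rate_hz
  r <- rle(labels)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths
  start_s <- starts_idx * hop_s
  end_s <- (ends_idx - 1L) * hop_s + win_s
  keep <- r$values != UNLABELLED
  track <- data.frame(start_s = start_s[keep], end_s = end_s[keep],
                      label = r$values[keep], stringsAsFactors = FALSE)
  class(track) <- c("label_track", "data.frame")
  track
}

#' Window-level confusion report for out-of-saddle detection
#'
#' Binary evaluation with `out_of_saddle` as the positive class. Windows
#' whose truth is `coasting` or `unlabelled` are excluded (the coasting
#' discrimination is reported separately, not as part of this binary score).
#' A prediction other than `out_of_saddle` counts as negative.
#'
#' @param predicted,truth Character window labels of equal length.
#' @return An object of class `confusion_report` with counts `tp, fp, tn,
#'   fn` and percentages `accuracy`, `sensitivity`, `specificity`.
#' @export
evaluate_binary <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop_argument("predicted and truth have different lengths")
  keep <- truth %in% c("in_saddle", "out_of_saddle")
  p <- predicted[keep]; tr <- truth[keep]
  pos <- "out_of_saddle"
  tp <- sum(tr == pos & p == pos)
  fn <- sum(tr == pos & p != pos)
  tn <- sum(tr != pos & p != pos)
  fp <- sum(tr != pos & p == pos)
  total <- tp + fp + tn + fn
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn, total = total,
                 accuracy = if (total) 100 * (tp + tn) / total else NA_real_,
                 sensitivity = if (tp + fn) 100 * tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp) 100 * tn / (tn + fp) else NA_real_),
            class = "confusion_report")
}

#' @export
print.confusion_report <- function(x, ...) {
  cat(sprintf("<confusion_report> %d windows (positive = out_of_saddle)\n",
              x$total))
  cat(sprintf("  tp %d  fp %d  tn %d  fn %d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  accuracy %.1f%%  sensitivity %.1f%%  specificity %.1f%%\n",
              x$accuracy, x$sensitivity, x$specificity))
  invisible(x)
}
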