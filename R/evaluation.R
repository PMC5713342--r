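# Confusion-matrix metrics, rank-based ROC/AUC and stratified k-fold
# cross-validation for the binary interaction classifier.

#' Confusion counts at a probability threshold
#'
#' @param labels Integer vector in \{0, 1\}.
#' @param probabilities Numeric vector of predicted probabilities, same
#'   length as `labels`.
#' @param threshold Probabilities at or above this value are called
#'   positive. Default 0.5.
#' @return A `ConfusionCounts` list with integer fields `TP`, `FP`, `TN`,
#'   `FN`.
#' @export
confusion <- function(labels, probabilities, threshold = 0.5) {
  if (length(labels) == 0L) stop("empty input", call. = FALSE)
  stopifnot(length(labels) == length(probabilities),
            all(labels %in% c(0L, 1L)))
  pred <- as.integer(probabilities >= threshold)
  structure(list(
    TP = sum(pred == 1L & labels == 1L),
    FP = sum(pred == 1L & labels == 0L),
    TN = sum(pred == 0L & labels == 0L),
    FN = sum(pred == 0L & labels == 1L)
  ), class = "ConfusionCounts")
}

#' Classification metrics from confusion counts
#'
#' Accuracy, precision, recall (sensitivity), specificity, Matthews
#' correlation coefficient and F1. A metric whose denominator is zero is
#' reported as `NA` (undefined), never silently zeroed.
#'
#' @param counts A `ConfusionCounts` object (or list with fields TP, FP,
#'   TN, FN).
#' @return Named numeric vector `ACC`, `PE`, `RE`, `SPE`, `MCC`, `F1`, all
#'   on the 0--1 scale (`MCC` in \[-1, 1\]).
#' @examples
#' classification_metrics(list(TP = 8, FN = 2, TN = 7, FP = 3))
#' @export
classification_metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  stopifnot(all(c(TP, FP, TN, FN) >= 0))
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  mcc_den <- sqrt(prod(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  c(
    ACC = safe(TP + TN, TP + FP + TN + FN),
    PE  = safe(TP, TP + FP),
    RE  = safe(TP, TP + FN),
    SPE = safe(TN, TN + FP),
    MCC = if (mcc_den > 0) (TP * TN - FP * FN) / mcc_den else NA_real_,
    F1  = safe(2 * TP, 2 * TP + FP + FN)
  )
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic:
#' the proportion of positive-negative score pairs in which the positive
#' outscores the negative, ties counted one half. Equivalent to the
#' trapezoidal area under the full-threshold-sweep ROC curve.
#'
#' @param labels Integer vector in \{0, 1\}; both classes must be present.
#' @param scores Numeric scores (higher means more likely positive).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores), all(labels %in% c(0L, 1L)))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC undefined: only one class present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve table
#'
#' False-positive rate, true-positive rate and threshold for every
#' distinct score, swept from the most to the least stringent threshold.
#'
#' @inheritParams roc_auc
#' @return `data.frame` with columns `threshold`, `FPR`, `TPR`.
#' @export
roc_curve <- function(labels, scores) {
  stopifnot(length(labels) == length(scores), all(labels %in% c(0L, 1L)))
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L), numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L), numeric(1))
  data.frame(threshold = thr,
             FPR = if (n_neg > 0) fpr / n_neg else NA_real_,
             TPR = if (n_pos > 0) tpr / n_pos else NA_real_)
}

#' Full metrics report for one evaluation
#'
#' @inheritParams confusion
#' @return Named numeric vector `ACC`, `PE`, `RE`, `SPE`, `MCC`, `F1`,
#'   `AUC` (AUC is `NA` when only one class is present).
#' @export
evaluate_predictions <- function(labels, probabilities, threshold = 0.5) {
  m <- classification_metrics(confusion(labels, probabilities, threshold))
  auc <- if (length(unique(labels)) == 2L) {
    roc_auc(labels, probabilities)
  } else {
    NA_real_
  }
  c(m, AUC = auc)
}

#' Stratified fold assignment
#'
#' Shuffles indices once under the seed and deals each class round-robin
#' into k near-equal folds, so every fold keeps the overall class balance.
#'
#' @param labels Integer vector in \{0, 1\}.
#' @param k Number of folds.
#' @param seed Integer seed controlling the shuffle.
#' @return Integer vector of fold ids in 1..k, one per observation.
#' @export
make_folds <- function(labels, k = 5L, seed = 1L) {
  stopifnot(k >= 2L, length(labels) >= k)
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- sample(which(labels == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' k-fold cross-validation of the neural-network classifier
#'
#' Observations are dealt into k stratified folds under the seed; for each
#' fold the model is trained on the remaining k-1 folds and all seven
#' metrics are computed on the held-out fold. Per-fold values are
#' aggregated as mean and sample (n-1) standard deviation.
#'
#' @param x Numeric feature matrix, one row per pair.
#' @param labels Integer vector in \{0, 1\}.
#' @param k Number of folds (default 5).
#' @param config An [mlp_config()]; its `input_dim` is taken from `x`.
#' @param seed Integer seed for fold assignment and per-fold model
#'   training.
#' @param threshold Classification threshold for the confusion-based
#'   metrics.
#' @param verbose Print per-fold progress.
#' @return List of class `cv_report` with `folds` (data.frame, one row per
#'   fold), `mean`, `sd`, and the fold assignment.
#' @export
cross_validate <- function(x, labels, k = 5L, config = mlp_config(ncol(x)),
                           seed = 1L, threshold = 0.5, verbose = FALSE) {
  stopifnot(nrow(x) == length(labels))
  if (length(unique(labels)) < 2L) {
    stop("cross-validation needs both classes", call. = FALSE)
  }
  config$input_dim <- ncol(x)
  fold <- make_folds(labels, k = k, seed = seed)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f
    cfg <- config
    cfg$seed <- seed + f  # distinct, reproducible per-fold init/shuffle
    model <- mlp_train(mlp_build(cfg), x[tr, , drop = FALSE],
                       labels[tr], verbose = verbose)
    p <- predict(model, x[!tr, , drop = FALSE])
    held <- labels[!tr]
    m <- classification_metrics(confusion(held, p, threshold))
    auc <- if (length(unique(held)) == 2L) roc_auc(held, p) else {
      warning("fold ", f, " holds a single class; AUC undefined")
      NA_real_
    }
    rows[[f]] <- data.frame(fold = f, t(m), AUC = auc)
    if (verbose) {
      message(sprintf("fold %d: ACC %.4f AUC %.4f", f, m[["ACC"]], auc))
    }
  }
  folds <- do.call(rbind, rows)
  metric_cols <- setdiff(names(folds), "fold")
  structure(list(
    folds = folds,
    mean = colMeans(folds[metric_cols]),
    sd = vapply(folds[metric_cols], stats::sd, numeric(1)),
    fold_assignment = fold,
    k = k, seed = seed
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %d)\n", x$k, x$seed))
  print(round(x$folds, 4), row.names = FALSE)
  cat("mean ± sd:\n")
  print(round(rbind(mean = x$mean, sd = x$sd), 4))
  invisible(x)
}
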