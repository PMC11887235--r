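#' Binary classification metrics from confusion counts
#'
#' `accuracy = (TP + TN) / total`, `sensitivity = TP / (TP + FN)`,
#' `specificity = TN / (TN + FP)`, balanced accuracy = mean of
#' sensitivity and specificity.  A zero denominator makes the affected
#' metric `NA` (an explicit undefined marker, never a silent 0); the
#' balanced accuracy is then the mean of the defined parts.
#'
#' @param tp,tn,fp,fn nonnegative counts, not all zero.
#' @return Named numeric vector `(accuracy, sensitivity, specificity,
#'   balanced_accuracy)`.
#' @export
binary_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("binary_metrics: counts must be nonnegative integers")
  total <- sum(counts)
  if (total == 0) stop("binary_metrics: all counts are zero")
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  bal <- mean(c(sens, spec), na.rm = TRUE)
  c(accuracy = (tp + tn) / total, sensitivity = sens, specificity = spec,
    balanced_accuracy = bal)
}

#' ROC curve and AUC
#'
#' Thresholds sweep the unique scores from high to low; tied scores are
#' merged into single curve points, and the AUC is the trapezoidal area
#' (equivalently, ties contribute half a concordant pair, matching the
#' normalized Mann-Whitney U statistic).
#'
#' @param truth binary vector (logical, or 0/1); both classes must be
#'   present.
#' @param scores numeric scores, larger = more positive.
#' @return List with `points` (data frame `fpr`, `tpr`, starting at
#'   (0,0) and ending at (1,1), non-decreasing in both coordinates) and
#'   `auc`.
#' @export
roc_curve <- function(truth, scores) {
  truth <- as.logical(truth)
  if (length(truth) != length(scores)) stop("roc_curve: length mismatch")
  np <- sum(truth); nn <- sum(!truth)
  if (np == 0 || nn == 0) stop("roc_curve: both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- truth[ord]
  ctp <- cumsum(y); cfp <- cumsum(!y)
  last <- c(diff(s) != 0, TRUE)        # last index within each tie group
  tpr <- c(0, ctp[last] / np)
  fpr <- c(0, cfp[last] / nn)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Per-stage one-vs-rest staging metrics
#'
#' Binarizes each stage against the rest and applies [binary_metrics()];
#' when probability rows are supplied, predictions are their argmax and
#' a per-stage one-vs-rest AUC is computed from the stage's probability
#' column.
#'
#' @param truth integer stages in 1..4.
#' @param predicted integer stages, or an `N x 4` matrix of stage
#'   probabilities.
#' @return An object of class `metrics_report`: `per_stage` (data frame
#'   with accuracy, sensitivity, specificity, balanced_accuracy, auc),
#'   `confusion` (4x4 count matrix, rows = truth), and `macro` (means
#'   over stages, `NA`s removed).
#' @export
stage_metrics <- function(truth, predicted) {
  truth <- as.integer(truth)
  k <- 4L
  if (!all(truth %in% 1:k)) stop("stage_metrics: truth stages must be in 1..4")
  probs <- NULL
  if (is.matrix(predicted)) {
    if (nrow(predicted) != length(truth) || ncol(predicted) != k)
      stop("stage_metrics: probability matrix must be N x 4")
    probs <- predicted
    predicted <- max.col(predicted, ties.method = "first")
  }
  predicted <- as.integer(predicted)
  if (length(predicted) != length(truth)) stop("stage_metrics: length mismatch")
  confusion <- matrix(0L, k, k,
                      dimnames = list(truth = paste0("T", 1:k),
                                      predicted = paste0("T", 1:k)))
  for (i in seq_along(truth))
    confusion[truth[i], predicted[i]] <- confusion[truth[i], predicted[i]] + 1L
  per <- data.frame(stage = paste0("T", 1:k), accuracy = NA_real_,
                    sensitivity = NA_real_, specificity = NA_real_,
                    balanced_accuracy = NA_real_, auc = NA_real_)
  for (s in 1:k) {
    tp <- sum(truth == s & predicted == s)
    fn <- sum(truth == s & predicted != s)
    fp <- sum(truth != s & predicted == s)
    tn <- sum(truth != s & predicted != s)
    bm <- binary_metrics(tp, tn, fp, fn)
    per[s, 2:5] <- bm
    if (!is.null(probs) && length(unique(truth == s)) == 2L)
      per$auc[s] <- roc_curve(truth == s, probs[, s])$auc
  }
  macro <- colMeans(per[, -1], na.rm = TRUE)
  structure(list(per_stage = per, confusion = confusion, macro = macro),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Per-stage one-vs-rest metrics:\n")
  print(x$per_stage, row.names = FALSE, digits = 4)
  cat(sprintf("Macro balanced accuracy: %.4f\n", x$macro[["balanced_accuracy"]]))
  invisible(x)
}

#' Patient-grouped k-fold cross-validation splits
#'
#' Partitions the manifest rows into `k` folds.  With
#' `group_by_patient`, whole patients are assigned to folds so no
#' patient appears on both sides of any split.  Deterministic given the
#' seed.
#'
#' @param manifest a [dataset_manifest()].
#' @param k number of folds; default 10.
#' @param seed RNG seed.
#' @param group_by_patient keep each patient's images in one fold.
#' @return List of `k` lists with `train` and `test` row indices.
#' @export
kfold_split <- function(manifest, k = 10L, seed = 0L,
                        group_by_patient = TRUE) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  n <- nrow(manifest)
  k <- as.integer(k)
  units <- if (group_by_patient) unique(manifest$patient_id) else seq_len(n)
  if (k > length(units))
    stop("kfold_split: k exceeds the number of ",
         if (group_by_patient) "patients" else "items")
  fold_of_unit <- withr::with_seed(as.integer(seed), {
    rep_len(seq_len(k), length(units))[sample.int(length(units))]
  })
  fold <- if (group_by_patient)
    fold_of_unit[match(manifest$patient_id, units)]
  else fold_of_unit
  lapply(seq_len(k), function(f)
    list(train = which(fold != f), test = which(fold == f)))
}
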