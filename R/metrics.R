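#' Evaluate probabilistic off-target predictions
#'
#' Computes the six evaluation metrics used throughout the transfer
#' harness from predicted probabilities and observed binary outcomes:
#' AUC-ROC (the probability that a random active site outranks a random
#' inactive one, ties counted one half, via the rank/Mann-Whitney
#' formulation), precision `TP / (TP + FP)`, recall `TP / (TP + FN)`, the
#' F1 score (harmonic mean of precision and recall), the Brier score
#' (mean squared difference between probability and outcome, threshold-
#' free) and accuracy `(TP + TN) / N`. Confusion counts are taken at the
#' decision threshold: predicted active iff `p >= threshold`. Precision,
#' recall and F1 are reported as 0 when their denominator is empty,
#' matching how degenerate all-negative predictions are conventionally
#' tabulated on imbalanced benchmarks.
#'
#' @param predictions A data frame with columns `p` (probabilities in
#'   `[0, 1]`) and `o` (observed 0/1 outcomes), as returned by
#'   [predict_proba()]; alternatively a numeric probability vector, with
#'   outcomes in `outcomes`.
#' @param threshold Decision threshold in `(0, 1)` (default 0.5).
#' @param outcomes Observed 0/1 outcomes when `predictions` is a vector.
#' @return A one-row tibble with `auc_roc`, `precision`, `recall`, `f1`,
#'   `brier`, `accuracy`, the confusion counts `tp`, `fp`, `fn`, `tn`, and
#'   `threshold`. If only one outcome class is present, `auc_roc` is `NA`
#'   with a warning; the other metrics are still returned.
#' @examples
#' compute_metrics(tibble::tibble(p = c(0.9, 0.8, 0.3), o = c(1, 0, 0)))
#' @export
compute_metrics <- function(predictions, threshold = 0.5, outcomes = NULL) {
  if (is.data.frame(predictions)) {
    if (!all(c("p", "o") %in% names(predictions))) {
      abort("`predictions` must have columns `p` and `o`.")
    }
    p <- predictions$p
    o <- predictions$o
  } else {
    p <- predictions
    o <- outcomes
  }
  if (length(p) != length(o) || length(p) < 1) {
    abort("Probabilities and outcomes must be nonempty and equal length.")
  }
  if (any(p < 0 | p > 1)) abort("Probabilities must lie in [0, 1].")
  if (!all(o %in% c(0, 1))) abort("Outcomes must be 0 or 1.")
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1) {
    abort("`threshold` must lie strictly between 0 and 1.")
  }

  pred <- as.integer(p >= threshold)
  tp <- sum(pred == 1L & o == 1)
  fp <- sum(pred == 1L & o == 0)
  fn <- sum(pred == 0L & o == 1)
  tn <- sum(pred == 0L & o == 0)

  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  accuracy <- (tp + tn) / length(o)
  brier <- mean((p - o)^2)
  auc <- auc_rank(p, o)

  tibble(
    auc_roc = auc, precision = precision, recall = recall, f1 = f1,
    brier = brier, accuracy = accuracy,
    tp = tp, fp = fp, fn = fn, tn = tn, threshold = threshold
  )
}

# Mann-Whitney AUC from midranks; ties between a positive and a negative
# count one half. NA with a warning when one class is absent.
auc_rank <- function(p, o) {
  n1 <- sum(o == 1)
  n0 <- sum(o == 0)
  if (n1 == 0 || n0 == 0) {
    warn("AUC-ROC is undefined with a single outcome class; returning NA.")
    return(NA_real_)
  }
  r <- rank(p, ties.method = "average")
  (sum(r[o == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
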