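# Classification metrics and stratified fold assignment. Precision, recall
# and F-measure are reported at the threshold maximizing F; AUC and AUPR are
# threshold-free. AUC uses the rank-sum (Mann-Whitney) form with half credit
# for ties; AUPR is the area under the interpolation-free precision-recall
# step curve.

#' Stratified fold assignment
#'
#' Splits samples into `k` folds whose sizes differ by at most one, with
#' each class distributed round-robin over a seeded random fold order so
#' that every fold's positive count is within one pair of exact
#' proportionality. Deterministic given `seed`.
#'
#' @param labels Binary 0/1 label vector; both classes must be present.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`, one per sample.
#' @export
stratified_folds <- function(labels, k = 5L, seed = 1L) {
  n <- length(labels)
  if (k < 2L) stop("k must be >= 2")
  if (n < k) stop("fewer samples (", n, ") than folds (", k, ")")
  if (length(unique(labels)) < 2L)
    stop("stratification requires both classes to be present")
  set.seed(seed)
  fold_order <- sample.int(k)
  # one continuous round-robin over classes keeps totals within 1 as well
  schedule <- rep_len(fold_order, n)
  folds <- integer(n)
  pos <- which(labels == 1)
  neg <- which(labels != 1)
  folds[sample(pos)] <- schedule[seq_along(pos)]
  folds[sample(neg)] <- schedule[length(pos) + seq_along(neg)]
  folds
}

#' Confusion-matrix metrics at a fixed threshold
#'
#' Predicted positives are scores strictly greater than `threshold`.
#' Conventions for empty denominators: precision 0 with no predicted
#' positives, recall 0 with no true positives, F 0 when precision + recall
#' is 0; otherwise `F = 2 * precision * recall / (precision + recall)`.
#'
#' @param labels Binary 0/1 labels.
#' @param scores Numeric scores in `[0, 1]`.
#' @param threshold Decision threshold.
#' @return Named list with `precision`, `recall`, `f_measure`.
#' @export
confusion_metrics <- function(labels, scores, threshold) {
  pred <- scores > threshold
  tp <- sum(pred & labels == 1)
  fp <- sum(pred & labels != 1)
  fn <- sum(!pred & labels == 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f_measure = f)
}

#' Best-threshold metrics
#'
#' Sweeps every distinct score (plus 0 and 1) as a candidate threshold and
#' returns the precision/recall/F triple maximizing F-measure; ties go to
#' the lowest threshold.
#'
#' @inheritParams confusion_metrics
#' @return Named list with `precision`, `recall`, `f_measure`,
#'   `best_threshold`.
#' @export
best_threshold_metrics <- function(labels, scores) {
  if (length(unique(labels)) < 2L)
    stop("best-threshold metrics require both classes")
  cand <- sort(unique(c(0, 1, scores)))
  best <- list(precision = 0, recall = 0, f_measure = -1, best_threshold = 0)
  for (th in cand) {
    cm <- confusion_metrics(labels, scores, th)
    if (cm$f_measure > best$f_measure) {
      best <- c(cm, best_threshold = th)
    }
  }
  best
}

#' Ranking metrics: AUC and AUPR
#'
#' AUC is the probability that a uniformly random positive outranks a
#' uniformly random negative, with ties counting one half (rank-sum form),
#' so it is invariant to strictly monotone score transforms. AUPR is the
#' area under the precision-recall step curve summed over distinct score
#' levels without interpolation (equivalent to average precision with tied
#' scores handled blockwise).
#'
#' @inheritParams confusion_metrics
#' @return Named list with `auc` and `aupr`.
#' @export
ranking_metrics <- function(labels, scores) {
  pos <- labels == 1
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L)
    stop("ranking metrics undefined with a single class")
  r <- rank(scores)  # average ranks give half credit for ties
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  # blockwise PR step curve over distinct thresholds, descending
  ord <- order(scores, decreasing = TRUE)
  s_sorted <- scores[ord]
  l_sorted <- labels[ord] == 1
  block_last <- which(!duplicated(s_sorted, fromLast = TRUE))  # block ends
  cum_tp <- cumsum(l_sorted)[block_last]
  cum_n <- block_last
  precision <- cum_tp / cum_n
  recall <- cum_tp / n_pos
  aupr <- sum(diff(c(0, recall)) * precision)
  list(auc = auc, aupr = aupr)
}

#' Two-sample t-test on per-repeat metric vectors
#'
#' Convenience wrapper for comparing two methods' per-repeat metric values
#' (Welch test).
#'
#' @param a,b Numeric vectors of per-repeat metric values.
#' @return The `htest` object from [stats::t.test()].
#' @export
metric_ttest <- function(a, b) stats::t.test(a, b)
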