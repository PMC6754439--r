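test_that("stratified folds balance sizes and class fractions", {
  # 10 pairs, 2 positives, k = 5: every fold gets exactly 2 pairs
  labels <- c(rep(1, 2), rep(0, 8))
  f <- stratified_folds(labels, k = 5, seed = 1)
  expect_equal(unname(table(f)), rep(2L, 5), ignore_attr = TRUE)
  # divisible case: every fold gets exactly 4 of the 20 positives
  labels2 <- c(rep(1, 20), rep(0, 80))
  f2 <- stratified_folds(labels2, k = 5, seed = 3)
  expect_equal(unname(table(f2)), rep(20L, 5), ignore_attr = TRUE)
  expect_equal(unname(table(f2[labels2 == 1])), rep(4L, 5),
               ignore_attr = TRUE)
  # general invariant: fold sizes and per-fold positives within 1
  for (seed in 1:4) {
    lab <- as.numeric(runif(53) < 0.3)
    if (sum(lab) < 2) lab[1:2] <- 1
    fk <- stratified_folds(lab, k = 4, seed = seed)
    expect_lte(diff(range(table(fk))), 1)
    expect_lte(diff(range(table(factor(fk[lab == 1], levels = 1:4)))), 1)
  }
  # determinism
  expect_identical(stratified_folds(labels2, 5, seed = 9),
                   stratified_folds(labels2, 5, seed = 9))
  expect_error(stratified_folds(c(0, 1), k = 5), "fewer samples")
  expect_error(stratified_folds(rep(1, 10), k = 2), "both classes")
})

test_that("confusion metrics match the hand-computed fixture", {
  labels <- c(1, 1, 0, 0)
  scores <- c(0.9, 0.4, 0.6, 0.1)
  got <- confusion_metrics(labels, scores, 0.5)
  # TP = 1 (0.9), FP = 1 (0.6), FN = 1 (0.4)
  expect_equal(got, list(precision = 0.5, recall = 0.5, f_measure = 0.5))
  # perfect separation
  perfect <- confusion_metrics(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9), 0.5)
  expect_equal(perfect, list(precision = 1, recall = 1, f_measure = 1))
  # threshold 1: nothing predicted positive
  none <- confusion_metrics(labels, scores, 1)
  expect_equal(none, list(precision = 0, recall = 0, f_measure = 0))
})

test_that("best threshold equals the exhaustive sweep maximum", {
  labels <- c(1, 1, 0, 0)
  scores <- c(0.9, 0.4, 0.6, 0.1)
  got <- best_threshold_metrics(labels, scores)
  cand <- sort(unique(c(0, 1, scores)))
  fs <- vapply(cand, function(th)
    confusion_metrics(labels, scores, th)$f_measure, numeric(1))
  expect_equal(got$f_measure, max(fs))
  expect_equal(got$best_threshold, cand[which.max(fs)])
  # F consistent with its own precision and recall
  expect_equal(got$f_measure,
               2 * got$precision * got$recall / (got$precision + got$recall))

  # perfectly separated: F = 1 at the lowest gap threshold
  sep <- best_threshold_metrics(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(sep$f_measure, 1)
  expect_equal(sep$best_threshold, 0.2)

  # all scores equal: the better of all-positive / all-negative
  flat <- best_threshold_metrics(c(1, 0, 0, 1), rep(0.5, 4))
  all_pos <- confusion_metrics(c(1, 0, 0, 1), rep(0.5, 4), 0)$f_measure
  expect_equal(flat$f_measure, max(all_pos, 0))
})

test_that("no fixed threshold beats the best-threshold F", {
  for (seed in 1:5) {
    set.seed(seed)
    labels <- rep(c(0, 1), 10)
    scores <- runif(20)
    best <- best_threshold_metrics(labels, scores)
    for (th in seq(0, 1, by = 0.05))
      expect_lte(confusion_metrics(labels, scores, th)$f_measure,
                 best$f_measure + 1e-12)
  }
})

test_that("AUC matches the pairwise-comparison oracle", {
  labels <- c(1, 1, 0, 0)
  scores <- c(0.9, 0.4, 0.6, 0.1)
  got <- ranking_metrics(labels, scores)
  expect_equal(got$auc, 3 / 4)  # 3 of 4 positive-negative pairs ordered
  # brute-force oracle with half credit for ties, random fixtures
  for (seed in 1:4) {
    set.seed(seed)
    lab <- rep(c(0, 1), c(7, 5))
    sc <- round(runif(12), 1)  # rounding forces some ties
    pos <- sc[lab == 1]; neg <- sc[lab == 0]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(ranking_metrics(lab, sc)$auc, mean(cmp))
  }
  # perfect ranking
  perfect <- ranking_metrics(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$aupr, 1)
  expect_error(ranking_metrics(c(1, 1), c(0.2, 0.3)), "single class")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(2)
  labels <- rep(c(0, 1), c(30, 20))
  scores <- runif(50)
  a1 <- ranking_metrics(labels, scores)$auc
  a2 <- ranking_metrics(labels, scores^3)$auc
  expect_equal(a1, a2)
})

test_that("AUPR equals the step-curve oracle and respects prevalence", {
  labels <- c(1, 1, 0, 0)
  scores <- c(0.9, 0.4, 0.6, 0.1)
  # walk the ranking by hand: prec 1 at recall .5, then 2/3 at recall 1
  expect_equal(ranking_metrics(labels, scores)$aupr, 0.5 * 1 + 0.5 * 2 / 3)
  # random scores on balanced large n: AUC near 1/2
  set.seed(7)
  lab <- rep(c(0, 1), each = 2000)
  sc <- runif(4000)
  expect_lt(abs(ranking_metrics(lab, sc)$auc - 0.5), 0.05)
})
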