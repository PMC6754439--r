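# Repeated stratified cross-validation of the full pipeline. Inside each
# training fold the interaction entries of held-out pairs are masked to
# zero before the GIP kernel, view selection, fusion and training see the
# matrix, so no test label can leak into the features.

#' Cross-validated evaluation of the DDI prediction pipeline
#'
#' For every repeat and fold: (1) assign all unordered drug pairs `i < j`
#' to stratified folds; (2) zero the held-out pairs (both orders) in a
#' copy of `Y`; (3) compute the GIP kernel from the masked matrix and add
#' it to the candidate views; (4) run entropy/redundancy selection and SNF
#' fusion on the candidates; (5) train the pair classifier on the training
#' pairs (optionally augmented with both orderings); (6) score the
#' held-out pairs as the average of their two directional scores; and
#' (7) compute AUC, AUPR and best-threshold precision/recall/F-measure.
#' Metrics are averaged per fold, then across folds and repeats
#' (`aggregate = "pooled"` instead pools scores over the folds of a repeat
#' before computing metrics).
#'
#' With `gip_scope = "fold"` (default) the GIP kernel, selection and fusion
#' are recomputed inside every training fold; `"global"` computes them once
#' from the full matrix, which is faster but lets test labels shape the
#' features (kept only for reproducing less careful protocols).
#'
#' @param views Named list of file-loaded similarity matrices (may be
#'   empty if `include_gip` is TRUE).
#' @param Y Binary symmetric interaction matrix.
#' @param k Number of folds (default 5).
#' @param repeats Number of repeats of the whole CV (default 1).
#' @param seed Integer seed; repeat `r` uses `seed + r - 1`.
#' @param c1,c2 Selection thresholds, see [select_similarities()].
#' @param snf_k,snf_t,snf_alpha Fusion parameters, see [snf_fuse()].
#' @param nn An [nn_config()] for the classifier.
#' @param gip_scope `"fold"` (mask test pairs, recompute per fold) or
#'   `"global"`.
#' @param gip_gamma GIP bandwidth multiplier, see [gip_bandwidth()].
#' @param include_gip Add the GIP kernel to the candidate views.
#' @param both_orders Train on both orderings of each pair.
#' @param include_self Include self-pairs in the evaluated universe.
#' @param aggregate `"per_fold"` or `"pooled"`.
#' @param keep_fold_details Keep per-fold audit information (test pairs,
#'   the masked interaction values at test positions, training pairs and
#'   selected views); memory-hungry, intended for leakage audits on small
#'   problems.
#' @return Object of class `ddi_cv`: `per_fold` data frame (one row per
#'   fold x repeat), `summary` (mean and sd per metric), the selection of
#'   the last fold, and call settings.
#' @export
run_cv <- function(views, Y, k = 5L, repeats = 1L, seed = 1L,
                   c1 = 0.6, c2 = 0.6,
                   snf_k = 20L, snf_t = 20L, snf_alpha = 1,
                   nn = nn_config(),
                   gip_scope = c("fold", "global"), gip_gamma = 1,
                   include_gip = TRUE, both_orders = TRUE,
                   include_self = FALSE,
                   aggregate = c("per_fold", "pooled"),
                   keep_fold_details = FALSE) {
  gip_scope <- match.arg(gip_scope)
  aggregate <- match.arg(aggregate)
  Y <- validate_interactions(Y, require_positive = TRUE)
  m <- nrow(Y)
  if (length(views) > 0L) .check_views(views)
  if (!include_gip && length(views) == 0L)
    stop("no candidate views: supply views or set include_gip = TRUE")
  pairs <- enumerate_pairs(m, include_self = include_self)
  labels <- Y[pairs]
  global_gip <- if (include_gip && gip_scope == "global")
    gip_kernel(Y, gip_gamma) else NULL
  rows <- list()
  details <- list()
  selection_last <- NULL
  for (r in seq_len(repeats)) {
    rep_seed <- seed + r - 1L
    folds <- stratified_folds(labels, k = k, seed = rep_seed)
    pooled_scores <- numeric(0)
    pooled_labels <- numeric(0)
    for (f in seq_len(k)) {
      test_idx <- which(folds == f)
      train_idx <- which(folds != f)
      test_pairs <- pairs[test_idx, , drop = FALSE]
      # mask held-out labels (both orders) before any feature computation
      Y_train <- Y
      Y_train[test_pairs] <- 0
      Y_train[test_pairs[, c(2L, 1L), drop = FALSE]] <- 0
      candidates <- views
      if (include_gip) {
        candidates$gip <- if (gip_scope == "global") global_gip
                          else gip_kernel(Y_train, gip_gamma)
      }
      sel <- select_similarities(candidates, c1 = c1, c2 = c2)
      fused <- snf_fuse(candidates[sel$selected],
                        K = snf_k, t = snf_t, alpha = snf_alpha)
      train_set <- build_pair_dataset(fused, Y_train,
                                      pairs[train_idx, , drop = FALSE],
                                      both_orders = both_orders)
      nn_fold <- nn
      nn_fold$seed <- rep_seed * 100L + f
      model <- mlp_train(train_set$x, train_set$y, nn_fold)
      scores <- score_pairs(model, fused, test_pairs)
      test_labels <- labels[test_idx]
      if (aggregate == "pooled") {
        pooled_scores <- c(pooled_scores, scores)
        pooled_labels <- c(pooled_labels, test_labels)
      } else {
        rows[[length(rows) + 1L]] <-
          data.frame(repeat_id = r, fold = f,
                     .fold_metrics(test_labels, scores))
      }
      selection_last <- sel
      if (keep_fold_details) {
        details[[length(details) + 1L]] <- list(
          repeat_id = r, fold = f,
          test_pairs = test_pairs,
          masked_values = c(Y_train[test_pairs],
                            Y_train[test_pairs[, c(2L, 1L), drop = FALSE]]),
          train_pairs = train_set$pairs,
          gip = if (include_gip) candidates$gip else NULL,
          fused = fused,
          selection = sel,
          scores = scores,
          labels = test_labels)
      }
    }
    if (aggregate == "pooled") {
      rows[[length(rows) + 1L]] <-
        data.frame(repeat_id = r, fold = NA_integer_,
                   .fold_metrics(pooled_labels, pooled_scores))
    }
  }
  per_fold <- do.call(rbind, rows)
  metric_cols <- c("precision", "recall", "f_measure", "auc", "aupr")
  summary <- data.frame(
    metric = metric_cols,
    mean = vapply(per_fold[metric_cols], mean, numeric(1)),
    sd = vapply(per_fold[metric_cols], stats::sd, numeric(1)),
    row.names = NULL)
  structure(list(per_fold = per_fold, summary = summary,
                 selection = selection_last,
                 settings = list(k = k, repeats = repeats, seed = seed,
                                 c1 = c1, c2 = c2, snf_k = snf_k,
                                 snf_t = snf_t, snf_alpha = snf_alpha,
                                 nn = nn, gip_scope = gip_scope,
                                 gip_gamma = gip_gamma,
                                 include_gip = include_gip,
                                 both_orders = both_orders,
                                 include_self = include_self,
                                 aggregate = aggregate),
                 fold_details = if (keep_fold_details) details else NULL),
            class = "ddi_cv")
}

.fold_metrics <- function(labels, scores) {
  bt <- best_threshold_metrics(labels, scores)
  rk <- ranking_metrics(labels, scores)
  data.frame(precision = bt$precision, recall = bt$recall,
             f_measure = bt$f_measure, best_threshold = bt$best_threshold,
             auc = rk$auc, aupr = rk$aupr)
}

#' @export
print.ddi_cv <- function(x, ...) {
  s <- x$settings
  cat("Stratified ", s$k, "-fold cross-validation, ", s$repeats,
      " repeat(s), seed ", s$seed, "\n", sep = "")
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-10s %.4f +/- %.4f\n", x$summary$metric[i],
                x$summary$mean[i], x$summary$sd[i]))
  invisible(x)
}

#' Mean of one metric across folds and repeats
#'
#' @param cv A `ddi_cv` result.
#' @param metric Metric name (column of `cv$per_fold`).
#' @return Scalar mean.
#' @export
cv_metric <- function(cv, metric = "auc") {
  if (!metric %in% names(cv$per_fold)) stop("unknown metric: ", metric)
  mean(cv$per_fold[[metric]])
}

#' Nested cross-validation hyperparameter search
#'
#' Outer stratified `k_outer`-fold loop over a grid of network
#' hyperparameters: every grid point is evaluated by training on
#' `k_outer - 1` folds and scoring the held-out fold, repeated so that
#' each fold is held out once; the grid point with the best mean
#' outer-fold AUPR wins. The grid follows the search space of the original
#' study: number of hidden layers 1..5, neurons per layer
#' 100..500, activation relu/tanh/sigmoid, dropout 0.3/0.5.
#'
#' @param views Named list of similarity matrices.
#' @param Y Binary interaction matrix.
#' @param grid Data frame with columns among `n_hidden`, `n_neurons`,
#'   `activation`, `dropout` (see [nn_grid()]); one row per candidate.
#' @param k_outer Number of outer folds (default 3).
#' @param base Baseline [nn_config()] supplying the remaining settings.
#' @param seed Integer seed shared by all candidates so they see the same
#'   folds.
#' @param ... Passed to [run_cv()] (selection/fusion/GIP settings).
#' @return List with `best_config` (an [nn_config()]), `best_row`, and
#'   `results` (the grid with a `mean_aupr` column).
#' @export
tune_nested_cv <- function(views, Y, grid, k_outer = 3L,
                           base = nn_config(), seed = 1L, ...) {
  grid <- as.data.frame(grid)
  if (nrow(grid) == 0L) stop("hyperparameter grid is empty")
  mean_aupr <- numeric(nrow(grid))
  configs <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cfg <- base
    row <- grid[g, , drop = FALSE]
    if (!is.null(row$n_hidden) || !is.null(row$n_neurons)) {
      n_hidden <- if (is.null(row$n_hidden)) length(cfg$hidden)
                  else row$n_hidden
      n_neurons <- if (is.null(row$n_neurons)) cfg$hidden[1L]
                   else row$n_neurons
      cfg$hidden <- rep(as.integer(n_neurons), n_hidden)
    }
    if (!is.null(row$activation)) cfg$activation <- as.character(row$activation)
    if (!is.null(row$dropout)) cfg$dropout <- row$dropout
    configs[[g]] <- cfg
    cv <- run_cv(views, Y, k = k_outer, repeats = 1L, seed = seed,
                 nn = cfg, ...)
    mean_aupr[g] <- cv_metric(cv, "aupr")
  }
  results <- cbind(grid, mean_aupr = mean_aupr)
  best <- which.max(mean_aupr)
  list(best_config = configs[[best]], best_row = results[best, , drop = FALSE],
       results = results)
}

#' Hyperparameter grid constructor
#'
#' @param n_hidden Numbers of hidden layers to try.
#' @param n_neurons Neurons per hidden layer to try.
#' @param activation Activation functions to try.
#' @param dropout Dropout rates to try.
#' @return Data frame with one row per combination.
#' @export
nn_grid <- function(n_hidden = 1:5, n_neurons = seq(100L, 500L, by = 100L),
                    activation = c("relu", "tanh", "sigmoid"),
                    dropout = c(0.3, 0.5)) {
  expand.grid(n_hidden = n_hidden, n_neurons = n_neurons,
              activation = activation, dropout = dropout,
              stringsAsFactors = FALSE)
}
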