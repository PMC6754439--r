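# Pipeline-level cross-validation tests use a small benchmark and a small
# network so they stay fast; the full-size study conditions are exercised
# in test-acceptance.R.

test_that("cross-validation bookkeeping: one row per fold, determinism", {
  bench <- synthetic_benchmark(m = 24, n_clusters = 3, seed = 2)
  cv <- small_cv(bench, nn = nn_config(hidden = c(8, 8), epochs = 3,
                                       batch_size = 32))
  expect_s3_class(cv, "ddi_cv")
  expect_equal(nrow(cv$per_fold), 3)
  expect_equal(cv$per_fold$fold, 1:3)
  expect_equal(cv$summary$metric,
               c("precision", "recall", "f_measure", "auc", "aupr"))
  expect_true(all(is.finite(cv$summary$mean)))
  # identical seed, identical report
  cv2 <- small_cv(bench, nn = nn_config(hidden = c(8, 8), epochs = 3,
                                        batch_size = 32))
  expect_equal(cv$per_fold, cv2$per_fold)
  # pooled aggregation gives one row per repeat
  cvp <- run_cv(bench$views, bench$Y, k = 3, repeats = 2, seed = 1,
                snf_k = 5, snf_t = 3,
                nn = nn_config(hidden = c(8, 8), epochs = 2, batch_size = 32),
                aggregate = "pooled")
  expect_equal(nrow(cvp$per_fold), 2)
})

test_that("held-out labels never reach the GIP kernel, fusion or training", {
  bench <- synthetic_benchmark(m = 20, n_clusters = 2, seed = 5)
  cv <- run_cv(bench$views, bench$Y, k = 4, repeats = 1, seed = 3,
               snf_k = 5, snf_t = 3,
               nn = nn_config(hidden = c(8, 8), epochs = 2, batch_size = 32),
               keep_fold_details = TRUE)
  expect_length(cv$fold_details, 4)
  pairs <- enumerate_pairs(20)
  all_test <- integer(0)
  for (d in cv$fold_details) {
    # masked interaction entries are zero, in both orders
    expect_true(all(d$masked_values == 0))
    # no held-out pair (in either order) appears among the training pairs
    test_keys <- c(paste(d$test_pairs[, 1], d$test_pairs[, 2]),
                   paste(d$test_pairs[, 2], d$test_pairs[, 1]))
    train_keys <- paste(d$train_pairs[, 1], d$train_pairs[, 2])
    expect_length(intersect(test_keys, train_keys), 0)
    # the GIP candidate equals the kernel of the masked matrix: test
    # labels demonstrably did not enter the feature computation
    Y_masked <- bench$Y
    Y_masked[d$test_pairs] <- 0
    Y_masked[d$test_pairs[, c(2, 1)]] <- 0
    expect_equal(d$gip, gip_kernel(Y_masked))
    all_test <- c(all_test, which(paste(pairs[, 1], pairs[, 2]) %in%
                                    test_keys))
  }
  # every unordered pair is held out exactly once across the folds
  expect_equal(sort(all_test), seq_len(nrow(pairs)))
})

test_that("planted structure is detected and vanishes under permutation", {
  bench <- synthetic_benchmark(m = 50, n_clusters = 4, seed = 8)
  nn <- nn_config(hidden = c(64, 64), epochs = 50, batch_size = 64)
  cv_signal <- run_cv(bench$views, bench$Y, k = 3, repeats = 1, seed = 4,
                      snf_k = 10, snf_t = 10, nn = nn)
  # permute drug labels of Y, breaking the similarity-interaction link
  set.seed(1)
  perm <- sample(50)
  Y_perm <- bench$Y[perm, perm]
  cv_null <- run_cv(bench$views, Y_perm, k = 3, repeats = 1, seed = 4,
                    snf_k = 10, snf_t = 10, nn = nn)
  auc_signal <- cv_metric(cv_signal, "auc")
  auc_null <- cv_metric(cv_null, "auc")
  expect_gt(auc_signal, 0.65)
  expect_gt(auc_signal, auc_null + 0.1)
  expect_lt(abs(auc_null - 0.5), 0.12)
  # AUPR beats prevalence under signal
  prevalence <- mean(bench$Y[upper.tri(bench$Y)])
  expect_gt(cv_metric(cv_signal, "aupr"), prevalence)
})

test_that("nested hyperparameter search reproduces a brute-force rerun", {
  bench <- synthetic_benchmark(m = 20, n_clusters = 2, seed = 6)
  grid <- nn_grid(n_hidden = 1:2, n_neurons = 8, activation = "relu",
                  dropout = 0.5)
  base <- nn_config(hidden = 8, epochs = 2, batch_size = 32)
  tuned <- tune_nested_cv(bench$views, bench$Y, grid, k_outer = 3,
                          base = base, seed = 2, snf_k = 5, snf_t = 3)
  expect_equal(nrow(tuned$results), 2)
  # brute-force re-execution of the outer loop per grid point
  for (g in 1:2) {
    cfg <- base
    cfg$hidden <- rep(8L, grid$n_hidden[g])
    cv <- run_cv(bench$views, bench$Y, k = 3, repeats = 1, seed = 2,
                 snf_k = 5, snf_t = 3, nn = cfg)
    expect_equal(tuned$results$mean_aupr[g], cv_metric(cv, "aupr"))
  }
  expect_equal(tuned$best_row$mean_aupr, max(tuned$results$mean_aupr))
  # the winning config is actually the returned one
  expect_equal(length(tuned$best_config$hidden),
               tuned$best_row$n_hidden)
  # grid of size one returns that configuration
  single <- tune_nested_cv(bench$views, bench$Y,
                           nn_grid(n_hidden = 1, n_neurons = 8,
                                   activation = "tanh", dropout = 0.3),
                           k_outer = 3, base = base, seed = 2,
                           snf_k = 5, snf_t = 3)
  expect_equal(single$best_config$activation, "tanh")
  expect_equal(single$best_config$dropout, 0.3)
  expect_error(tune_nested_cv(bench$views, bench$Y, nn_grid()[0, ]),
               "empty")
})
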