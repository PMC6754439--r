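test_that("entropy closed forms: uniform rows give log m, one-hot rows 0", {
  for (m in c(2, 5, 17)) {
    expect_equal(matrix_entropy(matrix(1, m, m)), log(m))
    expect_equal(matrix_entropy(matrix(0.37, m, m)), log(m))
    expect_equal(matrix_entropy(diag(m)), 0)
  }
  # permutation-like matrix: one positive entry per row
  P <- matrix(0, 4, 4)
  P[cbind(1:4, c(2, 3, 4, 1))] <- 0.8
  expect_equal(matrix_entropy(P), 0)
})

test_that("entropy matches the hand-derived two-row fixture", {
  A <- matrix(c(0.5, 0.1, 0.5, 0.9), 2, 2)  # rows (0.5,0.5) and (0.1,0.9)
  expected <- mean(c(log(2), -(0.1 * log(0.1) + 0.9 * log(0.9))))
  expect_equal(matrix_entropy(A), expected)
  expect_equal(round(expected, 5), 0.50912)
})

test_that("entropy agrees with the literal double-loop oracle", {
  for (seed in 1:5) {
    A <- random_similarity(6, seed = seed)
    expect_equal(matrix_entropy(A), entropy_oracle(A))
    expect_equal(matrix_entropy(A, exclude_diagonal = TRUE),
                 entropy_oracle(A, exclude_diagonal = TRUE))
  }
})

test_that("entropy is bounded by log m and invariant to row rescaling", {
  for (seed in 1:5) {
    A <- random_similarity(7, seed = seed)
    e <- matrix_entropy(A)
    expect_gte(e, 0)
    expect_lte(e, log(7) + 1e-12)
    # rescaling a row leaves its normalized distribution unchanged
    B <- A; B[3, ] <- 5 * B[3, ]
    expect_equal(matrix_entropy(B), e)
  }
})

test_that("zero-sum rows contribute zero entropy with a warning", {
  A <- matrix(1, 3, 3); A[2, ] <- 0
  expect_warning(e <- matrix_entropy(A), "zero-sum")
  expect_equal(e, 2 * log(3) / 3)
  expect_error(matrix_entropy(matrix(0, 2, 2)), "all rows")
})

test_that("entropy filter removes the uniform view and sorts ascending", {
  m <- 12
  views <- list(
    uniform = matrix(1 / m, m, m),             # entropy log m, always cut
    onehot = diag(m),                          # entropy 0, ranked first
    mid = random_similarity(m, seed = 2)^8     # peaked, intermediate
  )
  expect_gt(matrix_entropy(views$mid), 0)
  surviving <- entropy_rank_filter(views, c1 = 0.6)
  expect_false("uniform" %in% surviving)
  expect_equal(surviving[1], "onehot")
  ent <- vapply(views[surviving], matrix_entropy, numeric(1))
  expect_equal(surviving, names(sort(ent)))
  # all views random-like: selection cannot proceed
  expect_error(entropy_rank_filter(list(u = matrix(1, m, m)), c1 = 0.6),
               "empty")
})

test_that("affinity follows S = 1 / (1 + Frobenius distance)", {
  A <- diag(2)
  B <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(matrix_affinity(A, B), 1 / 3)  # D = 2
  expect_equal(matrix_affinity(A, A), 1)
  for (seed in 1:3) {
    X <- random_similarity(5, seed = seed)
    Y <- random_similarity(5, seed = seed + 10)
    expect_equal(matrix_affinity(X, Y), matrix_affinity(Y, X))
    expect_equal(matrix_affinity(X, Y), 1 / (1 + sqrt(sum((X - Y)^2))))
  }
  expect_error(matrix_affinity(diag(2), diag(3)), "dimension")
})

test_that("greedy selection matches a brute-force re-execution", {
  # four peaked views engineered so pairwise affinities straddle 0.6:
  # v_b is a slight perturbation of v_a (affinity > 0.6), v_c and v_d
  # are far from everything
  base <- random_similarity(6, seed = 1)^6
  matching <- diag(6)  # a disjoint perfect matching: peaked but far from base
  matching[cbind(c(1, 3, 5), c(2, 4, 6))] <- 1
  matching[cbind(c(2, 4, 6), c(1, 3, 5))] <- 1
  views <- list(
    v_a = base,
    v_b = pmin(base + 0.05, 1),
    v_c = matching,
    v_d = diag(6)
  )
  sel <- select_similarities(views, c1 = 0.95, c2 = 0.6)

  # literal re-execution of the iterative procedure
  ent <- vapply(views, matrix_entropy, numeric(1))
  ranked <- names(sort(ent[ent <= 0.95 * log(6)]))
  selected <- character(0)
  while (length(ranked) > 0) {
    pick <- ranked[which.min(ent[ranked])]
    selected <- c(selected, pick)
    ranked <- setdiff(ranked, pick)
    keep <- vapply(ranked, function(nm)
      matrix_affinity(views[[pick]], views[[nm]]) <= 0.6, logical(1))
    ranked <- ranked[keep]
  }
  expect_equal(sel$selected, selected)
  expect_true(length(sel$selected) >= 1)
  # the near-duplicate pair was actually straddling the threshold
  expect_gt(matrix_affinity(views$v_a, views$v_b), 0.6)
  expect_lt(matrix_affinity(views$v_a, views$v_c), 0.6)
})

test_that("selection invariants: subset ordering, reasons, affinity cap", {
  views <- list(
    dup1 = diag(8), dup2 = diag(8),           # identical: one must go
    flat = matrix(1, 8, 8),                   # high entropy: removed
    other = random_similarity(8, seed = 5)^6
  )
  sel <- select_similarities(views, c1 = 0.6, c2 = 0.6)
  expect_true(all(sel$selected %in% sel$ranked))
  expect_true(all(sel$ranked %in% names(views)))
  expect_equal(sel$eliminated[["flat"]], "high_entropy")
  # identical duplicates: lexicographic tie-break keeps dup1
  expect_true("dup1" %in% sel$selected)
  expect_equal(sel$eliminated[["dup2"]], "redundant_with:dup1")
  # any two selected views have affinity at most c2
  if (length(sel$selected) > 1) {
    combs <- utils::combn(sel$selected, 2)
    for (k in seq_len(ncol(combs)))
      expect_lte(matrix_affinity(views[[combs[1, k]]],
                                 views[[combs[2, k]]]), 0.6)
  }
  # single candidate below threshold is selected
  single <- select_similarities(list(only = diag(5)))
  expect_equal(single$selected, "only")
})

test_that("selection is deterministic given names and values", {
  views <- list(a = random_similarity(6, seed = 1)^6,
                b = random_similarity(6, seed = 2)^6)
  s1 <- select_similarities(views)
  s2 <- select_similarities(views)
  expect_identical(s1$selected, s2$selected)
  expect_identical(s1$entropies, s2$entropies)
})
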