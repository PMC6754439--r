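# Shared fixtures, built in code. Matrices are kept tiny; anything slow
# (network training) uses a deliberately small configuration.

# canonical 2-drug interaction matrix with one interaction
tiny_Y <- function() matrix(c(0, 1, 1, 0), 2, 2)

# random valid similarity matrix: symmetric, [0,1], unit diagonal
random_similarity <- function(m, seed = 1) {
  set.seed(seed)
  A <- matrix(runif(m * m), m, m)
  A <- (A + t(A)) / 2
  diag(A) <- 1
  A
}

# random valid interaction matrix with both classes present
random_interactions <- function(m, p = 0.3, seed = 1) {
  set.seed(seed)
  Y <- matrix(0, m, m)
  up <- upper.tri(Y)
  Y[up] <- as.numeric(runif(sum(up)) < p)
  if (sum(Y[up]) == 0) Y[1, 2] <- 1
  if (all(Y[up] == 1)) Y[1, 2] <- 0
  Y + t(Y)
}

# write a matrix as a bare delimited file (no headers)
write_bare_matrix <- function(A, path, sep = ",") {
  utils::write.table(A, path, sep = sep, row.names = FALSE,
                     col.names = FALSE)
  path
}

# small network configuration so training-based tests stay fast
small_nn <- function(...) {
  nn_config(hidden = c(16L, 16L), epochs = 10L, batch_size = 64L, ...)
}

# small synthetic benchmark + cv settings for pipeline-level tests
small_cv <- function(bench, nn = small_nn(), seed = 1, ...) {
  run_cv(bench$views, bench$Y, k = 3, repeats = 1, seed = seed,
         snf_k = 5, snf_t = 5, nn = nn, ...)
}

# independent row-entropy oracle: literal double loop over the formulas
entropy_oracle <- function(A, exclude_diagonal = FALSE) {
  m <- nrow(A)
  E <- numeric(m)
  for (i in seq_len(m)) {
    a <- A[i, ]
    if (exclude_diagonal) a <- a[-i]
    s <- sum(a)
    if (s == 0) next
    for (j in seq_along(a)) {
      p <- a[j] / s
      if (p > 0) E[i] <- E[i] - p * log(p)
    }
  }
  mean(E)
}

# permute drugs in a matrix (rows and columns together)
permute_matrix <- function(A, perm) A[perm, perm]
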