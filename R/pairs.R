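# Ordered-pair feature construction: the feature vector of pair (i, j) is
# row i of the fused similarity matrix concatenated with row j, so features
# are order-sensitive even though the interaction label is symmetric.

#' Feature vector of an ordered drug pair
#'
#' Concatenates row `i` and row `j` of the fused similarity matrix into a
#' length-`2m` vector. `pair_feature(F, i, j)` differs from
#' `pair_feature(F, j, i)` in general; self-pairs have identical halves.
#'
#' @param F Fused m x m similarity matrix.
#' @param i,j Drug indices in `1..m`.
#' @return Numeric vector of length `2 * nrow(F)`.
#' @export
pair_feature <- function(F, i, j) {
  m <- nrow(F)
  if (i < 1 || i > m || j < 1 || j > m)
    stop("pair indices must lie in 1..", m)
  c(F[i, ], F[j, ])
}

#' Enumerate the unordered pair universe used for training and evaluation
#'
#' All pairs `i < j`; self-pairs are excluded by default because
#' self-interaction is not a DDI (set `include_self = TRUE` to add them).
#'
#' @param m Number of drugs.
#' @param include_self Include the diagonal pairs `(i, i)`.
#' @return Two-column integer matrix of (i, j) indices.
#' @export
enumerate_pairs <- function(m, include_self = FALSE) {
  idx <- which(upper.tri(matrix(0, m, m), diag = include_self),
               arr.ind = TRUE)
  cbind(i = idx[, 1L], j = idx[, 2L])
}

#' Build a labelled pair dataset from the fused matrix
#'
#' One sample per listed pair: features are the concatenated rows of `F`
#' ([pair_feature()]), labels are the corresponding entries of `Y`
#' (zero-labelled pairs are treated as negatives, the standard
#' approximation when absence of evidence stands in for absence of
#' interaction). With `both_orders = TRUE` each non-self pair additionally
#' contributes its reversed ordering with the same label, which doubles the
#' training data and teaches the network the label symmetry.
#'
#' @param F Fused m x m similarity matrix.
#' @param Y Binary interaction matrix.
#' @param pairs Two-column matrix of (i, j) indices.
#' @param both_orders Also include each pair reversed (default FALSE).
#' @return List with feature matrix `x` (one row per sample), label vector
#'   `y` and the `pairs` matrix actually used (after augmentation).
#' @export
build_pair_dataset <- function(F, Y, pairs, both_orders = FALSE) {
  pairs <- matrix(as.integer(pairs), ncol = 2L,
                  dimnames = list(NULL, c("i", "j")))
  m <- nrow(F)
  if (length(pairs) > 0L && (min(pairs) < 1L || max(pairs) > m))
    stop("pair indices must lie in 1..", m)
  if (both_orders && nrow(pairs) > 0L) {
    rev_pairs <- pairs[pairs[, 1L] != pairs[, 2L], c(2L, 1L), drop = FALSE]
    colnames(rev_pairs) <- c("i", "j")
    pairs <- rbind(pairs, rev_pairs)
  }
  x <- cbind(F[pairs[, 1L], , drop = FALSE], F[pairs[, 2L], , drop = FALSE])
  y <- Y[pairs]
  list(x = unname(x), y = as.numeric(y), pairs = pairs)
}

#' Score unordered pairs with a trained model
#'
#' Scores each pair in both orderings and averages, making the reported
#' score symmetric in the pair even though the concatenation features are
#' not.
#'
#' @param model Trained [mlp_train()] model.
#' @param F Fused similarity matrix.
#' @param pairs Two-column matrix of (i, j) indices.
#' @return Numeric vector of symmetric scores in (0, 1).
#' @export
score_pairs <- function(model, F, pairs) {
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  x_fwd <- cbind(F[pairs[, 1L], , drop = FALSE], F[pairs[, 2L], , drop = FALSE])
  x_rev <- cbind(F[pairs[, 2L], , drop = FALSE], F[pairs[, 1L], , drop = FALSE])
  (mlp_predict(model, x_fwd) + mlp_predict(model, x_rev)) / 2
}
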