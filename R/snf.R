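# Similarity Network Fusion: iterative KNN-based cross-diffusion that merges
# several similarity matrices into one. Each view contributes a full
# (row-stochastic) transition kernel and a sparse local kernel restricted to
# the K nearest neighbours; at every iteration each view's full kernel is
# diffused through the average of the other views' kernels via its own local
# kernel, which propagates strong local affinities across views while
# suppressing view-specific noise.

#' Full (global) transition kernel of a similarity matrix
#'
#' `P[i, j] = W[i, j] / (2 * sum_{k != i} W[i, k])` off the diagonal and
#' `P[i, i] = 1/2`, so every row sums to 1 and half of each row's mass
#' stays on the drug itself.
#'
#' @param W Similarity matrix whose rows all have positive off-diagonal sum.
#' @return Row-stochastic m x m matrix.
#' @export
snf_global_kernel <- function(W) {
  off <- rowSums(W) - diag(W)
  if (any(off <= 0))
    stop("degenerate row(s) in similarity matrix: zero off-diagonal sum at ",
         paste(utils::head(which(off <= 0), 5L), collapse = ", "))
  P <- W / (2 * off)
  diag(P) <- 0.5
  P
}

#' Local (K-nearest-neighbour) kernel of a similarity matrix
#'
#' Keeps, for each row, only its `K` largest off-diagonal entries (ties
#' broken by lower column index) and normalizes them to sum to 1; all other
#' entries are 0. The sparse kernel encodes the assumption that local
#' similarities are more reliable than weak long-range ones.
#'
#' @param W Similarity matrix.
#' @param K Neighbourhood size, `1 <= K <= m - 1`.
#' @return m x m matrix whose rows sum to 1 where neighbour mass is
#'   positive.
#' @export
snf_local_kernel <- function(W, K) {
  m <- nrow(W)
  if (!is.numeric(K) || length(K) != 1L || K < 1 || K > m - 1)
    stop("K must lie in [1, m - 1]; got K = ", K, " with m = ", m)
  K <- as.integer(K)
  S <- matrix(0, m, m, dimnames = dimnames(W))
  for (i in seq_len(m)) {
    w <- W[i, ]
    w[i] <- -Inf                       # never a neighbour of itself
    nbr <- order(w, decreasing = TRUE)[seq_len(K)]  # stable: ties by index
    mass <- sum(W[i, nbr])
    if (mass > 0) S[i, nbr] <- W[i, nbr] / mass
  }
  S
}

#' Fuse similarity views by cross-diffusion
#'
#' A single view is returned unchanged (fusion is vacuous). Otherwise each
#' view `v` gets a global kernel `P_v` ([snf_global_kernel()]) and a local
#' kernel `S_v` ([snf_local_kernel()]); for `t` iterations every view is
#' updated as `P_v <- S_v %*% mean(P_u, u != v) %*% t(S_v)`, then
#' symmetrized, regularized by adding `alpha` to the diagonal, and
#' row-renormalized so kernels stay row-stochastic. The fused result is the
#' symmetrized mean of the final kernels.
#'
#' @param views Named list of similarity matrices with common dimension m.
#' @param K Neighbourhood size (default 20, capped at m - 1).
#' @param t Number of diffusion iterations (default 20).
#' @param alpha Diagonal regularizer added after each update (default 1).
#' @return Fused m x m similarity matrix: symmetric, finite, non-negative,
#'   every row with positive sum.
#' @export
snf_fuse <- function(views, K = 20, t = 20, alpha = 1) {
  .check_views(views)
  if (t < 1) stop("iteration count t must be >= 1")
  if (length(views) == 1L) return(views[[1L]])
  m <- nrow(views[[1L]])
  K <- min(K, m - 1L)
  P <- lapply(views, snf_global_kernel)
  S <- lapply(views, snf_local_kernel, K = K)
  n_view <- length(views)
  for (iter in seq_len(t)) {
    P_new <- vector("list", n_view)
    for (v in seq_len(n_view)) {
      mean_others <- Reduce(`+`, P[-v]) / (n_view - 1L)
      Pv <- S[[v]] %*% mean_others %*% t(S[[v]])
      Pv <- (Pv + t(Pv)) / 2
      diag(Pv) <- diag(Pv) + alpha
      P_new[[v]] <- Pv / rowSums(Pv)
    }
    P <- P_new
  }
  F_fused <- Reduce(`+`, P) / n_view
  F_fused <- (F_fused + t(F_fused)) / 2
  dimnames(F_fused) <- dimnames(views[[1L]])
  F_fused
}
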