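# Gaussian Interaction Profile (GIP) kernel: drugs whose known-interaction
# profiles are close in Euclidean distance get high similarity. The bandwidth
# is normalized by the mean squared profile norm so that the kernel scale is
# independent of dataset size.

#' GIP bandwidth parameter
#'
#' Computes `gamma_d = gamma_scale / mean_i(|Y_i|^2)` where `Y_i` is drug
#' `i`'s interaction profile (column `i` of `Y`) and `|Y_i|^2` its squared
#' Euclidean norm (for binary `Y`, the drug's interaction count). Dividing
#' by the average interaction count per drug makes the kernel scale
#' independent of dataset size.
#'
#' @param Y Binary symmetric interaction matrix with at least one
#'   interaction.
#' @param gamma_scale Dimensionless bandwidth multiplier (> 0, default 1).
#' @return Positive scalar bandwidth.
#' @export
#' @examples
#' Y <- matrix(c(0, 1, 1, 0), 2, 2)
#' gip_bandwidth(Y)  # mean squared profile norm is 1, so gamma_d = 1
gip_bandwidth <- function(Y, gamma_scale = 1) {
  if (!is.numeric(gamma_scale) || length(gamma_scale) != 1L || gamma_scale <= 0)
    stop("gamma_scale must be a positive scalar")
  Y <- validate_interactions(Y)
  mean_sq_norm <- mean(colSums(Y * Y))
  if (mean_sq_norm == 0)
    stop("GIP bandwidth undefined: interaction matrix is all zero")
  gamma_scale / mean_sq_norm
}

#' Gaussian Interaction Profile similarity
#'
#' `G[i, j] = exp(-gamma_d * ||Y_i - Y_j||^2)` over interaction profiles
#' (columns of `Y`), with the bandwidth from [gip_bandwidth()]. `G` is
#' symmetric with unit diagonal and entries in `(0, 1]`; two drugs with
#' identical profiles get similarity 1.
#'
#' When used inside cross-validation the interaction entries of held-out
#' pairs must be masked to zero in `Y` before calling this function (see
#' [run_cv()]), so that test labels never enter the features.
#'
#' @inheritParams gip_bandwidth
#' @return m x m GIP similarity matrix.
#' @export
#' @examples
#' Y <- matrix(c(0, 1, 1, 0), 2, 2)
#' gip_kernel(Y)[1, 2]  # exp(-2)
gip_kernel <- function(Y, gamma_scale = 1) {
  gamma_d <- gip_bandwidth(Y, gamma_scale)
  Y <- validate_interactions(Y)
  sq <- colSums(Y * Y)
  # ||Y_i - Y_j||^2 = |Y_i|^2 + |Y_j|^2 - 2 <Y_i, Y_j>
  d2 <- outer(sq, sq, "+") - 2 * crossprod(Y)
  d2[d2 < 0] <- 0  # guard tiny negative values from floating cancellation
  G <- exp(-gamma_d * d2)
  G <- (G + t(G)) / 2
  diag(G) <- 1
  dimnames(G) <- dimnames(Y)
  G
}
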