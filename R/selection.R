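# Entropy / distance heuristic for choosing an informative, non-redundant
# subset of similarity views before fusion. High mean row entropy marks a
# view as random-like (its rows spread similarity mass near-uniformly);
# high affinity between two views marks one as redundant.

#' Mean row entropy of a similarity matrix
#'
#' Each row is normalized to a probability distribution
#' `p_ij = a_ij / sum_k(a_ik)` and its Shannon entropy
#' `E_i = -sum_j p_ij log p_ij` computed with the convention
#' `0 log 0 = 0`; the matrix entropy is the mean of `E_i` over rows.
#' Natural logarithm; the maximum for an m x m matrix is `log(m)`
#' (attained by uniform rows), the minimum 0 (one-hot rows).
#'
#' @param A Square numeric matrix with finite non-negative entries (row
#'   entropies are defined for any such matrix; symmetry is not required
#'   here).
#' @param exclude_diagonal Drop the diagonal from row normalization
#'   (default FALSE: the diagonal is part of the row distribution).
#' @return Non-negative scalar entropy (nats).
#' @export
#' @examples
#' matrix_entropy(matrix(1, 4, 4))  # log(4)
matrix_entropy <- function(A, exclude_diagonal = FALSE) {
  if (!is.matrix(A) || !is.numeric(A) || nrow(A) != ncol(A))
    stop("matrix entropy needs a square numeric matrix")
  if (any(!is.finite(A)) || any(A < 0))
    stop("matrix entropy needs finite, non-negative entries")
  if (exclude_diagonal) diag(A) <- 0
  rs <- rowSums(A)
  if (all(rs == 0))
    stop("matrix entropy undefined: all rows sum to zero")
  if (any(rs == 0))
    warning(sum(rs == 0), " zero-sum row(s) contribute entropy 0")
  ok <- rs > 0
  P <- A[ok, , drop = FALSE] / rs[ok]
  H <- ifelse(P > 0, -P * log(P), 0)
  sum(rowSums(H)) / nrow(A)
}

#' Entropy filter and ranking of candidate views
#'
#' Removes every view whose entropy exceeds `c1 * log(m)` (random-like
#' views; a uniform view has entropy `log m` and is always removed for
#' `c1 < 1`) and returns the survivors ordered by ascending entropy,
#' ties broken lexicographically by view name.
#'
#' @param views Named list of similarity matrices with common dimension.
#' @param c1 Entropy threshold coefficient in (0, 1), default 0.6.
#' @param exclude_diagonal Passed to [matrix_entropy()].
#' @return Character vector of surviving view names, ascending entropy.
#' @export
entropy_rank_filter <- function(views, c1 = 0.6, exclude_diagonal = FALSE) {
  .check_views(views)
  if (!(c1 > 0 && c1 < 1)) stop("c1 must lie in (0, 1)")
  m <- nrow(views[[1L]])
  ent <- vapply(views, matrix_entropy, numeric(1),
                exclude_diagonal = exclude_diagonal)
  keep <- ent <= c1 * log(m)
  if (!any(keep))
    stop("similarity selection is empty: all ", length(views),
         " views have entropy above c1 * log(m) = ",
         format(c1 * log(m), digits = 4))
  surv <- names(views)[keep]
  surv[order(ent[keep], surv)]
}

#' Affinity between two similarity matrices
#'
#' `S(A, B) = 1 / (1 + D(A, B))` where `D` is the Euclidean (Frobenius)
#' distance over all `m^2` entries. `S` lies in `(0, 1]`, is symmetric in
#' its arguments and equals 1 iff `A == B`.
#'
#' @param A,B Similarity matrices of the same dimension.
#' @return Scalar affinity in (0, 1].
#' @export
#' @examples
#' matrix_affinity(diag(2), matrix(c(0, 1, 1, 0), 2, 2))  # D = 2, S = 1/3
matrix_affinity <- function(A, B) {
  if (!all(dim(A) == dim(B)))
    stop("matrix affinity: dimension mismatch (", nrow(A), "x", ncol(A),
         " vs ", nrow(B), "x", ncol(B), ")")
  1 / (1 + sqrt(sum((A - B)^2)))
}

#' Select an informative, non-redundant subset of similarity views
#'
#' Two-stage heuristic. First, views with entropy above `c1 * log(m)` are
#' removed ([entropy_rank_filter()]). Then a greedy pass over the ranked
#' list repeatedly moves the lowest-entropy view into the selected set and
#' eliminates every remaining view whose affinity with it exceeds `c2`
#' (recorded as `"redundant_with:<name>"`), until the list is empty. Any
#' two selected views therefore have pairwise affinity at most `c2`.
#'
#' @param views Named list of candidate similarity matrices.
#' @param c1 Entropy threshold coefficient in (0, 1), default 0.6.
#' @param c2 Redundancy affinity threshold in (0, 1), default 0.6.
#' @param exclude_diagonal Passed to [matrix_entropy()].
#' @return Object of class `ddi_selection`: list with `entropies` (all
#'   candidates), `entropy_threshold`, `ranked` (post-filter, ascending
#'   entropy), `selected`, and `eliminated` (named character vector of
#'   reasons, `"high_entropy"` or `"redundant_with:<name>"`).
#' @export
select_similarities <- function(views, c1 = 0.6, c2 = 0.6,
                                exclude_diagonal = FALSE) {
  .check_views(views)
  if (!(c2 > 0 && c2 < 1)) stop("c2 must lie in (0, 1)")
  m <- nrow(views[[1L]])
  ent <- vapply(views, matrix_entropy, numeric(1),
                exclude_diagonal = exclude_diagonal)
  ranked <- entropy_rank_filter(views, c1, exclude_diagonal)
  eliminated <- character(0)
  for (nm in setdiff(names(views), ranked))
    eliminated[nm] <- "high_entropy"
  selected <- character(0)
  remaining <- ranked
  while (length(remaining) > 0L) {
    pick <- remaining[1L]  # lowest entropy (list is sorted)
    selected <- c(selected, pick)
    remaining <- remaining[-1L]
    if (length(remaining) > 0L) {
      aff <- vapply(remaining, function(nm)
        matrix_affinity(views[[pick]], views[[nm]]), numeric(1))
      drop <- aff > c2
      for (nm in remaining[drop])
        eliminated[nm] <- paste0("redundant_with:", pick)
      remaining <- remaining[!drop]
    }
  }
  structure(list(entropies = ent,
                 entropy_threshold = c1 * log(m),
                 ranked = ranked,
                 selected = selected,
                 eliminated = eliminated,
                 c1 = c1, c2 = c2),
            class = "ddi_selection")
}

#' @export
print.ddi_selection <- function(x, ...) {
  cat("Similarity view selection (c1 =", x$c1, ", c2 =", x$c2, ")\n")
  cat("  entropy threshold c1*log(m):", format(x$entropy_threshold, digits = 4), "\n")
  ord <- order(x$entropies)
  for (nm in names(x$entropies)[ord]) {
    status <- if (nm %in% x$selected) "selected"
              else x$eliminated[[nm]]
    cat(sprintf("  %-20s E = %-8.4g %s\n", nm, x$entropies[[nm]], status))
  }
  invisible(x)
}

# shared validation of a named view list
.check_views <- function(views) {
  if (!is.list(views) || length(views) == 0L)
    stop("views must be a non-empty named list of matrices")
  if (is.null(names(views)) || any(!nzchar(names(views))) ||
      anyDuplicated(names(views)))
    stop("views must have unique non-empty names")
  dims <- vapply(views, nrow, integer(1))
  if (any(vapply(views, function(v) nrow(v) != ncol(v), logical(1))) ||
      length(unique(dims)) != 1L)
    stop("all views must be square matrices of a common dimension")
  invisible(TRUE)
}
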