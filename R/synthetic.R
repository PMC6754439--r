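# Self-contained benchmark generator with planted cluster structure. The
# premise the pipeline relies on is that similar drugs have similar
# interactions; the generator plants exactly that dependence: drugs fall
# into latent clusters, interactions occur preferentially between
# "compatible" cluster pairs, and the informative similarity views reflect
# the same clusters. Two adversarial views complete the benchmark: a
# near-uniform noise view (which the entropy filter must remove) and a
# near-duplicate of the first informative view (which the redundancy step
# must remove).

#' Generate a synthetic DDI benchmark
#'
#' Drugs are assigned to `n_clusters` balanced latent clusters and a
#' random symmetric compatibility relation over cluster pairs (including
#' same-cluster) is drawn with density `compat_density`, at least one pair
#' compatible. Interactions arise with probability `p_within` between
#' drugs of compatible clusters and `p_between` otherwise, symmetrized
#' with a zero diagonal.
#'
#' Each informative view reflects the clusters the way real chemical or
#' target similarity matrices do: a drug resembles a handful of
#' same-cluster analogues, graded by a latent position, so similarity is
#' `0.9 * exp(-|u_i - u_j| / 0.15)` within a cluster (per-view latent
#' positions `u ~ U(0, 1)`) and 0 between clusters, perturbed by
#' symmetric multiplicative noise `(1 + N(0, noise_sd))`, clipped to
#' `[0, 1]`, unit diagonal. The graded, sparse rows keep the mean row
#' entropy well below the selection threshold `0.6 * log(m)`; a flat dense
#' block design would be filtered out as random-like (see the methods
#' vignette for the entropy arithmetic).
#'
#' The optional uniform view has every off-diagonal entry `1/m` (row
#' entropy `log(m - 1)`, always above the threshold for `c1 = 0.6`), and
#' the optional duplicate view is the first informative view plus additive
#' symmetric noise with sd 0.001 (affinity with it far above `c2 = 0.6`).
#'
#' @param m Number of drugs (default 60).
#' @param n_clusters Number of latent clusters (default 4;
#'   `m >= 2 * n_clusters`).
#' @param p_within Interaction probability for compatible cluster pairs
#'   (default 0.35).
#' @param p_between Background interaction probability (default 0.02;
#'   must be below `p_within`).
#' @param n_informative Number of cluster-correlated views (default 3).
#' @param noise_sd Multiplicative view noise sd (default 0.05).
#' @param compat_density Probability that a cluster pair is compatible
#'   (default 0.2, giving a positive prevalence near the sparse public
#'   DDI benchmarks).
#' @param uniform_view Include the near-uniform noise view (default TRUE).
#' @param duplicate_view Include the near-duplicate view (default TRUE).
#' @param seed Integer seed; generation is fully reproducible.
#' @return List with `views` (named list of similarity matrices), `Y`
#'   (binary interaction matrix), `clusters` (integer assignment),
#'   `compat` (logical cluster-compatibility matrix) and `ids` (drug
#'   identifiers `"D001"...`).
#' @export
synthetic_benchmark <- function(m = 60L, n_clusters = 4L,
                                p_within = 0.35, p_between = 0.02,
                                n_informative = 3L, noise_sd = 0.05,
                                compat_density = 0.2,
                                uniform_view = TRUE, duplicate_view = TRUE,
                                seed = 1L) {
  if (m < 2L * n_clusters)
    stop("m must be at least 2 * n_clusters")
  if (!(p_between >= 0 && p_between < p_within && p_within <= 1))
    stop("need 0 <= p_between < p_within <= 1")
  if (n_informative < 1L) stop("need at least one informative view")
  set.seed(seed)
  ids <- sprintf("D%03d", seq_len(m))
  clusters <- sample(rep_len(seq_len(n_clusters), m))
  # symmetric compatibility over cluster pairs, incl. same-cluster
  compat <- matrix(FALSE, n_clusters, n_clusters)
  ut <- upper.tri(compat, diag = TRUE)
  compat[ut] <- stats::runif(sum(ut)) < compat_density
  compat <- compat | t(compat)
  if (!any(compat[ut])) {
    pick <- sample(which(ut), 1L)
    compat[pick] <- TRUE
    compat <- compat | t(compat)
  }
  # interactions
  p_pair <- ifelse(compat[cbind(rep(clusters, m), rep(clusters, each = m))],
                   p_within, p_between)
  p_mat <- matrix(p_pair, m, m)
  Y <- matrix(0, m, m)
  up <- upper.tri(Y)
  Y[up] <- as.numeric(stats::runif(sum(up)) < p_mat[up])
  Y <- Y + t(Y)
  if (sum(Y) == 0) {  # degenerate draw on tiny problems: force one interaction
    Y[1L, 2L] <- Y[2L, 1L] <- 1
  }
  dimnames(Y) <- list(ids, ids)
  same_cluster <- outer(clusters, clusters, "==")
  make_informative <- function() {
    u <- stats::runif(m)
    A <- 0.9 * exp(-abs(outer(u, u, "-")) / 0.15)
    A[!same_cluster] <- 0
    noise <- matrix(stats::rnorm(m * m, 0, noise_sd), m, m)
    noise <- (noise + t(noise)) / 2
    A <- A * (1 + noise)
    A <- pmin(pmax((A + t(A)) / 2, 0), 1)
    diag(A) <- 1
    dimnames(A) <- list(ids, ids)
    A
  }
  views <- list()
  for (v in seq_len(n_informative))
    views[[sprintf("informative%d", v)]] <- make_informative()
  if (uniform_view) {
    U <- matrix(1 / m, m, m, dimnames = list(ids, ids))
    diag(U) <- 0
    views[["uniform"]] <- U
  }
  if (duplicate_view) {
    noise <- matrix(stats::rnorm(m * m, 0, 0.001), m, m)
    noise <- (noise + t(noise)) / 2
    D <- pmin(pmax(views[["informative1"]] + noise, 0), 1)
    diag(D) <- 1
    dimnames(D) <- list(ids, ids)
    views[["duplicate"]] <- D
  }
  list(views = views, Y = Y, clusters = clusters, compat = compat, ids = ids)
}

#' Write a synthetic benchmark to disk in the loader formats
#'
#' Writes the drug-ID list, the interaction matrix and every view as CSV
#' (the formats [load_similarity_matrix()] and [load_interaction_matrix()]
#' read), plus a `truth.json` with the cluster assignment and
#' compatibility relation.
#'
#' @param bench Result of [synthetic_benchmark()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_benchmark <- function(bench, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(bench$ids, file.path(dir, "drugs.txt"))
  write_similarity_matrix(bench$Y, file.path(dir, "interactions.csv"),
                          ids = bench$ids)
  for (nm in names(bench$views))
    write_similarity_matrix(bench$views[[nm]],
                            file.path(dir, paste0(nm, ".csv")),
                            ids = bench$ids)
  jsonlite::write_json(list(clusters = bench$clusters,
                            compat = bench$compat),
                       file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}
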