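# End-to-end orchestration: load -> GIP -> select -> fuse -> classify ->
# cross-validated metrics + full-data prediction export, driven by a
# configuration list or YAML/JSON file.

#' Read a pipeline configuration file
#'
#' YAML or JSON (decided by extension). See [run_ndd()] for the accepted
#' fields.
#'
#' @param path Configuration file path.
#' @return Named configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
}

.cfg_get <- function(cfg, name, default) {
  if (is.null(cfg[[name]])) default else cfg[[name]]
}

#' Run the full DDI prediction pipeline
#'
#' Executes load -> GIP -> selection -> fusion -> cross-validated
#' evaluation, then refits on all data and exports ranked pair scores.
#' Inputs come either from files (`drugs`, `interactions`, `views` as a
#' name -> path map) or from the synthetic generator (`synthetic: {...}`
#' with [synthetic_benchmark()] arguments).
#'
#' Recognized configuration fields (all optional unless noted):
#' `drugs`, `interactions`, `views` (required unless `synthetic` given);
#' `synthetic` (list of generator arguments); `out_dir`; `seed`;
#' `k`, `repeats`, `aggregate`; `c1`, `c2`; `snf_k`, `snf_t`, `snf_alpha`;
#' `gip_scope`, `gip_gamma`, `include_gip`; `nn` (list of [nn_config()]
#' arguments); `threshold` (decision threshold for flagging candidate
#' DDIs, default 0.5).
#'
#' Outputs written to `out_dir` (if given): `report.json` (metrics
#' summary and resolved settings), `selection.json` (entropies,
#' eliminations), `predictions.tsv` (drug_id_1, drug_id_2, score, rank,
#' flag; sorted by descending score), `manifest.json`.
#'
#' @param config Configuration list or path to a YAML/JSON file.
#' @return List of class `ddi_run` with `cv` (a `ddi_cv`), `selection`
#'   (full-data selection), `predictions` (data frame of scored pairs),
#'   `settings`.
#' @export
run_ndd <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  seed <- .cfg_get(config, "seed", 1L)
  if (!is.null(config$synthetic)) {
    bench <- do.call(synthetic_benchmark,
                     c(config$synthetic,
                       if (is.null(config$synthetic$seed)) list(seed = seed)))
    views <- bench$views
    Y <- bench$Y
    ids <- bench$ids
  } else {
    if (is.null(config$drugs) || is.null(config$interactions))
      stop("config needs either 'synthetic' or 'drugs' + 'interactions'")
    ids <- read_drug_index(config$drugs)
    Y <- load_interaction_matrix(config$interactions, ids)
    view_paths <- config$views
    views <- list()
    for (nm in names(view_paths))
      views[[nm]] <- load_similarity_matrix(view_paths[[nm]], nm, ids)
  }
  nn <- do.call(nn_config, c(.cfg_get(config, "nn", list()),
                             if (is.null(config$nn$seed)) list(seed = seed)))
  settings <- list(
    k = .cfg_get(config, "k", 5L),
    repeats = .cfg_get(config, "repeats", 1L),
    seed = seed,
    c1 = .cfg_get(config, "c1", 0.6),
    c2 = .cfg_get(config, "c2", 0.6),
    snf_k = .cfg_get(config, "snf_k", 20L),
    snf_t = .cfg_get(config, "snf_t", 20L),
    snf_alpha = .cfg_get(config, "snf_alpha", 1),
    gip_scope = .cfg_get(config, "gip_scope", "fold"),
    gip_gamma = .cfg_get(config, "gip_gamma", 1),
    include_gip = .cfg_get(config, "include_gip", TRUE),
    aggregate = .cfg_get(config, "aggregate", "per_fold"),
    threshold = .cfg_get(config, "threshold", 0.5))
  message("[cv] evaluating pipeline: m = ", length(ids), ", ",
          length(views), " file view(s), k = ", settings$k,
          ", repeats = ", settings$repeats)
  cv <- run_cv(views, Y, k = settings$k, repeats = settings$repeats,
               seed = seed, c1 = settings$c1, c2 = settings$c2,
               snf_k = settings$snf_k, snf_t = settings$snf_t,
               snf_alpha = settings$snf_alpha, nn = nn,
               gip_scope = settings$gip_scope,
               gip_gamma = settings$gip_gamma,
               include_gip = settings$include_gip,
               aggregate = settings$aggregate)
  # discovery fit: full data, score every unordered pair
  message("[fit] refitting on all data for prediction export")
  candidates <- views
  if (settings$include_gip)
    candidates$gip <- gip_kernel(Y, settings$gip_gamma)
  sel <- select_similarities(candidates, c1 = settings$c1, c2 = settings$c2)
  fused <- snf_fuse(candidates[sel$selected], K = settings$snf_k,
                    t = settings$snf_t, alpha = settings$snf_alpha)
  pairs <- enumerate_pairs(length(ids))
  full_set <- build_pair_dataset(fused, Y, pairs, both_orders = TRUE)
  model <- mlp_train(full_set$x, full_set$y, nn)
  scores <- score_pairs(model, fused, pairs)
  ord <- order(scores, decreasing = TRUE)
  predictions <- data.frame(
    drug_id_1 = ids[pairs[ord, 1L]],
    drug_id_2 = ids[pairs[ord, 2L]],
    known = Y[pairs][ord],
    score = scores[ord],
    rank = seq_along(ord),
    flag = scores[ord] > settings$threshold)
  result <- structure(list(cv = cv, selection = sel,
                           predictions = predictions, settings = settings,
                           model = model),
                      class = "ddi_run")
  out_dir <- config$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    report <- list(settings = settings,
                   nn = unclass(nn),
                   summary = cv$summary,
                   per_fold = cv$per_fold)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(list(entropies = as.list(sel$entropies),
                              entropy_threshold = sel$entropy_threshold,
                              ranked = sel$ranked,
                              selected = sel$selected,
                              eliminated = as.list(sel$eliminated)),
                         file.path(out_dir, "selection.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.table(predictions, file.path(out_dir, "predictions.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_run_manifest(file.path(out_dir, "manifest.json"), ids,
                       names(candidates), Y,
                       extra = list(seed = seed, selected = sel$selected))
    message("[out] wrote report.json, selection.json, predictions.tsv, ",
            "manifest.json to ", out_dir)
  }
  result
}

#' @export
print.ddi_run <- function(x, ...) {
  print(x$cv)
  cat("Selected views:", paste(x$selection$selected, collapse = ", "), "\n")
  cat("Top prediction:", x$predictions$drug_id_1[1], "-",
      x$predictions$drug_id_2[1],
      sprintf("(score %.3f)\n", x$predictions$score[1]))
  invisible(x)
}
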