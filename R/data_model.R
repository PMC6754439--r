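# Core types, matrix file I/O and validation shared by all pipeline stages.
# All matrices are plain base-R numeric matrices indexed by a shared ordered
# drug-identifier vector; row/column k of every matrix in a run refers to the
# same drug.

#' Validate an ordered drug identifier list
#'
#' The drug index ties every matrix in a run together: position `k` of the
#' index corresponds to row and column `k` of every similarity and
#' interaction matrix.
#'
#' @param ids Character vector of unique drug identifiers (e.g. DrugBank
#'   accessions such as `"DB00642"`), length at least 2.
#' @return The validated character vector.
#' @export
#' @examples
#' drug_index(c("DB00001", "DB00002", "DB00003"))
drug_index <- function(ids) {
  ids <- as.character(ids)
  if (length(ids) < 2L)
    stop("a drug index needs at least 2 drugs, got ", length(ids))
  if (anyDuplicated(ids))
    stop("drug identifiers must be unique; duplicated: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(is.na(ids) | ids == ""))
    stop("drug identifiers must be non-missing, non-empty strings")
  ids
}

#' Read a drug identifier list from file (one identifier per line)
#'
#' @param path Path to a text file with one drug identifier per line.
#' @return Validated character vector of identifiers.
#' @export
read_drug_index <- function(path) {
  if (!file.exists(path)) stop("drug index file not found: ", path)
  ids <- readLines(path, warn = FALSE)
  drug_index(trimws(ids[nzchar(trimws(ids))]))
}

# Parse a delimited numeric matrix file. The delimiter (comma or tab) and an
# optional leading header row / identifier column are auto-detected: header
# cells are whatever fails numeric conversion.
.read_matrix_file <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character",
                           quote = "\"", comment.char = "")
  raw <- as.matrix(raw)
  is_num <- function(x) {
    x <- trimws(x)
    nzchar(x) & !is.na(suppressWarnings(as.numeric(x)))
  }
  row_ids <- col_ids <- NULL
  # a header row/column must be entirely non-numeric; isolated non-numeric
  # cells inside the body are format errors, not identifiers
  has_header_row <- all(!is_num(raw[1L, -1L]))
  has_header_col <- all(!is_num(raw[-1L, 1L]))
  if (has_header_row) {
    col_ids <- trimws(raw[1L, ])
    raw <- raw[-1L, , drop = FALSE]
  }
  if (has_header_col) {
    row_ids <- trimws(raw[, 1L])
    raw <- raw[, -1L, drop = FALSE]
    if (has_header_row) col_ids <- col_ids[-1L]
  } else if (has_header_row && length(col_ids) == ncol(raw) + 1L) {
    # header row had a leading cell above a numeric first column
    col_ids <- col_ids[-1L]
  }
  vals <- suppressWarnings(as.numeric(raw))
  if (anyNA(vals))
    stop("non-numeric or missing entries in matrix file: ", path)
  A <- matrix(vals, nrow = nrow(raw), ncol = ncol(raw))
  list(values = A, row_ids = row_ids, col_ids = col_ids)
}

# Reorder a loaded matrix so its header identifiers align with `ids`;
# header ids must be a permutation of the index.
.align_to_index <- function(parsed, ids, path) {
  A <- parsed$values
  for (dim_ids in list(parsed$row_ids, parsed$col_ids)) {
    if (!is.null(dim_ids) && !setequal(dim_ids, ids))
      stop("identifiers in ", path,
           " are not a permutation of the drug index")
  }
  if (!is.null(parsed$row_ids)) A <- A[match(ids, parsed$row_ids), , drop = FALSE]
  if (!is.null(parsed$col_ids)) A <- A[, match(ids, parsed$col_ids), drop = FALSE]
  A
}

#' Validate a similarity matrix
#'
#' Checks that `A` is a square numeric matrix with finite, non-negative
#' entries, symmetric within `tol`. Asymmetric input within reason is
#' symmetrized as `(A + t(A))/2` with a warning; asymmetry beyond `max_asym`
#' is an error.
#'
#' @param A Numeric m x m matrix.
#' @param name View label used in messages.
#' @param max_value Upper bound for entries (default `1 + 1e-8`; similarity
#'   views are expected in `[0, 1]`). Use `Inf` to disable.
#' @param tol Absolute symmetry tolerance below which no warning is issued.
#' @return The validated (possibly symmetrized) matrix.
#' @export
validate_similarity <- function(A, name = "similarity", max_value = 1 + 1e-8,
                                tol = 1e-8) {
  if (!is.matrix(A) || !is.numeric(A))
    stop(name, ": similarity must be a numeric matrix")
  if (nrow(A) != ncol(A))
    stop(name, ": similarity matrix must be square, got ",
         nrow(A), "x", ncol(A))
  if (any(!is.finite(A)))
    stop(name, ": similarity entries must be finite (no NA/NaN/Inf)")
  if (any(A < 0))
    stop(name, ": similarity entries must be non-negative")
  if (any(A > max_value))
    stop(name, ": similarity entries exceed ", format(max_value))
  asym <- max(abs(A - t(A)))
  if (asym > tol) {
    warning(name, ": asymmetric input (max |A - t(A)| = ",
            format(asym, digits = 3), "); symmetrizing as (A + t(A))/2")
  }
  A <- (A + t(A)) / 2
  A
}

#' Load a drug similarity matrix from a delimited text file
#'
#' Reads a comma- or tab-delimited m x m numeric matrix (delimiter
#' auto-detected), optionally carrying a header row and/or identifier
#' column; header identifiers must be a permutation of `ids` and are used
#' to align the matrix to the index order.
#'
#' @param path Path to the matrix file.
#' @param name View label (e.g. `"chemical"`, `"target"`).
#' @param ids Drug index (see [drug_index()]).
#' @return Validated m x m similarity matrix with `ids` as dimnames.
#' @export
load_similarity_matrix <- function(path, name, ids) {
  ids <- drug_index(ids)
  parsed <- .read_matrix_file(path)
  A <- .align_to_index(parsed, ids, path)
  m <- length(ids)
  if (nrow(A) != m || ncol(A) != m)
    stop(name, ": matrix in ", path, " is ", nrow(A), "x", ncol(A),
         " but the drug index has m = ", m)
  A <- validate_similarity(A, name = name)
  dimnames(A) <- list(ids, ids)
  A
}

#' Validate a binary interaction matrix
#'
#' Entries must be 0/1; the matrix must be symmetric (asymmetry is an
#' error, unlike similarity views, because interaction labels are facts,
#' not measurements); non-zero diagonal entries are zeroed with a warning
#' since self-interaction is not a DDI.
#'
#' @param Y Numeric m x m matrix of 0/1 values.
#' @param require_positive Require at least one interaction (default FALSE;
#'   the GIP kernel enforces it at use time).
#' @return The validated matrix.
#' @export
validate_interactions <- function(Y, require_positive = FALSE) {
  if (!is.matrix(Y) || !is.numeric(Y))
    stop("interaction matrix must be a numeric matrix")
  if (nrow(Y) != ncol(Y))
    stop("interaction matrix must be square, got ", nrow(Y), "x", ncol(Y))
  if (any(!is.finite(Y)) || !all(Y %in% c(0, 1)))
    stop("interaction matrix entries must all be 0 or 1")
  if (any(Y != t(Y)))
    stop("interaction matrix is not symmetric: Y[i,j] != Y[j,i] somewhere")
  if (any(diag(Y) != 0)) {
    warning("non-zero diagonal in interaction matrix; zeroing ",
            sum(diag(Y) != 0), " self-interaction entries")
    diag(Y) <- 0
  }
  if (require_positive && sum(Y) == 0)
    stop("interaction matrix has no interactions")
  Y
}

#' Load a binary drug-drug interaction matrix from a delimited text file
#'
#' @inheritParams load_similarity_matrix
#' @return Validated m x m 0/1 matrix with `ids` as dimnames.
#' @export
load_interaction_matrix <- function(path, ids) {
  ids <- drug_index(ids)
  parsed <- .read_matrix_file(path)
  Y <- .align_to_index(parsed, ids, path)
  m <- length(ids)
  if (nrow(Y) != m || ncol(Y) != m)
    stop("interaction matrix in ", path, " is ", nrow(Y), "x", ncol(Y),
         " but the drug index has m = ", m)
  Y <- validate_interactions(Y)
  dimnames(Y) <- list(ids, ids)
  Y
}

#' Count the ordered-pair universe of an interaction matrix
#'
#' Bookkeeping convention of the benchmark tables: the pair universe is all
#' `m^2` ordered pairs including self-pairs, positives are the entries of
#' `Y` equal to 1 (each unordered interaction counted in both directions),
#' and negatives are the remainder. Training/evaluation pair enumeration is
#' a separate decision made in [run_cv()] (unordered pairs, self-pairs
#' excluded).
#'
#' @param Y Validated m x m binary interaction matrix.
#' @return Named list with integer `total`, `positives`, `negatives`.
#' @export
#' @examples
#' Y <- matrix(c(0, 1, 1, 0), 2, 2)
#' count_pair_universe(Y)  # total 4, positives 2, negatives 2
count_pair_universe <- function(Y) {
  Y <- validate_interactions(Y)
  m <- nrow(Y)
  total <- as.double(m)^2
  positives <- sum(Y)
  list(total = total, positives = positives, negatives = total - positives)
}

#' Write a matrix as CSV with drug identifiers
#'
#' Round-trip companion of [load_similarity_matrix()]: the written file has
#' a header row and identifier column and reloads to the same values.
#'
#' @param A Matrix to write; dimnames are used as identifiers if present.
#' @param path Output file path.
#' @param ids Optional identifiers overriding `rownames(A)`.
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(A, path, ids = rownames(A)) {
  if (is.null(ids)) ids <- paste0("drug", seq_len(nrow(A)))
  df <- data.frame(id = ids, A, check.names = FALSE)
  colnames(df) <- c("id", ids)
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Write a run manifest recording the inputs of an analysis
#'
#' @param path Output JSON path.
#' @param ids Drug index.
#' @param view_names Names of the similarity views in the run.
#' @param Y Interaction matrix (for pair-universe counts).
#' @param extra Optional named list merged into the manifest.
#' @return The manifest list, invisibly.
#' @export
write_run_manifest <- function(path, ids, view_names, Y, extra = list()) {
  counts <- count_pair_universe(Y)
  manifest <- c(list(
    m = length(ids),
    views = as.character(view_names),
    pair_total = counts$total,
    pair_positives = counts$positives,
    pair_negatives = counts$negatives
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
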