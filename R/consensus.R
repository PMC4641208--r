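# Consensus scoring: P x M score matrix, similarity inversion, column-wise
# min-max normalization and row-average consensus.

#' Assemble a score matrix
#'
#' Collects per-method pairwise scores into the `P x M` matrix that the
#' consensus is computed from. Exactly one score per (pair, method) cell is
#' required.
#'
#' @param scores List of [method_score()] objects (any order).
#' @param pairs Two-column data frame or matrix of (query_id, db_id) giving
#'   the row order; defaults to the unique pairs in `scores` in order of
#'   first appearance.
#' @param methods Character vector giving the column order; defaults to the
#'   unique methods in `scores` in order of first appearance.
#' @return Object of class `ScoreMatrix`: `pair_index` (data frame
#'   query_id/db_id), `methods`, `values` (P x M), `kinds` (per method).
#' @export
build_score_matrix <- function(scores, pairs = NULL, methods = NULL) {
  df <- scores_to_df(scores)
  if (is.null(df) || !nrow(df)) stop("no scores given")
  if (is.null(pairs)) {
    pairs <- unique(df[, c("query_id", "db_id")])
  } else {
    pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
    names(pairs)[1:2] <- c("query_id", "db_id")
  }
  rownames(pairs) <- NULL
  if (is.null(methods)) methods <- unique(df$method)
  p <- nrow(pairs); m <- length(methods)

  kinds <- character(m); names(kinds) <- methods
  for (mm in methods) {
    k <- unique(df$kind[df$method == mm])
    if (length(k) != 1L)
      stop("method '", mm, "' has inconsistent or missing score kind")
    kinds[mm] <- k
  }

  pair_key <- paste(pairs$query_id, pairs$db_id, sep = "\r")
  row_i <- match(paste(df$query_id, df$db_id, sep = "\r"), pair_key)
  col_j <- match(df$method, methods)
  inside <- !is.na(row_i) & !is.na(col_j)

  cell <- paste(row_i[inside], col_j[inside])
  dup <- duplicated(cell)
  if (any(dup)) {
    d1 <- which(inside)[dup][1L]
    stop("duplicate score for pair (", df$query_id[d1], ", ", df$db_id[d1],
         ") method '", df$method[d1], "'")
  }
  values <- matrix(NA_real_, p, m, dimnames = list(NULL, methods))
  values[cbind(row_i[inside], col_j[inside])] <- df$value[inside]
  if (anyNA(values)) {
    hole <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop("missing score for pair (", pairs$query_id[hole[1L]], ", ",
         pairs$db_id[hole[1L]], ") method '", methods[hole[2L]], "'")
  }
  structure(list(pair_index = pairs[, c("query_id", "db_id")],
                 methods = methods, values = values, kinds = kinds),
            class = "ScoreMatrix")
}

#' Convert similarity columns to dissimilarities
#'
#' Similarity columns (bounded in `[0, 1]`, e.g. a TM-score) are replaced by
#' `1 - value` and relabeled as distances; distance columns pass through
#' unchanged. Applying this to a matrix with no similarity columns is an
#' error, which guards against double inversion.
#'
#' @param matrix A [build_score_matrix()] result.
#' @return A `ScoreMatrix` whose columns are all distances.
#' @export
to_dissimilarity <- function(matrix) {
  stopifnot(inherits(matrix, "ScoreMatrix"))
  sim <- which(matrix$kinds == "similarity")
  if (!length(sim))
    stop("no similarity columns to invert (already all distances?)")
  for (j in sim) {
    v <- matrix$values[, j]
    if (any(v < 0 | v > 1))
      stop("similarity column '", matrix$methods[j],
           "' has values outside [0, 1]; cannot invert")
    matrix$values[, j] <- 1 - v
    matrix$kinds[j] <- "distance"
  }
  matrix
}

#' Min-max normalize each method column
#'
#' Feature scaling per column: `(x - min) / (max - min)`, mapping every
#' method's dissimilarities onto `[0, 1]`. A degenerate column (max == min)
#' is set to all zeros: that method sees all pairs as equally similar and
#' contributes no discrimination.
#'
#' @param matrix A `ScoreMatrix` whose columns are all distances
#'   (see [to_dissimilarity()]).
#' @return The matrix with normalized values.
#' @export
minmax_normalize_columns <- function(matrix) {
  stopifnot(inherits(matrix, "ScoreMatrix"))
  if (any(matrix$kinds != "distance"))
    stop("all columns must be distances before normalization; run to_dissimilarity()")
  for (j in seq_along(matrix$methods)) {
    v <- matrix$values[, j]
    rng <- range(v)
    matrix$values[, j] <- if (rng[2L] > rng[1L]) (v - rng[1L]) / (rng[2L] - rng[1L]) else 0
  }
  matrix
}

#' Consensus scores from a normalized matrix
#'
#' Row means of the normalized `P x M` matrix: one consensus dissimilarity
#' per pair, 0 meaning most similar.
#'
#' @param normalized A normalized `ScoreMatrix`
#'   (see [minmax_normalize_columns()]).
#' @return Object of class `ConsensusResult`: `pair_index`, `methods`,
#'   `raw` (if attached), `normalized` (P x M), `consensus` (length P).
#' @export
consensus_scores <- function(normalized) {
  stopifnot(inherits(normalized, "ScoreMatrix"))
  v <- normalized$values
  if (any(v < 0 | v > 1)) stop("normalized values must lie in [0, 1]")
  structure(list(pair_index = normalized$pair_index,
                 methods = normalized$methods,
                 raw = attr(normalized, "raw_values"),
                 normalized = v, consensus = rowMeans(v)),
            class = "ConsensusResult")
}

#' Full consensus pipeline over raw method scores
#'
#' Convenience wrapper: invert similarities, min-max normalize, average.
#'
#' @param matrix A raw [build_score_matrix()] result.
#' @return A `ConsensusResult` carrying the raw values alongside.
#' @export
consensus_from_matrix <- function(matrix) {
  raw <- matrix$values
  if (any(matrix$kinds == "similarity")) matrix <- to_dissimilarity(matrix)
  norm <- minmax_normalize_columns(matrix)
  attr(norm, "raw_values") <- raw
  consensus_scores(norm)
}

#' Write / read a consensus result as TSV
#'
#' Lossless (to 6 decimals) round trip of pair ids, per-method raw and
#' normalized scores, and the consensus column. Column order is fixed:
#' `query_id`, `db_id`, `<method>_raw`..., `<method>_norm`..., `consensus`.
#'
#' @param result A `ConsensusResult` (with raw values attached).
#' @param path Output TSV path.
#' @export
write_scores_tsv <- function(result, path) {
  stopifnot(inherits(result, "ConsensusResult"))
  m <- result$methods
  raw <- result$raw
  if (is.null(raw)) raw <- matrix(NA_real_, nrow(result$normalized), length(m))
  df <- data.frame(result$pair_index, stringsAsFactors = FALSE)
  for (j in seq_along(m)) df[[paste0(m[j], "_raw")]] <- sprintf("%.6f", raw[, j])
  for (j in seq_along(m)) df[[paste0(m[j], "_norm")]] <- sprintf("%.6f", result$normalized[, j])
  df$consensus <- sprintf("%.6f", result$consensus)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scores_tsv
#' @return `read_scores_tsv` returns the `ConsensusResult` stored at `path`.
#' @export
read_scores_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("query_id", "db_id", "consensus") %in% names(df)))
    stop("malformed score file: missing required columns")
  raw_cols <- grep("_raw$", names(df), value = TRUE)
  norm_cols <- grep("_norm$", names(df), value = TRUE)
  methods <- sub("_raw$", "", raw_cols)
  if (!identical(methods, sub("_norm$", "", norm_cols)))
    stop("malformed score file: raw/norm column mismatch")
  num <- function(x) {
    v <- suppressWarnings(as.numeric(x))
    if (length(v) && anyNA(v)) stop("malformed score file: non-numeric cell")
    v
  }
  p <- nrow(df)
  as_mat <- function(cols) {
    vals <- if (p) vapply(df[cols], num, numeric(p)) else numeric(0)
    matrix(vals, nrow = p, ncol = length(cols), dimnames = list(NULL, methods))
  }
  structure(list(pair_index = df[, c("query_id", "db_id")],
                 methods = methods,
                 raw = as_mat(raw_cols),
                 normalized = as_mat(norm_cols),
                 consensus = num(df$consensus)),
            class = "ConsensusResult")
}
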