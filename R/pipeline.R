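# End-to-end pipeline: domains -> job farm -> per-method scores ->
# consensus -> clustering -> F-measure.

#' Run the full multicriteria comparison pipeline
#'
#' All-to-all comparison of `domains` with every registered method,
#' consensus scoring, average-linkage clustering of the consensus distance
#' matrix, and (when fold labels are present) F-measure evaluation at `C`
#' clusters.
#'
#' @param domains List of [protein_domain()] objects.
#' @param registry A [method_registry()].
#' @param n_workers Workers for the parallel job farm.
#' @param C Number of clusters to cut to (default 5).
#' @param threshold_angstrom,min_separation Contact-map parameters.
#' @return List with `jobs`, `scores` (list of [method_score()]), `matrix`
#'   (`ScoreMatrix`), `consensus` (`ConsensusResult`), `dist`
#'   (`DistanceMatrix`), `dendrogram`, `assignments`, and `f_report`
#'   (`FMeasureReport` or NULL when labels are absent).
#' @export
mcpsc_pipeline <- function(domains, registry = method_registry(),
                           n_workers = 1L, C = 5L,
                           threshold_angstrom = 8.0, min_separation = 2L) {
  store <- domain_store(domains)
  jobs <- generate_jobs(domains, domains, registry)
  scores <- execute_parallel(jobs, registry, store, n_workers,
                             threshold_angstrom, min_separation)
  mat <- build_score_matrix(scores)
  cons <- consensus_from_matrix(mat)
  dm <- consensus_to_distance_matrix(cons$pair_index, cons$consensus)
  dend <- hclust_average(dm)
  assignments <- cut_to_k(dend, C)
  labels <- stats::setNames(
    vapply(domains, function(d) d$fold_label %||% NA_character_, character(1)),
    vapply(domains, `[[`, character(1), "id"))
  f_report <- if (!anyNA(labels)) f_measure(assignments, labels, C)
  list(jobs = jobs, scores = scores, matrix = mat, consensus = cons,
       dist = dm, dendrogram = dend, assignments = assignments,
       f_report = f_report)
}

#' Cluster one dissimilarity column and score it against labels
#'
#' Helper for comparing individual methods to the consensus: builds the
#' symmetric distance matrix from a single method's dissimilarities,
#' clusters with average linkage, cuts to `C`, and computes the F-measure.
#'
#' @param pairs Two-column data frame of (query_id, db_id).
#' @param dissim Dissimilarity per pair (larger = less similar).
#' @param labels Named character vector: domain id -> fold class.
#' @param C Number of clusters.
#' @return An `FMeasureReport`.
#' @export
cluster_f <- function(pairs, dissim, labels, C) {
  dm <- consensus_to_distance_matrix(pairs, dissim)
  f_measure(cut_to_k(hclust_average(dm), C), labels, C)
}
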