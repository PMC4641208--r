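# Evaluation: consensus scores -> symmetric distance matrix -> average
# linkage clustering -> F-measure against fold labels.

#' Build a symmetric distance matrix from consensus scores
#'
#' Bridges pairwise consensus dissimilarities to clustering: the distance
#' between two domains is the mean of the two directed consensus values
#' (the built-in methods are near-symmetric; the compression distance is
#' symmetric by construction). The diagonal is forced to zero.
#'
#' @param pairs Two-column data frame/matrix of (query_id, db_id) covering
#'   all ordered pairs over the domain set.
#' @param consensus Numeric vector of consensus scores, one per pair row.
#' @return Object of class `DistanceMatrix`: `ids` (sorted) and `values`
#'   (K x K symmetric, zero diagonal).
#' @export
consensus_to_distance_matrix <- function(pairs, consensus) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  names(pairs)[1:2] <- c("query_id", "db_id")
  if (nrow(pairs) != length(consensus))
    stop("pair count != consensus length")
  ids <- sort(unique(c(pairs$query_id, pairs$db_id)))
  k <- length(ids)
  directed <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  directed[cbind(match(pairs$query_id, ids), match(pairs$db_id, ids))] <- consensus
  off <- which(upper.tri(directed) | lower.tri(directed))
  if (anyNA(directed[off])) {
    hole <- which(is.na(directed) & (upper.tri(directed) | lower.tri(directed)),
                  arr.ind = TRUE)[1L, ]
    stop("missing consensus for pair (", ids[hole[1L]], ", ", ids[hole[2L]], ")")
  }
  vals <- (directed + t(directed)) / 2
  diag(vals) <- 0
  structure(list(ids = ids, values = unname(vals)), class = "DistanceMatrix")
}

#' Construct a DistanceMatrix directly
#' @param ids Domain ids.
#' @param values K x K symmetric non-negative matrix, zero diagonal.
#' @return A `DistanceMatrix`.
#' @export
distance_matrix <- function(ids, values) {
  values <- as.matrix(values)
  k <- length(ids)
  stopifnot(nrow(values) == k, ncol(values) == k)
  if (any(values < 0)) stop("distances must be non-negative")
  if (max(abs(values - t(values))) > 1e-12) stop("matrix must be symmetric")
  if (any(diag(values) != 0)) stop("diagonal must be zero")
  structure(list(ids = as.character(ids), values = unname(values)),
            class = "DistanceMatrix")
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Agglomerative clustering: repeatedly merge the two closest clusters,
#' with inter-cluster distance the unweighted mean over all cross-pair
#' distances. Ties are broken by the lexicographically smallest pair of
#' cluster representative ids (a cluster is represented by its smallest
#' member id), so the dendrogram is fully deterministic.
#'
#' @param dm A `DistanceMatrix` with K >= 2.
#' @return Object of class `mcpsc_dendrogram`: `merge` (hclust convention:
#'   negatives are singletons), `height`, `labels`, `order`.
#' @export
hclust_average <- function(dm) {
  stopifnot(inherits(dm, "DistanceMatrix"))
  k <- length(dm$ids)
  if (k < 2L) stop("need at least 2 domains to cluster")
  d <- dm$values
  # active cluster state
  members <- as.list(seq_len(k))          # member leaf indices
  reps <- dm$ids                          # smallest member id per cluster
  sizes <- rep(1L, k)
  code <- -seq_len(k)                     # hclust merge codes
  active <- rep(TRUE, k)
  cd <- d                                 # cluster-to-cluster distances
  merge <- matrix(0L, k - 1L, 2L)
  height <- numeric(k - 1L)
  for (step in seq_len(k - 1L)) {
    act <- which(active)
    best <- NULL
    for (ii in seq_along(act)[-length(act)]) {
      i <- act[ii]
      for (j in act[(ii + 1L):length(act)]) {
        rij <- sort(c(reps[i], reps[j]))
        cand <- list(i = i, j = j, dist = cd[i, j], rep = rij)
        if (is.null(best) || cand$dist < best$dist ||
            (cand$dist == best$dist &&
             (cand$rep[1L] < best$rep[1L] ||
              (cand$rep[1L] == best$rep[1L] && cand$rep[2L] < best$rep[2L]))))
          best <- cand
      }
    }
    i <- best$i; j <- best$j
    merge[step, ] <- sort(c(code[i], code[j]))
    height[step] <- best$dist
    # merge j into i (UPGMA size-weighted average of cluster distances)
    for (l in act) {
      if (l == i || l == j) next
      cd[i, l] <- cd[l, i] <- (sizes[i] * cd[i, l] + sizes[j] * cd[j, l]) /
        (sizes[i] + sizes[j])
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    reps[i] <- min(reps[i], reps[j])
    code[i] <- step
    active[j] <- FALSE
  }
  structure(list(merge = merge, height = height, labels = dm$ids,
                 order = dendro_order(merge)),
            class = "mcpsc_dendrogram")
}

# leaf order for plotting, from the merge matrix (standard recursion)
dendro_order <- function(merge) {
  expand <- function(code) {
    if (code < 0L) -code
    else c(expand(merge[code, 1L]), expand(merge[code, 2L]))
  }
  expand(nrow(merge))
}

#' Convert a dendrogram to a stats::hclust object
#' @param dend An [hclust_average()] result.
#' @return An object of class `hclust` (usable with [stats::cutree()],
#'   plotting, or Newick export via the ape package).
#' @export
as_hclust <- function(dend) {
  structure(list(merge = dend$merge, height = dend$height,
                 order = dend$order, labels = dend$labels,
                 method = "average", call = match.call(),
                 dist.method = "consensus"),
            class = "hclust")
}

#' Cut a dendrogram into C clusters
#'
#' Undoes the last `C - 1` merges, i.e. keeps the first `K - C`
#' agglomerations, yielding exactly `C` clusters. Cluster labels are
#' integers `1..C` in order of first appearance over the input domains.
#'
#' @param dend An [hclust_average()] result.
#' @param C Number of clusters, `1 <= C <= K`.
#' @return Named integer vector of cluster assignments.
#' @export
cut_to_k <- function(dend, C) {
  k <- length(dend$labels)
  if (C < 1L || C > k) stop("C must be between 1 and ", k)
  parent <- seq_len(k)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  n_merges <- k - C
  if (n_merges > 0L) {
    comp_of_code <- integer(n_merges)   # component root per merge step
    for (s in seq_len(n_merges)) {
      side <- function(code) if (code < 0L) find(-code) else find(comp_of_code[code])
      a <- side(dend$merge[s, 1L]); b <- side(dend$merge[s, 2L])
      parent[b] <- a
      comp_of_code[s] <- find(a)
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  cl <- match(roots, unique(roots))
  stats::setNames(cl, dend$labels)
}

#' F-measure of a clustering against fold labels
#'
#' Each cluster is mapped to its majority true class (ties resolved to the
#' class of the lexicographically smallest domain id in the cluster). Per
#' cluster, true positives are members of the mapped class, false positives
#' the other members, and false negatives the mapped-class members found
#' outside the cluster; sums over clusters give precision
#' `P = TP / (TP + FP)`, recall `R = TP / (TP + FN)` and
#' `F = 2PR / (P + R)` (0 when `P + R = 0`).
#'
#' @param assignments Named integer/character vector: domain id -> cluster.
#' @param true_labels Named character vector: domain id -> fold class.
#' @param C Expected number of clusters (checked, optional).
#' @return Object of class `FMeasureReport`: `n_clusters`,
#'   `cluster_to_class`, `TP`, `FP`, `FN`, `precision`, `recall`,
#'   `f_measure`.
#' @export
f_measure <- function(assignments, true_labels, C = NULL) {
  ids <- names(assignments)
  if (is.null(ids)) stop("assignments must be named by domain id")
  missing_lab <- setdiff(ids, names(true_labels))
  if (length(missing_lab))
    stop("no true label for domain(s): ", paste(missing_lab, collapse = ", "))
  labs <- true_labels[ids]
  clusters <- split(ids, assignments[ids])
  if (!is.null(C) && length(clusters) != C)
    stop("clustering has ", length(clusters), " clusters, expected ", C)
  class_size <- table(labs)
  tp <- fp <- fn <- 0L
  mapping <- character(length(clusters))
  names(mapping) <- names(clusters)
  for (cn in names(clusters)) {
    mem <- clusters[[cn]]
    counts <- table(labs[mem])
    top <- names(counts)[counts == max(counts)]
    cls <- if (length(top) == 1L) top else {
      # tie: class of the lexicographically smallest id in the cluster
      tie_mem <- mem[labs[mem] %in% top]
      labs[[tie_mem[order(tie_mem)][1L]]]
    }
    mapping[cn] <- cls
    tp_c <- sum(labs[mem] == cls)
    tp <- tp + tp_c
    fp <- fp + (length(mem) - tp_c)
    fn <- fn + (class_size[[cls]] - tp_c)
  }
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  structure(list(n_clusters = length(clusters), cluster_to_class = mapping,
                 TP = as.integer(tp), FP = as.integer(fp), FN = as.integer(fn),
                 precision = p, recall = r, f_measure = f),
            class = "FMeasureReport")
}

#' @export
print.FMeasureReport <- function(x, ...) {
  cat(sprintf("<FMeasureReport> C=%d  TP=%d FP=%d FN=%d  P=%.3f R=%.3f F=%.3f\n",
              x$n_clusters, x$TP, x$FP, x$FN, x$precision, x$recall,
              x$f_measure))
  invisible(x)
}
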