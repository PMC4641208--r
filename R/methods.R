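# Pairwise comparison methods: compression distance (USM/NCD), rigid
# superposition (Kabsch), sequence-guided TM-score-like alignment, and the
# adapter for externally computed scores.

#' Construct a MethodScore
#'
#' One pairwise score from one method. `kind` records whether larger values
#' mean more similar (`"similarity"`) or less similar (`"distance"`); the
#' consensus stage uses it to orient all columns as dissimilarities.
#'
#' @param query_id,db_id Domain ids of the compared pair.
#' @param method Method name (e.g. `"usm"`, `"tm"`, `"rmsd"`).
#' @param value Non-negative finite score.
#' @param kind `"similarity"` or `"distance"`.
#' @return An object of class `MethodScore`.
#' @export
method_score <- function(query_id, db_id, method, value, kind) {
  kind <- match.arg(kind, c("similarity", "distance"))
  if (!is.finite(value) || value < 0)
    stop("score for (", query_id, ", ", db_id, ", ", method,
         ") must be finite and >= 0, got ", value)
  structure(list(query_id = as.character(query_id), db_id = as.character(db_id),
                 method = as.character(method), value = as.numeric(value),
                 kind = kind),
            class = "MethodScore")
}

#' Convert a list of MethodScore to a data frame
#' @param scores List of [method_score()] objects.
#' @return data.frame with columns query_id, db_id, method, value, kind.
#' @export
scores_to_df <- function(scores) {
  do.call(rbind, lapply(scores, function(s)
    data.frame(query_id = s$query_id, db_id = s$db_id, method = s$method,
               value = s$value, kind = s$kind, stringsAsFactors = FALSE)))
}

# gzip-format compressed byte length; stands in for Kolmogorov complexity.
# R's memCompress runs zlib at its build's fixed default level, so sizes are
# reproducible per compressor build.
compressed_size <- function(bytes) {
  n <- length(memCompress(bytes, type = "gzip"))
  if (n <= 0L) stop("degenerate compressor output (zero size)")
  n
}

# byte-wise lexicographic comparison of raw vectors
raw_lex_less <- function(a, b) {
  n <- min(length(a), length(b))
  ai <- as.integer(a[seq_len(n)]); bi <- as.integer(b[seq_len(n)])
  d <- which(ai != bi)
  if (length(d)) ai[d[1L]] < bi[d[1L]] else length(a) < length(b)
}

#' Compression sizes backing one USM score
#'
#' @param cm_a,cm_b [contact_map()] objects.
#' @return List with `c_x`, `c_y`, `c_xy`: gzip-compressed byte lengths of
#'   the two canonical serializations and of their concatenation in
#'   canonical (byte-lexicographic) order.
#' @export
compression_sizes <- function(cm_a, cm_b) {
  x <- serialize_contact_map(cm_a)
  y <- serialize_contact_map(cm_b)
  if (raw_lex_less(y, x)) { tmp <- x; x <- y; y <- tmp }
  list(c_x = compressed_size(x), c_y = compressed_size(y),
       c_xy = compressed_size(c(x, y)))
}

#' USM distance between two contact maps
#'
#' Normalized compression distance over the canonical contact-map
#' serializations: `(C(xy) - min(C(x), C(y))) / max(C(x), C(y))`, where
#' `C(.)` is the gzip-compressed byte length and `xy` the concatenation of
#' the two serializations in byte-lexicographic order (so the distance is
#' exactly symmetric). Values are clamped at zero; identical inputs give a
#' small positive residual bounded by compressor redundancy.
#'
#' @param cm_a,cm_b [contact_map()] objects.
#' @return A [method_score()] with method `"usm"`, kind `"distance"`.
#' @export
usm_distance <- function(cm_a, cm_b) {
  cs <- compression_sizes(cm_a, cm_b)
  val <- (cs$c_xy - min(cs$c_x, cs$c_y)) / max(cs$c_x, cs$c_y)
  method_score(cm_a$domain_id, cm_b$domain_id, "usm", max(0, val), "distance")
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares proper rotation and translation mapping point set `q` onto
#' `p`: `p_i ~ R q_i + t`. The reflection case is corrected so `det(R) = +1`.
#'
#' @param coords_p,coords_q Numeric `n x 3` matrices with equal `n >= 1`.
#' @return List with `rotation` (3x3), `translation` (length 3) and `rmsd`.
#' @export
kabsch_superpose <- function(coords_p, coords_q) {
  p <- as.matrix(coords_p); q <- as.matrix(coords_q)
  if (nrow(p) != nrow(q)) stop("point sets differ in length")
  if (nrow(p) < 1L) stop("need at least one point")
  cp <- colMeans(p); cq <- colMeans(q)
  pc <- sweep(p, 2L, cp); qc <- sweep(q, 2L, cq)
  h <- crossprod(qc, pc)            # 3x3 covariance
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  qr_ <- qc %*% t(rot)
  rmsd <- sqrt(mean(rowSums((pc - qr_)^2)))
  list(rotation = rot, translation = as.numeric(cp - rot %*% cq), rmsd = rmsd)
}

#' Global sequence alignment (Needleman-Wunsch)
#'
#' Linear gap penalty; traceback ties broken deterministically, preferring
#' diagonal, then up (gap in `seq_b`), then left. Only matched columns are
#' returned.
#'
#' @param seq_a,seq_b Non-empty character strings.
#' @param match,mismatch,gap Scoring parameters.
#' @return List with `pairs` (`n x 2` matrix of 0-based index pairs,
#'   strictly increasing in both columns) and `score`.
#' @export
align_sequences <- function(seq_a, seq_b, match = 1, mismatch = 0, gap = -1) {
  a <- strsplit(seq_a, "", fixed = TRUE)[[1L]]
  b <- strsplit(seq_b, "", fixed = TRUE)[[1L]]
  n <- length(a); m <- length(b)
  if (n < 1L || m < 1L) stop("sequences must be non-empty")
  f <- matrix(0, n + 1L, m + 1L)
  f[, 1L] <- gap * (0:n)
  f[1L, ] <- gap * (0:m)
  sub <- outer(a, b, function(x, y) ifelse(x == y, match, mismatch))
  for (i in seq_len(n))
    for (j in seq_len(m))
      f[i + 1L, j + 1L] <- max(f[i, j] + sub[i, j],
                               f[i, j + 1L] + gap,
                               f[i + 1L, j] + gap)
  # traceback: diagonal > up > left
  i <- n; j <- m
  pa <- integer(0); pb <- integer(0)
  while (i > 0L && j > 0L) {
    cur <- f[i + 1L, j + 1L]
    if (cur == f[i, j] + sub[i, j]) {
      pa <- c(i - 1L, pa); pb <- c(j - 1L, pb)
      i <- i - 1L; j <- j - 1L
    } else if (cur == f[i, j + 1L] + gap) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  list(pairs = cbind(pa, pb, deparse.level = 0), score = f[n + 1L, m + 1L])
}

# length-dependent TM-score distance scale, floored at 0.5 A
tm_d0 <- function(l_ref) max(0.5, 1.24 * (l_ref - 15)^(1/3) - 1.8)

#' TM-score-like structural comparison
#'
#' A built-in stand-in for an external structure aligner: the residue
#' correspondence comes from a global sequence alignment, then the
#' superposition is iteratively refined. Starting from the full
#' correspondence and from seed fragments of length L/2 and L/4 at each
#' quarter offset, each start superposes on the current subset, keeps
#' corresponded pairs within `2 * d0`, and repeats to convergence (at most
#' 20 iterations); the start giving the highest TM-score wins.
#' `tm_score = mean_i 1 / (1 + (d_i / d0)^2)` over all corresponded pairs,
#' normalized by the length of `b` (the database/reference domain), with
#' `d0 = max(0.5, 1.24 (L_ref - 15)^{1/3} - 1.8)`. The RMSD is reported over
#' the final kept pair set.
#'
#' @param a,b [protein_domain()] objects with length >= 5.
#' @return List of class `AlignmentResult`: `correspondence` (0-based index
#'   pairs), `rotation`, `translation`, `rmsd`, `tm_score`, `d0`, `n_kept`.
#' @export
tm_like_compare <- function(a, b) {
  stopifnot(inherits(a, "ProteinDomain"), inherits(b, "ProteinDomain"))
  if (a$length < 5L || b$length < 5L) stop("domains must have length >= 5")
  aln <- align_sequences(a$sequence, b$sequence)
  corr <- aln$pairs
  if (nrow(corr) < 1L) stop("empty correspondence")
  l_ref <- b$length
  d0 <- tm_d0(l_ref)
  pa <- a$ca_coords[corr[, 1L] + 1L, , drop = FALSE]
  pb <- b$ca_coords[corr[, 2L] + 1L, , drop = FALSE]
  L <- nrow(corr)

  seeds <- list(seq_len(L))
  for (frag in unique(pmax(3L, c(L %/% 2L, L %/% 4L)))) {
    for (off in unique(pmax(0L, (0:3) * (L %/% 4L)))) {
      s <- seq.int(off + 1L, min(off + frag, L))
      if (length(s) >= 3L) seeds <- c(seeds, list(s))
    }
  }

  score_fit <- function(fit) {
    d <- sqrt(rowSums((pa - (pb %*% t(fit$rotation) +
      matrix(fit$translation, L, 3L, byrow = TRUE)))^2))
    list(d = d, tm = sum(1 / (1 + (d / d0)^2)) / l_ref)
  }

  full_fit <- kabsch_superpose(pa, pb)
  best <- NULL
  for (s in seeds) {
    sub <- s
    fit <- kabsch_superpose(pa[sub, , drop = FALSE], pb[sub, , drop = FALSE])
    for (iter in seq_len(20L)) {
      sc <- score_fit(fit)
      keep <- which(sc$d < 2 * d0)
      if (length(keep) < 3L) { fit <- full_fit; sub <- seq_len(L); sc <- score_fit(fit); break }
      if (length(keep) == length(sub) && all(keep == sub)) break
      sub <- keep
      fit <- kabsch_superpose(pa[sub, , drop = FALSE], pb[sub, , drop = FALSE])
    }
    sc <- score_fit(fit)
    cand <- list(fit = fit, sub = sub, tm = sc$tm, d = sc$d)
    if (is.null(best) || cand$tm > best$tm) best <- cand
  }

  kept <- best$sub
  rmsd <- sqrt(mean(best$d[kept]^2))
  structure(list(correspondence = corr, rotation = best$fit$rotation,
                 translation = best$fit$translation, rmsd = rmsd,
                 tm_score = min(1, best$tm), d0 = d0, n_kept = length(kept)),
            class = "AlignmentResult")
}

# ---- method registry -------------------------------------------------------

#' Create a registry of pairwise comparison methods
#'
#' A registry maps method names to implementations with a declared score
#' `kind` and `routing` (`"sequential"` methods run in the coordinating
#' process; `"parallel"` methods go to the worker pool).
#'
#' @param default Populate with the built-in methods `"usm"` (distance,
#'   sequential), `"tm"` (similarity, parallel) and `"rmsd"` (distance,
#'   parallel)? The latter two share one alignment pass per pair.
#' @return An environment of class `MethodRegistry`.
#' @export
method_registry <- function(default = TRUE) {
  reg <- new.env(parent = emptyenv())
  class(reg) <- "MethodRegistry"
  if (default) {
    register_method(reg, "usm", kind = "distance", routing = "sequential",
      fn = function(q, d, ctx) usm_distance(ctx$cmap(q$id), ctx$cmap(d$id))$value)
    register_method(reg, "tm", kind = "similarity", routing = "parallel",
      fn = function(q, d, ctx) ctx$alignment(q, d)$tm_score)
    register_method(reg, "rmsd", kind = "distance", routing = "parallel",
      fn = function(q, d, ctx) ctx$alignment(q, d)$rmsd)
  }
  reg
}

#' Register a comparison method
#' @param registry A [method_registry()].
#' @param name Method name.
#' @param kind `"similarity"` or `"distance"`.
#' @param routing `"sequential"` or `"parallel"`.
#' @param fn Function `(query_domain, db_domain, ctx) -> numeric value`;
#'   `ctx` offers cached `cmap(id)` and `alignment(q, d)` accessors.
#' @export
register_method <- function(registry, name, kind, routing, fn) {
  stopifnot(inherits(registry, "MethodRegistry"))
  kind <- match.arg(kind, c("similarity", "distance"))
  routing <- match.arg(routing, c("sequential", "parallel"))
  assign(name, list(name = name, kind = kind, routing = routing, fn = fn),
         envir = registry)
  invisible(registry)
}

get_method <- function(registry, name) {
  if (!exists(name, envir = registry, inherits = FALSE))
    stop("unknown method '", name, "' (not in registry)")
  get(name, envir = registry, inherits = FALSE)
}

#' Method names in a registry
#' @param registry A [method_registry()].
#' @param routing Optional filter: `"sequential"` or `"parallel"`.
#' @return Sorted character vector of names.
#' @export
registry_methods <- function(registry, routing = NULL) {
  nm <- sort(ls(registry))
  if (!is.null(routing))
    nm <- nm[vapply(nm, function(n) get_method(registry, n)$routing == routing,
                    logical(1))]
  nm
}

#' Caching domain store
#'
#' Wraps a loader so each domain structure is loaded exactly once and reused
#' whenever the domain appears in a comparison; `$loads` counts loader calls.
#'
#' @param loader Function `id -> ProteinDomain`, or a named list/vector of
#'   domains used as a static table.
#' @return Environment of class `DomainStore` with `$get(id)` and `$loads`.
#' @export
domain_store <- function(loader) {
  if (!is.function(loader)) {
    domains <- loader
    if (inherits(domains, "ProteinDomain")) domains <- list(domains)
    nm <- vapply(domains, `[[`, character(1), "id")
    tab <- stats::setNames(domains, nm)
    loader <- function(id) {
      if (is.null(tab[[id]])) stop("unknown domain id '", id, "'")
      tab[[id]]
    }
  }
  store <- new.env(parent = emptyenv())
  store$cache <- new.env(parent = emptyenv())
  store$loads <- 0L
  store$get <- function(id) {
    if (!exists(id, envir = store$cache, inherits = FALSE)) {
      assign(id, loader(id), envir = store$cache)
      store$loads <- store$loads + 1L
    }
    get(id, envir = store$cache, inherits = FALSE)
  }
  class(store) <- "DomainStore"
  store
}

# Shared per-run context: caches contact maps, their compressed sizes and
# alignment results so each is computed once per domain (or pair).
run_context <- function(store, threshold_angstrom = 8.0, min_separation = 2L) {
  cmaps <- new.env(parent = emptyenv())
  alns <- new.env(parent = emptyenv())
  ctx <- list(
    store = store,
    cmap = function(id) {
      if (!exists(id, envir = cmaps, inherits = FALSE))
        assign(id, contact_map(store$get(id), threshold_angstrom, min_separation),
               envir = cmaps)
      get(id, envir = cmaps, inherits = FALSE)
    },
    alignment = function(q, d) {
      key <- paste0(q$id, "\r", d$id)
      if (!exists(key, envir = alns, inherits = FALSE))
        assign(key, tm_like_compare(q, d), envir = alns)
      get(key, envir = alns, inherits = FALSE)
    })
  ctx
}

#' Run a single comparison job
#'
#' Dispatches a [psc_job()] to its registered method. Structures, contact
#' maps and pair alignments are cached in `ctx`, so repeated appearances of
#' a domain cost one load.
#'
#' @param job A [psc_job()].
#' @param registry A [method_registry()].
#' @param store A [domain_store()].
#' @param ctx Optional shared context from a previous call; defaults to a
#'   fresh cache over `store`.
#' @return A [method_score()].
#' @export
run_method <- function(job, registry, store, ctx = NULL) {
  m <- get_method(registry, job$method)
  if (is.null(ctx)) ctx <- run_context(store)
  q <- store$get(job$query_id)
  d <- store$get(job$db_id)
  method_score(job$query_id, job$db_id, m$name, m$fn(q, d, ctx), m$kind)
}

#' Load externally computed scores from a TSV file
#'
#' Adapter so scores produced by real external aligners can replace the
#' built-in stand-ins in the consensus. The file must have a header with
#' columns `query_id`, `db_id`, `value`.
#'
#' @param tsv_path Path to the TSV file.
#' @param method_name Name under which the scores enter the score matrix.
#' @param kind `"similarity"` or `"distance"`.
#' @return List of [method_score()] objects.
#' @export
load_external_scores <- function(tsv_path, method_name, kind) {
  kind <- match.arg(kind, c("similarity", "distance"))
  df <- utils::read.delim(tsv_path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("query_id", "db_id", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("external score file missing column(s): ", paste(miss, collapse = ", "))
  vals <- suppressWarnings(as.numeric(df$value))
  if (anyNA(vals))
    stop("non-numeric value in external score file at row ",
         which(is.na(vals))[1L])
  key <- paste(df$query_id, df$db_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate pair (", df$query_id[dup[1L]], ", ", df$db_id[dup[1L]],
         ") in external score file")
  lapply(seq_len(nrow(df)), function(i)
    method_score(df$query_id[i], df$db_id[i], method_name, vals[i], kind))
}
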