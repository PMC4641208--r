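# Independent oracles: brute-force / enumeration references that the
# implementation is checked against. None of these share code with the
# package internals they verify.

# Optimal makespan by exhaustive assignment with pruning and empty-bin
# symmetry breaking. Feasible for <= 12 jobs and <= 4 workers.
brute_force_makespan <- function(weights, n_workers) {
  w <- sort(weights, decreasing = TRUE)
  n <- length(w)
  best <- sum(w)
  loads <- numeric(n_workers)
  rec <- function(i) {
    if (max(loads) >= best) return(invisible())
    if (i > n) { best <<- max(loads); return(invisible()) }
    for (j in seq_len(n_workers)) {
      loads[j] <<- loads[j] + w[i]
      rec(i + 1L)
      loads[j] <<- loads[j] - w[i]
      if (loads[j] == 0) break   # further empty bins are symmetric
    }
  }
  rec(1L)
  best
}

# Maximum global alignment score by full recursion (no DP sharing with the
# implementation). Only for tiny sequences.
enum_align_score <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
  rec <- function(i, j) {
    if (i > length(av)) return(gap * (length(bv) - j + 1L))
    if (j > length(bv)) return(gap * (length(av) - i + 1L))
    max(rec(i + 1L, j + 1L) + if (av[i] == bv[j]) match else mismatch,
        rec(i + 1L, j) + gap,
        rec(i, j + 1L) + gap)
  }
  rec(1L, 1L)
}

# Minimum superposition RMSD by direct search over rotations: coarse Euler
# grid then Nelder-Mead refinement of the best grid point. Never uses SVD.
grid_search_rmsd <- function(p, q, grid_deg = 20) {
  pc <- sweep(p, 2L, colMeans(p)); qc <- sweep(q, 2L, colMeans(q))
  rot_zyz <- function(ang) {
    cz1 <- cos(ang[1]); sz1 <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz2 <- cos(ang[3]); sz2 <- sin(ang[3])
    rz1 <- matrix(c(cz1, sz1, 0, -sz1, cz1, 0, 0, 0, 1), 3L)
    ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3L)
    rz2 <- matrix(c(cz2, sz2, 0, -sz2, cz2, 0, 0, 0, 1), 3L)
    rz1 %*% ry %*% rz2
  }
  obj <- function(ang) sqrt(mean(rowSums((pc - qc %*% t(rot_zyz(ang)))^2)))
  g <- seq(0, 2 * pi, by = grid_deg * pi / 180)
  gy <- seq(0, pi, by = grid_deg * pi / 180)
  best <- c(0, 0, 0); best_val <- obj(best)
  for (a1 in g) for (a2 in gy) for (a3 in g) {
    v <- obj(c(a1, a2, a3))
    if (v < best_val) { best <- c(a1, a2, a3); best_val <- v }
  }
  opt <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}

# TRUE when two cluster assignments describe the same partition (labels may
# differ).
same_partition <- function(a, b) {
  a <- a[sort(names(a))]; b <- b[sort(names(a))]
  length(unique(a)) == length(unique(b)) &&
    all(tapply(seq_along(a), a, function(ix)
      length(unique(b[ix])) == 1L)) &&
    !anyDuplicated(tapply(b, a, function(x) x[1L]))
}
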