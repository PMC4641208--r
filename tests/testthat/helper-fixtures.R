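# Shared fixtures, all built in code.

# Minimal two-chain PDB text: chain A has 5 residues (one with two altlocs),
# chain B has 4.
fixture_pdb_two_chains <- function() {
  paste(c(
    "HEADER    TEST FIXTURE",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ATOM      4  CA  MSE A   3       7.600   0.000   0.000  1.00  0.00           C",
    "ATOM      5  CA ASER A   7      11.400   0.000   0.000  0.50  0.00           C",
    "ATOM      6  CA BSER A   7      11.500   0.000   0.000  0.50  0.00           C",
    "ATOM      7  CA  LEU A   8      15.200   0.000   0.000  1.00  0.00           C",
    "HETATM    8  CA  HOH A 101      99.000  99.000  99.000  1.00  0.00           C",
    "ATOM      9  CA  VAL B   1       0.000   5.000   0.000  1.00  0.00           C",
    "ATOM     10  CA  VAL B   2       3.800   5.000   0.000  1.00  0.00           C",
    "ATOM     11  CA  VAL B   3       7.600   5.000   0.000  1.00  0.00           C",
    "ATOM     12  CA  VAL B   4      11.400   5.000   0.000  1.00  0.00           C",
    "END"), collapse = "\n")
}

# collinear C-alpha trace, spacing 3.8 A
collinear_domain <- function(n = 5L, spacing = 3.8) {
  aa <- rep(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], length.out = n)
  protein_domain("lin", "A", paste(aa, collapse = ""),
                 cbind((seq_len(n) - 1L) * spacing, 0, 0))
}

# ContactMap built directly from an explicit contact list (for compressor
# tests on maps that need not be geometrically realizable)
raw_cmap <- function(id, n, contacts, threshold = 8, min_sep = 2L) {
  contacts <- matrix(as.integer(contacts), ncol = 2L)
  ord <- order(contacts[, 1L], contacts[, 2L])
  structure(list(domain_id = id, n_residues = as.integer(n),
                 contacts = contacts[ord, , drop = FALSE],
                 threshold_angstrom = threshold,
                 min_separation = as.integer(min_sep)),
            class = "ContactMap")
}

# uniformly random duplicate-free contact map with the given seed
random_cmap <- function(id, n, n_contacts, seed) {
  set.seed(seed)
  all_pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  sep_ok <- all_pairs[, 2L] - all_pairs[, 1L] >= 2L
  pick <- sample(which(sep_ok), n_contacts)
  raw_cmap(id, n, cbind(all_pairs[pick, 1L] - 1L, all_pairs[pick, 2L] - 1L))
}

rigid_transform <- function(xyz, angle_deg = 37, axis = c(0, 0, 1),
                            shift = c(5, -2, 1)) {
  a <- angle_deg * pi / 180
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3L)
  R <- diag(3) + sin(a) * K + (1 - cos(a)) * K %*% K
  sweep(xyz %*% t(R), 2L, shift, `+`)
}

# dummy one-residue domains, enough for job-farm combinatorics
dummy_domains <- function(k, len = 100L) {
  lapply(seq_len(k), function(i)
    protein_domain(sprintf("d%04d", i), "A",
                   paste(rep("A", len), collapse = ""),
                   cbind(seq_len(len) * 3.8, 0, 0)))
}

# uniform noise draw under an isolated RNG stream
local_seed_runif <- function(n, seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  stats::runif(n)
}

# memoized 5x7 synthetic benchmark + full pipeline shared across test files
.bench_env <- new.env(parent = emptyenv())
get_bench35 <- function() {
  if (is.null(.bench_env$bench)) {
    .bench_env$bench <- make_benchmark(n_families = 5L, members_per_family = 7L,
                                       n_residues = 60L, noise_sd = 0.3,
                                       indel_rate = 0.05, seed = 1L)
    .bench_env$pipeline <- mcpsc_pipeline(.bench_env$bench$domains, C = 5L)
  }
  list(bench = .bench_env$bench, pipeline = .bench_env$pipeline)
}
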