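# Synthetic data: labeled fold families of C-alpha chains, PDB fixtures and
# simulated job runtimes, so the whole pipeline is testable offline.

#' Specify a synthetic fold family
#'
#' A family is a deterministic template backbone (idealized helix, extended
#' strand, or a mixed helix+strand chain) plus a sampling recipe: members
#' are the template under a random rigid transform, i.i.d. Gaussian
#' coordinate noise, and optional random single-residue deletions.
#'
#' @param family_id Family label attached to every member.
#' @param geometry `"helix"`, `"extended"` or `"mixed"`.
#' @param n_residues Template length (>= 10).
#' @param noise_sd Coordinate noise standard deviation in Angstrom (>= 0).
#' @param indel_rate Per-position deletion probability (in `[0, 0.2)`).
#' @param seed Seed for the template sequence and member sampling stream.
#' @param params Optional geometry overrides: `rise`, `turn_deg`, `radius`
#'   (helix); `step`, `amplitude` (extended).
#' @return Object of class `FamilySpec`.
#' @export
family_spec <- function(family_id, geometry = c("helix", "extended", "mixed"),
                        n_residues = 60L, noise_sd = 0.3, indel_rate = 0.05,
                        seed = 1L, params = list()) {
  geometry <- match.arg(geometry)
  if (n_residues < 10L) stop("n_residues must be >= 10")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (indel_rate < 0 || indel_rate >= 0.2)
    stop("indel_rate must be in [0, 0.2)")
  structure(list(family_id = as.character(family_id), geometry = geometry,
                 n_residues = as.integer(n_residues), noise_sd = noise_sd,
                 indel_rate = indel_rate, seed = as.integer(seed),
                 params = params),
            class = "FamilySpec")
}

# idealized helix trace: ~3.8 A between consecutive C-alpha
helix_coords <- function(n, rise = 1.5, turn_deg = 100, radius = 2.3) {
  t <- (seq_len(n) - 1L) * turn_deg * pi / 180
  cbind(radius * cos(t), radius * sin(t), (seq_len(n) - 1L) * rise)
}

# extended (strand-like) zigzag along x
extended_coords <- function(n, step = 3.3, amplitude = 0.95) {
  cbind((seq_len(n) - 1L) * step,
        amplitude * (-1)^(seq_len(n) - 1L),
        rep(0, n))
}

#' Build the deterministic template of a family
#'
#' The backbone comes from the spec's geometry (consecutive C-alpha spacing
#' close to the canonical 3.8 A); the sequence is drawn uniformly over the
#' 20 amino acids from the spec's seed, so repeated calls are identical.
#'
#' @param spec A [family_spec()].
#' @return A [protein_domain()] with id `<family_id>_template` and the
#'   family's fold label.
#' @export
make_family_template <- function(spec) {
  stopifnot(inherits(spec, "FamilySpec"))
  n <- spec$n_residues
  p <- spec$params
  xyz <- switch(spec$geometry,
    helix = helix_coords(n, p$rise %||% 1.5, p$turn_deg %||% 100,
                         p$radius %||% 2.3),
    extended = extended_coords(n, p$step %||% 3.3, p$amplitude %||% 0.95),
    mixed = {
      n1 <- n %/% 2L
      h <- helix_coords(n1, p$rise %||% 1.5, p$turn_deg %||% 100,
                        p$radius %||% 2.3)
      e <- extended_coords(n - n1, p$step %||% 3.3, p$amplitude %||% 0.95)
      # attach the strand 3.8 A beyond the last helix point, along +x
      offset <- h[n1, ] + c(3.8, 0, 0)
      rbind(h, sweep(e, 2L, offset, `+`))
    })
  seq_chars <- local_seed(spec$seed,
    sample(names(AA1TO3)[names(AA1TO3) != "X"], n, replace = TRUE))
  protein_domain(paste0(spec$family_id, "_template"), "A",
                 paste(seq_chars, collapse = ""), xyz,
                 fold_label = spec$family_id)
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9L), 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

#' Sample one family member from a template
#'
#' Member = template coordinates + i.i.d. Gaussian noise (sd `noise_sd`),
#' then a random rigid transform (uniform random rotation, translation
#' uniform in `[-20, 20]` A per axis); each position is independently
#' deleted with probability `indel_rate`. The member inherits the family's
#' fold label. Deterministic given `seed`.
#'
#' @param template A [protein_domain()] (usually [make_family_template()]).
#' @param noise_sd,indel_rate See [family_spec()].
#' @param seed RNG seed for this member.
#' @param id Member id; default derives from the template id and seed.
#' @return A [protein_domain()].
#' @export
sample_family_member <- function(template, noise_sd = 0.3, indel_rate = 0.05,
                                 seed = 1L, id = NULL) {
  stopifnot(inherits(template, "ProteinDomain"))
  if (is.null(id)) id <- paste0(sub("_template$", "", template$id), "_m", seed)
  local_seed(seed, {
    n <- template$length
    xyz <- template$ca_coords + matrix(stats::rnorm(3L * n, sd = noise_sd), n, 3L)
    rot <- random_rotation()
    xyz <- xyz %*% t(rot) +
      matrix(stats::runif(3L, -20, 20), n, 3L, byrow = TRUE)
    keep <- stats::runif(n) >= indel_rate
    if (!any(keep)) keep[1L] <- TRUE
    protein_domain(id, "A",
                   paste(strsplit(template$sequence, "")[[1L]][keep],
                         collapse = ""),
                   xyz[keep, , drop = FALSE],
                   fold_label = template$fold_label)
  })
}

#' Generate a labeled synthetic benchmark
#'
#' Emulates a small fold-classification benchmark: `n_families` families
#' with distinct template geometries (cycling helix / extended / mixed with
#' perturbed helix turn angles and strand steps so all templates differ),
#' each contributing `members_per_family` noisy members.
#'
#' @param n_families Number of families (>= 2).
#' @param members_per_family Members sampled per family.
#' @param n_residues,noise_sd,indel_rate Passed to every [family_spec()].
#' @param seed Master seed; family and member seeds derive from it.
#' @return List with `domains` (list of [protein_domain()]), `labels`
#'   (data frame `domain_id`, `fold_label`) and `specs`.
#' @export
make_benchmark <- function(n_families = 5L, members_per_family = 7L,
                           n_residues = 60L, noise_sd = 0.3,
                           indel_rate = 0.05, seed = 1L) {
  if (n_families < 2L) stop("need at least 2 families")
  geoms <- c("helix", "extended", "mixed")
  domains <- list()
  specs <- list()
  for (f in seq_len(n_families)) {
    variant <- (f - 1L) %/% length(geoms)
    spec <- family_spec(
      family_id = sprintf("fam%02d", f),
      geometry = geoms[((f - 1L) %% length(geoms)) + 1L],
      n_residues = n_residues, noise_sd = noise_sd, indel_rate = indel_rate,
      seed = seed * 1000L + f,
      params = list(turn_deg = 100 + 16 * variant, step = 3.3 - 0.15 * variant))
    tmpl <- make_family_template(spec)
    for (m in seq_len(members_per_family)) {
      mem <- sample_family_member(tmpl, noise_sd, indel_rate,
                                  seed = seed * 1000L + f * 100L + m,
                                  id = sprintf("%s_m%02d", spec$family_id, m))
      domains[[length(domains) + 1L]] <- mem
    }
    specs[[f]] <- spec
  }
  labels <- data.frame(
    domain_id = vapply(domains, `[[`, character(1), "id"),
    fold_label = vapply(domains, `[[`, character(1), "fold_label"),
    stringsAsFactors = FALSE)
  list(domains = domains, labels = labels, specs = specs)
}

#' Simulate per-job runtimes from a cost model
#'
#' `cost_j = model(attr_j) * exp(e_j)` with `e_j ~ N(0, noise_sd^2)`,
#' clamped to a small positive floor. Log-normal noise keeps costs positive
#' and makes relative (not absolute) timing error constant, which matches
#' how wall-clock jitter behaves.
#'
#' @param jobs A `JobList` from [generate_jobs()].
#' @param cost_model A [fit_cost_model()] result or a list with `form`,
#'   `coefficients` and optionally `attribute` (`"sum"`/`"product"`).
#' @param noise_sd Standard deviation of the log-scale noise (>= 0).
#' @param seed RNG seed.
#' @return Numeric cost vector, one entry per job.
#' @export
simulate_runtimes <- function(jobs, cost_model, noise_sd = 0, seed = 1L) {
  attribute <- cost_model$attribute
  if (is.null(attribute) || is.na(attribute)) attribute <- "product"
  attrs <- job_weights(jobs, attribute)
  base <- predict_cost(cost_model, attrs)
  eps <- if (noise_sd > 0)
    local_seed(seed, stats::rnorm(length(base), sd = noise_sd))
  else rep(0, length(base))
  pmax(base * exp(eps), 1e-9)
}

#' Write a domain as a minimal PDB file
#'
#' Emits fixed-width PDB v3 ATOM records (CA only, chain A, occupancy 1.00)
#' plus END, such that [read_pdb_domain()] round-trips id, chain, sequence
#' and coordinates at the format's 3-decimal precision.
#'
#' @param domain A [protein_domain()].
#' @param path Output path.
#' @export
write_pdb <- function(domain, path) {
  stopifnot(inherits(domain, "ProteinDomain"))
  if (any(abs(domain$ca_coords) > 9999.999))
    stop("coordinate exceeds PDB fixed-width field (|x| > 9999.999)")
  res3 <- aa_one_to_three(strsplit(domain$sequence, "")[[1L]])
  lines <- sprintf(
    "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(domain$length), res3, seq_len(domain$length),
    domain$ca_coords[, 1L], domain$ca_coords[, 2L], domain$ca_coords[, 3L])
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a benchmark to disk as PDB files plus a labels table
#'
#' @param benchmark A [make_benchmark()] result.
#' @param out_dir Output directory (created if absent).
#' @return The directory, invisibly; contains one `<id>.pdb` per domain and
#'   a `labels.tsv` with columns `domain_id`, `fold_label`.
#' @export
write_benchmark <- function(benchmark, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (d in benchmark$domains)
    write_pdb(d, file.path(out_dir, paste0(d$id, ".pdb")))
  utils::write.table(benchmark$labels, file.path(out_dir, "labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
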