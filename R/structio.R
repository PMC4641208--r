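# Structure I/O: PDB C-alpha traces and residue contact maps.

#' Construct a ProteinDomain
#'
#' A `ProteinDomain` is an ordered C-alpha trace: one id, one chain, a
#' one-letter sequence and an `n x 3` coordinate matrix in Angstrom. It is
#' the unit of comparison for every pairwise method in the package.
#'
#' @param id Domain identifier.
#' @param chain_id Chain the trace was taken from.
#' @param sequence One-letter amino-acid string (same length as the trace).
#' @param ca_coords Numeric matrix, one row per residue, columns x/y/z (A).
#' @param fold_label Optional fold-class label used by the evaluation module.
#' @return An object of class `ProteinDomain` with fields `id`, `chain_id`,
#'   `sequence`, `ca_coords`, `length`, `fold_label`.
#' @export
protein_domain <- function(id, chain_id, sequence, ca_coords, fold_label = NULL) {
  ca_coords <- as.matrix(ca_coords)
  if (ncol(ca_coords) != 3L)
    stop("ca_coords must have 3 columns")
  storage.mode(ca_coords) <- "double"
  n <- nrow(ca_coords)
  if (n < 1L) stop("empty domain: no C-alpha coordinates")
  if (nchar(sequence) != n)
    stop("sequence length (", nchar(sequence), ") != number of C-alpha records (", n, ")")
  if (!all(is.finite(ca_coords)))
    stop("non-finite coordinates in domain ", id)
  dimnames(ca_coords) <- NULL
  structure(
    list(id = as.character(id), chain_id = as.character(chain_id),
         sequence = sequence, ca_coords = ca_coords, length = n,
         fold_label = fold_label),
    class = "ProteinDomain")
}

#' @export
print.ProteinDomain <- function(x, ...) {
  cat(sprintf("<ProteinDomain %s> chain %s, %d residues%s\n", x$id, x$chain_id,
              x$length,
              if (!is.null(x$fold_label)) paste0(", fold ", x$fold_label) else ""))
  invisible(x)
}

#' Read a protein domain from a PDB file
#'
#' Keeps the C-alpha atoms of the first chain encountered in ATOM records
#' (or of `chain_override`), first MODEL only, one CA per residue (the first
#' acceptable altloc wins). Residues without a CA are skipped; HETATM records
#' are ignored; three-letter residue names are mapped to one-letter codes
#' with unknown residues becoming `'X'`.
#'
#' @param pdb PDB-format text (single string or character vector of lines) or
#'   a path to a PDB file.
#' @param chain_override Optionally select a specific chain id instead of the
#'   first one seen.
#' @param id Domain id; defaults to the file name without extension, or
#'   `"domain"` for literal text input.
#' @return A [protein_domain()].
#' @export
read_pdb_domain <- function(pdb, chain_override = NULL, id = NULL) {
  if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
    lines <- readLines(pdb, warn = FALSE)
    if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(pdb))
  } else {
    lines <- unlist(strsplit(pdb, "\n", fixed = TRUE), use.names = FALSE)
    if (is.null(id)) id <- "domain"
  }

  # First MODEL only: truncate at the first ENDMDL.
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1L] - 1L)]

  atom_idx <- grep("^ATOM  ", lines)
  if (!length(atom_idx)) stop("empty domain: no ATOM records in PDB input")

  parse_field <- function(l, from, to) substr(l, from, to)
  recs <- lines[atom_idx]
  if (any(nchar(recs) < 54L)) {
    bad <- atom_idx[which(nchar(recs) < 54L)[1L]]
    stop("malformed ATOM line at line ", bad, ": fewer than 54 columns")
  }
  atom_name <- trimws(parse_field(recs, 13, 16))
  altloc    <- parse_field(recs, 17, 17)
  res_name  <- trimws(parse_field(recs, 18, 20))
  chain     <- parse_field(recs, 22, 22)
  res_seq   <- trimws(parse_field(recs, 23, 26))
  icode     <- parse_field(recs, 27, 27)
  xs <- suppressWarnings(as.numeric(parse_field(recs, 31, 38)))
  ys <- suppressWarnings(as.numeric(parse_field(recs, 39, 46)))
  zs <- suppressWarnings(as.numeric(parse_field(recs, 47, 54)))
  if (anyNA(xs) || anyNA(ys) || anyNA(zs)) {
    bad <- atom_idx[which(is.na(xs) | is.na(ys) | is.na(zs))[1L]]
    stop("malformed ATOM line at line ", bad, ": non-numeric coordinate field")
  }

  sel_chain <- if (!is.null(chain_override)) as.character(chain_override) else chain[1L]
  keep <- chain == sel_chain & atom_name == "CA"
  if (!any(keep))
    stop("empty domain: no C-alpha atoms in chain '", sel_chain, "'")

  # One CA per residue: first acceptable altloc, residues ordered by first
  # appearance (insertion codes collapsed by appearance order).
  res_key <- paste0(res_seq[keep], "|", icode[keep])
  first <- !duplicated(res_key)
  ki <- which(keep)[first]

  protein_domain(
    id = id, chain_id = sel_chain,
    sequence = paste(aa_three_to_one(res_name[ki]), collapse = ""),
    ca_coords = cbind(xs[ki], ys[ki], zs[ki]))
}

#' Derive a residue contact map
#'
#' Two residues `i < j` are in contact when their C-alpha Euclidean distance
#' is at or below `threshold_angstrom` and their sequence separation
#' `j - i` is at least `min_separation`. Indices are 0-based, a canonical
#' convention for the serialized form fed to the compressor.
#'
#' @param domain A [protein_domain()].
#' @param threshold_angstrom Contact distance cutoff in Angstrom (> 0).
#' @param min_separation Minimum sequence separation (>= 1).
#' @return An object of class `ContactMap` with fields `domain_id`,
#'   `n_residues`, `contacts` (2-column 0-based integer matrix, `i < j`,
#'   sorted), `threshold_angstrom`, `min_separation`.
#' @export
contact_map <- function(domain, threshold_angstrom = 8.0, min_separation = 2L) {
  stopifnot(inherits(domain, "ProteinDomain"),
            threshold_angstrom > 0, min_separation >= 1L)
  n <- domain$length
  xyz <- domain$ca_coords
  contacts <- matrix(integer(0), ncol = 2L)
  if (n >= 2L) {
    d <- as.matrix(stats::dist(xyz))
    idx <- which(upper.tri(d), arr.ind = TRUE)
    sep_ok <- (idx[, 2L] - idx[, 1L]) >= min_separation
    hit <- sep_ok & d[idx] <= threshold_angstrom
    contacts <- cbind(idx[hit, 1L] - 1L, idx[hit, 2L] - 1L)
    if (nrow(contacts)) {
      ord <- order(contacts[, 1L], contacts[, 2L])
      contacts <- contacts[ord, , drop = FALSE]
    }
  }
  storage.mode(contacts) <- "integer"
  dimnames(contacts) <- NULL
  structure(
    list(domain_id = domain$id, n_residues = n, contacts = contacts,
         threshold_angstrom = threshold_angstrom,
         min_separation = as.integer(min_separation)),
    class = "ContactMap")
}

#' @export
print.ContactMap <- function(x, ...) {
  cat(sprintf("<ContactMap %s> %d residues, %d contacts (<= %.1f A, sep >= %d)\n",
              x$domain_id, x$n_residues, nrow(x$contacts),
              x$threshold_angstrom, x$min_separation))
  invisible(x)
}

#' Canonical byte serialization of a contact map
#'
#' Deterministic ASCII encoding used as the compressor input for the
#' compression-distance method: a header line `n=<n_residues>` followed by
#' one `i<TAB>j` line per contact in (i, j) lexicographic order, `\n` line
#' endings. Two maps differing in any contact serialize differently.
#'
#' @param cm A [contact_map()].
#' @return A raw vector.
#' @export
serialize_contact_map <- function(cm) {
  stopifnot(inherits(cm, "ContactMap"))
  lines <- sprintf("n=%d", cm$n_residues)
  if (nrow(cm$contacts))
    lines <- c(lines, sprintf("%d\t%d", cm$contacts[, 1L], cm$contacts[, 2L]))
  charToRaw(paste0(paste(lines, collapse = "\n"), "\n"))
}

#' Write a contact map as text
#'
#' Dumps the canonical serialization (see [serialize_contact_map()]) to a
#' `.cmap` file for inspection.
#'
#' @param cm A [contact_map()].
#' @param path Output file path.
#' @export
write_cmap <- function(cm, path) {
  writeBin(serialize_contact_map(cm), path)
  invisible(path)
}
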