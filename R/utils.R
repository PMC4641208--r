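# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All stochastic operations in the
# package go through this so no function perturbs global RNG state.
local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Three-letter -> one-letter amino acid codes; anything else maps to 'X'.
AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)
AA1TO3 <- c(stats::setNames(names(AA3TO1), unname(AA3TO1)), X = "UNK")

aa_three_to_one <- function(res3) {
  out <- AA3TO1[toupper(res3)]
  out[is.na(out)] <- "X"
  unname(out)
}

aa_one_to_three <- function(res1) {
  out <- AA1TO3[toupper(res1)]
  out[is.na(out)] <- "UNK"
  unname(out)
}
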