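## Internal helpers shared across analysis stages.

# Three-letter codes treated as protein residues (incl. common AMBER
# protonation-state variants of His/Cys/Asp/Glu/Lys).
.aa3 <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "HIE", "HID", "HIP", "CYX", "CYM", "ASH", "GLH", "LYN"
)

is_protein_residue <- function(residue_name) toupper(residue_name) %in% .aa3

# Minimum-image displacement for an n x 3 displacement matrix under an
# orthorhombic box (lengths in Angstrom).
min_image <- function(d, box) {
  stopifnot(length(box) == 3L, all(box > 0))
  d - sweep(round(sweep(d, 2L, box, "/")), 2L, box, "*")
}

# Euclidean row norms.
row_norms <- function(m) sqrt(rowSums(m * m))

# Uniformly distributed unit vectors (n x 3).
random_unit_vectors <- function(n) {
  v <- matrix(stats::rnorm(3L * n), ncol = 3L)
  v / row_norms(v)
}

# Derive a reproducible per-stream seed (< 2^31) from a base seed and a
# stream counter, so adding streams never perturbs existing ones.
stream_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(stream)) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ib <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_ib(name, " must be a single finite number")
  if ((strict && x <= lower) || (!strict && x < lower))
    stop_ib(name, " must be ", if (strict) "> " else ">= ", lower)
  invisible(x)
}
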