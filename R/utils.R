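# Shared constants and small helpers.

# Acceptable chemical-shift windows (ppm) per backbone atom class.
PPM_WINDOWS <- list(
  H  = c(-2, 14),
  N  = c(90, 140),
  CA = c(0, 200),
  CB = c(0, 200),
  C  = c(0, 200)
)

BACKBONE_ATOMS <- names(PPM_WINDOWS)

AA1 <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

AA3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL", X = "UNK"
)

AA3_TO_1 <- stats::setNames(names(AA3), AA3)

#' @keywords internal
aa_valid_atoms <- function(residue_type) {
  # Glycine has no CB; proline has no backbone amide H.
  vapply(residue_type, function(r) {
    atoms <- BACKBONE_ATOMS
    if (identical(r, "G")) atoms <- setdiff(atoms, "CB")
    if (identical(r, "P")) atoms <- setdiff(atoms, "H")
    list(atoms)
  }, vector("list", 1L))
}

ppm_in_window <- function(atom_name, shift_ppm) {
  lo <- vapply(atom_name, function(a) PPM_WINDOWS[[a]][1], numeric(1))
  hi <- vapply(atom_name, function(a) PPM_WINDOWS[[a]][2], numeric(1))
  shift_ppm >= lo & shift_ppm <= hi
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Scaled (1H, 15N) distance used both for peak tracking and the weighted CSP.
scaled_hn_distance <- function(dh, dn, n_weight = 5) {
  sqrt(dh^2 + (dn / n_weight)^2)
}

# Sub-seed derivation that stays inside 32-bit integer range.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + i * 9973) %% 2147483647)
}
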