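# In-code fixture builders shared across test files.

# Shift table from per-residue amide positions.
amide_table <- function(residue_number, h_ppm, n_ppm, residue_type = "A",
                        state_label = "free", molar_ratio = 0) {
  n <- length(residue_number)
  residue_type <- rep_len(residue_type, n)
  shift_table(
    data.frame(
      residue_number = rep(residue_number, each = 2),
      residue_type = rep(residue_type, each = 2),
      atom_name = rep(c("H", "N"), n),
      shift_ppm = as.numeric(rbind(h_ppm, n_ppm))
    ),
    state_label = state_label, molar_ratio = molar_ratio
  )
}

# Titration series from a reference and a list of per-ratio peak tibbles.
toy_series <- function(ref, peaks_by_ratio, protein_total = 80) {
  pk <- dplyr::bind_rows(purrr::imap(peaks_by_ratio, function(df, r) {
    df$molar_ratio <- as.numeric(r)
    df
  }))
  titration_series(pk[c("molar_ratio", "h_ppm", "n_ppm", "intensity")],
                   reference = ref, protein_total = protein_total)
}

peak_df <- function(h, n, intensity = 1) {
  tibble::tibble(h_ppm = h, n_ppm = n, intensity = rep_len(intensity,
                                                           length(h)))
}

# Toy 3-residue PDB text with exact coordinates.
toy_pdb_lines <- function() {
  c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A   2       4.000   5.000   6.000  1.00  0.00           C",
    "ATOM      4  CA  SER A   3       7.000   8.000   9.000  1.00  0.00           C",
    "END"
  )
}
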