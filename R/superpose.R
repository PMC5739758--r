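# Least-squares rigid-body superposition (Kabsch) and binding-pocket
# conservation between mapped homolog structures.

#' Kabsch superposition of mapped C-alpha pairs
#'
#' Finds the proper rotation R and translation t minimizing the
#' least-squares deviation `sum |R b_i + t - a_i|^2` over the mapped
#' residue pairs (closed-form SVD solution with determinant correction so
#' reflections are excluded), and reports the RMSD of the mapped atoms
#' after the transform.
#'
#' @param a,b `structure_ca` tibbles (see [read_structure_ca()]).
#' @param map Tibble `res_a`, `res_b` of residue pairs to superpose
#'   (e.g. from [map_equivalent_residues()]); `NULL` pairs residues with
#'   identical numbers present in both structures.
#' @return A list of class `superposition`: `rotation` (3x3, det +1),
#'   `translation` (length 3, Angstrom), `rmsd`, `n_atoms`.
#' @export
superpose_kabsch <- function(a, b, map = NULL) {
  if (is.null(map)) {
    shared <- intersect(a$residue_number, b$residue_number)
    map <- tibble::tibble(res_a = shared, res_b = shared)
  }
  ia <- match(map$res_a, a$residue_number)
  ib <- match(map$res_b, b$residue_number)
  missing <- is.na(ia) | is.na(ib)
  if (any(missing)) {
    rlang::abort(paste0(
      "mapped residue(s) missing a CA in one structure: ",
      paste(sprintf("(%s,%s)", map$res_a[missing], map$res_b[missing]),
            collapse = ", ")))
  }
  A <- as.matrix(a[ia, c("x", "y", "z")])
  B <- as.matrix(b[ib, c("x", "y", "z")])
  n <- nrow(A)
  if (n < 3L) rlang::abort("need at least 3 mapped atom pairs")

  ca <- colMeans(A)
  cb <- colMeans(B)
  Ac <- sweep(A, 2, ca)
  Bc <- sweep(B, 2, cb)
  sv_b <- svd(Bc)$d
  if (sv_b[2] < 1e-8 * max(sv_b[1], 1)) {
    warning("near-collinear atoms: rotation about the common axis is ",
            "undetermined (RMSD still minimal)", call. = FALSE)
  }
  H <- crossprod(Bc, Ac)  # sum over atoms of b_i a_i^T
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t_vec <- as.numeric(ca - R %*% cb)
  fitted <- sweep(Bc %*% t(R), 2, ca, "+")
  rmsd <- sqrt(mean(rowSums((fitted - A)^2)))
  structure(
    list(rotation = R, translation = t_vec, rmsd = rmsd, n_atoms = n),
    class = "superposition"
  )
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> RMSD %.3f A over %d CA pairs\n",
              x$rmsd, x$n_atoms))
  invisible(x)
}

#' Apply a superposition transform to coordinates
#'
#' @param structure A `structure_ca` tibble.
#' @param superposition A [superpose_kabsch()] result.
#' @return The structure with transformed coordinates.
#' @export
apply_superposition <- function(structure, superposition) {
  xyz <- as.matrix(structure[, c("x", "y", "z")])
  new <- sweep(xyz %*% t(superposition$rotation), 2,
               superposition$translation, "+")
  structure$x <- new[, 1]
  structure$y <- new[, 2]
  structure$z <- new[, 3]
  structure
}

#' Compare binding pockets across mapped homologs
#'
#' Conserved pairs are mapped residue pairs significant on both sides;
#' the Jaccard index over the mapped region is
#' `|conserved| / |pairs with either side significant|`. Significant
#' residues outside the mapped range are counted as unshared with a
#' warning.
#'
#' @param sig_a,sig_b Integer vectors of significant residues on each
#'   protein's numbering scale.
#' @param map Tibble `res_a`, `res_b` of equivalent residues.
#' @return A list of class `pocket_comparison`: `significant_a`,
#'   `significant_b`, `conserved_pairs` (tibble), `jaccard_mapped`,
#'   `unmapped_a`, `unmapped_b`.
#' @export
compare_pockets <- function(sig_a, sig_b, map) {
  sig_a <- sort(unique(as.integer(sig_a)))
  sig_b <- sort(unique(as.integer(sig_b)))
  unmapped_a <- setdiff(sig_a, map$res_a)
  unmapped_b <- setdiff(sig_b, map$res_b)
  if (length(unmapped_a) || length(unmapped_b)) {
    warning("significant residue(s) outside the mapped range counted as ",
            "unshared: A {", paste(unmapped_a, collapse = ","), "} B {",
            paste(unmapped_b, collapse = ","), "}", call. = FALSE)
  }
  in_a <- map$res_a %in% sig_a
  in_b <- map$res_b %in% sig_b
  conserved <- map[in_a & in_b, ]
  either <- sum(in_a | in_b) + length(unmapped_a) + length(unmapped_b)
  structure(
    list(
      significant_a = sig_a, significant_b = sig_b,
      conserved_pairs = conserved,
      jaccard_mapped = if (either > 0) nrow(conserved) / either else NA_real_,
      unmapped_a = unmapped_a, unmapped_b = unmapped_b
    ),
    class = "pocket_comparison"
  )
}

#' @export
print.pocket_comparison <- function(x, ...) {
  cat(sprintf(
    "<pocket_comparison> %d conserved pair(s), Jaccard %.3f (A: %d, B: %d)\n",
    nrow(x$conserved_pairs), x$jaccard_mapped,
    length(x$significant_a), length(x$significant_b)))
  invisible(x)
}

#' PyMOL-style selection string for a residue set
#'
#' @param residues Integer residue numbers.
#' @param object Structure object name used in the selection.
#' @param chain Chain identifier.
#' @return A single selection string.
#' @export
pymol_selection <- function(residues, object = "struct", chain = "A") {
  sprintf("%s and chain %s and resi %s", object, chain,
          paste(sort(unique(residues)), collapse = "+"))
}
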