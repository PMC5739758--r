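# HSQC peak tracking across a titration series.

#' Build a titration series
#'
#' A titration series holds the peak lists of every titration point (as a
#' single long tibble keyed by `molar_ratio`), the assigned free-state
#' reference, and the total protein concentration. The first point must
#' have ratio 0 and ratios must be strictly increasing.
#'
#' @param peaks Tibble with columns `molar_ratio`, `h_ppm`, `n_ppm`,
#'   `intensity` covering every titration point (ratio 0 included).
#' @param reference Free-state [shift_table()] with the assignments.
#' @param protein_total Total protein concentration in micromolar.
#' @return A list of class `titration_series`.
#' @export
titration_series <- function(peaks, reference, protein_total) {
  ratios <- sort(unique(peaks$molar_ratio))
  if (length(ratios) < 2L) rlang::abort("need at least two titration points")
  if (ratios[1] != 0) rlang::abort("first titration point must have ratio 0")
  if (any(diff(ratios) <= 0)) {
    rlang::abort("molar ratios must be strictly increasing")
  }
  if (!inherits(reference, "shift_table")) {
    rlang::abort("reference must be a shift_table")
  }
  structure(
    list(peaks = tibble::as_tibble(peaks), reference = reference,
         protein_total = as.numeric(protein_total), ratios = ratios),
    class = "titration_series"
  )
}

#' @export
print.titration_series <- function(x, ...) {
  cat("<titration_series> ", length(x$ratios), " points (ratios ",
      paste(x$ratios, collapse = ", "), "), protein ",
      x$protein_total, " uM, ", nrow(x$peaks), " peaks\n", sep = "")
  invisible(x)
}

# (H, N) reference positions of residues with both amide shifts assigned.
reference_positions <- function(reference) {
  wide <- tidyr::pivot_wider(
    reference[c("residue_number", "atom_name", "shift_ppm")],
    names_from = "atom_name", values_from = "shift_ppm"
  )
  if (!all(c("H", "N") %in% names(wide))) {
    rlang::abort("reference assignments must contain H and N shifts")
  }
  out <- wide[!is.na(wide$H) & !is.na(wide$N),
              c("residue_number", "H", "N")]
  names(out) <- c("residue_number", "h_ppm", "n_ppm")
  out
}

#' Track assigned peaks through a titration
#'
#' Point-to-point greedy nearest-neighbour matching: at each titration
#' point every residue's expected position is its last observed position
#' (starting from the free-state assignments), and peaks within the
#' per-axis tolerances are matched in order of increasing scaled distance
#' `d = sqrt(dH^2 + (dN/5)^2)`, ties broken by lower residue number. Each
#' peak matches at most one residue; residues with no candidate peak are
#' marked absent at that point. Point-to-point tracking (rather than
#' free-to-endpoint) follows fast-exchange trajectories that drift
#' further than the tolerance over the full titration.
#'
#' @param series A [titration_series()].
#' @param tol_h Matching tolerance on the 1H axis (ppm).
#' @param tol_n Matching tolerance on the 15N axis (ppm).
#' @param n_weight 15N scaling used in the match distance.
#' @return A tibble of class `peak_tracking`: one row per (ratio, residue)
#'   with `matched`, the matched peak position/intensity, the scaled match
#'   distance and the matched peak's row id within its titration point.
#' @export
track_peaks <- function(series, tol_h = 0.05, tol_n = 0.5, n_weight = 5) {
  if (tol_h <= 0 || tol_n <= 0) rlang::abort("tolerances must be > 0")
  ref <- reference_positions(series$reference)
  last <- ref
  out <- vector("list", length(series$ratios))
  for (k in seq_along(series$ratios)) {
    r <- series$ratios[k]
    pk <- series$peaks[series$peaks$molar_ratio == r, , drop = FALSE]
    dh <- outer(last$h_ppm, pk$h_ppm, "-")
    dn <- outer(last$n_ppm, pk$n_ppm, "-")
    ok <- abs(dh) <= tol_h & abs(dn) <= tol_n
    d <- scaled_hn_distance(dh, dn, n_weight)
    cand <- which(ok, arr.ind = TRUE)
    matched_peak <- rep(NA_integer_, nrow(last))
    matched_d <- rep(NA_real_, nrow(last))
    if (nrow(cand)) {
      ord <- order(d[cand], last$residue_number[cand[, 1]])
      cand <- cand[ord, , drop = FALSE]
      used_res <- logical(nrow(last))
      used_pk <- logical(nrow(pk))
      for (i in seq_len(nrow(cand))) {
        ri <- cand[i, 1]; pi <- cand[i, 2]
        if (used_res[ri] || used_pk[pi]) next
        used_res[ri] <- TRUE
        used_pk[pi] <- TRUE
        matched_peak[ri] <- pi
        matched_d[ri] <- d[ri, pi]
      }
    }
    hit <- !is.na(matched_peak)
    out[[k]] <- tibble::tibble(
      molar_ratio = r,
      residue_number = last$residue_number,
      matched = hit,
      h_ppm = ifelse(hit, pk$h_ppm[matched_peak], NA_real_),
      n_ppm = ifelse(hit, pk$n_ppm[matched_peak], NA_real_),
      intensity = ifelse(hit, pk$intensity[matched_peak], NA_real_),
      dist = matched_d,
      peak_id = matched_peak
    )
    # carry matched positions forward; absent residues keep last position
    upd <- out[[k]][out[[k]]$matched, ]
    idx <- match(upd$residue_number, last$residue_number)
    last$h_ppm[idx] <- upd$h_ppm
    last$n_ppm[idx] <- upd$n_ppm
  }
  res <- dplyr::bind_rows(out)
  attr(res, "tol_h") <- tol_h
  attr(res, "tol_n") <- tol_n
  attr(res, "n_weight") <- n_weight
  class(res) <- c("peak_tracking", class(res))
  res
}
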