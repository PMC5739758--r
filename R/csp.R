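# Weighted chemical shift perturbations, the significance threshold,
# exchange-regime classification and stoichiometry assessment.

#' Weighted combined chemical shift perturbation
#'
#' `delta = sqrt((dH^2 + (dN / n_weight)^2) / 2)`, the standard weighted
#' combination of amide 1H and 15N shift changes with the 15N change
#' down-weighted (default 5) to account for its larger ppm dispersion.
#'
#' @param delta_h 1H shift change (ppm).
#' @param delta_n 15N shift change (ppm).
#' @param n_weight 15N scaling factor (> 0).
#' @return Weighted CSP in ppm (vectorized).
#' @export
weighted_csp <- function(delta_h, delta_n, n_weight = 5) {
  if (n_weight <= 0) rlang::abort("n_weight must be > 0")
  sqrt((delta_h^2 + (delta_n / n_weight)^2) / 2)
}

#' Compute a per-residue CSP profile between two states
#'
#' For every residue with H and N assigned in both states:
#' `dH = H(bound) - H(free)`, `dN = N(bound) - N(free)` and the weighted
#' CSP via [weighted_csp()]. Prolines (no amide) are flagged `proline`;
#' residues assigned free but missing in the bound state are flagged
#' `disappeared`; residues not assigned in the free state are
#' `unassigned`. CSP values are reported only for `shifted`/`relocated`
#' residues.
#'
#' @param free,bound [shift_table()] objects on the same numbering scale.
#' @param n_weight 15N scaling factor.
#' @param residue_range Integer range (length-2) of residues the profile
#'   covers; defaults to the span of the free-state assignments.
#' @param relocated_residues Residues whose bound-state position came from
#'   separate bound-state assignment (e.g. NOESY re-assignment after the
#'   peak moved too far to track); flagged `relocated` instead of `shifted`.
#' @return A tibble of class `csp_profile` with one row per residue in the
#'   range: `residue_number`, `residue_type`, `delta_h`, `delta_n`,
#'   `delta_weighted`, `status`.
#' @export
compute_csp <- function(free, bound, n_weight = 5, residue_range = NULL,
                        relocated_residues = integer()) {
  fw <- amide_wide(free)
  bw <- amide_wide(bound)
  shared <- intersect(fw$residue_number, bw$residue_number)
  if (!length(shared)) {
    rlang::abort("no residues shared between states; numbering scales differ?")
  }
  residue_range <- residue_range %||% range(fw$residue_number)
  residues <- seq(residue_range[1], residue_range[2])

  types <- stats::setNames(free$residue_type, free$residue_number)
  types_b <- stats::setNames(bound$residue_type, bound$residue_number)

  fi <- match(residues, fw$residue_number)
  bi <- match(residues, bw$residue_number)
  delta_h <- bw$H[bi] - fw$H[fi]
  delta_n <- bw$N[bi] - fw$N[fi]

  type <- unname(types[as.character(residues)])
  type[is.na(type)] <- unname(types_b[as.character(residues[is.na(type)])])

  status <- dplyr::case_when(
    !is.na(type) & type == "P" ~ "proline",
    !is.na(fi) & !is.na(bi) & residues %in% relocated_residues ~ "relocated",
    !is.na(fi) & !is.na(bi) ~ "shifted",
    !is.na(fi) & is.na(bi) ~ "disappeared",
    TRUE ~ "unassigned"
  )
  keep <- status %in% c("shifted", "relocated")
  delta_h[!keep] <- NA_real_
  delta_n[!keep] <- NA_real_

  out <- tibble::tibble(
    residue_number = residues,
    residue_type = type,
    delta_h = delta_h,
    delta_n = delta_n,
    delta_weighted = ifelse(keep, weighted_csp(delta_h, delta_n, n_weight),
                            NA_real_),
    status = status
  )
  attr(out, "n_weight") <- n_weight
  attr(out, "ratio_compared") <- attr(bound, "molar_ratio", exact = TRUE)
  class(out) <- c("csp_profile", class(out))
  out
}

# residues with both amide shifts, one row each with columns H, N
amide_wide <- function(tbl) {
  sub <- tbl[tbl$atom_name %in% c("H", "N"),
             c("residue_number", "atom_name", "shift_ppm")]
  wide <- tidyr::pivot_wider(sub, names_from = "atom_name",
                             values_from = "shift_ppm")
  for (a in c("H", "N")) if (!a %in% names(wide)) wide[[a]] <- NA_real_
  wide[!is.na(wide$H) & !is.na(wide$N), ]
}

#' Significance threshold for a CSP profile
#'
#' Cutoff = mean + k * SD of the weighted CSPs, with the sample (n - 1)
#' standard deviation, computed over residues with a numeric CSP.
#' Residues whose endpoints were recovered by separate bound-state
#' assignment (`relocated`) are included by default: large perturbations
#' belong in the profile statistics once their endpoints are known.
#' `disappeared` residues (no endpoint at all) never enter the statistics.
#'
#' @param profile A [compute_csp()] profile.
#' @param k Multiplier on the standard deviation (default 1).
#' @param include_relocated Include `relocated` residues in the
#'   mean/SD? Default `TRUE`; set `FALSE` to compute the threshold over
#'   continuously tracked residues only.
#' @return A list of class `csp_threshold`: `mean`, `sd`, `k`, `cutoff`,
#'   `n_used`.
#' @export
compute_threshold <- function(profile, k = 1, include_relocated = TRUE) {
  statuses <- if (include_relocated) c("shifted", "relocated") else "shifted"
  vals <- profile$delta_weighted[profile$status %in% statuses]
  vals <- vals[is.finite(vals)]
  if (length(vals) < 2L) {
    rlang::abort("need at least 2 numeric CSP values for a threshold")
  }
  m <- mean(vals)
  s <- stats::sd(vals)
  structure(
    list(mean = m, sd = s, k = k, cutoff = m + k * s, n_used = length(vals)),
    class = "csp_threshold"
  )
}

#' @export
print.csp_threshold <- function(x, ...) {
  cat(sprintf(
    "<csp_threshold> cutoff %.4f ppm (mean %.4f + %g * sd %.4f, n = %d)\n",
    x$cutoff, x$mean, x$k, x$sd, x$n_used))
  invisible(x)
}

#' Select residues with significant CSPs
#'
#' Residues whose weighted CSP strictly exceeds the cutoff, in ascending
#' residue order. Disappeared residues (assigned free, no bound endpoint)
#' are reported in the `disappeared` attribute, never silently mixed into
#' the significant list.
#'
#' @param profile A [compute_csp()] profile.
#' @param threshold A [compute_threshold()] result.
#' @return Tibble of significant residues (`residue_number`,
#'   `delta_weighted`, `status`), with attributes `cutoff` and
#'   `disappeared`.
#' @export
select_significant <- function(profile, threshold) {
  sig <- profile[is.finite(profile$delta_weighted) &
                   profile$delta_weighted > threshold$cutoff,
                 c("residue_number", "delta_weighted", "status")]
  sig <- dplyr::arrange(sig, .data$residue_number)
  attr(sig, "cutoff") <- threshold$cutoff
  attr(sig, "disappeared") <-
    profile$residue_number[profile$status == "disappeared"]
  sig
}

#' Classify the exchange regime of each residue
#'
#' The discriminating feature is the discontinuity between a residue's
#' traceable trajectory and its bound-state endpoint. The endpoint is the
#' tracked position at the final titration point, unless bound-state
#' assignments are supplied and disagree with it by more than 3x the
#' (scaled) tracking tolerance, in which case the assignment is
#' authoritative (it corrects both untracked residues and peaks
#' mis-tracked onto a bystander); residues absent at the final point take
#' their endpoint from the assignments when available. A residue whose
#' endpoint jumps by more than 3x the scaled tolerance from its last
#' traceable position is in slow exchange (the peak vanished and
#' reappeared elsewhere, or relocated beyond tracking); a residue whose
#' endpoint continues its trajectory is in fast exchange; a residue with
#' no recoverable endpoint is undetermined.
#'
#' @param tracking A [track_peaks()] result.
#' @param bound_reference Optional bound-state [shift_table()] supplying
#'   authoritative endpoints (e.g. from NOESY re-assignment of the bound
#'   state).
#' @return Tibble: `residue_number`, `regime` (slow/fast/undetermined),
#'   `n_absent`, `absent_intermediate`, `relocated` (endpoint taken from
#'   the assignments), `displacement` (scaled ppm, free position to
#'   endpoint) and `trajectory_jump` (scaled ppm, last traced position to
#'   endpoint).
#' @export
classify_exchange <- function(tracking, bound_reference = NULL) {
  tol_h <- attr(tracking, "tol_h")
  tol_n <- attr(tracking, "tol_n")
  n_weight <- attr(tracking, "n_weight") %||% 5
  tol_d <- scaled_hn_distance(tol_h, tol_n, n_weight)
  ratios <- sort(unique(tracking$molar_ratio))
  final <- max(ratios)
  bound_pos <- if (!is.null(bound_reference)) {
    reference_positions(bound_reference)
  }
  dist2 <- function(p, q) {
    scaled_hn_distance(p$h_ppm[1] - q$h_ppm[1], p$n_ppm[1] - q$n_ppm[1],
                       n_weight)
  }

  split_res <- split(tracking, tracking$residue_number)
  rows <- purrr::map(split_res, function(tr) {
    tr <- tr[order(tr$molar_ratio), ]
    res <- tr$residue_number[1]
    free_pos <- tr[tr$molar_ratio == 0, c("h_ppm", "n_ppm")]
    inter <- tr$molar_ratio > 0 & tr$molar_ratio < final
    absent_intermediate <- any(!tr$matched[inter])
    matched_final <- isTRUE(tr$matched[tr$molar_ratio == final])
    pre <- tr[tr$molar_ratio < final & tr$matched, ]
    traj_last <- if (nrow(pre)) pre[nrow(pre), c("h_ppm", "n_ppm")]
                 else free_pos

    bp <- if (!is.null(bound_pos) && res %in% bound_pos$residue_number) {
      bound_pos[bound_pos$residue_number == res, c("h_ppm", "n_ppm")]
    }
    endpoint <- NULL
    relocated <- FALSE
    if (matched_final) {
      endpoint <- tr[tr$molar_ratio == final, c("h_ppm", "n_ppm")]
      if (!is.null(bp) && dist2(endpoint, bp) > 3 * tol_d) {
        endpoint <- bp
        relocated <- TRUE
      }
    } else if (!is.null(bp)) {
      endpoint <- bp
      relocated <- TRUE
    }
    displacement <- if (!is.null(endpoint)) dist2(endpoint, free_pos)
                    else NA_real_
    jump <- if (!is.null(endpoint)) dist2(endpoint, traj_last) else NA_real_
    regime <- if (is.null(endpoint)) {
      "undetermined"
    } else if (jump > 3 * tol_d) {
      "slow"
    } else {
      "fast"
    }
    tibble::tibble(
      residue_number = res,
      regime = regime,
      n_absent = sum(!tr$matched),
      absent_intermediate = absent_intermediate,
      relocated = relocated,
      displacement = displacement,
      trajectory_jump = jump
    )
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$residue_number)
  class(out) <- c("exchange_calls", class(out))
  out
}

#' Per-ratio mean CSP over the titration
#'
#' For each titration point, every residue's effective position is the
#' intensity-weighted centroid of the peaks attributable to it: its
#' tracked trajectory peak plus, for residues with a known bound-state
#' endpoint, the unclaimed peak nearest that endpoint (within tolerance).
#' In slow exchange this centroid moves from the free to the bound
#' position in proportion to the bound population, so the per-ratio mean
#' CSP traces the binding isotherm and flattens at saturation. The mean
#' is taken over residues with a defined position at every ratio.
#'
#' @param series A [titration_series()].
#' @param tracking A [track_peaks()] result for that series.
#' @inheritParams classify_exchange
#' @return Tibble: `molar_ratio`, `mean_csp`, `n_residues`.
#' @export
csp_by_ratio <- function(series, tracking, bound_reference = NULL) {
  tol_h <- attr(tracking, "tol_h")
  tol_n <- attr(tracking, "tol_n")
  n_weight <- attr(tracking, "n_weight") %||% 5
  ref <- reference_positions(series$reference)
  bound_pos <- if (!is.null(bound_reference)) {
    reference_positions(bound_reference)
  }
  ratios <- sort(unique(tracking$molar_ratio))
  per_res <- matrix(NA_real_, nrow = nrow(ref), ncol = length(ratios),
                    dimnames = list(ref$residue_number, ratios))
  for (k in seq_along(ratios)) {
    r <- ratios[k]
    pk <- series$peaks[series$peaks$molar_ratio == r, , drop = FALSE]
    tr <- tracking[tracking$molar_ratio == r, , drop = FALSE]
    tr <- tr[match(ref$residue_number, tr$residue_number), ]
    used <- tr$peak_id[!is.na(tr$peak_id)]
    for (i in seq_len(nrow(ref))) {
      h <- numeric(); n <- numeric(); w <- numeric()
      if (isTRUE(tr$matched[i])) {
        h <- tr$h_ppm[i]; n <- tr$n_ppm[i]; w <- tr$intensity[i]
      }
      if (!is.null(bound_pos)) {
        j <- match(ref$residue_number[i], bound_pos$residue_number)
        if (!is.na(j)) {
          dh <- pk$h_ppm - bound_pos$h_ppm[j]
          dn <- pk$n_ppm - bound_pos$n_ppm[j]
          cand <- which(abs(dh) <= tol_h & abs(dn) <= tol_n &
                          !(seq_len(nrow(pk)) %in% used))
          if (length(cand)) {
            best <- cand[which.min(scaled_hn_distance(dh[cand], dn[cand],
                                                      n_weight))]
            h <- c(h, pk$h_ppm[best]); n <- c(n, pk$n_ppm[best])
            w <- c(w, pk$intensity[best])
          }
        }
      }
      if (length(w)) {
        ch <- sum(h * w) / sum(w)
        cn <- sum(n * w) / sum(w)
        per_res[i, k] <- weighted_csp(ch - ref$h_ppm[i], cn - ref$n_ppm[i],
                                      n_weight)
      }
    }
  }
  common <- stats::complete.cases(per_res)
  tibble::tibble(
    molar_ratio = ratios,
    mean_csp = unname(colMeans(per_res[common, , drop = FALSE])),
    n_residues = sum(common)
  )
}

#' Assess binding stoichiometry from the CSP plateau
#'
#' The plateau onset is the smallest molar ratio after which every
#' subsequent increment of the per-ratio mean CSP stays below the
#' tolerance; the onset ratio is reported as the apparent binding
#' stoichiometry. If only the final ratio qualifies (no flat segment
#' observed), `plateau_reached` is `FALSE` and the final ratio is a lower
#' bound on the stoichiometry. A plateau onset below ratio 1 is flagged
#' with a warning (apparent sub-unity stoichiometry, e.g. saturation by
#' excess protein).
#'
#' @param per_ratio Tibble with columns `molar_ratio` and `mean_csp`
#'   (e.g. from [csp_by_ratio()]).
#' @param tolerance Plateau tolerance on mean-CSP increments (ppm).
#' @return A list of class `saturation_call`: `stoichiometry`,
#'   `plateau_reached`, `per_ratio_mean_csp`, `tolerance`.
#' @export
assess_saturation <- function(per_ratio, tolerance = 0.005) {
  per_ratio <- dplyr::arrange(tibble::as_tibble(per_ratio), .data$molar_ratio)
  r <- per_ratio$molar_ratio
  m <- per_ratio$mean_csp
  if (length(r) < 3L) rlang::abort("need at least 3 titration ratios")
  if (max(r) <= 1) {
    warning("no ratio above 1; saturation assessment may be unreliable",
            call. = FALSE)
  }
  inc <- diff(m)
  n <- length(r)
  onset_idx <- NA_integer_
  for (j in 2:n) {
    subsequent <- if (j < n) inc[j:(n - 1)] else numeric()
    if (all(abs(subsequent) < tolerance)) {
      onset_idx <- j
      break
    }
  }
  plateau_reached <- onset_idx < n
  stoichiometry <- r[onset_idx]
  if (plateau_reached && stoichiometry < 1) {
    warning(sprintf(
      "plateau onset at sub-unity ratio %.2g; apparent stoichiometry < 1",
      stoichiometry), call. = FALSE)
  }
  structure(
    list(stoichiometry = stoichiometry, plateau_reached = plateau_reached,
         per_ratio_mean_csp = per_ratio, tolerance = tolerance),
    class = "saturation_call"
  )
}

#' @export
print.saturation_call <- function(x, ...) {
  cat(sprintf("<saturation_call> stoichiometry %.3g (plateau %s)\n",
              x$stoichiometry,
              if (x$plateau_reached) "reached" else "NOT reached"))
  invisible(x)
}

#' Plot a CSP profile
#'
#' Per-residue weighted CSP bar plot with the significance cutoff drawn
#' as a dashed line; disappeared residues are marked along the axis.
#'
#' @param object A `csp_profile`.
#' @param threshold Optional [compute_threshold()] result for the cutoff
#'   line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.csp_profile <- function(object, threshold = NULL, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df[is.finite(df$delta_weighted), ],
                       ggplot2::aes(x = .data$residue_number,
                                    y = .data$delta_weighted)) +
    ggplot2::geom_col(width = 0.8, fill = "grey30") +
    ggplot2::labs(x = "Residue number",
                  y = expression(Delta * delta ~ "(ppm)")) +
    ggplot2::theme_minimal()
  gone <- df$residue_number[df$status == "disappeared"]
  if (length(gone)) {
    p <- p + ggplot2::geom_point(
      data = tibble::tibble(residue_number = gone, delta_weighted = 0),
      shape = 4, colour = "red3"
    )
  }
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold$cutoff,
                                 linetype = "dashed")
  }
  p
}

#' Plot the per-ratio mean CSP saturation curve
#'
#' @param object A `saturation_call`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.saturation_call <- function(object, ...) {
  ggplot2::ggplot(object$per_ratio_mean_csp,
                  ggplot2::aes(x = .data$molar_ratio, y = .data$mean_csp)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$stoichiometry,
                        linetype = "dashed") +
    ggplot2::labs(x = "Molar ratio (ligand:protein)",
                  y = expression(bar(Delta * delta) ~ "(ppm)")) +
    ggplot2::theme_minimal()
}
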