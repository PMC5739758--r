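# Synthetic-data generators with known ground truth: two-state titrations,
# saturation binding curves, structure pairs and the homolog fixture.

#' Simulate an HSQC titration under two-state binding
#'
#' Generates a full titration series with known ground truth. Free-state
#' amide shifts are drawn from generic backbone statistics
#' (H ~ N(8.3, 0.6), N ~ N(119, 4), truncated to the ppm windows); pocket
#' residues acquire fixed bound-state offsets; the bound protein fraction
#' at each ratio follows the exact 1:1 depletion equilibrium
#' ([bound_fraction_quadratic()]). Under slow exchange each pocket
#' residue contributes two peaks with intensities `(1 - f, f)`, and peaks
#' below the detection floor are dropped (intermediate-exchange
#' broadening modeled as intensity loss only); under fast exchange a
#' single peak sits at the population-weighted position. Gaussian
#' position noise is added at every non-zero ratio; the reference point
#' (ratio 0) is the exact assigned free state. Fully reproducible from
#' the seed.
#'
#' The defaults mirror a strongly bound slow-exchange protein-RNA
#' titration: 110 residues, 19 clustered pocket residues, 80 uM protein,
#' ratios 0 to 1.3, Kd 10 nM.
#'
#' @param n_residues Number of residues (numbered 1..n).
#' @param pocket_residues Residues perturbed on binding.
#' @param delta_bound Data frame `residue_number`, `delta_h`, `delta_n`
#'   of bound-state offsets (ppm); `NULL` draws offsets with
#'   |dH| ~ U(0.35, 0.65), |dN| ~ U(2.0, 3.5) and random signs.
#' @param kd Dissociation constant (nM).
#' @param protein_total Protein concentration (uM).
#' @param ratios Ligand:protein molar ratios (must start at 0).
#' @param exchange `"slow"` or `"fast"`.
#' @param noise_sigma Length-2 numeric `(ppm_H, ppm_N)` peak-position noise.
#' @param detection_floor Peaks with intensity below this fraction are
#'   dropped (must be < 1).
#' @param seed Integer seed.
#' @return A list: `series` (a [titration_series()]) and `ground_truth`
#'   (pocket residues, kd in nM, stoichiometry, per-residue true CSPs,
#'   and the free/bound [shift_table()]s).
#' @export
simulate_titration <- function(n_residues = 110,
                               pocket_residues = c(21, 22, 24, 25, 26, 27,
                                                   29, 30, 31, 32, 50, 61,
                                                   62, 63, 65, 66, 94, 95,
                                                   97),
                               delta_bound = NULL,
                               kd = 10,
                               protein_total = 80,
                               ratios = c(0, 0.3, 0.5, 0.7, 1, 1.3),
                               exchange = c("slow", "fast"),
                               noise_sigma = c(0.005, 0.03),
                               detection_floor = 0.25,
                               seed = 20171120) {
  exchange <- match.arg(exchange)
  if (!all(pocket_residues %in% seq_len(n_residues))) {
    rlang::abort("pocket_residues must lie within 1..n_residues")
  }
  if (ratios[1] != 0) rlang::abort("ratios must start at 0")
  if (detection_floor >= 1) rlang::abort("detection_floor must be < 1")

  withr::with_seed(seed, {
    types <- sample(setdiff(AA1, "P"), n_residues, replace = TRUE)
    h_free <- truncnorm_window(n_residues, 8.3, 0.6, PPM_WINDOWS$H)
    n_free <- truncnorm_window(n_residues, 119, 4, PPM_WINDOWS$N)

    if (is.null(delta_bound)) {
      np <- length(pocket_residues)
      delta_bound <- tibble::tibble(
        residue_number = as.integer(pocket_residues),
        delta_h = sample(c(-1, 1), np, TRUE) * stats::runif(np, 0.35, 0.65),
        delta_n = sample(c(-1, 1), np, TRUE) * stats::runif(np, 2.0, 3.5)
      )
    }
    small <- weighted_csp(delta_bound$delta_h, delta_bound$delta_n) <
      3 * weighted_csp(noise_sigma[1], noise_sigma[2])
    if (any(small)) {
      warning("pocket offset(s) below 3x the position noise; those ",
              "residues are unrecoverable by design: ",
              paste(delta_bound$residue_number[small], collapse = ", "),
              call. = FALSE)
    }

    dh <- dn <- rep(0, n_residues)
    idx <- delta_bound$residue_number
    dh[idx] <- delta_bound$delta_h
    dn[idx] <- delta_bound$delta_n
    h_bound <- h_free + dh
    n_bound <- n_free + dn

    kd_um <- kd / 1000
    point_list <- purrr::map(ratios, function(r) {
      if (r == 0) {
        return(tibble::tibble(molar_ratio = 0, h_ppm = h_free,
                              n_ppm = n_free, intensity = 1,
                              true_residue = seq_len(n_residues),
                              true_state = "free"))
      }
      l_total <- r * protein_total
      f <- bound_fraction_quadratic(protein_total, l_total, kd_um) *
        l_total / protein_total
      f <- min(f, 1)
      is_pocket <- seq_len(n_residues) %in% pocket_residues
      if (exchange == "slow") {
        free_pk <- tibble::tibble(
          molar_ratio = r, h_ppm = h_free, n_ppm = n_free,
          intensity = ifelse(is_pocket, 1 - f, 1),
          true_residue = seq_len(n_residues), true_state = "free"
        )
        bound_pk <- tibble::tibble(
          molar_ratio = r, h_ppm = h_bound[is_pocket],
          n_ppm = n_bound[is_pocket], intensity = f,
          true_residue = which(is_pocket), true_state = "bound"
        )
        pk <- dplyr::bind_rows(free_pk, bound_pk)
        pk <- pk[pk$intensity >= detection_floor, ]
      } else {
        pk <- tibble::tibble(
          molar_ratio = r,
          h_ppm = h_free + f * dh,
          n_ppm = n_free + f * dn,
          intensity = 1,
          true_residue = seq_len(n_residues), true_state = "averaged"
        )
      }
      pk$h_ppm <- pk$h_ppm + stats::rnorm(nrow(pk), 0, noise_sigma[1])
      pk$n_ppm <- pk$n_ppm + stats::rnorm(nrow(pk), 0, noise_sigma[2])
      pk
    })
    peaks <- dplyr::bind_rows(point_list)

    free_tbl <- shift_table(
      tibble::tibble(
        residue_number = rep(seq_len(n_residues), each = 2),
        residue_type = rep(types, each = 2),
        atom_name = rep(c("H", "N"), n_residues),
        shift_ppm = as.numeric(rbind(h_free, n_free))
      ),
      state_label = "free", molar_ratio = 0
    )
    bound_tbl <- shift_table(
      tibble::tibble(
        residue_number = rep(seq_len(n_residues), each = 2),
        residue_type = rep(types, each = 2),
        atom_name = rep(c("H", "N"), n_residues),
        shift_ppm = as.numeric(rbind(h_bound, n_bound))
      ),
      state_label = "bound", molar_ratio = max(ratios)
    )

    series <- titration_series(
      peaks[c("molar_ratio", "h_ppm", "n_ppm", "intensity")],
      reference = free_tbl, protein_total = protein_total
    )
    ground_truth <- list(
      pocket_residues = sort(as.integer(pocket_residues)),
      kd = kd,
      stoichiometry = 1,
      true_csp = tibble::tibble(
        residue_number = seq_len(n_residues),
        delta_h = dh, delta_n = dn,
        delta_weighted = weighted_csp(dh, dn)
      ),
      free_shifts = free_tbl,
      bound_shifts = bound_tbl,
      peak_origin = peaks,
      exchange = exchange
    )
    list(series = series, ground_truth = ground_truth)
  })
}

truncnorm_window <- function(n, mean, sd, window) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < window[1] | x > window[2])) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

#' Simulate a saturation binding curve
#'
#' Forward model of [fit_saturation()] plus multiplicative Gaussian
#' noise, seeded.
#'
#' @param kd Dissociation constant (nM).
#' @param probe_total Probe concentration (nM).
#' @param conc Titrant totals (nM); default a log grid 0.2-200 nM plus 0.
#' @param f_min,f_max Signal end points.
#' @param noise_frac Multiplicative noise fraction (of the local signal).
#' @param seed Integer seed.
#' @return A list: `curve` (tibble `conc`, `signal`) and `ground_truth`.
#' @export
simulate_saturation_curve <- function(kd = 2.07, probe_total = 2,
                                      conc = NULL, f_min = 0, f_max = 1,
                                      noise_frac = 0.01, seed = 20171120) {
  conc <- conc %||% c(0, 10^seq(log10(0.2), log10(200), length.out = 11))
  y0 <- saturation_signal(conc, probe_total, kd, f_min, f_max)
  y <- withr::with_seed(seed, {
    y0 * (1 + noise_frac * stats::rnorm(length(y0)))
  })
  list(
    curve = tibble::tibble(conc = conc, signal = y),
    ground_truth = list(kd = kd, probe_total = probe_total, f_min = f_min,
                        f_max = f_max, noise_frac = noise_frac)
  )
}

#' Random proper rotation matrix
#'
#' @param seed Optional integer seed.
#' @return A 3x3 orthonormal matrix with determinant +1.
#' @export
random_rotation <- function(seed = NULL) {
  gen <- function() {
    qr_dec <- qr(matrix(stats::rnorm(9), 3, 3))
    q <- qr.Q(qr_dec)
    # fix signs so Q is a uniform rotation, then enforce det +1
    q <- q %*% diag(sign(diag(qr.R(qr_dec))))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Simulate a pair of structures related by a rigid transform
#'
#' Random compact C-alpha coordinates; the second structure is the first
#' rotated and translated, plus optional per-coordinate Gaussian noise.
#' The planted transform is recorded in the ground truth.
#'
#' @param n_atoms Number of residues (>= 3).
#' @param rotation 3x3 rotation; `NULL` draws a random one.
#' @param translation Length-3 vector (Angstrom); `NULL` draws one.
#' @param noise_sigma Per-coordinate Gaussian noise SD (Angstrom).
#' @param seed Integer seed.
#' @return A list: `a`, `b` (`structure_ca` tibbles) and `ground_truth`.
#' @export
simulate_structure_pair <- function(n_atoms = 75, rotation = NULL,
                                    translation = NULL, noise_sigma = 0,
                                    seed = 20171120) {
  if (n_atoms < 3) rlang::abort("n_atoms must be >= 3")
  withr::with_seed(seed, {
    xyz <- matrix(stats::rnorm(n_atoms * 3, sd = 10), ncol = 3)
    rot <- rotation %||% random_rotation()
    trans <- translation %||% stats::rnorm(3, sd = 20)
    xyz_b <- sweep(xyz %*% t(rot), 2, trans, "+") +
      matrix(stats::rnorm(n_atoms * 3, sd = noise_sigma), ncol = 3)
    types <- sample(AA1, n_atoms, replace = TRUE)
    mk <- function(m, label) {
      out <- tibble::tibble(residue_number = seq_len(n_atoms),
                            residue_type = types,
                            x = m[, 1], y = m[, 2], z = m[, 3])
      attr(out, "label") <- label
      class(out) <- c("structure_ca", class(out))
      out
    }
    list(a = mk(xyz, "sim_a"), b = mk(xyz_b, "sim_b"),
         ground_truth = list(rotation = rot, translation = trans,
                             noise_sigma = noise_sigma))
  })
}

#' Homolog fixture: synthetic sequence pair, pocket lists and SSE ranges
#'
#' Ships the printed artifacts of the MSI2-RRM1 / MSI1-RBD1 comparison as
#' machine-readable fixtures: the 19- and 17-residue MSI2 significant-CSP
#' lists, the 17-residue MSI1 pronounced-CSP list, the seven severely
#' perturbed residues on each side, the shift-by-one residue
#' correspondence (MSI2 residue k maps to MSI1 residue k - 1), and the
#' MSI2 secondary-structure ranges (five beta strands, two helices,
#' structured core 23-100). The two sequences are SYNTHETIC stand-ins
#' constrained to the published residue identities at every listed
#' position and to ~80% pairwise identity; real MSI1/MSI2 sequences are a
#' user-supplied input, not bundled.
#'
#' @return A list: `msi2`, `msi1` ([sequence_record()]s, synthetic),
#'   `significant` (list of integer vectors: `msi2_19`, `msi2_17`,
#'   `msi1_17`, `msi2_severe7`, `msi1_severe7`), `residue_map` (tibble
#'   `res_a` = MSI2, `res_b` = MSI1), `sse` (tibble `element`, `start`,
#'   `end`) and `core_range`.
#' @export
make_fixture_protein <- function() {
  msi2_19 <- c(21L, 22L, 24L, 25L, 26L, 27L, 29L, 30L, 31L, 32L, 50L,
               61L, 62L, 63L, 65L, 66L, 94L, 95L, 97L)
  msi2_17 <- setdiff(msi2_19, c(21L, 22L))
  msi1_17 <- c(23L, 24L, 25L, 26L, 28L, 29L, 30L, 31L, 52L, 60L, 61L,
               62L, 64L, 65L, 93L, 94L, 96L)
  msi2_severe7 <- c(25L, 27L, 30L, 61L, 62L, 65L, 97L)
  msi1_severe7 <- c(24L, 26L, 29L, 60L, 61L, 64L, 96L)

  # Synthetic MSI2-like sequence over residues 21..111 with the published
  # identities planted at every listed position.
  pos2 <- 21:111
  filler <- rep(c("A", "D", "E", "L", "N", "T", "V", "S", "R", "K", "I",
                  "Q"), length.out = length(pos2))
  seq2 <- stats::setNames(filler, pos2)
  known2 <- c(`21` = "G", `22` = "K", `24` = "F", `25` = "I", `26` = "G",
              `27` = "G", `29` = "S", `30` = "W", `31` = "Q", `32` = "T",
              `50` = "C", `61` = "S", `62` = "R", `63` = "G", `64` = "F",
              `65` = "G", `66` = "F", `94` = "K", `95` = "V", `97` = "F",
              `111` = "K")
  seq2[names(known2)] <- known2

  # MSI1-like sequence over 20..103: shift-by-one copy of MSI2 residues
  # 21..104, with planted M52 and deterministic substitutions at filler
  # positions to bring identity to ~80%.
  pos1 <- 20:103
  seq1 <- stats::setNames(unname(seq2[as.character(pos1 + 1L)]), pos1)
  seq1["52"] <- "M"
  listed1 <- union(msi1_17, msi1_severe7)
  listed2_shifted <- (union(msi2_19, c(64L)) - 1L)
  protected <- union(listed1, listed2_shifted)
  eligible <- setdiff(pos1, c(protected, 52L))
  swap <- c(A = "G", D = "N", E = "Q", L = "M", N = "H", T = "S",
            V = "I", S = "T", R = "K", K = "R", I = "V", Q = "E")
  subs <- utils::head(eligible[seq(1, length(eligible), by = 4)], 16)
  seq1[as.character(subs)] <- unname(swap[seq1[as.character(subs)]])

  list(
    msi2 = sequence_record("MSI2-RRM1_synthetic",
                           paste(seq2, collapse = ""), 21L),
    msi1 = sequence_record("MSI1-RBD1_synthetic",
                           paste(seq1, collapse = ""), 20L),
    significant = list(
      msi2_19 = msi2_19, msi2_17 = msi2_17, msi1_17 = msi1_17,
      msi2_severe7 = msi2_severe7, msi1_severe7 = msi1_severe7
    ),
    residue_map = tibble::tibble(res_a = 21:104, res_b = 20:103),
    sse = tibble::tibble(
      element = c("b1", "a1", "b2", "b3", "a2", "b4", "b5"),
      start = c(24L, 34L, 47L, 64L, 73L, 84L, 89L),
      end = c(26L, 43L, 52L, 69L, 81L, 86L, 96L)
    ),
    core_range = c(23L, 100L)
  )
}

#' Write a simulated titration to disk in standard formats
#'
#' One Sparky `.list` per titration point plus the free-state reference
#' as a TSV shift table, so the pipeline can be exercised end-to-end
#' through files.
#'
#' @param series A [titration_series()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named list of the written paths.
#' @export
write_titration_files <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref_path <- file.path(dir, "reference_shifts.tsv")
  readr::write_tsv(tibble::as_tibble(series$reference), ref_path,
                   progress = FALSE)
  peak_paths <- purrr::map_chr(series$ratios, function(r) {
    pk <- series$peaks[series$peaks$molar_ratio == r, ]
    pl <- tibble::tibble(h_ppm = pk$h_ppm, n_ppm = pk$n_ppm,
                         intensity = pk$intensity,
                         residue_number = NA_integer_,
                         assignment = "?")
    path <- file.path(dir, sprintf("titration_ratio_%s.list",
                                   gsub("\\.", "p", format(r))))
    write_sparky_list(pl, path)
    path
  })
  invisible(list(reference = ref_path, peaks = peak_paths))
}
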