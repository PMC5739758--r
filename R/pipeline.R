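# Orchestration: configuration, the CSP stage, the structure-mapping
# stage and the binding-fit stage, each a single call over the module
# functions, with optional on-disk reports.

#' Build a run configuration
#'
#' All analysis parameters with their documented defaults. A
#' configuration round-trips losslessly through YAML
#' ([write_run_config()] / [read_run_config()]).
#'
#' @param n_weight 15N scaling in the weighted CSP (default 5).
#' @param k Threshold multiplier on the SD (default 1).
#' @param tol_h,tol_n Peak-tracking tolerances (ppm).
#' @param saturation_tol Plateau tolerance on mean-CSP increments (ppm).
#' @param include_relocated Include relocated residues in threshold
#'   statistics (see [compute_threshold()]).
#' @param matrix,gap_open,gap_extend Alignment parameters.
#' @param core_range Structured core used for superposition pairing and
#'   SSE annotation.
#' @param seed Global seed for stochastic steps (bootstrap, simulation).
#' @param n_boot Bootstrap replicates for binding fits.
#' @param out_dir Output directory for reports, or `NULL`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(n_weight = 5, k = 1, tol_h = 0.05, tol_n = 0.5,
                       saturation_tol = 0.005, include_relocated = TRUE,
                       matrix = "BLOSUM62", gap_open = 10, gap_extend = 0.5,
                       core_range = c(23, 100), seed = 20171120,
                       n_boot = 500, out_dir = NULL) {
  structure(
    list(n_weight = n_weight, k = k, tol_h = tol_h, tol_n = tol_n,
         saturation_tol = saturation_tol,
         include_relocated = include_relocated, matrix = matrix,
         gap_open = gap_open, gap_extend = gap_extend,
         core_range = core_range, seed = seed, n_boot = n_boot,
         out_dir = out_dir),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @param config A `run_config` list.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

stage_log <- function(stage, n_in, n_out) {
  message(sprintf("[%s] in: %d, out: %d", stage, n_in, n_out))
}

#' Run the CSP stage of the pipeline
#'
#' Chains peak tracking, bound-endpoint assembly, the weighted CSP
#' profile, the significance threshold, significant-residue selection,
#' exchange classification and stoichiometry assessment. The bound-state
#' shift table for the profile is assembled from the final titration
#' point's tracked positions, completed by the optional `bound_reference`
#' assignments for residues that could not be tracked there (those are
#' flagged `relocated`).
#'
#' @param series A [titration_series()].
#' @param config A [run_config()].
#' @param bound_reference Optional bound-state [shift_table()].
#' @return A list of class `csp_run`: `profile`, `threshold`,
#'   `significant`, `exchange`, `saturation`, `tracking`. Reports are
#'   written under `config$out_dir` when set.
#' @export
run_csp <- function(series, config = run_config(), bound_reference = NULL) {
  if (!inherits(series, "titration_series")) {
    rlang::abort("series must be a titration_series (field: series)")
  }
  if (is.null(series$reference)) {
    rlang::abort("missing reference assignments (field: reference)")
  }
  tracking <- track_peaks(series, tol_h = config$tol_h, tol_n = config$tol_n,
                          n_weight = config$n_weight)
  stage_log("track_peaks", nrow(series$peaks), nrow(tracking))

  final <- max(series$ratios)
  fin <- tracking[tracking$molar_ratio == final & tracking$matched, ]
  relocated <- integer()
  if (!is.null(bound_reference)) {
    # bound-state assignments are authoritative: where they disagree with
    # the tracked endpoint beyond 3x the scaled tolerance the tracker
    # followed the wrong peak, so the assignment replaces it
    bp <- reference_positions(bound_reference)
    tol_d <- scaled_hn_distance(config$tol_h, config$tol_n, config$n_weight)
    j <- match(fin$residue_number, bp$residue_number)
    d <- scaled_hn_distance(fin$h_ppm - bp$h_ppm[j], fin$n_ppm - bp$n_ppm[j],
                            config$n_weight)
    wrong <- !is.na(j) & d > 3 * tol_d
    fin$h_ppm[wrong] <- bp$h_ppm[j[wrong]]
    fin$n_ppm[wrong] <- bp$n_ppm[j[wrong]]
    relocated <- fin$residue_number[wrong]
  }
  rows <- tibble::tibble(
    residue_number = rep(fin$residue_number, each = 2),
    residue_type = "X",
    atom_name = rep(c("H", "N"), nrow(fin)),
    shift_ppm = as.numeric(rbind(fin$h_ppm, fin$n_ppm))
  )
  if (!is.null(bound_reference)) {
    extra <- bound_reference[!bound_reference$residue_number %in%
                               fin$residue_number, ]
    relocated <- sort(union(relocated, unique(extra$residue_number)))
    rows <- dplyr::bind_rows(rows, tibble::as_tibble(extra)[names(rows)])
  }
  types <- stats::setNames(series$reference$residue_type,
                           series$reference$residue_number)
  rows$residue_type <- unname(types[as.character(rows$residue_number)])
  rows$residue_type[is.na(rows$residue_type)] <- "X"
  bound_tbl <- shift_table(rows, state_label = "bound", molar_ratio = final)
  stage_log("bound_endpoints", nrow(fin) + length(relocated), nrow(bound_tbl))

  profile <- compute_csp(series$reference, bound_tbl,
                         n_weight = config$n_weight,
                         relocated_residues = relocated)
  stage_log("compute_csp", nrow(bound_tbl), nrow(profile))
  threshold <- compute_threshold(profile, k = config$k,
                                 include_relocated = config$include_relocated)
  significant <- select_significant(profile, threshold)
  stage_log("select_significant", nrow(profile), nrow(significant))
  profile$significant <- profile$residue_number %in%
    significant$residue_number

  exchange <- classify_exchange(tracking, bound_reference = bound_reference)
  stage_log("classify_exchange", nrow(tracking), nrow(exchange))
  per_ratio <- csp_by_ratio(series, tracking,
                            bound_reference = bound_reference)
  saturation <- assess_saturation(per_ratio,
                                  tolerance = config$saturation_tol)
  stage_log("assess_saturation", nrow(per_ratio), 1L)

  out <- structure(
    list(profile = profile, threshold = threshold,
         significant = significant, exchange = exchange,
         saturation = saturation, tracking = tracking, config = config),
    class = "csp_run"
  )
  if (!is.null(config$out_dir)) write_csp_run(out, config$out_dir)
  out
}

write_csp_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_report(run$profile, file.path(dir, "csp_profile.tsv"), "tsv")
  write_report(
    list(threshold = run$threshold[c("mean", "sd", "k", "cutoff", "n_used")],
         significant = run$significant$residue_number,
         disappeared = attr(run$significant, "disappeared"),
         stoichiometry = run$saturation$stoichiometry,
         plateau_reached = run$saturation$plateau_reached),
    file.path(dir, "csp_summary.json"), "json"
  )
  readr::write_tsv(tibble::as_tibble(run$exchange),
                   file.path(dir, "exchange_calls.tsv"), progress = FALSE)
  invisible(dir)
}

#' @export
print.csp_run <- function(x, ...) {
  cat("<csp_run>\n")
  print(x$threshold)
  cat("  significant residues (", nrow(x$significant), "): ",
      paste(x$significant$residue_number, collapse = ", "), "\n", sep = "")
  print(x$saturation)
  invisible(x)
}

#' Run the structure-mapping stage
#'
#' Chains global alignment, residue mapping, pocket comparison and
#' (when both structures are provided) Kabsch superposition over the
#' mapped residues inside the structured core. Superposition is skipped
#' gracefully when structures are absent.
#'
#' @param seq_a,seq_b [sequence_record()]s for the two homologs.
#' @param sig_a,sig_b Significant residue sets on each numbering scale.
#' @param struct_a,struct_b Optional `structure_ca` tibbles.
#' @param config A [run_config()].
#' @return A list of class `map_run`: `alignment`, `residue_map`,
#'   `pockets`, `superposition` (`NULL` when skipped).
#' @export
run_map <- function(seq_a, seq_b, sig_a, sig_b, struct_a = NULL,
                    struct_b = NULL, config = run_config()) {
  alignment <- global_align(seq_a, seq_b, matrix = config$matrix,
                            gap_open = config$gap_open,
                            gap_extend = config$gap_extend)
  rmap <- map_equivalent_residues(alignment)
  stage_log("global_align", nrow(alignment$columns), nrow(rmap))
  pockets <- compare_pockets(sig_a, sig_b, rmap)
  stage_log("compare_pockets", length(sig_a) + length(sig_b),
            nrow(pockets$conserved_pairs))
  superposition <- NULL
  if (!is.null(struct_a) && !is.null(struct_b)) {
    core <- rmap[rmap$res_a >= config$core_range[1] &
                   rmap$res_a <= config$core_range[2] &
                   rmap$res_a %in% struct_a$residue_number &
                   rmap$res_b %in% struct_b$residue_number, ]
    superposition <- superpose_kabsch(struct_a, struct_b, core)
    stage_log("superpose_kabsch", nrow(core), superposition$n_atoms)
  } else {
    message("[superpose_kabsch] skipped: structures absent")
  }
  out <- structure(
    list(alignment = alignment, residue_map = rmap, pockets = pockets,
         superposition = superposition, config = config),
    class = "map_run"
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(
      list(identity_fraction = alignment$identity_fraction,
           score = alignment$score,
           conserved_pairs = pockets$conserved_pairs,
           jaccard_mapped = pockets$jaccard_mapped,
           rmsd = if (is.null(superposition)) NULL else superposition$rmsd,
           superposition_skipped = is.null(superposition)),
      file.path(config$out_dir, "map_summary.json"), "json"
    )
  }
  out
}

#' @export
print.map_run <- function(x, ...) {
  cat("<map_run>\n")
  print(x$alignment)
  print(x$pockets)
  if (!is.null(x$superposition)) print(x$superposition)
  else cat("  superposition: skipped\n")
  invisible(x)
}

#' Run the binding-fit stage
#'
#' @param curve Data frame `conc`, `signal`.
#' @param type `"saturation"` or `"competition"`.
#' @param probe_total Probe concentration (nM).
#' @param probe_kd,protein_total Competition-assay parameters
#'   (required for `type = "competition"`).
#' @param config A [run_config()].
#' @return A [fit_saturation()] or [fit_competition()] object; a JSON
#'   report is written under `config$out_dir` when set.
#' @export
run_fit <- function(curve, type = c("saturation", "competition"),
                    probe_total, probe_kd = NULL, protein_total = NULL,
                    config = run_config()) {
  type <- match.arg(type)
  fit <- if (type == "saturation") {
    fit_saturation(curve, probe_total = probe_total, n_boot = config$n_boot,
                   seed = config$seed)
  } else {
    if (is.null(probe_kd) || is.null(protein_total)) {
      rlang::abort("competition fits need probe_kd and protein_total")
    }
    fit_competition(curve, probe_kd = probe_kd, probe_total = probe_total,
                    protein_total = protein_total)
  }
  stage_log("run_fit", nrow(curve), 1L)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(as.list(glance(fit)),
                 file.path(config$out_dir, paste0(type, "_fit.json")),
                 "json")
  }
  fit
}
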