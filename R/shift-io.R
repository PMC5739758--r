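# Readers/writers for the formats the pipeline touches: assigned shift tables
# (TSV and a read-only NMR-STAR 3.1 Atom_chem_shift subset), Sparky peak
# lists, PDB C-alpha coordinates, FASTA sequences, and TSV/JSON reports.

#' Construct a validated shift table
#'
#' A shift table holds the assigned backbone resonances of one sample state
#' (e.g. the free protein, or the ligand-bound endpoint): one row per
#' (residue, atom) with its chemical shift in ppm.
#'
#' Validation enforces the atom-class ppm windows (H in \[-2, 14\], N in
#' \[90, 140\], CA/CB/C in \[0, 200\]) as hard errors — out-of-window values
#' are never silently kept — and drops atoms that cannot exist for the
#' residue type (glycine CB, proline amide H) with a warning. Duplicate
#' (residue, atom) rows are an integrity error.
#'
#' @param df Data frame with columns `residue_number` (integer),
#'   `residue_type` (1-letter amino-acid code), `atom_name`
#'   (one of H, N, CA, CB, C) and `shift_ppm` (numeric, ppm).
#' @param state_label Label for the sample state, e.g. `"free"` or `"bound"`.
#' @param molar_ratio Ligand:protein molar ratio of the state (0 for free).
#' @return A tibble of class `shift_table`, sorted by residue then atom,
#'   with attributes `state_label` and `molar_ratio`.
#' @export
shift_table <- function(df, state_label = "free", molar_ratio = 0) {
  required <- c("residue_number", "residue_type", "atom_name", "shift_ppm")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    rlang::abort(paste0(
      "shift table is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  tbl <- tibble::as_tibble(df[required])
  tbl$residue_number <- as.integer(tbl$residue_number)
  tbl$residue_type <- toupper(as.character(tbl$residue_type))
  tbl$atom_name <- toupper(as.character(tbl$atom_name))
  tbl$shift_ppm <- as.numeric(tbl$shift_ppm)

  unknown <- !tbl$atom_name %in% BACKBONE_ATOMS
  if (any(unknown)) {
    message(sum(unknown), " row(s) with atoms outside {",
            paste(BACKBONE_ATOMS, collapse = ", "), "} ignored")
    tbl <- tbl[!unknown, ]
  }

  bad_window <- !ppm_in_window(tbl$atom_name, tbl$shift_ppm)
  if (any(bad_window)) {
    rlang::abort(paste0(
      "shift(s) outside the atom-class ppm window: ",
      paste(sprintf("%s%d %s=%.3f", tbl$residue_type[bad_window],
                    tbl$residue_number[bad_window], tbl$atom_name[bad_window],
                    tbl$shift_ppm[bad_window]),
            collapse = "; ")
    ))
  }

  valid <- aa_valid_atoms(tbl$residue_type)
  impossible <- !mapply(function(a, ok) a %in% ok, tbl$atom_name, valid)
  if (any(impossible)) {
    warning(sum(impossible), " record(s) with atoms invalid for their ",
            "residue type dropped (e.g. Gly CB, Pro H)", call. = FALSE)
    tbl <- tbl[!impossible, ]
  }

  key <- paste(tbl$residue_number, tbl$atom_name)
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    rlang::abort(paste0("duplicate (residue, atom) record(s): ",
                        paste(dup, collapse = "; ")))
  }

  tbl <- dplyr::arrange(tbl, .data$residue_number, .data$atom_name)
  attr(tbl, "state_label") <- state_label
  attr(tbl, "molar_ratio") <- as.numeric(molar_ratio)
  class(tbl) <- c("shift_table", class(tbl))
  tbl
}

#' Read an assigned chemical-shift table
#'
#' Supports two dialects: a simple TSV with columns
#' `residue_number`, `residue_type`, `atom_name`, `shift_ppm`, and a
#' read-only subset of NMR-STAR 3.1 (the `Atom_chem_shift` loop, as found
#' in BMRB deposits). Only backbone atoms H, N, CA, CB, C are kept; other
#' rows are ignored with a logged count.
#'
#' @param path File path.
#' @param dialect `"tsv"` or `"nmrstar"`.
#' @inheritParams shift_table
#' @return A [shift_table()].
#' @export
read_shift_table <- function(path, dialect = c("tsv", "nmrstar"),
                             state_label = "free", molar_ratio = 0) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  df <- switch(dialect,
    tsv = readr::read_tsv(path, show_col_types = FALSE, progress = FALSE),
    nmrstar = parse_nmrstar_shifts(path)
  )
  shift_table(df, state_label = state_label, molar_ratio = molar_ratio)
}

# Minimal NMR-STAR 3.1 reader: locates the loop carrying _Atom_chem_shift.*
# tags and extracts sequence id, residue type, atom id and shift value.
parse_nmrstar_shifts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  loop_starts <- which(trimws(lines) == "loop_")
  if (!length(loop_starts)) {
    rlang::abort(paste0("no loop_ found in NMR-STAR file: ", path))
  }
  for (start in loop_starts) {
    i <- start + 1L
    tags <- character()
    while (i <= length(lines) && startsWith(trimws(lines[i]), "_")) {
      tags <- c(tags, trimws(lines[i]))
      i <- i + 1L
    }
    if (!any(grepl("^_Atom_chem_shift\\.", tags))) next
    col <- function(name) {
      j <- match(paste0("_Atom_chem_shift.", name), tags)
      if (is.na(j)) {
        rlang::abort(paste0("Atom_chem_shift loop lacks tag ", name,
                            " (line ", start, ")"))
      }
      j
    }
    idx <- c(seq = col("Seq_ID"), comp = col("Comp_ID"),
             atom = col("Atom_ID"), val = col("Val"))
    rows <- list()
    while (i <= length(lines)) {
      ln <- trimws(lines[i])
      if (ln %in% c("stop_", "")) {
        if (ln == "stop_") break
        i <- i + 1L
        next
      }
      fields <- strsplit(ln, "\\s+")[[1]]
      if (length(fields) < length(tags)) {
        rlang::abort(paste0("malformed Atom_chem_shift row at line ", i,
                            ": expected ", length(tags), " fields, got ",
                            length(fields)))
      }
      val <- suppressWarnings(as.numeric(fields[idx[["val"]]]))
      if (is.na(val)) {
        rlang::abort(paste0("non-numeric shift value at line ", i))
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        residue_number = as.integer(fields[idx[["seq"]]]),
        residue_type = AA3_TO_1[toupper(fields[idx[["comp"]]])] %||% "X",
        atom_name = toupper(fields[idx[["atom"]]]),
        shift_ppm = val
      )
      i <- i + 1L
    }
    out <- dplyr::bind_rows(rows)
    out$residue_type[is.na(out$residue_type)] <- "X"
    return(out)
  }
  rlang::abort(paste0("no Atom_chem_shift loop found in: ", path))
}

#' Read a Sparky peak list
#'
#' Parses the Sparky `.list` dialect: one header line, then whitespace-
#' separated rows `assignment w1 w2 [height]`. Assignment strings such as
#' `"G21N-H"` are parsed to residue number 21; `"?"` (or `"?-?"`) yields an
#' unassigned peak. A missing height column defaults to intensity 1.
#'
#' @param path File path.
#' @param axis_order Which axis is w1: `"n_h"` (w1 = 15N, w2 = 1H, the
#'   default) or `"h_n"`.
#' @return A tibble of class `peak_list` with columns `h_ppm`, `n_ppm`,
#'   `intensity`, `residue_number` (NA for unassigned) and `assignment`.
#' @export
read_sparky_list <- function(path, axis_order = c("n_h", "h_n")) {
  axis_order <- match.arg(axis_order)
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) <= 1L) {
    return(empty_peak_list())
  }
  body <- lines[-1L]
  rows <- purrr::imap(body, function(ln, k) {
    fields <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(fields) < 3L) {
      rlang::abort(paste0("too few fields in peak list row ", k + 1L))
    }
    w1 <- suppressWarnings(as.numeric(fields[2]))
    w2 <- suppressWarnings(as.numeric(fields[3]))
    if (is.na(w1) || is.na(w2)) {
      rlang::abort(paste0("non-numeric ppm field at line ", k + 1L,
                          " of ", path))
    }
    height <- if (length(fields) >= 4L) {
      h <- suppressWarnings(as.numeric(fields[4]))
      if (is.na(h)) rlang::abort(paste0("non-numeric height at line ", k + 1L))
      h
    } else {
      1.0
    }
    res <- parse_sparky_assignment(fields[1])
    tibble::tibble(assignment = fields[1], w1 = w1, w2 = w2,
                   intensity = height, residue_number = res)
  })
  df <- dplyr::bind_rows(rows)
  if (axis_order == "n_h") {
    out <- tibble::tibble(h_ppm = df$w2, n_ppm = df$w1,
                          intensity = df$intensity,
                          residue_number = df$residue_number,
                          assignment = df$assignment)
  } else {
    out <- tibble::tibble(h_ppm = df$w1, n_ppm = df$w2,
                          intensity = df$intensity,
                          residue_number = df$residue_number,
                          assignment = df$assignment)
  }
  bad <- !ppm_in_window(rep("H", nrow(out)), out$h_ppm) |
    !ppm_in_window(rep("N", nrow(out)), out$n_ppm)
  if (any(bad)) {
    rlang::abort(paste0(sum(bad), " peak(s) with ppm outside the 1H/15N ",
                        "windows; check axis_order"))
  }
  class(out) <- c("peak_list", class(out))
  out
}

empty_peak_list <- function() {
  out <- tibble::tibble(h_ppm = numeric(), n_ppm = numeric(),
                        intensity = numeric(), residue_number = integer(),
                        assignment = character())
  class(out) <- c("peak_list", class(out))
  out
}

parse_sparky_assignment <- function(s) {
  m <- regmatches(s, regexpr("[A-Za-z](-?[0-9]+)", s))
  if (!length(m) || startsWith(s, "?")) return(NA_integer_)
  as.integer(sub("^[A-Za-z]", "", m))
}

#' Write peaks as a Sparky list
#'
#' @param peaks A `peak_list` tibble (see [read_sparky_list()]).
#' @param path Output path.
#' @param axis_order Axis convention to write, matching [read_sparky_list()].
#' @return Invisibly, `path`.
#' @export
write_sparky_list <- function(peaks, path, axis_order = c("n_h", "h_n")) {
  axis_order <- match.arg(axis_order)
  assignment <- peaks$assignment %||% ifelse(
    is.na(peaks$residue_number), "?",
    sprintf("X%dN-H", peaks$residue_number)
  )
  assignment[is.na(assignment)] <- "?"
  w1 <- if (axis_order == "n_h") peaks$n_ppm else peaks$h_ppm
  w2 <- if (axis_order == "n_h") peaks$h_ppm else peaks$n_ppm
  header <- "      Assignment         w1         w2   Data Height"
  rows <- sprintf("%17s %10.4f %10.4f %14.6g", assignment, w1, w2,
                  peaks$intensity)
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read C-alpha coordinates from a PDB file
#'
#' Extracts one CA atom per residue from the requested chain of a
#' PDB-format file (first MODEL for multi-model NMR entries). Alternate
#' locations are resolved by highest occupancy, then first encountered.
#' Residues without a CA atom are skipped with a warning.
#'
#' @param path PDB file path.
#' @param chain Chain identifier; `NULL` takes the first chain present.
#' @return A tibble of class `structure_ca` with columns `residue_number`,
#'   `residue_type`, `x`, `y`, `z` (Angstrom) and attribute `label`.
#' @export
read_structure_ca <- function(path, chain = NULL) {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  atoms <- pdb$atom
  chains <- unique(atoms$chain)
  if (is.null(chain)) chain <- chains[1]
  if (!chain %in% chains) {
    rlang::abort(paste0("chain '", chain, "' not found in ", path,
                        " (available: ", paste(chains, collapse = ", "), ")"))
  }
  sel <- atoms[atoms$chain == chain & atoms$elety == "CA" &
                 atoms$type == "ATOM", , drop = FALSE]
  all_res <- unique(atoms$resno[atoms$chain == chain & atoms$type == "ATOM"])
  missing_ca <- setdiff(all_res, unique(sel$resno))
  if (length(missing_ca)) {
    warning("residue(s) without a CA atom skipped: ",
            paste(missing_ca, collapse = ", "), call. = FALSE)
  }
  if (!nrow(sel)) rlang::abort(paste0("no CA atoms in chain ", chain))
  sel$o[is.na(sel$o)] <- 1
  # altloc rule: highest occupancy, ties broken by file order
  sel <- sel[order(sel$resno, -sel$o), , drop = FALSE]
  sel <- sel[!duplicated(sel$resno), , drop = FALSE]
  sel <- sel[order(sel$resno), , drop = FALSE]
  if (any(!is.finite(c(sel$x, sel$y, sel$z)))) {
    rlang::abort("non-finite coordinates in PDB file")
  }
  out <- tibble::tibble(
    residue_number = as.integer(sel$resno),
    residue_type = unname(AA3_TO_1[toupper(sel$resid)]),
    x = sel$x, y = sel$y, z = sel$z
  )
  out$residue_type[is.na(out$residue_type)] <- "X"
  attr(out, "label") <- paste0(basename(path), ":", chain)
  class(out) <- c("structure_ca", class(out))
  out
}

#' Write a C-alpha trace as a PDB file
#'
#' @param structure A `structure_ca` tibble.
#' @param path Output path.
#' @param chain Chain identifier to write.
#' @return Invisibly, `path`.
#' @export
write_structure_pdb <- function(structure, path, chain = "A") {
  resid3 <- unname(AA3[structure$residue_type])
  resid3[is.na(resid3)] <- "UNK"
  rows <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(nrow(structure)), resid3, chain, structure$residue_number,
    structure$x, structure$y, structure$z, 1, 0
  )
  writeLines(c(rows, "END"), path)
  invisible(path)
}

#' Create a sequence record
#'
#' @param identifier Sequence name.
#' @param sequence 1-letter amino-acid string (20 canonical letters plus X).
#' @param first_residue_number Residue number of the first letter.
#' @return A one-row tibble of class `sequence_record`.
#' @export
sequence_record <- function(identifier, sequence, first_residue_number = 1L) {
  sequence <- toupper(gsub("\\s", "", sequence))
  letters_used <- unique(strsplit(sequence, "")[[1]])
  bad <- setdiff(letters_used, c(AA1, "X"))
  if (length(bad)) {
    rlang::abort(paste0("sequence contains non-canonical letter(s): ",
                        paste(bad, collapse = ", ")))
  }
  out <- tibble::tibble(identifier = identifier, sequence = sequence,
                        first_residue_number = as.integer(first_residue_number))
  class(out) <- c("sequence_record", class(out))
  out
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @param first_residue_number Residue number of the first letter of each
#'   sequence (recycled across records).
#' @return A tibble of `sequence_record` rows.
#' @export
read_fasta_sequences <- function(path, first_residue_number = 1L) {
  seqs <- Biostrings::readAAStringSet(path)
  first <- rep_len(as.integer(first_residue_number), length(seqs))
  recs <- purrr::map2(seq_along(seqs), first, function(i, f) {
    sequence_record(names(seqs)[i], as.character(seqs[[i]]), f)
  })
  out <- dplyr::bind_rows(recs)
  class(out) <- c("sequence_record", class(out))
  out
}

#' Write sequence records as FASTA
#'
#' @param records A `sequence_record` tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta_sequences <- function(records, path) {
  set <- Biostrings::AAStringSet(records$sequence)
  names(set) <- records$identifier
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Shift residue numbering by a constant offset
#'
#' Converts between numbering scales, e.g. from a construct scale that
#' starts at -3 (expression-tag residues included, numbering passing
#' through 0) to the biological scale on which the first structured
#' residue is 21: an offset of +24 maps -3 to 21. Applying offset `a`
#' then `b` equals applying `a + b`.
#'
#' @param x A `shift_table`, `peak_list` or `sequence_record` object (any
#'   data frame with a `residue_number` or `first_residue_number` column).
#' @param offset Integer added to every residue number.
#' @return The same type of object with numbering shifted.
#' @export
apply_numbering_offset <- function(x, offset) {
  offset <- as.integer(offset)
  if ("residue_number" %in% names(x)) {
    x$residue_number <- x$residue_number + offset
  } else if ("first_residue_number" %in% names(x)) {
    x$first_residue_number <- x$first_residue_number + offset
  } else {
    rlang::abort("no residue numbering column found")
  }
  x
}

#' Write an analysis report to TSV or JSON
#'
#' CSP profiles are written with the fixed column order
#' `residue`, `delta_H`, `delta_N`, `delta_weighted`, `status` (plus
#' `significant` when present); floats are serialized at 6 significant
#' digits. Fit and comparison objects are serialized as JSON via their
#' list representation.
#'
#' @param x A `csp_profile` tibble, a fit object, or any list/tibble.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return Invisibly, `path`.
#' @export
write_report <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- report_frame(x)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) signif(v, 6))
    readr::write_tsv(df, path, progress = FALSE)
  } else {
    obj <- if (is.data.frame(x)) report_frame(x) else unclass_deep(x)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 6,
                         pretty = TRUE, na = "null")
  }
  invisible(path)
}

report_frame <- function(x) {
  if (inherits(x, "csp_profile")) {
    df <- data.frame(
      residue = x$residue_number,
      delta_H = x$delta_h,
      delta_N = x$delta_n,
      delta_weighted = x$delta_weighted,
      status = x$status,
      stringsAsFactors = FALSE
    )
    if ("significant" %in% names(x)) df$significant <- x$significant
    df
  } else {
    as.data.frame(x)
  }
}

unclass_deep <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(x))
  if (is.list(x)) return(lapply(x, unclass_deep))
  x
}

#' Read a CSP profile written by [write_report()]
#'
#' @param path TSV path.
#' @return A `csp_profile` tibble.
#' @export
read_csp_profile <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  out <- tibble::tibble(
    residue_number = as.integer(df$residue),
    delta_h = as.numeric(df$delta_H),
    delta_n = as.numeric(df$delta_N),
    delta_weighted = as.numeric(df$delta_weighted),
    status = as.character(df$status)
  )
  if ("significant" %in% names(df)) out$significant <- df$significant
  class(out) <- c("csp_profile", class(out))
  out
}
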