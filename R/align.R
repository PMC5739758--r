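# Global sequence alignment, residue correspondence and secondary-structure
# annotation for cross-homolog pocket comparison.

#' Global pairwise sequence alignment
#'
#' Needleman-Wunsch with affine gap penalties (a gap of length L costs
#' `gap_open + L * gap_extend`), BLOSUM62 by default. Returns the aligned
#' columns with residue numbers on each sequence's own numbering scale,
#' the alignment score, and the identity fraction computed over columns
#' where both sequences are non-gap.
#'
#' @param a,b [sequence_record()] objects (one row each).
#' @param matrix Substitution matrix name (a matrix shipped with
#'   Biostrings, e.g. `"BLOSUM62"`) or an actual scoring matrix.
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @return A list of class `alignment_result`: `columns` (tibble `aa_a`,
#'   `res_a`, `aa_b`, `res_b`, gaps as NA), `score`, `identity_fraction`,
#'   and `identity_full` (identical columns / all alignment columns).
#' @export
global_align <- function(a, b, matrix = "BLOSUM62", gap_open = 10,
                         gap_extend = 0.5) {
  for (s in list(a, b)) {
    if (!is.data.frame(s) || !nrow(s) || !nzchar(s$sequence[1])) {
      rlang::abort("both sequences must be non-empty sequence_records")
    }
  }
  submat <- if (is.matrix(matrix)) matrix else get_submatrix(matrix)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a$sequence[1]), Biostrings::AAString(b$sequence[1]),
    type = "global", substitutionMatrix = submat,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  al_a <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  al_b <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  res_a <- ifelse(al_a == "-", NA_integer_,
                  a$first_residue_number[1] - 1L + cumsum(al_a != "-"))
  res_b <- ifelse(al_b == "-", NA_integer_,
                  b$first_residue_number[1] - 1L + cumsum(al_b != "-"))
  cols <- tibble::tibble(aa_a = al_a, res_a = as.integer(res_a),
                         aa_b = al_b, res_b = as.integer(res_b))
  both <- cols$aa_a != "-" & cols$aa_b != "-"
  ident <- both & cols$aa_a == cols$aa_b
  structure(
    list(
      columns = cols,
      score = Biostrings::score(pa),
      identity_fraction = if (any(both)) sum(ident) / sum(both) else NA_real_,
      identity_full = sum(ident) / nrow(cols),
      ids = c(a$identifier[1], b$identifier[1])
    ),
    class = "alignment_result"
  )
}

get_submatrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "<alignment_result> %s vs %s: score %.1f, identity %.1f%% (%d columns)\n",
    x$ids[1], x$ids[2], x$score, 100 * x$identity_fraction, nrow(x$columns)))
  invisible(x)
}

#' Map equivalent residues from an alignment
#'
#' @param alignment An [global_align()] result.
#' @return Tibble `res_a`, `res_b` for mutually aligned (non-gap) columns,
#'   strictly increasing in both coordinates.
#' @export
map_equivalent_residues <- function(alignment) {
  cols <- alignment$columns
  keep <- !is.na(cols$res_a) & !is.na(cols$res_b)
  tibble::tibble(res_a = cols$res_a[keep], res_b = cols$res_b[keep])
}

#' Annotate residues with secondary-structure elements
#'
#' Labels each residue with its containing element, `"loop"` when inside
#' the structured core but between elements, and `"disordered"` outside
#' the core (flexible termini).
#'
#' @param residues Integer vector of residue numbers.
#' @param sse_ranges Tibble with columns `element`, `start`, `end`
#'   (inclusive, non-overlapping).
#' @param core_range Length-2 integer range of the structured core.
#' @return Tibble `residue_number`, `sse`.
#' @export
annotate_sse <- function(residues, sse_ranges, core_range = c(23, 100)) {
  o <- order(sse_ranges$start)
  sse_ranges <- sse_ranges[o, ]
  if (nrow(sse_ranges) > 1 &&
        any(sse_ranges$start[-1] <= sse_ranges$end[-nrow(sse_ranges)])) {
    rlang::abort("secondary-structure intervals overlap")
  }
  lab <- vapply(residues, function(r) {
    hit <- which(r >= sse_ranges$start & r <= sse_ranges$end)
    if (length(hit)) {
      sse_ranges$element[hit[1]]
    } else if (r >= core_range[1] && r <= core_range[2]) {
      "loop"
    } else {
      "disordered"
    }
  }, character(1))
  tibble::tibble(residue_number = as.integer(residues), sse = lab)
}
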