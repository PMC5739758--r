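test_that("TSV shift tables read with validation", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "residue_number\tresidue_type\tatom_name\tshift_ppm",
    "21\tG\tH\t8.45",
    "21\tG\tN\t109.2"
  ), path)
  tbl <- read_shift_table(path, dialect = "tsv")
  expect_s3_class(tbl, "shift_table")
  expect_equal(nrow(tbl), 2L)
  expect_equal(tbl$shift_ppm, c(8.45, 109.2))

  # glycine has no CB: dropped with a warning, not an error
  writeLines(c(
    "residue_number\tresidue_type\tatom_name\tshift_ppm",
    "21\tG\tH\t8.45",
    "21\tG\tN\t109.2",
    "21\tG\tCB\t35.0"
  ), path)
  expect_warning(tbl2 <- read_shift_table(path), "invalid for their")
  expect_equal(nrow(tbl2), 2L)

  # duplicate (residue, atom) is an integrity error
  writeLines(c(
    "residue_number\tresidue_type\tatom_name\tshift_ppm",
    "21\tG\tH\t8.45",
    "21\tG\tH\t8.46"
  ), path)
  expect_error(read_shift_table(path), "duplicate")

  # out-of-window ppm values are rejected, never silently kept
  writeLines(c(
    "residue_number\tresidue_type\tatom_name\tshift_ppm",
    "21\tG\tH\t109.2"
  ), path)
  expect_error(read_shift_table(path), "window")
})

test_that("NMR-STAR Atom_chem_shift loops parse, ignoring non-backbone atoms", {
  path <- withr::local_tempfile(fileext = ".str")
  writeLines(c(
    "data_test",
    "save_assigned_chemical_shifts",
    "   loop_",
    "      _Atom_chem_shift.ID",
    "      _Atom_chem_shift.Seq_ID",
    "      _Atom_chem_shift.Comp_ID",
    "      _Atom_chem_shift.Atom_ID",
    "      _Atom_chem_shift.Val",
    "      1 21 GLY H 8.45",
    "      2 21 GLY N 109.2",
    "      3 22 LYS H 8.10",
    "      4 22 LYS HB2 1.85",
    "   stop_",
    "save_"
  ), path)
  expect_message(tbl <- read_shift_table(path, dialect = "nmrstar"),
                 "ignored")
  expect_equal(nrow(tbl), 3L)
  expect_equal(tbl$residue_type[tbl$residue_number == 21], c("G", "G"))
  expect_equal(tbl$shift_ppm[tbl$residue_number == 22], 8.10)

  writeLines(c("data_x", "loop_", "_Other.tag", "1", "stop_"), path)
  expect_error(read_shift_table(path, dialect = "nmrstar"),
               "Atom_chem_shift")
})

test_that("Sparky lists parse assignments, defaults and errors", {
  path <- withr::local_tempfile(fileext = ".list")
  writeLines(c(
    "      Assignment         w1         w2   Data Height",
    "         G21N-H     109.20       8.45     1.0e6",
    "              ?     115.00       7.90"
  ), path)
  pk <- read_sparky_list(path)
  expect_equal(nrow(pk), 2L)
  expect_equal(pk$residue_number[1], 21L)
  expect_equal(pk$h_ppm[1], 8.45)   # w1 = 15N by default
  expect_equal(pk$n_ppm[1], 109.20)
  expect_equal(pk$intensity[1], 1e6)
  expect_true(is.na(pk$residue_number[2]))
  expect_equal(pk$intensity[2], 1.0)  # missing height defaults to 1

  writeLines(c("header", "G21N-H  abc  8.45"), path)
  expect_error(read_sparky_list(path), "line 2")

  writeLines("      Assignment         w1         w2", path)
  expect_equal(nrow(read_sparky_list(path)), 0L)
})

test_that("Sparky writer round-trips through the reader", {
  pk <- tibble::tibble(
    h_ppm = c(8.45, 7.90), n_ppm = c(109.2, 115.0),
    intensity = c(1e6, 1), residue_number = c(21L, NA),
    assignment = c("G21N-H", "?")
  )
  path <- withr::local_tempfile(fileext = ".list")
  write_sparky_list(pk, path)
  back <- read_sparky_list(path)
  expect_equal(back$h_ppm, pk$h_ppm, tolerance = 1e-4)
  expect_equal(back$n_ppm, pk$n_ppm, tolerance = 1e-4)
  expect_equal(back$residue_number, pk$residue_number)
})

test_that("PDB CA extraction honors altloc and chain rules", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(toy_pdb_lines(), path)
  s <- read_structure_ca(path, chain = "A")
  expect_equal(nrow(s), 3L)
  expect_equal(s$x, c(1, 4, 7))
  expect_equal(s$residue_type, c("A", "G", "S"))

  expect_error(read_structure_ca(path, chain = "Z"), "chain 'Z'")

  # altloc: keep the highest-occupancy location
  writeLines(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       2.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA  GLY A   2       3.000   0.000   0.000  1.00  0.00           C",
    "ATOM      4  CA  SER A   3       4.000   0.000   0.000  1.00  0.00           C",
    "END"
  ), path)
  s2 <- read_structure_ca(path, chain = "A")
  expect_equal(s2$x[s2$residue_number == 1], 2.0)

  # residue with no CA is skipped with a warning
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  N   GLY A   2       3.000   0.000   0.000  1.00  0.00           N",
    "ATOM      3  CA  SER A   3       4.000   0.000   0.000  1.00  0.00           C",
    "END"
  ), path)
  expect_warning(s3 <- read_structure_ca(path, chain = "A"), "without a CA")
  expect_equal(s3$residue_number, c(1L, 3L))
})

test_that("numbering offsets act as a group and pass through zero", {
  tbl <- amide_table(c(-3L, 0L, 4L), c(8.1, 8.2, 8.3), c(110, 115, 120))
  shifted <- apply_numbering_offset(tbl, 24)
  expect_equal(unique(shifted$residue_number), c(21L, 24L, 28L))
  expect_equal(apply_numbering_offset(tbl, 0), tbl)
  expect_equal(
    apply_numbering_offset(apply_numbering_offset(tbl, 7), -7), tbl)
  # offset a then b equals offset a + b, over several random offsets
  withr::with_seed(11, {
    for (rep in 1:5) {
      a <- sample(-30:30, 1)
      b <- sample(-30:30, 1)
      expect_equal(
        apply_numbering_offset(apply_numbering_offset(tbl, a), b),
        apply_numbering_offset(tbl, a + b)
      )
    }
  })
  # sequence records shift their first residue number
  sr <- sequence_record("x", "GKFI", -3L)
  expect_equal(apply_numbering_offset(sr, 24)$first_residue_number, 21L)
})

test_that("FASTA round-trips and rejects non-canonical letters", {
  recs <- dplyr::bind_rows(
    sequence_record("seq1", "GKTFIQ", 21L),
    sequence_record("seq2", "AKTFXQ", 20L)
  )
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_sequences(recs, path)
  back <- read_fasta_sequences(path, first_residue_number = c(21L, 20L))
  expect_equal(back$sequence, recs$sequence)
  expect_equal(back$first_residue_number, recs$first_residue_number)
  expect_error(sequence_record("bad", "AKTJ"), "non-canonical")
})

test_that("CSP profile reports round-trip with fixed columns", {
  free <- amide_table(1:3, c(8.0, 8.1, 8.2), c(115, 116, 117))
  bound <- amide_table(1:2, c(8.1, 8.1), c(115.5, 116), state_label = "bound",
                       molar_ratio = 1)
  profile <- compute_csp(free, bound)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_report(profile, path, format = "tsv")
  header <- readLines(path, n = 1)
  expect_equal(strsplit(header, "\t")[[1]],
               c("residue", "delta_H", "delta_N", "delta_weighted", "status"))
  back <- read_csp_profile(path)
  expect_equal(back$delta_weighted, signif(profile$delta_weighted, 6))
  expect_equal(back$status, profile$status)

  # empty profile writes a header-only file
  empty <- profile[0, ]
  class(empty) <- class(profile)
  write_report(empty, path, format = "tsv")
  expect_equal(length(readLines(path)), 1L)

  # JSON report is valid and re-readable
  jpath <- withr::local_tempfile(fileext = ".json")
  write_report(profile, jpath, format = "json")
  parsed <- jsonlite::read_json(jpath)
  expect_equal(length(parsed), 3L)  # one object per residue row
})
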