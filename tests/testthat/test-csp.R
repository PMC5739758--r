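test_that("weighted CSP matches hand-evaluated values exactly", {
  expect_equal(weighted_csp(0, 0), 0)
  expect_equal(weighted_csp(0.1, 0.5), 0.1, tolerance = 1e-12)
  expect_equal(weighted_csp(0.3, 0), sqrt(0.09 / 2), tolerance = 1e-12)
  expect_equal(weighted_csp(0.3, 0), 0.2121320, tolerance = 1e-6)
})

test_that("weighted CSP invariances and lower bounds hold", {
  withr::with_seed(7, {
    dh <- stats::rnorm(200, 0, 0.3)
    dn <- stats::rnorm(200, 0, 2)
    dd <- weighted_csp(dh, dn)
    expect_equal(dd, weighted_csp(-dh, -dn))
    expect_true(all(dd >= abs(dh) / sqrt(2) - 1e-14))
    expect_true(all(dd >= abs(dn) / (sqrt(2) * 5) - 1e-14))
  })
})

test_that("CSP profiles carry per-residue status flags", {
  # the proline H row is dropped by table validation (no amide proton)
  free <- suppressWarnings(shift_table(data.frame(
    residue_number = rep(c(1L, 2L, 3L, 4L), each = 2),
    residue_type = rep(c("A", "P", "G", "K"), each = 2),
    atom_name = rep(c("H", "N"), 4),
    shift_ppm = c(8.0, 115, 8.1, 116, 8.2, 117, 8.3, 118)
  )))
  suppressWarnings(
    bound <- amide_table(c(1L, 3L, 5L), c(8.1, 8.2, 7.9), c(115.5, 117, 119),
                         residue_type = c("A", "G", "R"),
                         state_label = "bound", molar_ratio = 1)
  )
  profile <- compute_csp(free, bound, residue_range = c(1, 5),
                         relocated_residues = 3L)
  expect_equal(profile$status,
               c("shifted", "proline", "relocated", "disappeared",
                 "unassigned"))
  expect_equal(profile$delta_h[1], 0.1, tolerance = 1e-12)
  expect_equal(profile$delta_n[1], 0.5, tolerance = 1e-12)
  expect_equal(profile$delta_weighted[1], 0.1, tolerance = 1e-12)
  expect_true(all(is.na(profile$delta_weighted[profile$status %in%
                                                 c("disappeared",
                                                   "unassigned",
                                                   "proline")])))
  # disjoint numbering scales are an input error
  far <- amide_table(100:102, c(8, 8, 8), c(115, 116, 117))
  expect_error(compute_csp(free, far), "shared")
})

test_that("threshold is mean + k * sample SD over numeric CSPs", {
  prof <- tibble::tibble(
    residue_number = 1:4,
    delta_weighted = c(0.1, 0.1, 0.1, 0.1),
    status = "shifted"
  )
  class(prof) <- c("csp_profile", class(prof))
  th <- compute_threshold(prof)
  expect_equal(th$sd, 0)
  expect_equal(th$cutoff, 0.1)

  prof2 <- prof[1:2, ]
  prof2$delta_weighted <- c(0, 0.2)
  class(prof2) <- class(prof)
  th2 <- compute_threshold(prof2, k = 1)
  expect_equal(th2$mean, 0.1, tolerance = 1e-12)
  expect_equal(th2$sd, 0.1414214, tolerance = 1e-6)
  expect_equal(th2$cutoff, 0.1 + stats::sd(c(0, 0.2)), tolerance = 1e-12)
  expect_equal(compute_threshold(prof2, k = 0)$cutoff, th2$mean)

  prof3 <- prof[1, ]
  class(prof3) <- class(prof)
  expect_error(compute_threshold(prof3), "at least 2")

  # relocated residues enter by default, can be excluded
  prof4 <- tibble::tibble(
    residue_number = 1:3,
    delta_weighted = c(0.1, 0.2, 0.9),
    status = c("shifted", "shifted", "relocated")
  )
  class(prof4) <- class(prof)
  expect_equal(compute_threshold(prof4)$n_used, 3L)
  expect_equal(compute_threshold(prof4, include_relocated = FALSE)$n_used, 2L)
})

test_that("significant selection is strict and recovers the fixture pocket", {
  pocket <- c(21L, 22L, 24L, 25L, 26L, 27L, 29L, 30L, 31L, 32L, 50L,
              61L, 62L, 63L, 65L, 66L, 94L, 95L, 97L)
  residues <- 21:111
  prof <- tibble::tibble(
    residue_number = residues,
    delta_weighted = ifelse(residues %in% pocket, 0.15, 0.05),
    status = "shifted"
  )
  class(prof) <- c("csp_profile", class(prof))
  th <- list(mean = 0.05, sd = 0.05, k = 1, cutoff = 0.1)
  class(th) <- "csp_threshold"
  sig <- select_significant(prof, th)
  expect_equal(sig$residue_number, pocket)

  # a residue exactly at the cutoff is excluded (strict inequality)
  prof$delta_weighted[prof$residue_number == 40] <- 0.1
  sig2 <- select_significant(prof, th)
  expect_false(40 %in% sig2$residue_number)

  # all below cutoff: empty selection
  prof$delta_weighted <- 0.01
  expect_equal(nrow(select_significant(prof, th)), 0L)

  # disappeared residues are reported separately, never silently included
  prof$status[prof$residue_number == 60] <- "disappeared"
  prof$delta_weighted[prof$residue_number == 60] <- NA_real_
  sig3 <- select_significant(prof, th)
  expect_false(60 %in% sig3$residue_number)
  expect_equal(attr(sig3, "disappeared"), 60L)
})
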