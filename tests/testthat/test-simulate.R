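test_that("titration simulations are reproducible and honor invariants", {
  s1 <- simulate_titration(seed = 77)
  s2 <- simulate_titration(seed = 77)
  expect_identical(s1$series$peaks, s2$series$peaks)
  expect_identical(s1$ground_truth$true_csp, s2$ground_truth$true_csp)
  s3 <- simulate_titration(seed = 78)
  expect_false(identical(s1$series$peaks, s3$series$peaks))

  expect_equal(s1$series$ratios, c(0, 0.3, 0.5, 0.7, 1, 1.3))
  # reference point: every peak exactly at the assigned free position
  ref <- csppocket:::reference_positions(s1$series$reference)
  at0 <- s1$series$peaks[s1$series$peaks$molar_ratio == 0, ]
  expect_equal(at0$h_ppm, ref$h_ppm)
  expect_equal(at0$intensity, rep(1, nrow(at0)))
})

test_that("slow exchange splits pocket peaks by population and drops dim ones", {
  # kd -> 0 with ratio 0.5 gives a 50/50 split
  sim <- simulate_titration(n_residues = 10, pocket_residues = c(4L, 8L),
                            kd = 1e-6, ratios = c(0, 0.5, 1, 1.3),
                            noise_sigma = c(0, 0), detection_floor = 0.3,
                            seed = 10)
  pk <- sim$ground_truth$peak_origin
  at05 <- pk[pk$molar_ratio == 0.5 & pk$true_residue == 4, ]
  expect_equal(nrow(at05), 2L)
  expect_equal(sort(at05$intensity), c(0.5, 0.5))
  # at saturating ratio only the bound peak survives the detection floor
  at13 <- pk[pk$molar_ratio == 1.3 & pk$true_residue == 4, ]
  expect_equal(at13$true_state, "bound")
  expect_gte(min(at13$intensity), 0.999)
})

test_that("fast exchange yields single population-weighted peaks", {
  sim <- simulate_titration(n_residues = 10, pocket_residues = 5L,
                            delta_bound = tibble::tibble(
                              residue_number = 5L, delta_h = 0.4,
                              delta_n = 2.0),
                            kd = 1e-6, ratios = c(0, 0.5, 1, 1.3),
                            exchange = "fast", noise_sigma = c(0, 0),
                            seed = 11)
  pk <- sim$ground_truth$peak_origin
  free_h <- pk$h_ppm[pk$molar_ratio == 0 & pk$true_residue == 5]
  at05 <- pk[pk$molar_ratio == 0.5 & pk$true_residue == 5, ]
  expect_equal(nrow(at05), 1L)
  expect_equal(at05$h_ppm - free_h, 0.2, tolerance = 1e-9)
})

test_that("noise-free titrations give exact end-to-end pocket recovery", {
  sim <- simulate_titration(noise_sigma = c(0, 0), seed = 13)
  run <- suppressMessages(run_csp(
    sim$series, run_config(),
    bound_reference = sim$ground_truth$bound_shifts))
  expect_equal(run$significant$residue_number,
               sim$ground_truth$pocket_residues)
  expect_equal(run$saturation$stoichiometry, 1.0)
})

test_that("saturation curves are exact at zero noise and refit cleanly", {
  sim <- simulate_saturation_curve(kd = 2.07, probe_total = 2,
                                   noise_frac = 0, seed = 5)
  expect_equal(sim$curve$signal,
               saturation_signal(sim$curve$conc, 2, 2.07, 0, 1))
  expect_equal(sim$curve$signal[sim$curve$conc == 0], 0)
  fit <- fit_saturation(sim$curve, probe_total = 2, n_boot = 0)
  expect_lt(rel_err(fit$kd, 2.07), 1e-6)
})

test_that("structure pairs plant a recoverable transform", {
  sim <- simulate_structure_pair(10, noise_sigma = 0, seed = 21)
  sp <- superpose_kabsch(sim$a, sim$b)
  expect_lt(sp$rmsd, 1e-10)
  expect_equal(sp$rotation %*% sim$ground_truth$rotation, diag(3),
               tolerance = 1e-8)
  expect_error(simulate_structure_pair(2), ">= 3")
})

test_that("the homolog fixture is internally consistent", {
  fx <- make_fixture_protein()
  expect_length(fx$significant$msi2_19, 19L)
  expect_length(fx$significant$msi2_17, 17L)
  expect_length(fx$significant$msi1_17, 17L)
  # the seven severely perturbed residues map one-for-one by shift-by-one
  m <- fx$residue_map
  mapped <- m$res_b[match(fx$significant$msi2_severe7, m$res_a)]
  expect_equal(mapped, fx$significant$msi1_severe7)
  # SSE lookup agrees with the printed ranges
  ann <- annotate_sse(66L, fx$sse, fx$core_range)
  expect_equal(ann$sse, "b3")
  # the synthetic sequences align gaplessly over the shared span with the
  # shift-by-one correspondence and ~80% identity
  al <- global_align(fx$msi2, fx$msi1)
  expect_gt(al$identity_fraction, 0.75)
  expect_lt(al$identity_fraction, 0.85)
  am <- map_equivalent_residues(al)
  sub <- am[am$res_a %in% 21:104, ]
  expect_equal(sub$res_b, sub$res_a - 1L)
})

test_that("simulated series round-trip through files", {
  sim <- simulate_titration(n_residues = 12, pocket_residues = c(3L, 9L),
                            seed = 33)
  dir <- withr::local_tempdir()
  paths <- write_titration_files(sim$series, dir)
  ref <- read_shift_table(paths$reference, dialect = "tsv")
  expect_equal(ref$shift_ppm, sim$series$reference$shift_ppm)
  pk0 <- read_sparky_list(paths$peaks[1])
  at0 <- sim$series$peaks[sim$series$peaks$molar_ratio == 0, ]
  expect_equal(pk0$h_ppm, at0$h_ppm, tolerance = 1e-4)
  expect_equal(pk0$n_ppm, at0$n_ppm, tolerance = 1e-4)
})
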