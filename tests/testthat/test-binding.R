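test_that("quadratic bound fraction matches hand-evaluated cases", {
  # stoichiometric limit kd -> 0: all of the limiting species binds
  expect_equal(bound_fraction_quadratic(1, 2, 0), 0.5, tolerance = 1e-12)
  expect_equal(bound_fraction_quadratic(2, 1, 0), 1.0, tolerance = 1e-12)
  # p = l = kd = 1: bound = (3 - sqrt(5)) / 2
  expect_equal(bound_fraction_quadratic(1, 1, 1), (3 - sqrt(5)) / 2,
               tolerance = 1e-12)
  # excess protein saturates the probe
  expect_gte(bound_fraction_quadratic(1000, 2, 2), 0.99)
  expect_equal(bound_fraction_quadratic(0, 2, 1), 0)
  expect_equal(bound_fraction_quadratic(5, 0, 1), 0)
  expect_error(bound_fraction_quadratic(-1, 1, 1), "non-negative")
})

test_that("quadratic bound fraction is monotone and within [0, 1]", {
  p <- 10^seq(-2, 3, length.out = 40)
  f <- bound_fraction_quadratic(p, 2, 5)
  expect_true(all(f >= 0 & f <= 1))
  expect_true(all(diff(f) > 0))  # increasing in protein
  kd <- 10^seq(-2, 3, length.out = 40)
  g <- bound_fraction_quadratic(10, 2, kd)
  expect_true(all(diff(g) < 0))  # decreasing in kd
})

test_that("quadratic solution agrees with a numeric equilibrium solver", {
  grid <- expand.grid(p = 10^seq(-2, 3, length.out = 6),
                      l = 10^seq(-2, 3, length.out = 6),
                      kd = 10^seq(-3, 3, length.out = 6))
  got <- bound_fraction_quadratic(grid$p, grid$l, grid$kd)
  want <- mapply(solve_bound_numeric, grid$p, grid$l, grid$kd)
  expect_equal(got, unname(want), tolerance = 1e-10)
})

test_that("saturation fits recover noiseless parameters to 1e-6", {
  sim <- simulate_saturation_curve(kd = 4.2, probe_total = 2, f_min = 0.2,
                                   f_max = 1.7, noise_frac = 0, seed = 1)
  fit <- fit_saturation(sim$curve, probe_total = 2, n_boot = 0)
  expect_equal(fit$verdict, "binding")
  expect_lt(rel_err(fit$kd, 4.2), 1e-6)
  expect_lt(rel_err(fit$f_min, 0.2), 1e-6)
  expect_lt(rel_err(fit$f_max, 1.7), 1e-6)
  expect_lt(fit$residual_ss, 1e-16)
})

test_that("flat curves return a no-binding verdict", {
  curve <- tibble::tibble(conc = c(0, 1, 2, 5, 10, 20), signal = 1)
  fit <- fit_saturation(curve, probe_total = 2, n_boot = 0)
  expect_equal(fit$verdict, "no-binding")
  expect_true(is.na(fit$kd))
  g <- glance(fit)
  expect_equal(g$verdict, "no-binding")
})

test_that("noisy Kd recovery is accurate and the CI covers the truth", {
  withr::with_seed(606, {
    errs <- covs <- numeric(20)
    for (i in 1:20) {
      kd <- exp(stats::runif(1, log(0.5), log(20)))
      sim <- simulate_saturation_curve(kd = kd, probe_total = 2,
                                       noise_frac = 0.01, seed = 3000 + i)
      fit <- fit_saturation(sim$curve, probe_total = 2, n_boot = 200,
                            seed = 4000 + i)
      errs[i] <- rel_err(fit$kd, kd)
      covs[i] <- kd >= fit$ci95_kd[1] && kd <= fit$ci95_kd[2]
    }
    expect_lt(median(errs), 0.10)
    expect_gte(mean(covs), 0.75)  # full calibration checked at larger n
  })
})

test_that("tidy and glance expose the fitted parameters", {
  sim <- simulate_saturation_curve(kd = 2.07, noise_frac = 0.01, seed = 2)
  fit <- fit_saturation(sim$curve, probe_total = 2, n_boot = 50)
  td <- tidy(fit)
  expect_equal(td$term, c("kd", "f_min", "f_max"))
  expect_true(td$conf.low[1] < fit$kd && td$conf.high[1] > fit$kd)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("competition model reduces to the saturation model at zero dose", {
  frac0 <- competition_bound_fraction(0, protein_total = 10, probe_total = 2,
                                      probe_kd = 2, ki = 5)
  expect_equal(frac0, bound_fraction_quadratic(10, 2, 2), tolerance = 1e-10)
})

test_that("competitive equilibrium agrees with the cubic-root oracle", {
  doses <- c(0, 10^seq(-1, 4, length.out = 12))
  got <- competition_bound_fraction(doses, protein_total = 10,
                                    probe_total = 2, probe_kd = 2, ki = 50)
  want <- vapply(doses, solve_competition_polyroot, numeric(1),
                 pt = 10, lt = 2, kd = 2, ki = 50)
  expect_equal(got, want, tolerance = 1e-8)

  # competitor chemically identical to the probe (ki = kd), equal totals:
  # at high dose the probe keeps the minority share of the protein
  high <- competition_bound_fraction(2000, protein_total = 10,
                                     probe_total = 2, probe_kd = 2, ki = 2)
  oracle <- solve_competition_polyroot(2000, 10, 2, 2, 2)
  expect_equal(high, oracle, tolerance = 1e-8)
})

test_that("competition fits recover a planted Ki and flag flat curves", {
  doses <- c(0, 10^seq(0, 4, length.out = 11))
  y <- competition_signal(doses, protein_total = 10, probe_total = 2,
                          probe_kd = 2, ki = 80, f_min = 0.1, f_max = 1.1)
  fit <- fit_competition(tibble::tibble(conc = doses, signal = y),
                         probe_kd = 2, probe_total = 2, protein_total = 10)
  expect_equal(fit$verdict, "displacement")
  expect_lt(rel_err(fit$ki, 80), 1e-5)
  expect_gt(fit$top, fit$bottom)
  expect_true(is.finite(fit$ic50) && fit$ic50 > 0)

  flat <- tibble::tibble(conc = doses, signal = 0.5)
  fit2 <- fit_competition(flat, probe_kd = 2, probe_total = 2,
                          protein_total = 10)
  expect_equal(fit2$verdict, "no-displacement")
  expect_true(is.na(fit2$ki))
})
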