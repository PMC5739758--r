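# Binding isotherm models and fits for FP/TR-FRET assays: exact 1:1
# saturation with ligand depletion (quadratic) and competitive
# displacement (one protein, two ligands; cubic equilibrium).

#' Bound probe fraction under the exact 1:1 equilibrium
#'
#' Solves the two-species equilibrium exactly (the "quadratic" or
#' ligand-depletion model): the complex concentration is the physically
#' valid root of `(p - b)(l - b) = kd * b`, evaluated in the
#' cancellation-safe form `b = 2 p l / (s + sqrt(s^2 - 4 p l))` with
#' `s = p + l + kd`. Required whenever the probe concentration is
#' comparable to Kd, where the hyperbolic approximation is biased.
#'
#' @param p_total Total protein concentration (nM), vectorized.
#' @param l_total Total labeled-ligand (probe) concentration (nM).
#' @param kd Dissociation constant (nM); `kd = 0` is handled as the
#'   stoichiometric limit `b = min(p, l)`.
#' @return Fraction of the probe bound, in `[0, 1]` (0 when `l_total` = 0).
#' @export
bound_fraction_quadratic <- function(p_total, l_total, kd) {
  n <- max(length(p_total), length(l_total), length(kd))
  p <- rep_len(as.numeric(p_total), n)
  l <- rep_len(as.numeric(l_total), n)
  k <- rep_len(as.numeric(kd), n)
  if (any(p < 0) || any(l < 0) || any(k < 0)) {
    rlang::abort("concentrations and kd must be non-negative")
  }
  s <- p + l + k
  disc <- s^2 - 4 * p * l
  disc[disc < 0] <- 0
  b <- ifelse(s > 0, 2 * p * l / (s + sqrt(disc)), 0)
  ifelse(l > 0, b / l, 0)
}

#' Saturation-binding forward model
#'
#' `signal = f_min + (f_max - f_min) * bound_fraction`, with the bound
#' fraction from [bound_fraction_quadratic()] (or the naive hyperbola
#' `x / (kd + x)` for comparison).
#'
#' @param x Titrant (protein) total concentrations (nM).
#' @param probe_total Probe concentration (nM).
#' @param kd Dissociation constant (nM).
#' @param f_min,f_max Signal at zero and full saturation.
#' @param model `"quadratic"` (exact, default) or `"hyperbolic"`.
#' @return Predicted signal.
#' @export
saturation_signal <- function(x, probe_total, kd, f_min = 0, f_max = 1,
                              model = c("quadratic", "hyperbolic")) {
  model <- match.arg(model)
  frac <- switch(model,
    quadratic = bound_fraction_quadratic(x, probe_total, kd),
    hyperbolic = x / (kd + x)
  )
  f_min + (f_max - f_min) * frac
}

# Free protein concentration for the one-protein/two-ligand competitive
# equilibrium: p satisfies p (1 + Lt/(kd+p) + Ct/(ki+p)) = Pt.
# Bracketing Brent step polished by Newton iterations to machine precision.
free_protein_competitive <- function(c_total, protein_total, probe_total,
                                     probe_kd, ki) {
  vapply(c_total, function(ct) {
    f <- function(p) {
      p + probe_total * p / (probe_kd + p) + ct * p / (ki + p) - protein_total
    }
    if (protein_total == 0) return(0)
    p <- stats::uniroot(f, c(0, protein_total),
                        tol = .Machine$double.eps^0.75 *
                          max(1, protein_total))$root
    for (i in 1:4) {
      fp <- 1 + probe_total * probe_kd / (probe_kd + p)^2 +
        ct * ki / (ki + p)^2
      p <- p - f(p) / fp
      if (p < 0) p <- 0
    }
    p
  }, numeric(1))
}

#' Bound probe fraction in a competition assay
#'
#' Exact one-protein/two-ligand equilibrium: given the totals and both
#' dissociation constants, the free protein concentration is the root of
#' a cubic (solved by a safeguarded bracketed root with Newton polish)
#' and the probe-bound fraction is `p / (kd + p)`. Reduces to
#' [bound_fraction_quadratic()] at zero competitor.
#'
#' @param c_total Competitor total concentrations (nM), vectorized.
#' @param protein_total,probe_total Totals (nM).
#' @param probe_kd Probe dissociation constant (nM).
#' @param ki Competitor dissociation constant (nM).
#' @return Fraction of probe bound.
#' @export
competition_bound_fraction <- function(c_total, protein_total, probe_total,
                                       probe_kd, ki) {
  if (probe_kd <= 0 || ki <= 0) rlang::abort("probe_kd and ki must be > 0")
  if (any(c_total < 0) || protein_total < 0 || probe_total < 0) {
    rlang::abort("concentrations must be non-negative")
  }
  p <- free_protein_competitive(c_total, protein_total, probe_total,
                                probe_kd, ki)
  p / (probe_kd + p)
}

#' Competition-assay forward model
#'
#' @inheritParams competition_bound_fraction
#' @param f_min,f_max Signal for free and bound probe.
#' @return Predicted signal at each competitor dose.
#' @export
competition_signal <- function(c_total, protein_total, probe_total, probe_kd,
                               ki, f_min = 0, f_max = 1) {
  frac <- competition_bound_fraction(c_total, protein_total, probe_total,
                                     probe_kd, ki)
  f_min + (f_max - f_min) * frac
}

# Variable projection: for a fixed nonlinear parameter the model is
# linear in (f_min, f_max - f_min); profile those out by least squares.
vp_solve <- function(frac, y) {
  # closed-form 2-parameter least squares (intercept + amplitude)
  n <- length(y)
  s1 <- sum(frac)
  s2 <- sum(frac^2)
  det <- n * s2 - s1^2
  if (det < 1e-12 * max(n * s2, 1)) {
    # degenerate (constant bound fraction): intercept-only fit
    coefs <- c(mean(y), 0)
  } else {
    sy <- sum(y)
    sfy <- sum(frac * y)
    coefs <- c(s2 * sy - s1 * sfy, n * sfy - s1 * sy) / det
  }
  fitted <- coefs[1] + coefs[2] * frac
  list(coef = coefs, rss = sum((y - fitted)^2), fitted = fitted)
}

# 1-D multi-start + local refinement over log(theta).
vp_optimize <- function(rss_fun, log_lo, log_hi, n_grid = 25, tol = 1e-10) {
  grid <- seq(log_lo, log_hi, length.out = n_grid)
  vals <- vapply(grid, rss_fun, numeric(1))
  j <- which.min(vals)
  lo <- grid[max(1, j - 1)]
  hi <- grid[min(n_grid, j + 1)]
  opt <- stats::optimize(rss_fun, c(lo, hi), tol = tol)
  if (vals[j] < opt$objective) list(par = grid[j], value = vals[j])
  else list(par = opt$minimum, value = opt$objective)
}

# Robust noise scale from successive differences of the signal.
noise_from_differences <- function(y) {
  if (length(y) < 3) return(0)
  stats::sd(diff(y)) / sqrt(2)
}

#' Fit a saturation binding curve
#'
#' Least-squares fit of
#' `y = f_min + (f_max - f_min) * bound_fraction_quadratic(x, probe, kd)`
#' with the linear parameters profiled out and Kd found by multi-start
#' search on a log grid spanning `[min(x>0)/10, max(x) * 10]` followed by
#' local refinement. A 95% confidence interval on Kd comes from a seeded
#' residual-resampling bootstrap (log-scale Student-t interval using the
#' bootstrap standard error, calibrated for small point counts). Curves with no dynamic range (signal
#' span below 3x the noise estimate) return a `"no-binding"` verdict.
#'
#' @param curve Data frame with columns `conc` (titrant totals, nM,
#'   strictly increasing, `>= 0`) and `signal`.
#' @param probe_total Probe concentration (nM).
#' @param model `"quadratic"` (exact ligand-depletion, default) or
#'   `"hyperbolic"` for comparison.
#' @param n_boot Bootstrap replicates for the Kd interval.
#' @param seed Seed for the bootstrap resampling.
#' @return An object of class `binding_fit`: `kd`, `f_min`, `f_max`,
#'   `residual_ss`, `ci95_kd`, `verdict` (`"binding"` or `"no-binding"`),
#'   plus the data and fitted values. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @export
fit_saturation <- function(curve, probe_total, model = c("quadratic",
                                                         "hyperbolic"),
                           n_boot = 500, seed = 20171120) {
  model <- match.arg(model)
  x <- as.numeric(curve$conc)
  y <- as.numeric(curve$signal)
  if (length(x) < 5L) rlang::abort("need at least 5 titration points")
  if (any(x < 0) || any(diff(x) <= 0)) {
    rlang::abort("concentrations must be non-negative and strictly increasing")
  }
  noise <- noise_from_differences(y)
  if (diff(range(y)) < 3 * noise || diff(range(y)) == 0) {
    return(new_binding_fit(kd = NA_real_, f_min = mean(y), f_max = mean(y),
                           residual_ss = sum((y - mean(y))^2),
                           ci95_kd = c(NA_real_, NA_real_),
                           verdict = "no-binding", model = model,
                           probe_total = probe_total, curve = curve,
                           fitted = rep(mean(y), length(y)),
                           n_boot = n_boot, seed = seed))
  }
  frac_fun <- function(kd) switch(model,
    quadratic = bound_fraction_quadratic(x, probe_total, kd),
    hyperbolic = x / (kd + x)
  )
  rss_fun <- function(logkd) vp_solve(frac_fun(exp(logkd)), y)$rss
  xmin <- min(x[x > 0])
  opt <- vp_optimize(rss_fun, log(xmin / 10), log(max(x) * 10))
  kd <- exp(opt$par)
  sol <- vp_solve(frac_fun(kd), y)

  boot_kd <- bootstrap_kd(y_fitted = sol$fitted, resid = y - sol$fitted,
                          frac_fun = frac_fun, kd_hat = kd,
                          n_boot = n_boot, seed = seed)
  # log-scale t interval with the bootstrap SE: percentile intervals
  # undercover for a nonlinear parameter at typical assay sizes (~12
  # points), so use Student-t quantiles with n - 3 degrees of freedom
  ci <- if (n_boot >= 2) {
    tq <- stats::qt(0.975, df = max(length(y) - 3, 1))
    exp(log(kd) + c(-1, 1) * tq * stats::sd(log(boot_kd)))
  } else {
    c(NA_real_, NA_real_)
  }
  new_binding_fit(
    kd = kd, f_min = unname(sol$coef[1]),
    f_max = unname(sol$coef[1] + sol$coef[2]),
    residual_ss = sol$rss,
    ci95_kd = ci,
    verdict = "binding", model = model, probe_total = probe_total,
    curve = curve, fitted = sol$fitted, n_boot = n_boot, seed = seed
  )
}

bootstrap_kd <- function(y_fitted, resid, frac_fun, kd_hat, n_boot, seed) {
  if (n_boot < 1) return(rep(kd_hat, 2))
  # modified residuals: inflate by sqrt(n / (n - p)) so the resampled
  # noise matches the error variance (p = 3 fitted parameters)
  n <- length(resid)
  resid <- resid * sqrt(n / max(n - 3, 1))
  withr::with_seed(seed, {
    lo <- log(kd_hat) - log(100)
    hi <- log(kd_hat) + log(100)
    vapply(seq_len(n_boot), function(b) {
      yb <- y_fitted + sample(resid, length(resid), replace = TRUE)
      f <- function(logkd) vp_solve(frac_fun(exp(logkd)), yb)$rss
      exp(vp_optimize(f, lo, hi, n_grid = 9, tol = 1e-5)$par)
    }, numeric(1))
  })
}

new_binding_fit <- function(...) {
  structure(list(...), class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  if (x$verdict == "no-binding") {
    cat("<binding_fit> verdict: no-binding (no dynamic range)\n")
  } else {
    cat(sprintf(
      "<binding_fit> Kd %.3g nM [95%% CI %.3g, %.3g], span %.3g..%.3g (%s)\n",
      x$kd, x$ci95_kd[1], x$ci95_kd[2], x$f_min, x$f_max, x$model))
  }
  invisible(x)
}

#' @export
tidy.binding_fit <- function(x, ...) {
  tibble::tibble(
    term = c("kd", "f_min", "f_max"),
    estimate = c(x$kd, x$f_min, x$f_max),
    conf.low = c(x$ci95_kd[1], NA, NA),
    conf.high = c(x$ci95_kd[2], NA, NA)
  )
}

#' @export
glance.binding_fit <- function(x, ...) {
  tibble::tibble(kd = x$kd, f_min = x$f_min, f_max = x$f_max,
                 residual_ss = x$residual_ss, verdict = x$verdict,
                 n = nrow(x$curve), n_boot = x$n_boot)
}

#' @export
autoplot.binding_fit <- function(object, ...) {
  df <- tibble::as_tibble(object$curve)
  xg <- df$conc[df$conc > 0]
  grid <- tibble::tibble(conc = exp(seq(log(min(xg)), log(max(xg)),
                                        length.out = 200)))
  grid$signal <- if (object$verdict == "binding") {
    saturation_signal(grid$conc, object$probe_total, object$kd,
                      object$f_min, object$f_max, model = object$model)
  } else {
    mean(df$signal)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$conc, y = .data$signal)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Titrant total (nM)", y = "Signal") +
    ggplot2::theme_minimal()
}

#' Fit a competition (displacement) curve
#'
#' Fits the exact competitive equilibrium for the competitor dissociation
#' constant Ki with the signal scale profiled out; also reports the
#' empirical IC50 (dose at half-displacement on the fitted curve).
#' Monotone-flat curves within noise return a `"no-displacement"`
#' verdict (the scrambled-control case).
#'
#' @param curve Data frame with columns `conc` (competitor totals, nM)
#'   and `signal`.
#' @param probe_kd Probe Kd (nM) from the direct saturation fit.
#' @param probe_total,protein_total Assay totals (nM).
#' @return An object of class `competition_fit`: `ki`, `top`, `bottom`,
#'   `ic50`, `residual_ss`, `verdict`.
#' @export
fit_competition <- function(curve, probe_kd, probe_total, protein_total) {
  x <- as.numeric(curve$conc)
  y <- as.numeric(curve$signal)
  if (length(x) < 5L) rlang::abort("need at least 5 competitor doses")
  noise <- noise_from_differences(y)
  if (diff(range(y)) < 3 * noise || diff(range(y)) == 0) {
    return(structure(
      list(ki = NA_real_, top = mean(y), bottom = mean(y), ic50 = NA_real_,
           residual_ss = sum((y - mean(y))^2), verdict = "no-displacement",
           probe_kd = probe_kd, probe_total = probe_total,
           protein_total = protein_total, curve = curve,
           fitted = rep(mean(y), length(y))),
      class = "competition_fit"
    ))
  }
  frac_fun <- function(ki) {
    competition_bound_fraction(x, protein_total, probe_total, probe_kd, ki)
  }
  rss_fun <- function(logki) vp_solve(frac_fun(exp(logki)), y)$rss
  xpos <- x[x > 0]
  opt <- vp_optimize(rss_fun, log(min(xpos) / 100), log(max(xpos) * 100))
  ki <- exp(opt$par)
  sol <- vp_solve(frac_fun(ki), y)
  f_min <- unname(sol$coef[1])
  f_max <- unname(sol$coef[1] + sol$coef[2])
  top <- competition_signal(0, protein_total, probe_total, probe_kd, ki,
                            f_min, f_max)
  bottom <- f_min  # competitor -> Inf displaces all probe
  ic50 <- tryCatch({
    half <- (top + bottom) / 2
    g <- function(logc) {
      competition_signal(exp(logc), protein_total, probe_total, probe_kd,
                         ki, f_min, f_max) - half
    }
    exp(stats::uniroot(g, c(log(min(xpos)) - 10, log(max(xpos)) + 10))$root)
  }, error = function(e) NA_real_)
  structure(
    list(ki = ki, top = top, bottom = bottom, ic50 = ic50,
         residual_ss = sol$rss, verdict = "displacement",
         f_min = f_min, f_max = f_max, probe_kd = probe_kd,
         probe_total = probe_total, protein_total = protein_total,
         curve = curve, fitted = sol$fitted),
    class = "competition_fit"
  )
}

#' @export
print.competition_fit <- function(x, ...) {
  if (x$verdict == "no-displacement") {
    cat("<competition_fit> verdict: no-displacement\n")
  } else {
    cat(sprintf("<competition_fit> Ki %.3g nM (IC50 %.3g nM), top %.3g, ",
                x$ki, x$ic50, x$top))
    cat(sprintf("bottom %.3g\n", x$bottom))
  }
  invisible(x)
}

#' @export
tidy.competition_fit <- function(x, ...) {
  tibble::tibble(term = c("ki", "top", "bottom", "ic50"),
                 estimate = c(x$ki, x$top, x$bottom, x$ic50))
}

#' @export
glance.competition_fit <- function(x, ...) {
  tibble::tibble(ki = x$ki, ic50 = x$ic50, top = x$top, bottom = x$bottom,
                 residual_ss = x$residual_ss, verdict = x$verdict,
                 n = nrow(x$curve))
}

#' @export
autoplot.competition_fit <- function(object, ...) {
  df <- tibble::as_tibble(object$curve)
  xg <- df$conc[df$conc > 0]
  grid <- tibble::tibble(conc = exp(seq(log(min(xg)), log(max(xg)),
                                        length.out = 200)))
  grid$signal <- if (object$verdict == "displacement") {
    competition_signal(grid$conc, object$protein_total, object$probe_total,
                       object$probe_kd, object$ki, object$f_min, object$f_max)
  } else {
    mean(df$signal)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$conc, y = .data$signal)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Competitor total (nM)", y = "Signal") +
    ggplot2::theme_minimal()
}
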