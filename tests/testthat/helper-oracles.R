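# Independent oracles used across tests: exhaustive alignment enumeration,
# exhaustive peak assignment, and a numeric equilibrium root-finder.

# Enumerate all global alignment paths for sequence lengths (la, lb) once
# per shape; per path keep the diagonal index pairs and the affine gap
# bookkeeping (number of gap runs, total gapped columns).
align_paths <- local({
  cache <- new.env(parent = emptyenv())
  function(la, lb) {
    key <- paste(la, lb)
    if (!is.null(cache[[key]])) return(cache[[key]])
    paths <- list()
    rec <- function(i, j, moves) {
      if (i == la && j == lb) {
        paths[[length(paths) + 1L]] <<- moves
        return(invisible())
      }
      if (i < la && j < lb) rec(i + 1L, j + 1L, c(moves, "D"))
      if (i < la) rec(i + 1L, j, c(moves, "A"))
      if (j < lb) rec(i, j + 1L, c(moves, "B"))
    }
    rec(0L, 0L, character())
    out <- lapply(paths, function(mv) {
      i <- cumsum(mv != "B")
      j <- cumsum(mv != "A")
      dsel <- mv == "D"
      runs <- rle(mv)
      list(ai = i[dsel], bj = j[dsel],
           gap_runs = sum(runs$values != "D"),
           gap_len = sum(mv != "D"))
    })
    cache[[key]] <- out
    out
  }
})

# Best global affine-gap score by scoring every alignment explicitly.
brute_align_score <- function(a, b, sub, gap_open, gap_extend) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  paths <- align_paths(length(av), length(bv))
  max(vapply(paths, function(p) {
    s <- if (length(p$ai)) sum(sub[cbind(av[p$ai], bv[p$bj])]) else 0
    s - p$gap_runs * gap_open - p$gap_len * gap_extend
  }, numeric(1)))
}

# Exhaustive peak-to-residue assignment: maximize matches, then minimize
# total scaled distance. Residue i may take any peak within tolerance or
# stay unmatched.
brute_assignment <- function(ref, peaks, tol_h, tol_n, n_weight = 5) {
  nr <- nrow(ref)
  np <- nrow(peaks)
  cand <- lapply(seq_len(nr), function(i) {
    dh <- peaks$h_ppm - ref$h_ppm[i]
    dn <- peaks$n_ppm - ref$n_ppm[i]
    ok <- which(abs(dh) <= tol_h & abs(dn) <= tol_n)
    list(peaks = ok, d = sqrt(dh[ok]^2 + (dn[ok] / n_weight)^2))
  })
  best <- list(matches = -1L, total = Inf, assign = rep(NA_integer_, nr))
  rec <- function(i, used, assign, total, matches) {
    if (i > nr) {
      if (matches > best$matches ||
            (matches == best$matches && total < best$total)) {
        best <<- list(matches = matches, total = total, assign = assign)
      }
      return(invisible())
    }
    rec(i + 1L, used, assign, total, matches)  # leave i unmatched
    ci <- cand[[i]]
    for (k in seq_along(ci$peaks)) {
      p <- ci$peaks[k]
      if (!used[p]) {
        used[p] <- TRUE
        assign[i] <- p
        rec(i + 1L, used, assign, total + ci$d[k], matches + 1L)
        used[p] <- FALSE
        assign[i] <- NA_integer_
      }
    }
  }
  rec(1L, logical(np), rep(NA_integer_, nr), 0, 0L)
  best
}

# Numeric oracle for the 1:1 equilibrium: root of (p - b)(l - b) = kd b.
solve_bound_numeric <- function(p, l, kd) {
  if (l == 0 || p == 0) return(0)
  f <- function(b) (p - b) * (l - b) - kd * b
  b <- stats::uniroot(f, c(0, min(p, l)), tol = .Machine$double.eps)$root
  b / l
}

# Numeric oracle for the competitive equilibrium via the cubic's roots.
solve_competition_polyroot <- function(ct, pt, lt, kd, ki) {
  a2 <- kd + ki + lt + ct - pt
  a1 <- kd * ki + ki * lt + kd * ct - pt * (kd + ki)
  a0 <- -pt * kd * ki
  roots <- polyroot(c(a0, a1, a2, 1))
  real <- Re(roots[abs(Im(roots)) < 1e-8 * max(1, Mod(roots))])
  p <- real[real >= -1e-12 & real <= pt + 1e-9]
  p <- max(min(p[1], pt), 0)
  p / (kd + p)
}

rel_err <- function(x, truth) abs(x - truth) / abs(truth)
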