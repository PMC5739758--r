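---
title: "Methods: CSP pocket mapping, exchange classification and binding fits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CSP pocket mapping, exchange classification and binding fits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csppocket)
```

## The measurement and the model

An ¹H–¹⁵N HSQC spectrum of an ¹⁵N-labeled protein shows one peak per
backbone amide. Titrating a ligand perturbs the chemical environment of
residues at and around the binding interface, moving their peaks. The
per-residue perturbation between the free state and a bound state is
summarized by the weighted combined CSP

$$\Delta\delta = \sqrt{\frac{(\Delta\delta_H)^2 +
(\Delta\delta_N / w)^2}{2}},$$

with the ¹⁵N weight $w = 5$ by default (¹⁵N shifts disperse over a ~5x
wider ppm range than ¹H). `compute_csp()` implements this exactly;
$w$ is exposed as `n_weight` for sensitivity analyses.

Significance is a profile-relative cutoff: mean plus $k$ standard
deviations of the numeric $\Delta\delta$ values, $k = 1$ by default.
Two small choices matter at the margin and are fixed as follows:

- **Sample SD** (denominator $n-1$): conservative at the profile sizes
  involved (~100 residues).
- **Strict inequality** at the cutoff: a residue exactly at the line is
  not called significant.

### Exchange regimes and relocated endpoints

Tightly bound complexes are in slow exchange: free and bound states give
separate peaks whose intensities track the populations. During a
titration an interface residue's free peak fades and a bound peak grows
elsewhere; in between, exchange broadening can push both below the
detection limit. Peak tracking (`track_peaks()`) therefore runs point to
point: each residue's expected position at a titration point is its last
observed position, and peaks are matched greedily within per-axis
tolerances (`tol_h` = 0.05 ppm, `tol_n` = 0.5 ppm by default) in order
of increasing scaled distance $d = \sqrt{\Delta h^2 + (\Delta n/5)^2}$,
ties broken toward the lower residue number. Point-to-point tracking
follows fast-exchange drifts whose total excursion exceeds the
tolerance; it cannot follow a slow-exchange relocation, which is the
point: the discontinuity is the signal.

Relocated endpoints must come from somewhere, and the pipeline mirrors
experimental practice: a bound-state shift table (e.g. from ¹⁵N-edited
NOESY re-assignment of the complex) can be supplied to `run_csp()` and
`classify_exchange()`. Those assignments are treated as authoritative.
Where the tracker found a final-point match that disagrees with the
assignment by more than 3x the scaled tolerance, the tracker has almost
certainly latched onto a bystander peak (in crowded spectra a vanished
peak's tolerance box often contains someone else's peak), and the
assignment replaces it; such residues are flagged `relocated`.

`classify_exchange()` then calls regimes from the trajectory
discontinuity: a residue whose endpoint jumps more than 3x the scaled
tolerance from its last traceable position is **slow**; one whose
endpoint continues its trajectory is **fast**; one with no recoverable
endpoint is **undetermined**. A residue that drops out at one point but
returns to the same position is called fast, not slow: slow exchange
relocates peaks, transient dropouts at an unchanged position are
overlap or noise artifacts.

### Threshold statistics and relocated residues

Whether relocated residues' (large) CSPs belong in the threshold mean
and SD is a genuine design choice; `compute_threshold()` exposes it as
`include_relocated`. The default is `TRUE`: once endpoints are known
from bound-state assignment, those residues are ordinary profile members
and excluding them would turn the cutoff into a noise statistic — for a
chi-distributed noise floor, mean + 1 SD sits near the 85th percentile,
so ~15% of unperturbed residues would clear it. Including the relocated
values puts the cutoff between the noise mode and the perturbed mode,
which is what a profile-relative threshold is for. Setting
`include_relocated = FALSE` reproduces the stricter reading (threshold
over continuously tracked residues only), with relocated residues then
reported alongside rather than tested.

### Stoichiometry from the CSP plateau

`csp_by_ratio()` computes, per titration point, each residue's
intensity-weighted centroid over the peaks attributable to it (its
trajectory peak, plus the unclaimed peak nearest its bound endpoint
when one is known). In slow exchange this centroid interpolates between
free and bound positions in proportion to the bound population, so the
per-ratio mean CSP traces the binding isotherm and flattens at
saturation. `assess_saturation()` reports the plateau onset — the
smallest molar ratio after which all subsequent mean-CSP increments stay
below a tolerance (0.005 ppm by default, roughly the position noise of a
well-resolved peak) — as the apparent stoichiometry. If no flat segment
is observed the final ratio is reported as a lower bound
(`plateau_reached = FALSE`); a plateau before ratio 1 is flagged as
apparent sub-unity stoichiometry (e.g. saturation by excess protein or
an impure ligand stock).

## Binding isotherms

With a 2 nM fluorescent probe and a low-nM Kd, free and total titrant
concentrations differ materially, so the hyperbolic isotherm is biased.
`bound_fraction_quadratic()` solves the 1:1 equilibrium exactly:

$$b = \frac{2\,p\,l}{(p + l + K_d) + \sqrt{(p + l + K_d)^2 - 4\,p\,l}},$$

the cancellation-safe form of the quadratic root (the naive
"minus" form loses precision when $4pl \ll (p+l+K_d)^2$). `fit_saturation()`
profiles the two linear parameters (baseline and amplitude) out in
closed form and searches Kd on a log grid spanning
$[\min(x>0)/10,\ 10\max(x)]$ followed by local refinement — a
multi-start strategy immune to the local minima of joint 3-parameter
descent. The hyperbolic model remains available (`model =
"hyperbolic"`) for comparison.

Uncertainty comes from a seeded residual-resampling bootstrap (500
replicates by default), with residuals inflated by $\sqrt{n/(n-p)}$ to
restore the error variance absorbed by fitting. The reported 95%
interval is a log-scale Student-t interval ($df = n - 3$) using the
bootstrap standard error: percentile-type intervals systematically
undercover for a nonlinear parameter at typical assay sizes (~12
points), while the t interval is calibrated there.

Competition curves use the exact one-protein/two-ligand equilibrium:
free protein solves
$p\,(1 + L_t/(K_d + p) + C_t/(K_i + p)) = P_t$ (a cubic), obtained by a
bracketed root on $[0, P_t]$ — the left side is strictly increasing —
polished with Newton steps to machine precision. At zero competitor this
reduces to the quadratic model exactly, which is asserted in tests.
`fit_competition()` reports Ki, the fitted top/bottom signals and the
empirical IC50. Curves whose signal span is below 3x a
difference-based noise estimate return `no-binding` /
`no-displacement` verdicts instead of a forced parameter.

## What the synthetic data emulate — and what they do not

`simulate_titration()` generates the study conditions as its defaults:
110 residues with 19 clustered pocket residues, 80 µM protein, molar
ratios 0, 0.3, 0.5, 0.7, 1, 1.3, slow exchange with Kd 10 nM, Gaussian
position noise (σH 0.005, σN 0.03 ppm) and a 0.25 relative detection
floor. Free-state shifts are generic backbone amide statistics
(H ~ N(8.3, 0.6), N ~ N(119, 4) ppm, truncated to the physical
windows) — the goal is the statistical structure of a crowded HSQC, not
spectral realism for any particular protein. Pocket offsets default to
|ΔδH| ~ U(0.35, 0.65) and |ΔδN| ~ U(2.0, 3.5) ppm with random signs
(weighted Δδ ≈ 0.38–0.68 ppm), the signature of strongly perturbed
slow-exchange interface residues; offsets are a per-residue input for
weaker scenarios. The bound protein fraction at each ratio follows the
exact depletion equilibrium, slow exchange splits each pocket peak into
free/bound components with intensities $(1-f, f)$, and components below
the detection floor are dropped.

Deliberately not modeled: lineshapes and intermediate-exchange
broadening beyond intensity loss, peak-overlap statistics of real
spectra beyond what random positions produce, ¹H/¹⁵N chemical-shift
correlations, temperature/pH drifts, and prolines (excluded from the
default residue alphabet; the profile machinery handles them when
present). Passing the recovery tests therefore demonstrates the
pipeline's correctness under two-state thermodynamics and realistic
crowding — not robustness to every pathology of real spectra.

`simulate_structure_pair()` plants a known rigid transform plus
per-coordinate noise; the expected minimal RMSD for noise σ on one
structure is ≈ √3·σ, which the tests check to 20%.
`make_fixture_protein()` ships the published MSI2-RRM1/MSI1-RBD1 pocket
lists, shift-by-one residue correspondence and secondary-structure
ranges as data; its two sequences are *synthetic stand-ins* constrained
to the published residue identities at every listed position and ~80%
overall identity (real sequences are a user-supplied input, not
bundled).

## Structure mapping choices

Alignment is Needleman–Wunsch with affine gaps (BLOSUM62, open 10,
extend 0.5 — standard protein defaults; the gap convention is
`open + L * extend` for a gap of length L). Identity is reported over
mutually non-gap columns (`identity_fraction`) and over all alignment
columns (`identity_full`); published identity figures for homolog pairs
often differ by exactly this denominator choice, so both are kept.
Superposition is the closed-form Kabsch solution (SVD with determinant
correction to exclude reflections); near-collinear atom sets trigger a
warning because the rotation about the common axis is then undetermined
although the RMSD is still minimal. The "equivalent Cα" pairing for
homolog superposition is the mapped residues inside the structured core
(23–100 by default) present in both structures. Secondary-structure
ranges are configuration inputs, not computed: the published ranges are
shipped as a fixture, which avoids depending on a secondary-structure
algorithm for values the source states.

## Validation scale

The test suite and `scripts/acceptance.R` validate at sizes chosen to
exercise the statistics without waste: 20 independent titration seeds
for pocket recovery (recovering ≥18/19 planted residues with ≤1 false
positive), pooled exchange classification over the same runs, 200
simulated binding curves (median relative Kd error and bootstrap CI
coverage), ≥1000 short sequence pairs against a brute-force alignment
enumeration, a 1000-point log grid against a numeric equilibrium
solver, and 100 random rotations per noisy superposition fixture. All
stochastic steps derive from a single seed.

## Known limitations

- Greedy nearest-neighbour tracking is not a global assignment; it can
  mis-pair peaks in locally crowded regions. Supplying bound-state
  assignments corrects the endpoint (and the package treats them as
  authoritative), but intermediate-point mis-pairings can still bias
  the per-ratio mean CSP slightly.
- Per-residue Kd estimation from fast-exchange trajectories is out of
  scope (the target system is slow-exchange), as are lineshape analysis
  and relaxation dispersion.
- The NMR-STAR reader covers the `Atom_chem_shift` loop only; writing
  NMR-STAR and parsing mmCIF are not supported.
- Bootstrap intervals assume exchangeable residuals after inflation;
  grossly heteroscedastic or correlated noise would need a dedicated
  error model.
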