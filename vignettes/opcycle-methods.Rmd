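---
title: "Methods: cell-cycle, photobleaching and enrichment estimators in opcycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-cycle, photobleaching and enrichment estimators in opcycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opcycle)
```

`opcycle` estimates how long an oligodendrocyte precursor (OP) population
spends in each phase of the cell cycle, how mobile a tagged histone is in
its nucleus, and whether a differential set of chromatin-accessibility
peaks is enriched for transcription-factor motifs. This vignette explains
each model, its assumptions, the tunable parameters, the numerical
choices, and what the bundled simulator does and does not emulate.

## 1. Cumulative labeling

### Model and assumptions

The target is an *asynchronous, steady-state* population: each cycling
cell sits at a uniformly distributed age within a cycle of fixed phase
durations `T_G1, T_S, T_G2, T_M` (summing to `T_C`), and the counted
population size is constant — on division one daughter replaces its
parent. A fraction `G` (growth fraction) of cells is cycling; the rest
are quiescent. Under continuous label availability a cell becomes
EdU-positive when its trajectory first enters S-phase, so the labeling
index is

```
L.I.(t) = min( G · (t + T_S) / T_C , G ),
```

a line with intercept `y0 = G·T_S/T_C` and slope `m = G/T_C`, plateauing
abruptly at `G` when `t = T_C − T_S`. Inverting: `T_C = G/m`,
`T_S = y0·G/m` (`expected_li()`, `estimate_tc_ts()`).

The assumptions that matter: uniform age structure (violated shortly
after a perturbation that synchronizes cells), fixed phase durations (no
inter-cell variability), stationary population (no net growth during the
labeling window), and permanent label retention. The simulator implements
exactly this model, which is the point: it quantifies the estimator's
behavior *when its own assumptions hold*, and its bias when they are
deliberately broken (e.g. chase times that outrun G2+M; see §3).

### Fitting choices

`fit_labeling_curve()` fits the pre-plateau points by weighted least
squares:

* **Plateau exclusion.** Points with observed L.I. at or above
  `g·(1 − plateau_tol)` are excluded; `plateau_tol = 0.02` by default.
  The linear model only holds on the rise, and including plateau points
  would flatten the slope and inflate `T_C`.
* **Growth fraction resolution.** With `g = "auto"`, `G` is set to the
  maximum observed L.I. only when at least two points lie within 2% of
  it — i.e. the plateau was actually sampled. Otherwise `G` defaults
  to 1, the value measured for perinatal OP populations; a knockout
  time course that never reaches its plateau cannot identify `G` from
  the data alone.
* **Weights.** Counts are binomial, so weights are
  `n_total / (li(1 − li) + ε)` with `ε = 1/(4·n_total)`; the ridge `ε`
  keeps points at L.I. 0 or 1 at finite weight (it equals the binomial
  variance bound at p = 1/2 scaled into the denominator, so it never
  dominates an interior point).
* **Uncertainty.** Standard errors of `T_C` and `T_S` are first-order
  (delta-method) propagations using the full coefficient covariance from
  the weighted fit. This matches the `± h`-style uncertainties usually
  reported with these estimates without asserting anything stronger.
* **Degenerate inputs.** Fewer than two distinct pre-plateau times, an
  all-plateau curve, or a non-positive fitted slope raise errors naming
  the problem; a negative fitted intercept is clipped to 0 for `T_S`
  with a warning.

### Study-size choices

The stochastic validation in the test suite and acceptance script uses
20 replicate simulated studies of 500 cells per timepoint at
t = 3, 6, …, 24 h — the scale of a well-powered in-vivo labeling study
(hundreds of cells scored per animal, one litter per timepoint). At this
size the median recovered `T_C` sits within a few percent of the planted
76.6 h; the residual upward bias (≈2–4%) is real and instructive — noise
on a reciprocal (`T_C = G/m`) is skewed — and is one of the things the
simulator exists to make visible.

## 2. Mixture correction for incomplete recombination

Cre recombination reaches only 75–85% of the target population, so a
conditional-knockout average mixes knockout and wild-type-like cells.
Two corrections are implemented, and they answer different questions:

* **Arithmetic** (`correct_mixture_arithmetic()`): treats the measured
  average cycle time as a weighted arithmetic mean of subpopulation
  cycle times: `(T_avg − (1−f)·T_wt)/f`. With `T_avg = 179`,
  `f = 0.8`, `T_wt = 77` this gives 204.5 h (reported as 205 h).
* **Slope-consistent** (`correct_mixture_harmonic()`): the labeling
  curve of a mixture has slope `Σ wᵢ gᵢ/T_Cᵢ` (weights mix *rates*, not
  durations), so an average obtained by inverting a fitted slope should
  be corrected on the rate scale:
  `T_ko = f·g / (m_avg − (1−f)·g/T_wt)`. Applied to `m_avg = 1/179`
  this gives ≈268 h — a larger correction, because slow cells are
  under-represented in a fitted slope.

Which is "right" depends on how the average was computed upstream. The
arithmetic form is the package default for reports because it operates
directly on the quantity practitioners tabulate (a cycle time); the
harmonic form is provided for slope-level analyses, and the two agree at
`f = 1` (an invariant the tests assert). Both raise an
inconsistent-mixture error when the requested correction implies a
non-positive knockout cycle time.

## 3. G2 and G1

The Methods literature for the labeled-mitoses ("percent labeled
mitoses") approach gives, for an instantaneous pulse and chase `t`,
`f_pH3 = (t − T_G2)/T_S` while the labeled front is inside M. The package
inverts this as

```
T_G2 = t_chase − f_pH3 · T_S     (estimate_g2)
```

**This reconstruction is a design decision, flagged prominently**: the
source analyses report G2 values without printing the formula, and this
is the standard labeled-mitoses inversion that reproduces both reported
values (1.8 h and 3.0 h) from the printed pH3+ fractions. Its validity
window matters:

* exact while `t_chase ≤ T_G2 + T_M` (simulator check: bias < 1 h at
  10,000 cells);
* upward-biased once labeled mitoses have had time to divide
  (`t_chase > T_G2 + T_M` deflates `f_pH3`); the simulator confirms the
  bias direction;
* at `f_pH3 = 0` the chase time is only a *lower bound* on G2 and the
  result is flagged as such;
* `f_pH3 · T_S > t_chase` clips to 0 with a warning flag rather than
  returning a negative duration.

G1 follows by subtraction, `T_G1 = T_C − T_S − T_G2 − T_M`
(`estimate_g1`). `T_M` defaults to 0 — pulse-chase counts at these chase
times cannot separate M from G1 — so the G1 estimate is documented as an
upper bound. Negative results raise an inconsistent-durations error.

The pH3+ fraction is computed among EdU+ cells (the ratio used in the
quantitative text), not among all OLIG2+ cells.

## 4. The simulator

`simulate_cohort()` draws the steady-state age structure directly:
subpopulation by weight, cycling status by growth fraction, cycle
position uniform on `[0, T_C)`. `run_cumulative_edu()` and
`run_pulse_chase()` are then *deterministic* given the cohort — a cell
labels iff its forward distance to S-phase is within the label window,
and is pH3+ iff its advanced position (modulo `T_C`) lies in M. All
randomness therefore lives in one place, and both experiment simulators
are exactly reproducible from the cohort seed.
`simulate_labeling_experiment()` mirrors the in-vivo design of one
independent cohort (litter) per timepoint, deriving one child seed per
timepoint from the run seed.

Choices, and what is *not* modeled:

* **Division rule.** One daughter is retained per division, keeping the
  counted population stationary — required for the linear model's
  validity. This is an analysis assumption, not a claim about biology:
  a perinatal OP population actually grows, and both daughters of a
  labeled division carry label. The estimators' behavior under
  population growth is precisely the kind of question the simulator
  could probe, but growth is not implemented.
* **EdU availability.** Cumulative labeling uses a continuous window
  (`pulse_window = Inf`); pulse-chase uses an instantaneous pulse
  (`pulse_window = 0`). In-vivo bioavailability after a single injection
  is somewhere in between and unmeasured, which is why the window is a
  parameter rather than a constant.
* **pH3 positivity** spans exactly M-phase; no partial-phase
  immunoreactivity or antibody-sensitivity effects.
* No spatial structure, mitogen consumption, contact inhibition, or
  cell-to-cell variation in phase durations. Passing tests therefore
  demonstrate correctness of the estimators *under the stated model*,
  not robustness to every way real tissue departs from it.

Invariants asserted in the suite: age-uniformity of cycle positions
(Kolmogorov–Smirnov distance below `3·√(ln 2 / n)` at n = 10,000),
pointwise agreement of simulated labeling with the closed form within 3
binomial standard errors, population-size constancy, and determinism per
seed.

## 5. Photobleaching: FRAP and FLIP

### Normalization

`normalize_frap()` applies double normalization then full-scale
normalization:

1. background-subtract the bleach and reference ROIs;
2. divide bleach by reference and scale the pre-bleach mean to 1 — any
   acquisition bleaching *shared* by the two ROIs cancels in this ratio
   (asserted to 1e-12 in the tests);
3. full-scale: subtract the first post-bleach value and divide by one
   minus it, so the series runs from 0 (just after the bleach) toward 1
   (complete recovery).

Degenerate inputs raise errors: a reference that does not exceed
background anywhere, or a "bleach" frame that is not actually below the
pre-bleach mean. The bleach frame can be supplied or auto-detected as
the largest single-frame drop in the bleach ROI.

### Fitting

The exchange model is a single exponential — the analyses this package
supports report only a mobile fraction, `T½` and `R²`, which a
diffusion-reaction model would over-parameterize. `fit_recovery()` fits

```
dn(t) = d0 + a · (1 − exp(−k·t))
```

on the *double-normalized* series with the bleach depth `d0` free, and
reports `mobile_fraction = a / (1 − d0)` and `t_half = ln 2 / k`. On
noise-free data this is bit-identical to fitting `A·(1 − exp(−k·t))` on
the full-scale series. On noisy data it is substantially more precise,
for a mechanical reason worth recording: full-scale normalization anchors
the series to the *single* first post-bleach frame, so that frame's
measurement error rescales the entire series and propagates
one-for-one into the fitted plateau. Estimating the depth from every
frame removes that error channel; at 5% frame noise it is the difference
between ~7% and ~2–4% RMSE on the mobile fraction.

Numerical choices:

* **Rate location.** A separable profile search first: for each of 50
  log-spaced candidate rates between `ln 2/(20·t_max)` and
  `ln 2/(2·Δt)`, the linear parameters `(d0, a)` have a closed-form
  least-squares solution; the best candidate seeds a
  Levenberg–Marquardt polish (`minpack.lm::nlsLM`, `ftol = 1e-10`, at
  most 10,000 evaluations). Single-start exponential fits of noisy
  recoveries otherwise fall into ridge solutions (tiny `k`, runaway
  amplitude).
* **Identifiability guard.** If the polished rate satisfies
  `k·t_max ≤ 0.2`, the asymptote lies far beyond the acquisition
  window; the fit is flagged `k_identifiable = FALSE` and the mobile
  fraction is reported from the observed late plateau rather than the
  extrapolated asymptote. Flat series short-circuit to mobile fraction
  0 with the same flag. Optimizer failures set `converged = FALSE`;
  nothing is raised.
* **Reporting.** The mobile fraction is clipped to `[0, 1.05]` (small
  overshoot tolerated); the raw value is kept in
  `mobile_fraction_raw`. `t_half·k = ln 2` holds exactly for every
  converged fit.

`analyze_flip()` fits `immobile + mobile·exp(−k·t)` to the
double-normalized *distal*-ROI series of a FLIP acquisition (continuous
bleaching elsewhere in the nucleus drains the mobile pool). FRAP and
FLIP mobile fractions from the same ground truth agree within 0.03 at
zero noise, an invariant in the suite.

The trace generator plants ground truth (`frap_sim_params`): mobile
fraction, rate, bleach depth (default 0.3), shared acquisition-bleach
rate, Gaussian frame noise as a fraction of the pre-bleach signal, and
the acquisition geometry (default 10 pre-bleach frames, 124 post-bleach
frames at 2 Hz, matching a typical confocal protocol). It does not model
diffusion within the bleached spot, photophysics (blinking,
reversible dark states), or cell movement. The validation grid —
mobile fractions 0.1–0.9, noise 0, 0.01 and 0.05, 20 seeds per cell —
bounds the bias at zero noise below 0.005 and the RMSE at 5% noise below
0.05. The chromatin-bound benchmark conditions (73% bound for control,
33% for knockout chromatin) are recovered from 20 noisy traces each with
mean absolute error below 0.02.

## 6. Peak and gene-set enrichment

`fold_enrichment()` computes the occurrence-fraction ratio
`(k_fg/n_fg)/(k_bg/n_bg)` with:

* a **one-sided** exact test (`P(X ≥ k_fg)` at fixed 2×2 margins,
  computed with the hypergeometric tail) — one-sided because the
  scientific question is enrichment of a motif in down-regulated peaks;
  the tests verify agreement with brute-force enumeration over all
  tables with total count ≤ 30 and with `fisher.test`;
* a 95% CI from the log-ratio normal approximation with variance
  `1/k_fg − 1/n_fg + 1/k_bg − 1/n_bg`;
* `fold = Inf` flagged (not raised) when the background count is zero.

`enrich_motifs()` maps this over the motif columns of a foreground and a
background peak table and adds Benjamini–Hochberg adjusted p-values; the
source analyses are silent on multiplicity, so raw and adjusted values
are reported side by side. The background defaults to whatever peak set
the caller supplies — typically all non-foreground peaks; whether that
should exclude peaks changed in the other direction is a question for
the caller, not the statistic. Folds are printed to one decimal,
matching the conventional "~1.7-fold" precision; machine output keeps
full precision.

`set_overlap_test()` gives the hypergeometric upper tail for gene-set
overlap, the expected overlap `n_a·n_b/N`, and the Jaccard index.

Motif scanning itself is out of scope: the package consumes peak tables
already annotated with boolean motif columns (and
`generate_peak_universe()` produces synthetic ones with planted
occurrence probabilities for validation).

## 7. Reporting conventions

Durations are in hours, times in photobleaching in seconds, fractions in
`[0, 1]` internally with percent only at input/output boundaries. Report
strings round durations to one decimal below 10 h and to the nearest
integer above (half-up, with a one-nanohour epsilon so values computed
as x.4999… by floating point round as intended). JSON machine output is
written at full (15 significant digit) precision; every simulated table
is accompanied by a sidecar JSON recording the seed and generator
parameters. Stochastic runs derive all child seeds deterministically
from one integer run seed.

## 8. Known limitations

* The linear cumulative-labeling framework is the analysis target, not a
  gold standard: it ignores population growth, double-labeled daughters
  and duration variability, and the simulator shares the first two
  omissions by design (it implements the model, so it validates the
  estimators, not the model).
* The G2 estimator's formula is a reconstruction (see §3) and is only
  exact within its validity window.
* FRAP/FLIP fits assume one freely exchanging pool; genuinely
  multi-component recoveries will show as depressed `R²` rather than
  being resolved.
* The mixture corrections assume the unrecombined subpopulation cycles
  exactly like wild type and that the recombined fraction is known; both
  are approximations in real conditional knockouts.
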