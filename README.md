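# opcycle

Cell-cycle kinetics of oligodendrocyte precursor (OP) populations, from
labeling time courses, photobleaching assays and chromatin-accessibility
peak sets.

Proliferating OPs are the main dividing cell population of the developing
CNS white matter, and perturbations of chromatin remodeling (e.g. loss of
the INO80 complex) slow their division cycle dramatically — almost
entirely by stretching G1. Quantifying *which* phase of the cycle changes
requires several estimators that are individually simple but easy to get
subtly wrong: cumulative-labeling regression, correction for mixed
(recombined/unrecombined) populations in a conditional knockout,
labeled-mitoses G2 estimation, photobleaching curve fits, and enrichment
statistics on differential peak sets. `opcycle` implements all of them,
together with a seeded simulator that generates every input the
estimators consume, so each estimator can be validated against planted
ground truth.

## The models

**Cumulative labeling.** Under continuous EdU availability, the labeling
index of an asynchronous steady-state population rises linearly,

    L.I.(t) = y0 + m·t,   until the plateau  L.I. = G,

where G is the growth fraction (fraction of cells cycling). The cycle
time and S-phase duration follow as

    T_C = G / m,    T_S = y0 · G / m.

`fit_labeling_curve()` fits the pre-plateau points by weighted least
squares (inverse binomial variance weights) and returns a `cumlab_fit`
object with delta-method standard errors on T_C and T_S.

**Mixture correction.** When a fraction `f_rec` of the population carries
the knockout and the remainder cycles like wild type with cycle time
`T_C,wt`, the population-average estimate understates the knockout cycle
time. Treating the measured average as a weighted arithmetic mean,

    T_C,ko = (T_C,avg − (1 − f_rec) · T_C,wt) / f_rec.

A slope-consistent alternative (the labeling-curve slope of a mixture is
the weighted sum of subpopulation slopes) is provided as
`correct_mixture_harmonic()`.

**G2 from labeled mitoses.** After an instantaneous EdU pulse and a chase
of `t_chase` hours, the fraction of EdU+ cells that are in mitosis (pH3+)
is `(t_chase − T_G2)/T_S` while the labeled front is inside M, so

    T_G2 = t_chase − f_pH3 · T_S,

and `T_G1 = T_C − T_S − T_G2 − T_M` (an upper bound with `T_M = 0`).

**Photobleaching.** FRAP/FLIP traces are double-normalized (background
subtraction, reference-ROI ratio, pre-bleach scaling — which cancels
acquisition bleaching) and fitted with a single-exponential exchange
model; the recovery amplitude is the mobile (unbound) fraction of the
tagged histone and `T½ = ln 2 / k`.

**Peak enrichment.** Motif fold enrichment between a differential peak
set and a background set, `(k_fg/n_fg)/(k_bg/n_bg)`, with a one-sided
exact test, log-ratio confidence interval and BH correction across
motifs; plus a hypergeometric test for gene-set overlap.

## Worked example

```r
library(opcycle)

# simulate a cumulative-labeling study at the control condition
spec <- population_spec(phase_durations(t_g1 = 61.3, t_s = 13.5, t_g2 = 1.8))
d <- simulate_labeling_experiment(spec, times = seq(3, 24, 3),
                                  n_per_time = 500, seed = 1)
summary(fit_labeling_curve(d, g = 1))
#> Cumulative-labeling fit
#>   m  = 0.012607 /h   y0 = 0.191544   G = 1 (fixed)
#>   T_C = 79 h   T_S = 15 h
#>   se(m) = 0.000783, se(y0) = 0.0113
#>   T_C = 79.32 +/- 4.93 h,  T_S = 15.19 +/- 1.79 h
#>   points used: 8 of 8
```

The planted truth was T_C = 76.6 h, T_S = 13.5 h: 500 cells per timepoint
recover the cycle time to within its standard error. The remaining
headline quantities are closed-form:

```r
correct_mixture_arithmetic(179, 0.8, 77)   # 204.5  -> reported "205 h"
estimate_g2(4, 0.165, 13.5)                # 1.7725 -> reported "1.8 h"
estimate_g2(4, 0.060, 16.7)                # 2.998  -> reported "3.0 h"
estimate_g1(76.6, 13.5, 1.8)               # 61.3 h (upper bound on G1)
estimate_g1(179, 16.7, 3)                  # 159.3 h

fold_enrichment(100, 1000, 100, 10000)
#> 10.0-fold enrichment (10.0% vs 1.0%), one-sided exact p = 1.17e-51
#>   95% CI on fold: [7.64, 13.09]

# photobleaching: recover a planted mobile fraction from a noisy trace
tr <- generate_frap_trace(frap_sim_params(0.27, 0.1, noise_sd = 0.01), seed = 1)
fit_recovery(tr)
#> FRAP fit: mobile fraction = 0.265, T1/2 = 7.12 s, R^2 = 0.9511
```

A mobile fraction of 0.27 corresponds to 73% of the histone bound to
chromatin — the control condition; the knockout condition plants 0.67
mobile (33% bound).

There is also a small command line (`inst/cli/opcycle.R`) with
subcommands `simulate`, `fit-cumulative`, `g2`, `mixture`, `frap`,
`flip`, `enrich`, `overlap` and `demo`; `demo` recomputes every worked
example above and prints a pass/fail table.

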