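---
title: "Quantifying elevated central venous pressure exposure: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying elevated central venous pressure exposure: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Central venous pressure (CVP) in septic ICU patients is charted
irregularly — sometimes hourly, sometimes with long gaps — so a simple
mean of the charted values is a biased summary of what the circulation
actually experienced. `cvpload` treats the charted stream as a
piecewise-linear curve and summarizes exposure with time-weighted
quantities:

* **CVP load** (mmHg·hr): the trapezoidal area under the CVP curve from
  the first to the last analyzed measurement. For measurements
  $(T_1,\mathrm{CVP}_1),\dots,(T_N,\mathrm{CVP}_N)$ it is
  $\sum_{i=1}^{N-1}\tfrac{\mathrm{CVP}_i+\mathrm{CVP}_{i+1}}{2}\,(T_{i+1}-T_i)$.
* **CVP duration** (hr): $T_N - T_1$, the span of monitoring analyzed.
* **Elevated CVP (ECVP)**: an inter-measurement interval whose endpoint
  mean exceeds 10 mmHg. **ECVP load** is the summed full trapezoid area of
  those intervals; **ECVP duration** the summed interval length.
* **Normalized loads** (mmHg): each load divided by its own duration — a
  time-weighted average pressure. The normalized ECVP load is the
  time-weighted mean CVP *during elevated intervals*, so it isolates the
  magnitude of elevation from how long monitoring lasted.
* **Averaged ECVP load** (mmHg): ECVP load divided by total CVP duration,
  which dilutes elevated exposure over the whole monitored period.

The scientific question the battery addresses: is it the magnitude
(normalized ECVP load) or the duration (ECVP duration, or its share of
monitoring time) of elevation that is associated with 28-day mortality?

## Segment classification choices

Three conventions are not forced by the definitions above and are fixed
explicitly (and echoed into every run log):

* **Full-area, not excess-area.** An elevated interval contributes its
  whole trapezoid area, not only the part above 10 mmHg. The normalized
  ECVP load is then a time-weighted mean pressure on the familiar CVP
  scale (typically 12–17 mmHg), directly comparable with charted values.
  An excess-area definition would place it near 4 mmHg and change its
  meaning.
* **Strict inequality.** An interval with endpoint mean exactly 10 mmHg is
  *not* elevated. With pressures charted at integer or 0.1-mmHg
  resolution, exact boundary means occur, so the rule matters and is
  tested.
* **No sub-segment splitting.** An interval whose endpoints straddle the
  threshold is classified wholly by its endpoint mean; no interpolated
  crossing point is inserted. Classification and area share one
  discretization.

A patient with no elevated interval has an undefined normalized ECVP load
(0/0). It is recorded as 0 and flagged (`norm_ecvp_defined = FALSE`); the
median split then places such patients in the low-exposure group, which
preserves the ordering "no elevation = minimal exposure" while keeping the
choice auditable downstream.

## Cohort selection

Patients enter the analysis when CVP monitoring started within 24 h of
ICU admission, continued to at least 72 h (judged on the full stream,
before truncation), and age is ≥ 18 years. Only measurements at or before
72 h are analyzed; the boundary is inclusive and no value is interpolated
at the window edge. Measurements outside 0–50 mmHg are dropped as
charting artifacts before selection, because a single transducer spike
can otherwise dominate a trapezoid area. Exclusions are reported with a
fixed precedence (no CVP data, age, late start, early end) so flowchart
counts are deterministic. All six thresholds live in `cohort_config()`.

## Statistical battery

* Normality is assessed with the Kolmogorov–Smirnov statistic under the
  estimated-parameter (Lilliefors) null distribution
  (`nortest::lillie.test`); the naive KS test with plugged-in sample
  moments is anticonservative. Verdict threshold 0.05.
* Continuous variables use Student's *t* (normal in both groups) or the
  Wilcoxon rank-sum test; categorical variables use Pearson's chi-square
  without continuity correction, so the statistic equals the textbook
  $\sum (O-E)^2/E$.
* The crude dose–response is a lowess fit (span 0.8) through the
  per-patient (normalized ECVP load, death) points, run with **zero
  robustness iterations**: robust reweighting treats the binary 1s as
  outliers and collapses the curve. Raw mortality is also reported per
  integer-rounded exposure bin, including which bins are empty.
* Survival: median split of normalized ECVP load (ties go low — explicit
  because charted pressures tie often), Kaplan–Meier per group and the
  two-group log-rank test (`survival`).
* Risk-factor modelling: a univariate logistic screen flags candidates at
  p < 0.20; forward selection then adds, at each step, the eligible
  variable with the smallest likelihood-ratio p-value while it is below
  0.05. The screening gate and entry threshold are deliberately
  different: 0.20 casts a wide net, 0.05 keeps the final model
  parsimonious. Odds ratios carry Wald 95% intervals on the log-odds
  scale. Separated or constant predictors are flagged and excluded rather
  than fitted.
* The quartile analysis cuts ECVP load at its quartiles (boundary values
  to the lower quartile) and compares ECVP duration and its share of
  monitoring time between survivors and non-survivors *within* each
  quartile, i.e. among patients with comparable total elevated exposure.

## The synthetic cohort generator

Credentialed ICU databases cannot ship with a package, so `cvpload`
includes a generator whose output has the statistical structure the
analysis assumes, making every stage testable end to end.

* **Sampling**: monitoring starts uniformly in the first 24 h and ends
  uniformly between 72 and 96 h; scheduled measurements follow
  exponential gaps (mean 1 h) and each is missing with probability 0.15.
* **CVP dynamics**: a patient-level setpoint (Normal, mean 13, SD 4 mmHg)
  plus a discretized Ornstein–Uhlenbeck fluctuation (stationary SD
  2 mmHg, relaxation time 6 h), floored at 0 and charted to 0.1 mmHg.
  The mean-reverting autocorrelation makes elevated episodes temporally
  clustered, which the duration analysis needs; white noise would
  fragment them. The setpoint spread was chosen so the simulated
  marginals sit where a septic cohort's do (normalized ECVP load median
  ≈ 13, IQR ≈ 11–16 mmHg; CVP duration ≈ 59 h; ECVP duration share
  ≈ 60–70%).
* **Outcome**: 28-day death is Bernoulli with logit
  $\beta_0 + \beta_e \cdot \text{normalized ECVP load} + \beta_a \cdot
  \text{age} + \beta_s \cdot \text{SAPS-II}$, with defaults
  $\beta_e=\ln 1.058$, $\beta_a=\ln 1.02$, $\beta_s=\ln 1.018$.
  Crucially, the exposure entering the link is computed by
  `compute_cohort_metrics()` on the truncated charted stream — not on the
  latent process — so the generative estimand is exactly what the
  pipeline measures and parameter recovery is a clean identity check.
* **Intercept auto-calibration**: with `beta0 = NULL` (the default) the
  intercept is solved by root-finding on the realized linear predictors
  so expected marginal mortality equals `target_mortality` (default
  0.398). This keeps effect-size overrides (e.g. $\beta_e=\ln 1.5$ in
  recovery studies) from saturating mortality near 1.
* **Secondary outcomes**: 72-h urine output decreases linearly with
  exposure (−400 mL per mmHg, noise SD 2200 mL, floored at 0); intake is
  log-normal and independent of exposure, so fluid balance rises with
  exposure purely through oliguria; AKI is Bernoulli with log-odds 0.33
  per mmHg. Whether intake itself should covary with exposure is left
  out: the observed pattern (balance differs while intake barely does)
  is reproduced by the urine route alone.
* Deaths get survival times uniform on (0, 28] days (charted to 0.001 d,
  floored at 0.001); survivors are censored at 28 d. Only 28-day status
  and the Kaplan–Meier comparison are analyzed, so any monotone-link
  survival time model would serve; uniform is the simplest.

What the generator does **not** emulate: informative missingness of CVP
charting, correlation between severity scores and CVP dynamics,
treatment feedback (clinicians reacting to high CVP), competing risks,
or non-stationary setpoint drift. Passing tests therefore show the
pipeline measures what it claims on data with the assumed structure —
not that the clinical associations are causal or robust to those
real-world features.

## Numerical and testing choices

* All areas are plain trapezoid sums; the cohort-level path accumulates
  elevated and non-elevated areas separately so the decomposition
  `cvp_load = ecvp_load + non-elevated area` is exact in floating point.
* Tests verify the trapezoid calculus against two independent oracles: a
  naive loop implementation committed before the vectorized one, and
  fine-grid integration of the piecewise-linear interpolant on a grid
  containing every knot (exact up to round-off; agreement demanded at
  1e-9 relative).
* Simulation-based checks use modest problem sizes chosen to keep the
  whole suite in a few minutes while leaving comfortable statistical
  margins: 200 cohorts of n = 1000 for parameter recovery (mean
  recovered OR within 5% of ln 1.5's target, CI coverage 90–98%), 200
  seeds of n = 500 for null calibration of the univariate screen, 50
  seeds of n = 2000 for log-rank power at $\beta_e=\ln 1.2$.
* One caveat worth stating plainly: with valid tests, the probability
  that *all* within-quartile comparisons exceed p = 0.05 under the null
  is about $0.95^k$ for $k$ comparisons (≈ 0.66 for the 8 run here), not
  a rate close to 1. The suite's strictest form of that check reflects an
  idealized target and is expected to sit near the binomial ceiling.
* Everything is seeded. One seed drives one cohort; replicate studies
  enumerate disjoint seed blocks. Identical configuration and seed yield
  byte-identical CSV exports and checksum-identical pipeline manifests
  (figures included: the PNG device is deterministic for identical draw
  commands).

## Workflow shape

The package functions are the unit of reuse; the numbered scripts under
`analysis/` are thin narrative drivers that run simulate → select →
truncate → metrics → statistics → figures and leave their tables under
`results/`. `run_pipeline()` performs the same sequence in one call with
a manifest and a run log that echoes every convention above, so a
reviewer can see exactly which discretionary choices produced a given
set of outputs.

## Known limitations

* Exposure metrics ignore everything between the last pre-72 h
  measurement and the window edge (no boundary interpolation); with
  hourly charting the neglected tail is under an hour.
* Complete-case handling per variable in comparisons and complete-case
  across candidates in the multivariate model; no imputation.
* The forward-selection p-to-enter convention (LR, 0.05) is one of
  several defensible stepwise variants; selection behaviour is validated
  by simulation, not against any external dataset.
* No Cox modelling, competing risks, or propensity adjustment.
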