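---
title: "A harm-benefit model of kidney transplant wait-list eligibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A harm-benefit model of kidney transplant wait-list eligibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txbenefit)
```

## The question and the model

Eligibility discussions for the deceased-donor kidney wait list usually rest
on net life-years gained, which makes transplantation look beneficial for
essentially every group. This package takes a different, proportion-based
view: for a candidate with baseline mortality rate MR (deaths per 100
patient-years), what are the probabilities that listing ends in *no benefit*
(death on the list), *harm* (transplanted, but dead before the transplant
has repaid its early risk in cumulative life years), or *benefit*?

The assumptions, deliberately minimal:

* **Exponential wait-list survival.** A fixed annual hazard `m = MR/100`,
  so `S_wl(t) = exp(-m t)` and life expectancy is `1/m = 100/MR` years.
  Constant hazard is a simplification — real dialysis mortality rises with
  age (Gompertz-type) — and it flatters transplantation at long horizons;
  the model is therefore conservative about projected harm.
* **Piecewise-constant relative risk after transplant.** The transplant
  arm's hazard is `r(t) * m` with `r(t)` stepping through an increased-risk
  period (surgery, early immunosuppression), an equivalent-risk period, and
  an open-ended reduced-risk period. Profiles may have any number of
  segments; the final one is open-ended.
* **Deterministic waiting time** `w`: everyone who survives `w` years on
  the list is transplanted at exactly `w`. Stochastic waiting, list removal
  and competing non-death exits are out of scope.
* **Fixed MR over time**, and an increased-risk period whose magnitude and
  duration do not vary with MR.

Two characteristic times drive everything. The *time to equal percent
survival* is where the survival curves cross, i.e. where the cumulative
relative-risk exposure `∫ r(u) du` equals `t`; both cumulative hazards are
proportional to `m`, so this time depends only on the profile. The *time to
equal cumulative life years* `t*` is where the restricted areas under the
two survival curves balance — later than the crossing, and the clinically
meaningful boundary: a transplanted patient dying before `t*` has lived
less, in expectation, than if the organ had gone elsewhere.

```{r characteristic-times}
pub <- rr_profile_preset("published")
time_to_equal_survival(pub)
time_to_equal_life_years(pub, m = 0.15)
```

## Parameters and presets

The three-period profile uses r = 2.26 (first 0.2 y), 1, and 0.44, values
calibrated against an elderly (70+) deceased-donor cohort with 4-year
survival of 66% transplanted vs 51% wait-listed and curves crossing between
1.5 and 2 years. Two presets are shipped:

* `"published"` — equal-risk period of 0.8 y (reduced risk from 1.0 y).
  Its closed-form crossing time is 1.45 y, slightly before the 1.5–2 y
  window.
* `"extended"` — equal-risk period of 1.0 y (reduced risk from 1.2 y),
  crossing at 1.65 y. This variant reproduces the reported outcome tables
  to within ±3 percentage points in every harm/benefit cell and is the
  default in `scenario()`.

Neither preset reproduces every published number exactly; the source
analysis's internal implementation is not recoverable from its stated
parameters, and we surface rather than patch the gap (see the calibration
section). Where the two presets disagree materially (the baseline
equivalence mortality rate: ≈ 34.6 continuous under `"published"`, ≈ 30.8
under `"extended"`, against a reported 28), both are available and the
discrepancy is documented instead of being tuned away.

Hold status: a fraction `p` of the list is inactive with `rho = 2.2`-fold
mortality and is never transplanted. Relative risks quoted against the
whole list are re-expressed against the active comparator by the mixture
factor `(1 - p) + p * rho` (1.24 at `p = 0.2`). By default only the
increased- and reduced-risk periods are scaled — the equivalent-risk period
is pinned at 1 by construction — with `scale_equal_segment = TRUE` available
as a sensitivity analysis. Unrounded products (2.8024, 0.5456) are carried
through computation; 2.8 and 0.55 are display roundings.

## Numerical choices

* All survival, hazard and restricted-AUC quantities are exact segment
  algebra; no quadrature anywhere in the computation path. The test suite
  checks the closed forms against trapezoid Riemann sums (step 1e-4) to
  1e-8.
* `t*` is found by bracketing upward from the survival crossing (doubling,
  capped at `200/m` with a typed `no_catchup` condition) and bisecting the
  exact AUC difference to below 1e-13 — comfortably inside the 1e-10 root
  tolerance the tests assert.
* Crossing-time conventions: identical curves (all `r = 1`) and profiles
  that never accumulate excess hazard return 0; cumulative hazards that
  touch without crossing return the touch point; a persistent excess
  signals `txbenefit_no_crossing` rather than returning a sentinel.
* The integer-grid equivalence search returns the largest integer MR with
  `P(benefit) >= P(harm)` after verifying that the benefit share is
  monotone decreasing over the grid; the continuous mode solves
  `S_tx(t*(m)) = 1/2` on MR in [5, 60]. Waiting time cancels out of the
  harm:benefit odds — `exp(-m w)` scales both — which the tests assert to
  1e-12.
* Display rounding is half-away-from-zero (whole percents; one decimal for
  times and life expectancies; two significant figures for ratios),
  matching the tables' formatting; `round()`'s half-to-even would disagree
  on exact halves.

## Calibration

`fit_relative_risks()` inverts the anchor set exactly: `m` from the
wait-list anchor, then `r1` and `r3` from a 2×2 linear system (equal
cumulative hazard at the observed crossing; transplant survival at the
horizon), with the equivalent-risk ratio fixed — the period boundaries are
assumptions, not free parameters, which keeps the system exactly
determined. Because it is exactly determined, the once-considered
least-squares mode over an (r1, r3) grid has no reachable input and was not
built; misfit is made visible instead through implied anchors and
residuals. Fitting the anchor triple (51%, 66%, 1.6 y) returns
r1 ≈ 2.915, r3 ≈ 0.362 — not the quoted 2.26/0.44, whose own implied
anchors are 64.9% and 1.45 y:

```{r calibration}
fit_relative_risks(calibration_targets(0.51, 0.66, 1.6, horizon = 4))
implied_anchors(pub, fit_baseline_mr(0.51, 4))
```

The quoted triple and the quoted anchors are mutually inconsistent under
this model family; the calibrator reports the residual rather than
resolving it. Parameter recovery is exact (to 1e-10) whenever the anchors
are generated from the forward model.

## The microsimulation as synthetic data and stochastic oracle

`run_microsim()` draws, per patient and in a fixed order, a death-on-list
time (exponential), a post-transplant death time (exact inverse of the
piecewise-linear cumulative hazard — no rejection), and a counterfactual
wait-list residual used for the paired restricted-life-year comparison at
`t*`. It emulates exactly what the closed forms assume: fixed hazards,
deterministic waiting, no drop-out. Passing tests therefore validate the
mathematics, not the realism of the model — features of real registries
(time-varying hazards, removal from the list, organ-quality strata,
informative hold status) are absent by design. Cohort sizes used in the
checked runs are 2×10⁵ in the unit tests and 10⁶ in the end-to-end
convergence check; at 10⁶ all three empirical probabilities sit within 3
binomial standard errors of the closed forms and the paired life-year
difference at `t*` is statistically zero, which is the stochastic
confirmation of the AUC-equality root. The per-patient event table is
exportable CSV, so the simulator doubles as a synthetic-data generator.

## Known limitations

Beyond the structural simplifications above: no quality-of-life weighting,
no net-life-year or number-needed-to-treat accounting, no
expanded-criteria-donor strata, and no dependence of the early-risk period
on baseline mortality — all of which would tilt the balance further toward
harm for high-mortality candidates, so the reported harm probabilities are
best read as lower bounds within the model family.
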