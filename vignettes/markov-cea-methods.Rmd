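---
title: "Model and methods: cost-effectiveness of adjuvant osimertinib"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: cost-effectiveness of adjuvant osimertinib}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osicea)
```

## The decision problem

Three years of adjuvant osimertinib after resection of EGFR-mutant
non-small-cell lung cancer delays recurrence dramatically, but at a drug
price above $200,000 per year and — so far — without mature overall-survival
evidence. The package implements the standard health-economic answer to
"is that worth it?": a two-arm cohort-level Markov model that converts the
trial's disease-free survival (DFS) benefit, an *assumed* overall-survival
benefit, costs, and health-state utilities into discounted
quality-adjusted life years (QALYs) and dollars per arm, summarized as the
incremental cost-effectiveness ratio (ICER) against a $195,000/QALY
willingness-to-pay threshold (three times US GDP per capita).

## Health states and transitions

Four states: no evidence of disease (`NED`), progressive disease without
CNS involvement (`PD_CNSneg`), progressive disease with CNS involvement
(`PD_CNSpos`), and absorbing `Death`. Everyone starts in `NED`. All times
are in **years**; the default cycle length is one month.

DFS in each arm is described by two fitted log-normal distributions, one
for CNS-positive and one for CNS-negative disease (all on the log-time
scale, time in years):

| arm, CNS status | meanlog | sdlog |
|---|---|---|
| placebo, CNS+ | 1.94 | 1.22 |
| placebo, CNS− | 1.11 | 1.44 |
| osimertinib, CNS+ | 2.66 | 0.91 |
| osimertinib, CNS− | 2.19 | 1.13 |

The time unit must be years: the implied medians (e.g. `exp(1.11)` ≈ 3.0
years for CNS-negative placebo DFS, `exp(1.94)` ≈ 7.0 years for the rarer
CNS-positive events) are only clinically coherent on that scale given the
trial's 19.6-month pooled placebo median DFS.

Each DFS *event* is split between recurrence (entering the matching PD
state) and death using the trial's printed event counts — 33/39 (CNS+) and
118/120 (CNS−) recurrences in the placebo arm, 4/6 and 31/31 in the
osimertinib arm. The fractions are always recomputed from the integer
counts. Background (non-disease) mortality for a 63-year-old US male is a
configurable annual probability, default 0.012/yr; it is a sensitivity
parameter, not a trial quantity.

Post-progression survival follows a gamma distribution with shape 1.86 and
**rate** 0.56 per year, fitted to reconstructed overall survival of
EGFR-TKI-treated metastatic disease. The rate (not scale) reading is a
deliberate, calibrated choice: it implies a mean post-progression survival
of 1.86/0.56 ≈ 3.3 years, consistent with observed metastatic outcomes,
and it reproduces the published placebo cost profile, whereas the scale
reading (mean ≈ 1.0 year) is far off on both counts. The assumed 5%
overall-survival benefit of osimertinib is a hazard ratio of 0.95 applied
multiplicatively to the post-progression cumulative hazard; the
deterministic sweep varies the risk reduction from 0 to 45%.

Post-progression mortality and the two-year re-treatment window depend on
*time since progression*, not model time. The engine therefore expands each
PD state into cycle-indexed tunnel sub-states internally and aggregates
them back to the four reported states in the trace. Conditioning on time
since progression is the clinically coherent reading (a patient who
progresses in year 6 is not already three years into their metastatic
survival curve).

### Two NED-exit structures

How the two DFS distributions jointly empty the `NED` state is genuinely
open, and the package implements both readings:

* **`competing`** — both processes contend within every cycle as competing
  risks for the whole cohort. Marginal per-cycle probabilities are
  converted to hazards, summed (with background mortality), and the joint
  exit probability is allocated proportionally to the cause-specific
  hazards. `build_transition_matrix()` exposes exactly this row.
* **`stratified`** (default) — the cohort is split once, at baseline, into
  a CNS-positive-destined stratum and a CNS-negative stratum, with weights
  equal to each arm's share of CNS-positive DFS events (39/159 placebo,
  6/37 osimertinib); each stratum leaves `NED` by its own distribution.
  This matches reading the two fitted curves as subgroup-specific DFS
  rather than cause-specific incidence.

The two structures bracket the plausible interpretations. Under competing
risks the joint NED-exit hazard is the sum of the two and the placebo
cohort recurs with a median near 2.0 years; under stratification the
mixture survival is heavier-tailed. Calibrating against the published
base-case results decides the default: the stratified structure reproduces
the published per-arm QALYs (within about 3%) and the QALY difference
(within 4%), which the competing structure misses by 13% and 40%
respectively, and those QALY totals are the quantities the calibration
step names. The competing structure remains available
(`structure = "competing"`) and reproduces the published placebo cost
profile more closely; the published figures are not jointly reproducible
by any single structure we examined (see *Known limitations*).

## Accounting conventions

* **Cycle length** 1 month, configurable. Halving it moves every
  discounted total by well under 1% (a tested property), so discretization
  error is below reporting precision.
* **Half-cycle correction** applies to state-occupancy accruals (costs and
  QALYs use the mean of start- and end-of-cycle occupancy); one-time,
  transition-triggered payments (progression work-up, CNS+ lump sum,
  end-of-life, adverse events) are charged on the entrant mass of the
  cycle in which they occur. Accruals and one-time payments are both
  discounted to the cycle midpoint — costs at 3%/yr, QALYs at 5%/yr —
  except genuine time-zero payments, which are undiscounted.
* **Drug windows.** Adjuvant osimertinib is charged on NED occupancy
  during model years 0–3 (osimertinib arm); re-treatment is charged on PD
  occupancy during the first two years after progression (both arms — at
  recurrence, placebo patients start osimertinib and osimertinib patients
  restart it). A configurable `drug_discount_fraction` scales both lines.
* **One-time costs.** EGFR testing is charged at model start in the
  osimertinib arm and at progression in the placebo arm. Adverse-event
  costs and disutilities are probability-weighted one-time quantities at
  treatment initiation (NED rows, osimertinib arm), at progression (PD
  rows, both arms), and at CNS-positive progression (CNS rows —
  disutilities only; their costs are already folded into the CNS+ lump
  sum). End-of-life costs follow every death and are booked in the
  post-progression cost bucket regardless of the state the patient died
  from, keeping the pre-progression bucket a pure NED-care quantity.
* **Utilities**: NED 0.830 (placebo) / 0.812 (osimertinib), PD 0.71
  (CNS−) / 0.55 (CNS+); Death contributes zero.

## Survival toolbox

`fit_parametric()` maximizes the right-censored log-likelihood
$\sum_{\text{events}} \log f(t_i) + \sum_{\text{censored}} \log S(t_i)$
through `flexsurv::flexsurvreg()` for six families: exponential, Weibull,
gamma, log-normal, log-logistic and generalized gamma. The generalized
gamma uses the Prentice log-time parameterization `(mu, sigma, Q)` — the
classic trap; the parameter conventions for every family are fixed in one
place (`?survival_families`). AIC and BIC are recomputed from the stored
log-likelihood and parameter count, so the stored criteria always satisfy
their definitions exactly.

`select_model()` ranks by AIC and flags the BIC winner separately. Note
that for data generated by a family that another candidate *nests* (the
generalized gamma contains the log-normal at Q = 0), AIC retains a
non-vanishing probability of preferring the larger family at any sample
size; BIC is the consistent criterion. The selection tests encode exactly
that behaviour rather than pretending AIC is consistent.

`ph_check()` is the proportional-hazards diagnostic between arms: a
two-group Cox model with the scaled-Schoenfeld score test for a
time-varying coefficient (`survival::cox.zph`), verdict at α = 0.05. With
the published fits the assumption fails between arms, which is why every
arm/stratum carries its own distribution.

## Reconstruction of individual patient data

`reconstruct_ipd()` inverts the product-limit estimator: given digitized
`(time, survival)` coordinates and the numbers-at-risk table, it allocates
whole events (at the digitized drop times) and censorings (spread
uniformly within each inter-risk interval) so the Kaplan-Meier estimate of
the output reproduces the input curve and the implied at-risk counts match
the table. The censoring count per interval is iterated to reconciliation;
non-integer allocations are rounded half-away-from-zero with a carried
remainder so totals are conserved; a ±1–2 subject slack absorbs integer
rounding at interval boundaries, and anything beyond that raises a
reconciliation error naming the interval. When the total event count is
known it is honoured by a final rebalancing pass beyond the last tabulated
risk time. The procedure is deterministic.

## The synthetic-data generator

`simulate_ipd()` draws event times from any of the six families, censors
by an independent exponential process plus an administrative cutoff, and
is the ground truth for every reconstruction and fitting test: round trips
(simulate → digitize → reconstruct → Kaplan-Meier) must agree within 0.02
absolute survival at all grid points, and maximum-likelihood fits at
n = 2000 must recover the generating parameters. Exponential-plus-
administrative censoring is the standard generative stand-in; it does not
emulate real trials' staggered accrual, informative censoring, or
digitization noise from reading pixels off a plot. Passing round trips
therefore demonstrate correctness of the algorithms, not robustness to
sloppy digitization.

## Probabilistic sensitivity analysis

`run_psa()` re-runs the full model with every input resampled:
moment-matched Beta for probabilities and utilities (20% relative standard
error), Gamma for costs (20%), Normal for log-time locations and
log-Normal for positive survival parameters and the OS hazard ratio (10%).
These distribution assignments are this package's choice and are
overridable (`rel_se`, `sd_scale`). Invalid draws are rejected and
resampled with a count. Draws are reproducible bit-for-bit under a fixed
seed; degenerate (zero-spread) distributions collapse every draw onto the
base case, and tight distributions centre the cloud on the base case
within Monte-Carlo error — all tested properties. Draws with non-positive
QALY gains are kept in the cost-effectiveness plane output and excluded
from summary ICERs.

## Problem sizes used in the test suite

Parameter-recovery fits use n = 2000, information-criterion selection
n = 5000, reconstruction round trips n = 150–200 with quarter-year
digitization grids, the PSA property checks 200 draws; these sizes give
Monte-Carlo error comfortably below every asserted tolerance.

## Known limitations

* The published per-arm cost components this model is calibrated against
  are internally inconsistent (pre- plus post-progression costs do not sum
  to the printed totals in either arm), and the printed adjuvant drug
  expenditure implies fewer on-treatment years than the published DFS fits
  allow. No single coherent parameterization reproduces every printed
  figure; the default structure reproduces the QALY surface and reports
  its cost deviations openly in the reproduction test suite.
* The published sensitivity of the ICER to the assumed overall-survival
  benefit is much stronger than a hazard ratio on post-progression
  mortality can produce under any structure examined here; the sweep's
  monotonicity is preserved and tested, but its published threshold
  crossing at a 25–30% risk reduction is not reproduced.
* No treatment lines beyond osimertinib re-treatment at first recurrence;
  no stage-stratified sub-models; no interval-censored or left-truncated
  reconstruction; cohort-level only (no microsimulation).
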