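---
title: "Modelling the cost-utility of tight-control Crohn's disease management"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the cost-utility of tight-control Crohn's disease management}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(crohncea)
```

## The modelling problem

Crohn's disease is a chronic relapsing inflammatory bowel disease. Two
management strategies for adalimumab-treated patients are compared: *tight
control* (TC), where dose escalation is driven by biomarkers of inflammation
(C-reactive protein, fecal calprotectin), and *conventional management* (CM),
where escalation follows symptoms. Tight control reaches mucosal healing and
clinical remission more often, but biologic doses are expensive; the economic
question is whether the earlier, more aggressive strategy pays for itself
through avoided hospitalizations, lower ongoing care costs, better quality of
life and — from a societal viewpoint — less workplace absenteeism.

`crohncea` answers that question with a discrete-time Markov cohort model
over health states defined by the Crohn's Disease Activity Index (CDAI):

* **remission** (CDAI < 150),
* **moderate** (150 ≤ CDAI < 300),
* **severe** (300 ≤ CDAI < 450),
* **very severe** (CDAI ≥ 450).

Hospitalization is *not* an occupancy state. It is a **toll**: an event with
a per-admission cost (and an optional utility decrement, default 0) whose
occurrence never redirects the occupancy trajectory. The states determine
costs, utility and hospitalization risk each week.

## Transition model

Transitions between visit assessments are estimated with an ordered probit.
For a transition whose destination category is $k \in \{1,\dots,4\}$,

$$P(k \mid x) = \Phi(\tau_k - x\beta) - \Phi(\tau_{k-1} - x\beta),
\qquad \tau_0 = -\infty,\ \tau_4 = +\infty,$$

with strictly increasing thresholds $\tau$. The covariate block $x$ holds
indicators of the lagged state (remission is the reference), the treatment
arm, treatment-by-lagged-state interactions (so the treatment effect may
differ by origin state), the time since the last CDAI measurement
(`gap_weeks`, entered linearly in weeks — the functional form is an
assumption), and a dummy for the visit window of peak clinical remission.
There is no free intercept; identification is absorbed into the thresholds,
the standard ordered-probit convention.

Estimation choices (`fit_ordered_probit()`):

* BFGS quasi-Newton on the negative log-likelihood with analytic gradients.
  The thresholds are optimized as (first threshold, log-increments) so the
  ordering constraint cannot be violated during line search; the reported
  covariance is the inverse of the observed information evaluated
  numerically at the optimum *in the original $(\beta, \tau)$
  parameterization*, which is what the probabilistic sensitivity analysis
  needs.
* If a terminal response category is empty (plausible in small samples),
  severe and very severe responses are pooled with a warning, mirroring how
  baseline severity is usually reported pooled; predictions then assign the
  pooled mass to severe.
* All-constant covariate columns are dropped with a warning and re-embedded
  as zero coefficients with zero covariance, keeping the parameter vector a
  fixed shape for downstream draws.
* Quasi-separation (a coefficient running away) triggers a refit with an L2
  ridge penalty (default `1e-4`) so the covariance stays finite.

The test suite cross-checks the estimator against `MASS::polr` on simulated
data — same likelihood, independently implemented — and verifies parameter
recovery from the package's own generator at 2,500 patients per arm.

## Hospitalization risk

Hospitalization risk is a binary probit on an any-event-per-interval
indicator with the same covariate block plus an intercept
(`fit_hosp_probit()`). The published description of this component is brief,
and we read it as a probit with multiple covariates rather than a jointly
correlated multi-equation system; no correlation structure between the state
and hospitalization equations is estimated. The fitted per-interval
probability at a reference gap $g$ (the mean observed inter-visit gap) is
converted to a weekly probability by

$$p_{\text{week}} = 1 - (1 - p_{\text{interval}})^{1/g}.$$

## Cohort engine

`run_cohort()` evolves one arm's cohort weekly:

* **Weeks 0–48** — visit-week distributions are predicted by iterating the
  fitted transition matrices across the schedule (weeks 0, 2, 6, 11, 23, 35,
  48) and then linearly interpolated to a weekly grid; interpolation of
  simplex points preserves the unit sum, and renormalization only triggers
  beyond `1e-12` of floating-point drift. A sensitivity path substitutes the
  *observed* visit-week state frequencies for the predictions.
* **Weeks 49 to the horizon** (default 260 weeks, five years) — the cohort
  evolves by repeated application of the one-week transition matrix
  (`gap_weeks = 1`, peak dummy 0). This is precisely what the gap and peak
  covariates are for: they let the trial-period regression produce a
  one-week matrix suitable for extrapolation.

Cycle length is one week, so no half-cycle correction is applied (its
magnitude at weekly resolution is negligible relative to parameter
uncertainty); week-0 flows are accrued, so an $H$-week horizon accrues
$H + 1$ weekly quantities. Expected hospitalization events per member per
week are the occupancy-weighted weekly risks; admissions are instantaneous
costed events with no modelled length of stay.

## Economics

All monetary values are 2020 Canadian dollars. `econ_params()` carries the
payer inputs with their one-way sensitivity ranges: hospitalization $16,491
per admission (14,687–22,066), fecal calprotectin $40.00 per test,
C-reactive protein $10.15 (3.72–16.60), adalimumab $785.45 per 40 mg dose
with a biosimilar discount of 0 (0–0.40), hourly wage $29.51 (24.10–32.73),
36.9 hours per standard work week (34.8–37.2), a 1.5% annual discount rate
(0–3%) applied as $(1+r)^{-\text{week}/52}$, and a willingness to pay of
$50,000 per QALY.

Two parameter tables are **synthetic placeholders**, clearly marked as such:
the per-state utilities (the published CDAI-to-EQ-5D mapping is proprietary
to its source data and is not reproduced; an SF-6D-style narrower-range
table is provided for the utility-source sensitivity analysis) and the
per-state weekly "other direct medical" costs (the severity-stratified
resource-use source is likewise only available in aggregate). Both preserve
the severity ordering — worse state, lower utility, higher cost — and should
be replaced for any real decision problem.

Biomarker monitoring is costed on the tight-control schedule only: weeks 0
and 11 and every 12 weeks thereafter.

**Adalimumab dosing** is config, not data: both arms follow induction
(160 mg week 0, 80 mg week 2) and 40 mg every other week from week 4. A
fraction of each cohort escalates to weekly dosing — under TC 40% from week
11 (the first biomarker review after induction), under CM 15% from week 26.
The CM escalation reflects that conventional care also escalates, just later
and on symptoms; it front-loads the *incremental* drug cost of tight
control, which is why the incremental cost-effectiveness ratio (ICER)
declines as the horizon extends: the early escalation differential is
gradually repaid by persistent hospitalization, care-cost and QALY
advantages. The escalated fractions are assumptions (the source trial
reports only aggregate drug-cost differences).

**Absenteeism** is a non-reference (societal) component: expected hours
missed out of a standard work week, monetized at the average wage — the
human-capital approach. Because a state-transition model needs a state-level
link while trials report arm-level productivity effects, absenteeism
fractions attach to health states; the pipeline estimates them from the
work-productivity observations (mean fraction among patients concurrently in
each state).

`evaluate_cea()` reports per-arm discounted component totals, incremental
cost and QALYs, the ICER (or a dominance label when one strategy is both
cheaper and more effective), and net monetary benefit, for the reference
case (direct costs) and the absenteeism-inclusive case.

## Sensitivity analysis

* **One-way (tornado)** — each parameter moves alone to the ends of its
  declared range; the baseline moderate share (0–100%) re-runs the cohort
  model, the SF-6D utility swap is a one-sided bar, everything else
  re-evaluates the economics on fixed traces. Bars are sorted by extent.
* **Horizon sweep** — the full pipeline re-evaluated on a grid of horizons
  (each at least the last visit week).
* **Probabilistic (PSA)** — second-order Monte Carlo, default 1,000 draws.
  Regression coefficient vectors are drawn as
  $\hat\theta + L^\top z$ with $L L^\top$ the Cholesky factorization of each
  fit's covariance, preserving the estimated correlations; ordered-probit
  draws violating the threshold ordering are rejected and redrawn (simple
  and unbiased when the violation probability is small, and logged). Unit
  costs and wages are gamma-distributed and utilities and absenteeism
  fractions beta-distributed, matched to the base mean and a coefficient of
  variation of 0.2; the families and CV are modelling choices — the only
  distributional statement inherited from the source analysis is the
  Cholesky treatment of the regression covariances. A single seed drives the
  run: coefficient and parameter tables are drawn up front in a fixed
  order, so a seed fully determines the draw table.
* **CEAC** — for each willingness-to-pay $\lambda$ on a grid (default 0 to
  100,000 by 2,500 — the grid is ours), the fraction of draws with positive
  net monetary benefit, reported with and without absenteeism.

PSA with all variances switched off reproduces the deterministic result
exactly, and the acceptability curve is tested against a brute-force recount
of the stored draw table.

## The synthetic trial generator

Patient-level data from the source trial are not public, so
`generate_trial()` produces trials with *known ground truth* that emulate
its stated conditions: 122 patients per arm; visits at weeks 0, 2, 6, 11,
23, 35, 48; a baseline mix of 74% moderate and 26% severe/very severe
(split 20/6 — only the pooled figure is reported, the split is ours);
state dynamics from the ordered-probit process at documented true
coefficients with a TC-favouring treatment effect; crude hospitalization
rates calibrated to 28.0 (CM) and 13.2 (TC) events per 100 patient-years;
work-productivity observations at weeks 0, 11, 23, 35, 48; and 5%
completely-at-random missingness of CDAI (never at baseline, since
carry-forward imputation cannot start from nothing — such patients are
excluded with a logged reason).

Mechanics worth knowing:

* CDAI scores are drawn uniformly within the realized state's band (the top
  band capped at 600), so `state_from_cdai()` inverts the draw exactly —
  only the band matters downstream.
* Inter-visit hospitalization counts are Poisson with intensity
  $\lambda_0 \cdot m(\text{lagged state}) \cdot \text{gap}$, with severity
  multipliers $m = (0.5, 1, 2, 3)$. The base intensity $\lambda_0$ is
  calibrated *exactly* in expectation: the expected state occupancy at each
  visit is computed from the true transition matrices, so
  $\lambda_0 = (r/100)\,y \,/\, \sum_j g_j\,\mathbb{E}[m(s_{j-1})]$ where
  $r$ is the target rate, $y$ the follow-up years and $g_j$ the interval
  lengths. A probit fit to these Poisson-driven indicators is a deliberate
  (and at these rates, mild) model mismatch; what the pipeline needs from
  it — a severity gradient and an arm difference — survives, and is tested.
* The true treatment effect is sized so the modelled five-year QALY gain is
  of the order of a quarter of a QALY, matching the scale of gains reported
  for biomarker-driven escalation.

What the generator does **not** emulate: informative dropout (missingness
is MCAR), within-patient CDAI autocorrelation beyond the Markov state,
biomarker trajectories and the escalation decision process itself (the
model consumes arm labels), mortality, and surgery as a distinct event.
Passing tests therefore demonstrate that the estimation and economics
machinery is correct and internally consistent — not that the published
cost-effectiveness numbers are reproduced, which requires the original
patient-level data. The published exact ICERs, component cost changes and
CEAC probabilities are covered qualitatively only: direction of component
effects, declining ICER with horizon, dominance once absenteeism enters.

## Numerical and testing choices

* Convergence: BFGS relative tolerance `1e-12`, at most 500 iterations; a
  fit failing both the optimizer status and a `1e-4` gradient-norm check
  errors out rather than returning silently.
* Probabilities are floored at `1e-300` inside likelihoods; occupancy rows
  are validated to sum to 1 within `1e-9` and propagation is exact to
  `1e-12` against path-enumeration and closed-form two-state oracles.
* Degenerate inputs error early: non-monotone thresholds, duplicate visit
  weeks, missing CDAI in design construction, constant hospitalization
  outcomes (complete separation), inverted sensitivity ranges, horizons
  shorter than the last visit.
* Deterministic code paths are bit-reproducible: refitting identical rows
  gives identical objects, and a seed fixes the generator and the PSA draw
  table exactly.
* Problem sizes: tests recover parameters at 2,500 patients per arm,
  check rate calibration at 600–2,000 per arm, and exercise the PSA
  machinery at 25–250 draws (the exactness properties it checks do not
  depend on the draw count); the acceptance script uses 2,000 per arm for
  rates and 5,000 baselines for the severity mix.

## Known limitations

* No mortality or surgery states; the five-year horizon limits the harm of
  that omission but real decision models should include both.
* Last-observation-carried-forward is the source analysis's imputation
  rule, faithfully implemented; it is known to understate uncertainty.
* Extrapolation beyond week 48 assumes the one-week transition law learned
  from the trial persists for four more years.
* Utility and other-direct-cost tables are placeholders (see above).
* The ICER magnitudes produced on synthetic defaults are internally
  consistent but are not, and cannot be, estimates of the published ones.
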