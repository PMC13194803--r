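---
title: "Model structure, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirvcea)
```

This vignette documents the scientific and numerical choices behind
`mirvcea`: a cohort Markov cost-utility model of mirvetuximab
soravtansine (MIRV) versus single-agent chemotherapy in FRα-positive,
platinum-resistant ovarian cancer, evaluated from the German statutory
health insurance perspective.

## The state-transition model

Three health states — stable (progression-free, on treatment),
progressive, dead — with 28-day cycles. The whole cohort starts stable;
stable patients may remain, progress, or die; progressive patients may
remain or die; no return from progressive to stable; death is absorbing.
The step equation is

- stable′ = stable · (1 − p_sp − p_sd)
- progressive′ = stable · p_sp + progressive · (1 − p_pd)
- dead′ = dead + stable · p_sd + progressive · p_pd

Costs and utilities accrue on start-of-cycle occupancy by default — the
convention of the common commercial Markov tools — with an optional
half-cycle correction (`model_settings(half_cycle_correction = TRUE)`)
for sensitivity; whether the original evaluation applied one is not
knowable, so the flag defaults to off. Death accrues zero cost and zero
utility.

Key settings, with defaults:

| Parameter | Default | Unit | Rationale |
|---|---|---|---|
| `cycle_days` | 28 | days | four-week treatment interval shared by both arms |
| `horizon_cycles` | 65 | cycles | five-year horizon; 65 = ⌊5·365.25/28⌋ ≈ 4.98 y |
| `annual_discount_rate` | 0.03 | 1/year | IQWiG-style 3% on costs and utilities |
| `start_age` | 64 | years | median age of the modelled population |

Discounting compounds on the day grid,
(1+r)^(−cycle·28/365.25), so cycle 0 has factor 1.

## Survival extrapolation

Trial follow-up (~24 months) is shorter than the model horizon (60
months), so the PFS and OS curves of each arm are extrapolated with
parametric families: exponential, Weibull, Gompertz, log-logistic,
log-normal (`surv_model()` documents the parameterisations).

**Objective.** Digitized Kaplan–Meier coordinates carry no at-risk
counts, so maximum likelihood is not available; the fit minimises the
sum of squared residuals on the survival proportion,
SSR = Σᵢ (S_model(tᵢ) − sᵢ)². Information criteria use the
Gaussian-residual least-squares forms AIC = n·ln(SSR/n) + 2k and
BIC = n·ln(SSR/n) + k·ln(n).

**Optimisation.** Levenberg–Marquardt least squares on unconstrained
coordinates (log-transformed positive parameters), multi-started from a
data-driven grid — scale anchored at the empirical median of the curve,
shapes spread over {0.5, 1, 2} (Gompertz shape over a signed grid) —
keeping the best final SSR. Gompertz and log-logistic fits are
initialisation-sensitive, hence the multi-start. Convergence tolerances
are tight (`ftol = ptol = 1e-15`) so noise-free self-generated curves
are recovered to ~1e-8 relative error or better.

**Selection.** Converged fits are ranked by AIC; near-ties
(|ΔAIC| < 0.01) break by BIC, then SSR, then fewer parameters, then the
declared family order (recorded in a `tie` column). The full ranking
table is returned so a reviewer can overrule the automatic choice on
clinical-plausibility grounds — the published analysis also included a
qualitative review of the extrapolated shapes. PFS and OS are fitted
independently per arm (four fits in the base case); whether the original
model tied endpoints together is not stated, and per-endpoint fitting is
the less constrained choice.

**Degenerate inputs.** A curve with no decline (all points 1) admits no
informative fit; it is flagged non-converged with infinite criteria
rather than returning an arbitrary model.

## From survival curves to transition probabilities

On the cycle grid t_c = c · 28/30.4375 months, the stable occupancy
targets S_PFS(t_c) and the alive fraction targets S_OS(t_c) (S_OS is
clipped to ≥ S_PFS first; clip counts are reported). Given the step
equation above, the per-cycle probabilities are solved so that the
cohort trace reproduces both curves *exactly* when background mortality
is zero — the package's central internal-consistency guarantee, verified
to 1e-9 in the test suite.

One attribution question has no unique answer: the two published cohort
curves cannot separate death before progression from death after it.
The progressive compartment absorbs as many OS-implied deaths as it can
(p_pd solved from the OS decrement); any remainder — inevitable in the
earliest cycles, when the progressive compartment is still nearly empty
but OS already declines — is carried by the stable state on top of
background mortality. This errs toward progression-free mortality, the
same direction the original analysis acknowledges for its own handling,
and degenerates to background-only stable-state death whenever the
disease curves are flat (no double counting).

Background mortality comes from an annual life table at the attained
age (start age + elapsed model time, floored to whole years; the last
row carries forward beyond the table), converted to per-cycle scale by
1 − (1 − p_annual)^(28/365.25). It applies only where the OS curve does
not already embed it — i.e. it is never added to the OS-matching
progressive-state death probability.

The survivor-fraction identity used throughout is
P = 1 − y^(1/t) for the constant per-cycle event probability consistent
with a fraction y surviving t cycles. (The equivalent form
1 − e^(ln y / t) is the standard one; a sign-flipped variant sometimes
seen in print yields negative probabilities and is treated as a
typographical slip.)

## Economic inputs

All euro amounts are per 28-day cycle, GKV perspective, defaults in
`default_config()`:

- **Drug acquisition.** MIRV €18,231.66 per cycle (a second published
  figure, €18,281.66, is carried as `mirv_cost_per_cycle_alt`; the two
  are never reconciled in the source, and the tabulated value is the
  default). The standard arm supports two modes: `blended` (the single
  published average, €1,276.83, the default) and `weighted`
  (proportion-weighted sum of the per-drug monthly costs — about €447,
  roughly 2.9× smaller than the blended figure; the discrepancy is
  exposed rather than resolved). An optional dose-based calculator
  (€30.39/mg at 6 mg/kg adjusted ideal body weight) is configurable but
  not part of the base case.
- **Monitoring and imaging.** €96.96 per cycle, plus imaging €141.12 in
  cycles 1–9 and €70.56 from cycle 10 (the source's two descriptions of
  the switch conflict by one cycle; "cycles 1 to 9 early" is the reading
  kept). Premedication €82.06 (MIRV) / €27.93 (standard).
- **Adverse events.** Grade ≥3 events enter only if a Pearson chi-square
  test (2×2 event-by-arm, no continuity correction, arm sizes 227/226)
  shows p < 0.05 — both default events (anemia, neutropenia) pass. Cost
  = cumulative incidence × per-episode DRG tariff / 60, amortised over
  the 60-month horizon with months ≈ cycles (an approximation the
  four-week cycle makes small). The per-episode tariffs are inferred
  from the intervention-arm cells; applying them at the comparator
  incidences reproduces the comparator cells within 1%, a cross-arm
  consistency check in the test suite.
- **Utilities.** 0.61 stable, 0.5 progressive; optional per-arm linear
  decline per cycle (0.005 "slow", 0.01 "rapid" scenarios), floored at
  0. Treatment components accrue in the stable state only (treatment
  runs until progression); the progressive state accrues no modelled
  cost, consistent with post-progression therapy being out of scope.

## Sensitivity analyses

**Deterministic.** One-at-a-time multipliers: drug prices ±50%
(per arm), adverse-event and monitoring costs ±25%, each state utility
±20% (applied one-at-a-time for the tornado; the exact pairing in the
source is unstated). Tornado bars are |ICUR(high) − ICUR(low)|, sorted
descending. The bivariate utility analysis raises the *intervention
arm's* utilities only, over a (stable, progressive) grid, matching the
published scenario design. Scenario reruns cover horizons {5, 10} years
and discount rates {0%, 3%, 5%}.

**Threshold price.** The incremental cost is affine in the MIRV
per-cycle price, so the price→ICUR map is monotone; `price_threshold()`
brackets and bisects to ±€0.01 and verifies the inverse by rerunning the
model (|ICUR(p*) − WTP|/WTP < 1e-4).

**Probabilistic.** Gamma for costs (moment-matched), beta for utilities
(sd = 95%-halfwidth/1.96, moment-matched), and two lognormal(0, 0.10)
multipliers per iteration — one for death-type probabilities (p_sd,
p_pd), one for progression (p_sp) — shared across cycles and arms,
products clipped to [0, 1]. The published distributions come without
spreads; the deterministic ranges are re-expressed as 95% intervals
(sd = multiplier·mean/1.96), a transparent default that keeps the two
analyses consistent. The sampled progressive utility is capped at the
sampled stable utility to preserve state ordering. Each parameter draws
from its own deterministic substream of the master seed, so results are
reproducible and adding a parameter does not reshuffle existing draws.
The headline summary is the mean of per-iteration ICURs with a normal
95% CI (iterations with ΔQALY ≤ 0 are counted and excluded from the
ratio mean); the ratio of means is reported alongside as the
economically standard alternative. The CEAC is the fraction of
iterations with positive net monetary benefit at each WTP.

## The synthetic-data generator

`synthetic_trial_spec()` emulates what the pipeline would receive from
digitizing published Kaplan–Meier figures: per-arm PFS/OS curves sampled
monthly over 24 months (the trial's approximate follow-up), additive
Gaussian noise on the survival proportion (default scenarios use
sd 0.02, a plausible plot-digitization error), clipped to [0, 1] and
projected to monotone non-increasing by a running minimum; time 0 stays
exactly 1. Ground truth defaults: log-logistic for the intervention arm
and Weibull for the comparator (the families the base-case selection
chooses), shapes 1.5/2.0 and 1.2/1.3 (mildly rising hazards typical of
progression and death in this population), scales set so the medians
equal the trial's published medians. OS dominates PFS by construction
and specs violating that are rejected. A geometric life table
(`generate_life_table()`: ~1% annual mortality at 64, ×1.09 per year)
stands in for a national female life table.

What the generator does **not** emulate — and therefore what passing
tests cannot show about real digitized data: step-function KM geometry
and censoring marks, risk-table-based reconstruction, correlated
digitization errors along a curve, informative censoring, and any
systematic bias of the plot-digitization software. Tests on these
fixtures validate the machinery (fitting, decomposition, accounting,
uncertainty propagation), not the clinical estimates.

A related identifiability caveat: over a 24-month window at
digitization-level noise, some families are mutually
near-indistinguishable — log-logistic and log-normal most of all (both
log-location-scale with very similar shapes), and the exponential versus
its two-parameter supersets. The family-recovery regression test
therefore uses a Weibull truth with a clearly increasing hazard, where
the selector identifies the generating family in well over 80% of noisy
replicates; for a log-logistic truth the selection between it and the
log-normal is genuinely close and the ranking table, not the automatic
winner, is the trustworthy output. This mirrors practice: extrapolation
family choice should be reviewed, not fully automated.

## Numerical conventions and edge cases

- Months-per-cycle constant 28/30.4375; cycle c covers [t_c, t_{c+1}),
  occupancy evaluated at cycle start.
- All probabilities clipped to [0, 1]; clip events (including OS < PFS
  grid points) are counted, attached as attributes, and messaged.
- Currency is kept at full double precision internally; CSV artifacts
  are dot-decimal, euro-sign-free; printed output rounds to 2 decimals.
- A perfect fit (SSR = 0) would make ln(SSR) undefined; SSR is floored
  at 1e-300 inside the criteria so rankings stay finite and ordered.
- ICUR/ICER are reported as NA with a dominance flag when incremental
  cost and effect have opposite signs, and NA when the denominator is 0.
- Problem sizes in the shipped tests: path-enumeration oracle
  equivalence on 6-cycle instances; trace reconstruction on the full
  65-cycle horizon; 200 replicates for noisy family recovery; 10⁵ draws
  for distribution moments; 1,000-iteration PSA for the end-to-end run
  (the production default is 10,000; the estimator is the same, only the
  Monte Carlo error differs).

## Known limitations

- The two-curve decomposition cannot identify where deaths occur
  relative to progression; the stable-state attribution above likely
  overstates progression-free mortality and thus understates both costs
  and QALYs accrued in the stable state.
- Treatment discontinuation, dose reductions, and post-progression
  therapy are out of scope (as in the source analysis); drug cost
  accrues for the full stable occupancy.
- PSA spreads are assumption-driven (DSA ranges as 95% intervals), so
  the absolute PSA quantities on synthetic fixtures are illustrative;
  the monotonicity, collapse, and reproducibility properties are what
  the tests guarantee.
- Utilities come from adjacent literature rather than the trial
  population; the bivariate and decline scenarios exist precisely to
  probe that transferability.
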