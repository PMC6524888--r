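---
title: "Model structure and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vtecea)
```

## The decision problem

After an unprovoked venous thromboembolism (VTE) — a deep venous thrombosis
(DVT) or pulmonary embolism (PE) — patients finish roughly six months of
anticoagulation and then face a choice: stop, accepting a substantial
recurrence risk (about 11% in the first year off treatment, approaching 40%
at ten years), or continue a direct oral anticoagulant indefinitely, trading
recurrence protection against bleeding risk and drug cost. `vtecea`
implements a cohort state-transition model of that trade-off: extended
low-dose apixaban (2.5 mg twice daily) versus no extended treatment, followed
over the cohort's remaining lifetime, with results expressed as an
incremental cost-effectiveness ratio (ICER) in euros per quality-adjusted
life-year (QALY).

## States and cycles

The cohort moves among twelve health states in three-month cycles: the two
index states (index DVT, index PE), event-free on treatment, event-free off
treatment (including discontinuers), recurrent DVT, recurrent PE, non-intracranial
major bleeding (MB), clinically relevant nonmajor bleeding (CRNMB),
intracranial bleed (IC), chronic thromboembolic pulmonary hypertension
(CTEPH), VTE-related death, and death from other causes. Severe
postthrombotic syndrome (PTS) is a background process rather than a state:
a fraction of DVT-history patients progressively acquires its maintenance
cost and utility decrement.

Internally the engine expands this space along two axes that the twelve
public states cannot carry:

* **History tracks.** CTEPH risk applies to patients with a PE history and
  PTS to patients with a DVT history, so the cohort is partitioned into
  three tracks (DVT only, PE history, both); a recurrent PE moves a DVT-track
  patient into the "both" track, and symmetrically for recurrent DVT.
* **Bleed origin.** The MB and CRNMB event states are split by treatment
  status so that a bleed never changes whether a patient is anticoagulated.

Event states are one-cycle states whose *outgoing* hazards equal those of the
treatment track they belong to. Sub-cycle treatment interruptions after
bleeds (14 days after non-IC MB with probability 0.4727, 2 days after CRNMB)
are far below the three-month resolution, so they reduce drug-cost accrual
only and do not pause event risk; the same reasoning applies to the event
states themselves. Recurrence survivors resume anticoagulation (apixaban in
the treated arm, the initial LMWH/VKA regimen in the untreated arm, which is
why that arm carries INR monitoring costs); IC-bleed survivors stop
anticoagulation permanently and, per the model's stated limitation, have no
further recurrent events.

## Transition probabilities

All period conversions, hazard ratios and aging adjustments act on the rate
scale (`1 - (1 - p)^k`), never by direct probability multiplication, so
probabilities stay in `[0, 1]`.

* **Recurrent VTE + VTE-related death.** During the trial window (extended
  months 6–18) the four per-interval risks per arm are used directly; they
  are intention-to-treat estimates, so on-treatment states use their own
  arm's values, while off-treatment states (discontinuers) use the untreated
  values. Beyond 18 months the post-cessation cumulative-incidence curve
  (11.0%/19.6%/29.1%/39.9% at 1/3/5/10 years) is converted to per-cycle
  probabilities under a piecewise-constant hazard; anticoagulated states
  scale that hazard by the trial's hazard-scale treatment effect,
  `log(1 - cumulative treated risk)/log(1 - cumulative untreated risk)` ≈ 0.174.
  The first knot of the published curve is printed as 0.0110 with a CI of
  0.0950–0.1250; the loader stores 0.110 and records the correction, since
  the CI and the cited 11% first-year recurrence identify the printed value
  as a typo.
* **Bleeding.** MB and CRNMB risks are constant 12-month risks converted to
  cycle probabilities — the interpretation under which the 12-month
  validation run reproduces the published event counts (2/4 MB and 24/19
  CRNMB from 804/829 patients); reading them as per-cycle risks gives
  roughly fourfold counts. Within the trial window they apply as observed;
  the aging adjustment (rate factor 1.970 per decade above the baseline age
  of 56.9) applies to the constant risks carried beyond 18 months, which is
  the period the source ties the adjustment to. By default each arm keeps
  its own bleeding risks beyond 18 months (`engine_control(post18_bleeding =
  )` switches both arms to the untreated values), which matches the
  lifetime event pattern of the published model (more CRNMB on apixaban,
  whose CRNMB risk is higher, 3.00% vs 2.30%/year).
* **Recurrent-event split.** Recurrence mass divides into VTE death /
  recurrent PE / recurrent DVT as 0.1188/0.2475/0.6337 — the means of a
  Dirichlet whose effective sample size is set to 101, because the published
  proportions are exactly 12/101, 25/101 and 64/101.
* **Competing risks.** Within a cycle, independent cause-specific risks are
  composed as a product of survivals; each cause receives a share of the
  total exit probability proportional to its rate. This is order-independent
  and validated against the patient-level microsimulation.
* **Mortality.** Background mortality comes from a life table mixed 58%/42%
  male/female (no sex-differential attrition, since none is described for
  the source model), converted to the cycle length on the rate scale.
  Hazard ratios compose multiplicatively: the index-event HR (4.41) applies
  lifelong to everyone — this is also what places lifetime QALYs near 11
  rather than the ~17 ordinary mortality would give — with post-IC (2.60)
  and post-CTEPH (1.30) factors on top. Age 100 is terminal.
* **Other transitions.** Non-event discontinuation (6.67%/12 months) applies
  to on-treatment states in both arms; CTEPH (1.25%/year) to PE-history
  patients (configurable to index-PE only); severe PTS (8.12%/5 years) accrues
  among DVT-history patients over the first five model years.

No half-cycle correction is applied by default: the published validation
counts are reproduced without it, and `engine_control(half_cycle = TRUE)`
enables it for sensitivity.

## Economics

Costs (euro, 2015 price year) and QALYs are discounted discretely at cycle
start at 4%/year and 1.5%/year respectively, the Dutch reference-case rates;
the clock starts at entry to the extended phase in the base case and at the
index event in scenario 1. Event costs are one-off; CTEPH and PTS carry
per-cycle maintenance costs; drug costs accrue per person-day on each
regimen net of interruption days; travel tariffs accrue per qualifying
visit (recurrent PE/DVT, IC bleed, CTEPH onset, INR monitoring visits);
productivity losses use the friction-cost method, `min(absence days,
friction period) x hours/day x hourly wage x employment probability`. The
healthcare-payer perspective simply zeroes the two categories outside the
healthcare sector (productivity, travel). Utility decrements are additive
with a floor at zero (the source does not state additive vs multiplicative;
additive is the switchable default), applied as one-off event disutilities
(decrement x duration) and per-cycle state decrements for IC, CTEPH and PTS.

**The shipped cost/utility registry is a placeholder.** The authoritative
unit values live in the source model's supplementary material, outside this
package; every shipped entry carries `provenance: placeholder` and is
enumerated by the loader. Published cost-effectiveness figures (base-case
ICER €9,653, payer €14,490, incremental 0.359 QALY, 70.0%/91.4% probability
cost-effective at €20,000/€50,000 per QALY) are therefore *not* reproducible
from the packaged fixture and are asserted nowhere; they become comparable
only when a user supplies a transcribed registry, which flips
`is_authoritative()` and opens that gate. The placeholder values are
order-of-magnitude plausible for the Dutch setting so that the pipeline
exercises every cost category.

## Sensitivity analysis

The probabilistic analysis draws every uncertain parameter independently
(beta for probabilities, gamma or lognormal for ratios and costs, the joint
Dirichlet for the event split), both arms sharing each draw, and records
incremental cost/effect pairs; the acceptability curve is the fraction of
draws with non-negative net monetary benefit at each willingness-to-pay
threshold. Distributions are moment-matched from the mean and a standard
error of (CI width)/3.92, falling back to 30% of the mean when no CI is
stated; asymmetric CIs are honoured only through each family's natural skew.
Out-of-range draws are redrawn (preserving the family) and counted.
Iteration `i` uses seed `master_seed + i`, so single iterations are
reproducible in isolation. The univariate sweep varies one parameter at a
time across its stated 95% CI (or fitted 2.5/97.5 percentiles) and sorts by
ICER range.

## Validation and the synthetic fixtures

The validation harness re-runs the engine at the extension trial's settings
(804 vs 829 patients, 12 months) and compares event counts and relative
risks with the trial. With the packaged parameters the model reproduces the
published model counts exactly after rounding: 13 vs 72 recurrent VTE +
VTE-related death, 2 vs 4 major bleeds, 24 vs 19 CRNMB. The all-cause death
row is reported but excluded from the pass/fail surface because it is
dominated by the background life table. Relative risks are computed on
unrounded counts with the printed denominators (804/829) and come out one
rounding step above the published model RRs (0.19/0.51/1.31 vs
0.18/0.50/1.26); the published RRs are instead consistent with the source
trial's actual treated-arm size of 840, an internal inconsistency of the
source table that this package does not paper over.

Because no national life table ships with the package, tests and packaged
analyses use a synthetic Gompertz–Makeham table
(`q(age) = 1 - exp(-(A + B e^(C age)))` per sex) calibrated so the annual
death probability at 56.9 years is ≈0.57% and remaining life expectancy
≈26 years — typical of a high-income period table. Lifetime results that
depend on the real national table (for example the published lifetime event
counts of 292 vs 603 recurrent VTE) are consequently checked only
qualitatively: extended treatment must reduce recurrent VTE and major
bleeding and increase CRNMB and discontinuation.

Two independent oracles guard the engine. A patient-level event-history
generator reproduces the censoring structure assumed by the interval-risk
estimator (first-event censoring, ITT denominators), closing the loop
estimator → probabilities → simulator → estimator. A microsimulation pushes
individual walkers through *exactly* the engine's per-cycle matrices;
expected counts must agree within Monte-Carlo error (Poisson-scale standard
errors, appropriate for rare events). The test suite runs the oracle
comparison over ten randomly drawn parameter sets at 100,000 walkers and a
12-cycle horizon — sizes chosen to give sub-event resolution while keeping
the default test run fast — re-examining any marginal 3-sigma excursion at
four times the walker count before declaring bias, since ~100 comparisons at
a 3-sigma bound are expected to produce occasional excursions under a
correct engine. The beta-fit check requires the fitted 2.5/97.5 percentiles
to sit within 0.35 x the CI half-width of the stated bounds, a tolerance
fixed from the moment-matching skew observed across all published beta rows
(the worst case, 0.32 x half-width, is the asymmetric five-year PTS CI).

## Degenerate inputs and numerical choices

A probability of exactly 1 cannot be rescaled between period bases (infinite
rate) and is refused; identity conversions (same basis, zero decades of
aging) return the input bit-for-bit. Cause allocation with a certain cause
assigns the whole cycle to it; an all-zero hazard set yields an identity
row. Age-adjusted bleeding probabilities above 0.999 are clamped with a
warning. Transition rows must sum to 1 within 1e-9 and contain no negative
cell, or the engine stops naming the offending transition. A cohort of zero
patients produces an all-zero trace; horizons beyond age 100 are truncated
with a warning.

## Known limitations

The model is memoryless beyond the engineered history tracks: time since an
apixaban discontinuer's personal cessation is approximated by time since the
extended phase began, recurrence risk is not elevated after a prior
recurrence, and no recurrent events follow an IC bleed. Resumed LMWH/VKA
efficacy beyond the trial window is approximated by the apixaban treatment
effect. CTEPH and IC states carry no further recurrence risk. Parameters are
sampled independently in the probabilistic analysis (no correlation
structure is described in the source). The synthetic life table reproduces
the *shape* of a national table, not any country's actual rates, so absolute
lifetime counts and ICERs from the packaged fixture are illustrative, not
authoritative.
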