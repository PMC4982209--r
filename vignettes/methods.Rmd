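---
title: "Methods: one-year costs and quality-adjusted survival after ARDS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: one-year costs and quality-adjusted survival after ARDS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models, assumptions and design choices
behind `ardsecon`, in the spirit of a statistical methods appendix. It
states no empirical result beyond what the package's own tests and
`scripts/acceptance.R` compute.

## The estimand and the partitioned QALY model

The package estimates one-year quality-adjusted survival for a cohort of
ICU patients ventilated for ARDS. Because quality of life is only
assessed at 6 and 12 months, per-patient QALY integration is not
possible; instead, the cohort's person-time is partitioned into periods
and each period's Kaplan-Meier area is weighted by a single period
utility:

* a ventilated period of length equal to the cohort *mean* of
  ventilated days, weighted by the utility of an unconscious patient
  (−0.4, the EQ-5D scoring-manual value). The cohort mean is used
  deliberately — the method weights average ventilated days, not
  per-patient ventilation histories;
* four follow-up periods ending at 3, 6, 9 and 12 months (91.3, 182.6,
  274.0 and 365 days), weighted by utilities u₃, u₆, u₉, u₁₂.

u₆ and u₁₂ are survivor means over all available questionnaires at each
wave, scored with the UK time-trade-off (TTO) tariff for EQ-5D-3L
(additive decrement model; constant 0.081, N3 term 0.269, per-dimension
level-2/3 decrements as bundled in `inst/extdata/eq5d_uk_tto.yaml`;
range −0.594 to 1). Assuming a linear change in quality of life between
the two assessments, u₉ = (u₆+u₁₂)/2 is the interpolated mid-point and
u₃ = u₆ − (u₁₂−u₆)/2 the backward extrapolation of the same line. With
only two assessment points, anchoring the first post-ventilation period
is genuinely open (0, u₃ or u₆ are all defensible and shift the cohort
QALY by roughly ±0.03); this implementation uses the single
6-to-12-month line throughout, which is the most literal reading of a
"linear change between assessments" and keeps the estimator a smooth
function of (u₆, u₁₂). The extrapolation is not clamped to the tariff
range; in practice survivor means sit far from the boundaries.

The Kaplan-Meier estimator is the standard product-limit form with
events before censorings at ties (implemented directly so the bootstrap
loop stays cheap; tests cross-check it against `survival::survfit` and a
hand product-limit oracle). Period areas are exact step-function
integrals, converted at 365.25 days/year. Confidence intervals are a
seeded nonparametric bootstrap over patients (1,000 resamples,
percentile interval by default); when no observation is censored before
the horizon the bootstrap uses the identity
∫ₐᵇ S = mean((min(T,b)−a)₊), which is exact for step functions.

## Costing model

Costing is bottom-up: unit costs × volumes, summed per patient, by care
pathway, in 2012 GBP (the bundled HCHS index restates other price
years).

* **Initial ICU stay**: per-day organ-support tier cost (a lookup keyed
  by number of organs supported, 0–6; unconfigured tiers are an error,
  not an extrapolation), renal replacement, X-rays, chest drains, drug
  units at per-unit prices, plus a ventilation day cost of
  `(machine price / 5-year life + annual maintenance) / utilisation`
  and a single-use circuit cost once per ventilated patient. The 5-year
  machine life is the stated assumption; the utilisation rate
  (365 days/year) and machine price are configuration with documented
  defaults, as no source values are available.
* **Post-ICU hospital stay**: days from ICU discharge to death or
  hospital discharge at the required level of care (ward/HDU), ICU
  readmission days at the ICU daily rate, an emergency transfer cost
  when discharged to another hospital, itemised serious-adverse-event
  costs passed through without grouping.
* **Post-hospital year**: NHS component (GP, outpatient and community
  visits at service unit costs, inpatient days, aids and equipment) and
  patient/carer component (patient + carer miles × petrol rate, lost
  earnings, out-of-pocket items). Both components are *missing*, not
  zero, unless the patient returned both the 6- and 12-month
  questionnaires — mirroring how the source tables restrict to
  completers — and missing carer information propagates to a missing
  patient/carer component.

The engine is exactly linear in the unit-cost table (reported monetary
amounts such as lost earnings are pass-through data, not unit costs),
additive across pathways, and tested against a naive row-by-row oracle.
The bundled `unit_costs.yaml` is illustrative: the national
reference-cost, formulary and PSSRU sources are not redistributable.
Its post-ICU ward day (£297) is anchored to the published daily
quartile, and the organ-day tiers are chosen so a typical ICU day costs
≈£1,700, the published scale. Every entry is replaceable.

## Missing-cost imputation

Post-hospital costs among one-year survivors are multiply imputed at
the level of the four wave totals (NHS and patient/carer at 6 and
12 months) by chained equations: each incomplete variable is regressed
on complete baseline covariates (age, sex, APACHE II, PaO₂:FiO₂, arm,
ICU days) plus the other, currently imputed, cost variables. Each
imputation draws regression parameters from their posterior and then
applies predictive mean matching with k = 5 donors, so imputed values
are observed donor values — automatically non-negative and
skew-respecting — with an explicit floor at 0 on top (the "truncated
model" constraint). Ten datasets, ten cycles by default (a single
incomplete variable converges immediately; the cycles matter when
several wave totals are missing in overlapping patterns). Pooling is
Rubin's rules with the standard small-sample degrees of freedom. The
conditional model family and predictor set are not pinned down by any
source, so both are configuration (`imputation_spec()`); PMM was chosen
over a parametric tobit-style draw because it satisfies the truncation
constraint by construction. Simulation tests (500 missing-at-random
replicates) check near-unbiasedness (<5 % of an SD) against a known
truth, a materially larger complete-case bias, and 92–98 % coverage of
the pooled interval.

## The synthetic cohort generator

The generator defines the study conditions under which the pipeline is
exercised; its defaults are the published summaries, not tuning knobs:

* **Survival**: death within the year with probability 0.512; a
  fraction 0.958 of deaths uniform on days 1–30 and the rest uniform on
  days 31–365. The two-component uniform mixture is the simplest shape
  matching the published curve (steep first month, flat after day 60).
  The early fraction is the in-hospital share of one-year deaths
  ((343+47)/407) computed from the published counts; with the
  calibration constants below, a closed-form area calculation puts the
  implied cohort QALY at ≈0.267 before any simulation.
* **Lengths of stay**: ICU stay lognormal matched by moments to
  17.0 ± 16.5 days; post-ICU days lognormal with mean 16.6 days
  (hospital mean 33.6). Stay is drawn independently of survival time:
  the joint distribution is unreported, and preserving the published
  marginal moments was judged more useful for testing than inventing a
  correlation. Consequences (e.g. in-hospital death shares that differ
  from the trial flow chart) are accepted and documented.
* **Ventilated days**: a Beta-distributed fraction of the ICU stay with
  mean 11/17. The mean of 11 days is a calibration constant — the
  source reports no ventilated-day summary — chosen (jointly with the
  mixture above) so the default pipeline's quality-adjusted survival
  lands near the published 0.27. It is ordinary configuration.
* **EQ-5D states**: a latent normal utility (SD 0.37, the published
  band SD) snapped to the nearest of the 243 tariff values. The latent
  mean is solved numerically so the *quantised* expectation equals the
  wave target (0.5622 / 0.5831); using the target directly would bias
  the realised mean ≈0.02 downward because of clamping at full health.
* **Non-response**: logistic in standardised age and APACHE II with a
  numerically calibrated intercept hitting the marginal non-response
  (41.1 % at 6 months, 47.2 % at 12 months); the default slope
  (0.3 log-odds per SD of each) encodes that completers are younger and
  less severely ill — a missing-at-random mechanism by construction.
* **Seeds**: one master seed with fixed per-table sub-streams, so
  regenerating one table never perturbs another.

What the generator does *not* emulate: treatment effects (both arms are
identical, so arm contrasts are null), correlation between severity and
cost or utility beyond the response mechanism, within-patient utility
trajectories, seasonal or centre effects. Tests passing on this cohort
therefore demonstrate the pipeline's arithmetic and statistical
properties, not clinical realism of any particular joint distribution.

## Numerical choices and degenerate inputs

Probabilities and SDs are validated with errors naming the offending
field. Ties in the product-limit estimator: events before censorings.
Group-of-one summaries flag an undefined CI rather than fabricating
one. A zero QALY difference makes the ICER an explicit undefined
condition, never ±Inf; sign combinations that make the ratio misleading
are flagged as dominance. Logistic separation (a single-outcome group)
is an explicit error. The report bundle contains no timestamps, so a
fixed configuration reproduces byte-identical output.

## Problem sizes

Default test and acceptance runs use cohorts of 10,000 patients for the
quality-adjusted-survival reproduction (Monte-Carlo error ≈0.005), 20 ×
795 replicates for generator calibration, 500 replicates for the
imputation bias/coverage and bootstrap-coverage studies (n = 150–200
per replicate, binomial SE on coverage ≈1 %), and 50-patient cohorts
for exact oracle comparisons. These sizes keep each study's Monte-Carlo
error comfortably below the property margins being asserted.

## Known limitations

No discounting (one-year horizon); no extrapolation beyond 365 days; no
EQ-5D-5L or non-UK tariffs; partial EQ-5D responses are rejected rather
than partially scored; no MNAR sensitivity analysis; the ICER carries
no uncertainty interval (the separately published full
cost-effectiveness analysis, with acceptability curves, is out of
scope). The bundled unit costs are stand-ins: absolute cost levels from
the default configuration are illustrative even though their scale is
anchored to published quartiles.
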