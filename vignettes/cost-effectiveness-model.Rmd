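---
title: "A three-state cohort model for the cost-effectiveness of type 2 diabetes remission programmes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A three-state cohort model for the cost-effectiveness of type 2 diabetes remission programmes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remitce)
```

## The problem

Structured weight-management programmes delivered in primary care — total
diet replacement with low-energy formula sachets, staged food
reintroduction, and practitioner-supported weight-loss maintenance — can put
type 2 diabetes into remission. Remission is usually temporary: in trial
follow-up roughly 46% of intervention participants were in remission at 12
months, 36% at 2 years, and about 10% five years after entry. The
health-economic question is whether the programme's delivery cost (formula
diet, practitioner time, set-up) is offset by lower healthcare resource use
and by the survival and quality-of-life benefits that accrue during periods
of remission, from the perspective of a national health service.

`remitce` implements that evaluation end to end as a reusable, tested
pipeline, and pairs it with a synthetic participant-level cohort generator,
because the underlying trial data are individual health records and cannot
be distributed. Every statistical stage can therefore be exercised, and its
calibration measured, without any access to the original data.

## Model structure

The core is a Markov cohort model with three states: living with type 2
diabetes, in remission from diabetes, and dead. The cohort enters at age 54
(59% women), all alive with diabetes. Cycles are annual; state occupancy is
evaluated at cycle start with no half-cycle correction — annual accounting
of this kind reproduces the arithmetic of the published summary tables
exactly, and the model's comparisons are between arms run under identical
conventions. Each cycle:

* The proportion of survivors in remission is set by an **arm-level
  remission schedule** `S(t)` (remission does not outlive the cohort's
  mortality: the schedule multiplies the surviving fraction, which keeps
  occupancies conserved).
* Survivors in remission die at the annual probability of people *without*
  diabetes; survivors with diabetes die at the higher with-diabetes
  probability. This mortality contrast is the survival pathway of the
  intervention's benefit.
* Costs, life-years and QALYs accrue by state and are discounted at 3.5%
  per year, the first model year undiscounted (a configuration switch,
  `year_one_discounted`, exposes the alternative convention).

The lifetime horizon runs to age 110; a restricted five-year horizon is
also reported, because by five years remission maintenance is mature enough
that the short-horizon result relies very little on extrapolation.

### Remission schedule

`S(1)` is the arm's 12-month remission proportion; maintenance beyond 12
months is estimated among remitters by Kaplan-Meier and multiplied back by
the 12-month proportion. Relapse is treated as absorbing — late second
remissions are deliberately not recognised, a simplification that matches
how the trial data were analysed. Beyond year 5 the proportion continues to
decline at the average annual rate observed between years 1 and 5,
`r = (S(5)/S(1))^(1/4)`, and remission is assumed extinct beyond 10 years
from entry.

Two classification rules govern the survival data. A year with no recorded
status is deemed a relapse at that year if the next available record shows
remission reversed; otherwise the participant is censored at the first year
from which no further record exists. One numerical subtlety matters for
calibration: a participant censored at an unrecorded visit was last
actually observed the year before, so `km_remission()` places such
censorings just before the unrecorded visit (at `t - 0.5`). Leaving them in
the year-`t` risk set — where they cannot possibly be observed to relapse —
inflates the year-5 estimate by about 11% under study-like censoring
(verified against the generator's known retention); with the placement used
here the estimator recovers the truth within Monte-Carlo error.
Administratively complete follow-up (in remission at the final assessment)
stays censored *at* that visit, with relapses processed before censorings
in the usual product-limit tie convention.

### Costs

Annual healthcare costs (primary care, other community contacts, secondary
care, hospital admissions, medicines) are estimated by the **Kaplan-Meier
sampling average**: the mean among participants under observation in each
arm-year, taken as representative of the modelled surviving cohort and
multiplied by the proportion alive. Without censoring this reduces to the
complete-case mean. Beyond year 5 every survivor is assigned the control
arm's year-5 cost for people not in remission, reduced by a proportional
saving `s` while in remission, where `s` is the average over years 2-5 of
one minus the remission/non-remission cost ratio (arms pooled, clipped to
[0, 1]).

Intervention costs apply to the intervention arm in years 1-5 only: a flat
set-up share in year 1, sachets at the packaged sachet price, and
practitioner appointments at a per-minute staff cost times a default
30-minute duration (the trial recorded appointment durations but the
publication prints only counts, so duration is an explicit knob).
Hospitalisation costing supports national-tariff-style excess bed-days
beyond a per-category trim point.

### Utilities

The remission effect on EQ-5D-3L utility is estimated from the repeated
measures panel by a linear **generalised estimating equation** with an
exchangeable working correlation and robust (sandwich) standard errors,
implemented directly in the package (cluster-level closed forms; with one
visit per subject it reduces exactly to ordinary least squares). The
exchangeable structure is the natural choice for a short panel of annual
visits; baseline covariates (age, sex, diabetes duration, weight, HbA1c)
can be included and were reported not to be significant in the source
analysis. Because control-arm utility data end at two years, the regression
models utility on *remission status* rather than on treatment arm; the
model then assigns every survivor the UK population-norm utility for their
age and sex with **relative decrements** for the two alive states: the
diabetes decrement is `(norm - predicted utility with diabetes at entry
age)/norm`, and the remission decrement is smaller by `effect/norm`. Death
has utility zero.

## The synthetic cohort generator

The generator is first-class, tested code: it defines the study conditions
under which every calibration claim in this package is evaluated.

* **Design**: two arms of 149, entry age 54, 59% women; 12-month remission
  0.46 / 0.05; conditional retention through years 2-5 of (0.783, 0.646,
  0.646, 0.646); annual dropout hazard 0.04, independent of remission by
  default (a dependence knob exists for informative-censoring
  experiments); single annual assessments additionally missing with
  probability 0.05; 58% of intervention participants in the years 3-5
  extension, which is what gates EQ-5D visits beyond year 2.
* **Costs**: per-category annual costs are gamma distributed (a point mass
  at zero when the mean is zero), multiplied by a participant-level
  lognormal frailty with CV 0.8 shared across categories and years. The
  frailty is what gives participant-year totals their published marginal
  dispersion (total SD ≈ 3500 against a mean of ~1800 in the control arm)
  and induces the within-participant cost correlation that a bootstrap of
  real records would see; within-category SDs are back-solved from the
  published marginal SDs (floored at 0.3 × mean, which binds for the
  well-behaved primary-care category). Years 2-5 means are split by
  remission status so that the implied proportional saving equals the
  packaged `s` while arm-year marginal means are preserved.
* **Intervention use**: sachets and visits by programme phase and year,
  gamma at the published means/SDs (total diet replacement and food
  reintroduction in year 1; weight-loss management and rescue packages
  through year 5).
* **EQ-5D**: utility = baseline mean (0.7702) + subject effect (SD 0.08) +
  0.037 × in-remission + visit noise (SD 0.07), clamped to the EQ-5D-3L UK
  index range [−0.594, 1]. The noise scales are deliberately modest: with
  them, ceiling clamping biases the estimated remission effect by under 3%,
  which is inside the tolerance of the recovery checks. Larger, more
  realistic noise would need an explicit ceiling-robust estimand.

What the generator does *not* emulate: HbA1c and weight trajectories,
medication-level prescribing, EQ-5D dimension profiles, correlated
cost-category shocks beyond the shared frailty, or informative censoring
(by default). Passing recovery tests on this cohort therefore shows the
estimators are correct under these assumptions — not that the assumptions
hold in any particular real dataset.

## Calibration of the packaged base case

The publication prints summary results but not all of its inputs (per-year
cost means, mortality rates, unit prices, years 3-4 remission). The
packaged defaults are therefore explicit calibration choices, solved once
and frozen in `R/defaults.R`:

* **Years 3-4 remission**: geometric interpolation between the printed
  year-2 and year-5 values (S = 0.46, 0.36, 0.233, 0.150, 0.097). A
  log-linear decline is the natural interpolant for a survival proportion;
  it is also the choice under which the five-year incremental QALY lands
  near the published 0.043 — a flatter interpolation overshoots the
  quality-of-life pathway.
* **Mortality**: Gompertz schedule `q(age) = a·e^{b(age-54)}` for people
  free of diabetes (slope b = 0.092, female rates 0.60 of male), scaled by
  a hazard ratio of 1.447 while living with diabetes; `a` and the hazard
  ratio were solved so the control arm's undiscounted life expectancy is
  23.48 years and the lifetime incremental QALY gain is 0.080.
* **Cost means**: control-arm per-year means follow a linear ramp
  (1604 → 1862 GBP, years 1-5), intervention means a proportional scaling
  (0.735), solved against the published discounted arm totals (7928 and
  5837 over five years; control lifetime 28476). The ramp's pooled mean
  sits ~5% below the published pooled participant-year means — the printed
  pooled means cannot be reconciled exactly with the printed discounted
  totals under any plausible survival, and the totals take precedence
  because they drive the cost-effectiveness arithmetic.
* **Remission saving fraction**: s = 0.810, solved so the lifetime
  incremental total cost equals −496 GBP.
* **Intervention unit costs**: the published component table (set-up 68,
  sachets 904 + 161, practitioner time 507 + 120) sums to 1760, above the
  published discounted total of 1691; the discounted sachet+time components
  alone sum to 1692 ≈ 1691, so whether set-up is inside the printed total
  is ambiguous. The packaged sachet price (1.451 GBP) is calibrated so the
  *discounted five-year total including set-up* equals 1691, leaving
  components ~4% under the printed ones; both discounted and undiscounted
  component tables are emitted by `analysis/02_costing.R`.
* **Utility levels**: the diabetes decrement (0.0939) anchors the control
  arm's five-year discounted QALYs at the published 3.37 (the intervention
  arm then lands on the published 3.41); the remission decrement follows
  from the 0.037 effect. Lifetime QALY levels come out ~1% above the
  published ones — levels are anchored at five years, increments are what
  the model is for.

With these defaults the deterministic model reproduces, without further
adjustment: five-year incremental cost −400, lifetime incremental cost
−496, lifetime healthcare totals 26289/28476, incremental life-years 0.084,
lifetime incremental QALYs 0.080 and five-year incremental QALYs 0.045
(published: 0.043).

## Probabilistic analysis

Uncertainty is propagated by 1000 iterations combining resampled
participant-level data (remission histories, healthcare resource use,
intervention use re-estimated in full each iteration), a Monte-Carlo draw
of the utility effect, and beta-distributed mortality draws (method of
moments around each packaged rate, SE = 15% of the rate — a stated knob,
since the source rates carry no printed uncertainty; draws are clipped so
remission never carries higher mortality than diabetes). Percentile
intervals use the empirical 2.5/97.5 points of the draws; the
cost-effectiveness acceptability curve is the fraction of draws with
positive net monetary benefit on a £0-50,000 grid (£1,000 steps), which at
threshold zero equals the probability of cost-saving exactly.

`run_psa()` offers two resampling schemes, and the distinction matters for
synthetic-data calibration:

* `"bootstrap"` — arm-stratified resampling with replacement at the
  original arm sizes, the scheme one applies to real trial data. Its draws
  are centred on the *supplied cohort's* point estimates.
* `"parametric"` — each iteration draws a fresh cohort from the generator
  truth and re-runs the whole estimation chain (including the utility
  regression, whose refit plays the role of the utility-effect draw).

A single simulated cohort of 149 per arm is itself one draw from the
sampling distribution that the bootstrap approximates: its point estimate
of the incremental cost differs from the generator truth by an amount
comparable to the bootstrap spread (≈ ±1100 GBP). A bootstrap centred on
that one draw therefore gives a probability of cost-saving anywhere from
~0.3 to ~0.95 depending on the cohort seed — not a defect of either
estimator, just what a single 298-participant study can say. Calibration
statements about the *method* ("with these study conditions, the
probability of cost-saving is about two-thirds") are statements about the
truth-centred distribution, so the calibration checks and the acceptance
workflow use the parametric scheme; the bootstrap scheme is exercised and
property-tested in its own right.

## Scenario analyses

`apply_scenario()` modifies the base inputs along the published axes:
scaling the mortality benefit of remission (interpolating the remission
death probability between the without-diabetes and with-diabetes rates),
scaling the utility effect, halving the whole remission schedule (years 1
and 2 included), switching years 1-5 costing from arm-level to
arm-by-remission-status means (intervention costs stay assigned by arm),
and restricting the horizon to five years. Scenario PSAs share one seed so
differences between rows are attributable to the modification; as a
consequence, scenarios that only touch utilities reproduce the base-case
cost draws bit for bit.

## Numerical and design notes

* Occupancy is conserved to 1e-12 each cycle; death is absorbing; the
  engine is tested against an independently written scalar per-cycle loop.
* Ages beyond the packaged norm table are clamped to its last band with a
  warning; mortality tables that stop short of the horizon are an error.
* The ICER is reported as a dominance label when ΔC < 0 and ΔQ > 0, and as
  signed infinity with a flag when ΔQ = 0.
* Percentile intervals use type-1 (inverse-ECDF) quantiles so that with two
  draws they are the draw extremes.
* Ties at an annual visit: relapses are processed before recorded
  censorings (see the remission section for unrecorded visits).
* Problem sizes in the shipped workflow: the acceptance workflow uses 50
  replicate panels/arms for the recovery studies and 1000 PSA iterations;
  `analysis/07_scenarios.R` defaults to 300 iterations per scenario, a
  size chosen to keep the full eight-scenario table to a few minutes while
  leaving the Monte-Carlo error on each probability below ~0.03. All are
  configuration values, not limits of the method.

## Known limitations

* The packaged mortality, unit-cost and per-year cost-mean defaults are
  calibration constructs, not national statistics; anyone applying the
  package to real data should replace them (`make_mortality_table()`,
  `unit_costs(path=)`, `estimate_inputs()`).
* The cost model attributes all within-participant cost correlation to one
  multiplicative frailty; real records correlate through admission
  episodes and chronic prescribing with heavier tails than a gamma.
* The utility analysis conditions on remission status only; weight loss
  without remission, which plausibly carries utility and cost benefits of
  its own, is visible in the cost data but not modelled as a pathway.
* Remission beyond 10 years, second remissions, and diabetes
  complication sub-states are out of scope by design.
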