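# remitce

Cost-effectiveness modelling of primary-care weight-management programmes
that induce remission of type 2 diabetes, for health economists and
methodologists who want the full analysis chain — survival-based remission
modelling, censored-cost estimation, repeated-measures utility regression,
a Markov cohort model and probabilistic sensitivity analysis — as tested,
reusable R code rather than a spreadsheet.

## The model

A three-state Markov cohort model (type 2 diabetes → remission → death;
relapse back to diabetes, death absorbing) with annual cycles, entry at age
54 with 59% women, and UK discounting of 3.5% per year for costs and
outcomes. The arms differ through:

* **Remission**: the arm-level proportion in remission at year *t* is
  `S(t) = p₁₂ × M(t)`, with `p₁₂` the 12-month remission proportion and
  `M(t)` Kaplan–Meier maintenance among remitters under the trial's
  censoring rules. Beyond year 5, `S(t) = S(5)·r^(t−5)` with
  `r = (S(5)/S(1))^(1/4)`, and `S(t) = 0` after 10 years.
* **Mortality**: while in remission the cohort dies at without-diabetes
  rates, otherwise at with-diabetes rates (`q_nd ≤ q_d` at every age), so
  remission buys life-years.
* **Costs**: annual healthcare costs enter as Kaplan–Meier sampling-average
  means per arm-year (means among those under observation, applied to the
  modelled proportion alive); beyond year 5, the control arm's year-5
  non-remission cost applies, cut by a proportional saving `s` during
  remission. Intervention delivery costs (set-up, formula-diet sachets,
  practitioner time) apply to the intervention arm in years 1–5 only.
* **Utilities**: every survivor gets the UK population-norm utility for
  their age/sex with a relative decrement per alive state; the decrement
  gap is driven by a remission effect on EQ-5D-3L utility of 0.037,
  estimated by an exchangeable-correlation GEE with robust SEs.

Outputs are discounted costs, life-years and QALYs per arm over 5-year and
lifetime horizons, the incremental cost-effectiveness ratio or a dominance
label, net monetary benefit, bootstrap/Monte-Carlo probabilistic
sensitivity analysis with a cost-effectiveness acceptability curve (CEAC),
and the published set of structural scenario analyses.

Because the underlying trial data are individual NHS records, the package
ships a synthetic participant-level cohort generator
(`generate_cohort()`) calibrated to the published summary tables; it is
first-class, tested code and defines the conditions under which every
calibration claim here is checked. See the methods vignette
(`vignettes/cost-effectiveness-model.Rmd`) for the model, the calibration
choices and their rationale.

## Worked example

```r
library(remitce)

ce <- summarize_ce(run_model(base_case_inputs()))
print(ce)
```

prints (packaged calibrated base case, GBP 2020/21):

```
Cost-effectiveness summary (lifetime horizon)
 five_year:
    hc_cost                interv    5837.00  control    7928.00  incr  -2091.000
    ic_cost                interv    1691.00  control       0.00  incr   1691.000
    total_cost             interv    7528.00  control    7928.00  incr   -400.000
    qaly                   interv       3.41  control       3.37  incr      0.045
 full:
    total_cost             interv   27980.00  control   28476.00  incr   -496.000
    qaly                   interv      11.14  control      11.06  incr      0.080
    life_years             interv      23.56  control    23.48  incr      0.084
  cost per QALY: dominant
```

Read: over five years the programme costs £1691 per participant to deliver
but saves £2091 in healthcare resource use, a net saving of £400; over a
lifetime the saving grows to £496 while adding 0.080 QALYs (0.084
life-years), so the intervention *dominates* usual care — cheaper and more
effective. A probabilistic run quantifies the uncertainty:

```r
co  <- generate_cohort(generator_params(seed = 1))
psa <- run_psa(co, n_iter = 1000, seed = 3, resample = "parametric")
print(psa)
#> PSA: 1000 iterations (seed 3, 0 redrawn)
#>   incremental cost: -515 (95% CI -2718, 1489)
#>   incremental QALY: 0.078 (95% CI 0.035, 0.134)
#>   P(cost-saving) = 0.685; P(cost-effective at 20k) = 0.960
plot_ceac(psa)
```

About two-thirds of draws are cost-saving outright, and at a willingness to
pay of £20,000 per QALY roughly 95% are cost-effective.

## The analysis workflow

The numbered drivers under `analysis/` run the full study and write tidy
tables under `results/`:

| script | stage |
|---|---|
| `01_simulate.R` | draw the synthetic cohort, write it as CSV + manifest |
| `02_costing.R` | per-annum cost summary, KM sampling-average means, intervention cost components |
| `03_remission.R` | relapse/censoring classification, KM schedules, extrapolation |
| `04_utility.R` | GEE utility regression and state-utility decrements |
| `05_base_case.R` | deterministic model (packaged and data-estimated inputs) |
| `06_psa.R` | 1000-iteration PSA (bootstrap and parametric), CEAC figure |
| `07_scenarios.R` | structural scenario table under a shared seed |

Each is a thin narrative over package functions; everything computational
lives in `R/` and is unit-tested.

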