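# periopcea

Trial-based cost-effectiveness analysis of perioperative, cardiac
output-guided haemodynamic therapy versus usual care in high-risk patients
undergoing major gastrointestinal surgery.

Whether fluid and inotrope therapy guided by cardiac output monitoring is
worth adopting is an economic question as much as a clinical one: the
intervention adds equipment and drug costs but may avert complications,
critical-care days and deaths. `periopcea` implements the full
health-economic evaluation of a two-arm, multi-site randomised trial of this
question — from patient-level records to 6-month and lifetime
cost-effectiveness, decision uncertainty and value of information — as a
reusable, tested R pipeline. Because the trial's patient-level data are not
publicly deposited, the package ships a synthetic-trial generator with known
ground truth, so every stage of the analysis is testable end to end.

## What it computes

For intervention vs usual care, with willingness to pay λ per QALY:

* **QALYs** by the area-under-the-curve method: each patient's EQ-5D-3L
  profiles at randomisation, 30 days and 6 months are scored to a utility
  index *u* with the UK general-population value set, and
  QALY = ∫ u(t) dt over the half-year, anchored at the day-30 score, with
  zero utility at assessments after death.
* **Costs** from resource use at 2012–13-style unit costs: reference
  procedure cost minus the embedded average stay (avoiding double counting),
  critical-care days by level, ward days, monitor use, dopexamine, fluids
  and blood products.
* **Incremental cost and QALY** (Δc, Δq) by bivariate regression — cost and
  QALY equations with identical covariates (age, sex, urgency, surgical
  category, post-operative location, ASA grade, comorbidities, baseline
  EQ-5D) and a random site intercept, so the SUR point estimates equal
  per-equation least squares, with the cross-equation covariance taken from
  the residual correlation. Missing utilities are multiply imputed (chained
  equations, predictive mean matching) and pooled by Rubin's rules.
* **Incremental net monetary benefit** INB(λ) = λΔq − Δc, its
  **cost-effectiveness acceptability curve** P(INB(λ) > 0) over £0–£50,000,
  and pre-specified subgroup analyses.
* **Lifetime extrapolation**: survivors at 6 months accrue further QALYs
  under age-sex-matched life-table mortality (base case; parametric
  survival models ranked by AIC and screened for plausibility as a
  sensitivity), with quality of life interpolated to population norms
  between years 1 and 2, discounted at 3.5% per annum.
* **Expected value of perfect information**: under normal INB,
  EVPI = σ·[φ(z) − z·Φ(−z)] with z = |μ|/σ per patient, scaled to the
  discounted effective population.

## Worked example

Simulate the default synthetic trial (734 patients, 17 sites, 7.6% vs 11.5%
six-month mortality, true Δc = −£400, Δq = 0.01) and run the full pipeline:

```r
library(periopcea)

cfg <- analysis_config(trial = trial_design(seed = 2),
                       m_imputations = 20, seed = 2,
                       subgroups = "recruitment_timing")
res <- run_analysis(cfg)
print(res)
```

```
Cost-effectiveness analysis of 734 patients

Cost-effectiveness estimate [6m base case]
  incremental cost :    -1117 (-2081 to -153) GBP
  incremental QALY :   -0.008 (-0.025 to 0.009)
  INB at 20000/QALY:      952 (-68 to 1972) GBP

Cost-effectiveness estimate [lifetime base case]
  incremental cost :    -1117 (-2081 to -153) GBP
  incremental QALY :    0.182 (-0.224 to 0.588)
  INB at 20000/QALY:     4764 (-3335 to 12863) GBP

  P(cost-effective at 20000/QALY), lifetime: 88%

Expected value of perfect information at 20,000 GBP/QALY
  INB 4764 (SD 4132) GBP
  per patient : 255 GBP
  population  : 69.00 million GBP (270,503 patients)
```

Reading this: the intervention saved money on average (lower critical-care
and ward use more than offset the monitor and dopexamine), the 6-month QALY
difference is small and uncertain, and most of the lifetime QALY gain comes
from the mortality difference projected over remaining life expectancy. At
£20,000/QALY the lifetime incremental net benefit is positive with an 88%
probability of cost-effectiveness, and resolving the remaining uncertainty
would be worth about £255 per future patient (£69M over the eligible
population) — the case for a confirmatory trial.

`run_analysis()` also writes CSV/JSON outputs (arm summaries, incremental
estimates, CEACs, sensitivity and subgroup tables, run log) when
`out_dir` is set, and `inst/scripts/run_analysis.R` wraps it for the shell.
Individual stages are exported: `generate_trial()`, `eq5d_index()`,
`compute_qalys()`, `compute_costs()`, `impute_trial()`, `fit_bivariate()`,
`pool_estimates()`, `inb()`, `ceac()`, `lifetime_cea()`, `evpi()`.

## Limitations

Unit costs, the life table and the population utility norms bundled here are
documented placeholders/synthetic stand-ins (the published schedules are not
redistributed); supply your own tables for analyses of real data. See the
methods vignette (`vignettes/methods.Rmd`) for the model, its assumptions
and the design choices.
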