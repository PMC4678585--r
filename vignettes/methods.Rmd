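---
title: "Methods: trial-based and lifetime cost-effectiveness in periopcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-based and lifetime cost-effectiveness in periopcea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periopcea)
```

`periopcea` evaluates perioperative, cardiac output-guided haemodynamic
therapy against usual care from an NHS perspective. This vignette is the
package's own account of the models it implements, the parameters that
matter, the numerical choices, and what the synthetic-data tests do and do
not establish.

## Outcomes: utilities and QALYs

EQ-5D-3L profiles are scored with a pluggable value set
(`eq5d_value_set()`): index = 1 − constant − per-dimension level decrements
− an N3 term if any dimension is at its worst level. The bundled UK
general-population tariff has floor −0.594 (profile 33333); states worse
than death score negatively and are integrated as such — the QALY is
reported, never clipped. Coefficients live in a versioned CSV
(`inst/extdata/uk_mvh_valueset.csv`); the engine hard-codes nothing.

QALYs use the area under the utility–time curve over 0.5 years with
assessments at 0, 1/12 and 1/2 years (1 month = 30.4375 days, 6 months =
182.625 days, so year fractions are exact). The base case anchors t = 0 at
the **day-30** index: both arms' randomisation scores reflect the surgery
itself, so the post-operative value is the more meaningful baseline for the
curve. The randomisation score is *not* discarded — it enters the
regression as a covariate; the two roles are distinct. Decedents score zero
at every assessment after death (base case) or, in a sensitivity variant,
decline linearly from the last observed value to zero at the death date.
Death before the day-30 assessment makes the whole base-case curve zero.
A missing utility that the rules need is flagged for imputation, never
silently substituted — in particular a missing day-30 anchor in a survivor
is imputed, not replaced by the randomisation value.

## Costs

Per-patient 6-month cost = adjusted surgery cost + critical-care days by
level + ward days + intervention equipment/drugs + fluids and blood.
National reference costs average over the procedure *and* its hospital
stay, while bed days are costed from each patient's observed stay, so the
average length of stay at the ward rate plus one recovery day is subtracted
from the reference cost (floored at zero with a warning). Choices the
source schedules leave open, fixed here: intra-operative and post-operative
fluid volumes are costed at the same per-ml rates; blood products are per
ml (a per-unit tariff is expressible by dividing by unit volume); the
monitor is costed per patient-use with no duration structure; usual-care
patients in whom a monitor was used incur its cost (intention-to-treat
costing of actual resource use). The base case adds no staff time; two
staffing scenarios (`s1`, `s2`) add it back as pure add-ons so their effect
on any total is an exact closed-form shift.

## Six-month estimation

Costs and QALYs are analysed jointly: both equations share the identical
covariate set (age, sex, urgency, surgical category, post-operative
location, ASA grade, renal impairment, diabetes, cardiac/respiratory risk,
baseline EQ-5D) plus a site effect, so the seemingly-unrelated-regression
point estimates coincide with per-equation least squares. Each equation is
fitted as a linear mixed model with a random site intercept (default) or
with site fixed effects and cluster-robust errors (`site_mode =
"fixed_cluster"`); the source analysis names a random site effect but not
the estimator, so the mixed model is the default and the robust variant the
fallback. The cross-equation covariance of the two treatment coefficients
is `r`·se~c~·se~q~ with `r` the level-1 residual correlation.

Missing utilities among survivors are imputed by chained equations with
Bayesian predictive mean matching (donor pool 5): coefficients are drawn
from their posterior and each missing value takes an observed donor value
with the nearest drawn prediction. Matching keeps imputations inside the
observed support of the value set; Gaussian draws clipped at the utility
ceiling showed a small systematic downward shift in masking experiments,
which is why matching is the method. Post-death utilities are structural
zeros, not missing. `m = 20` imputations by default (the source does not
state m; 20 is standard practice), each seeded as `seed + j`. Estimates are
pooled by Rubin's rules: mean point estimate; total covariance = mean
within-imputation covariance + (1 + 1/m) × between-imputation covariance,
element-wise.

INB(λ) = λΔq − Δc with variance λ²V~q~ + V~c~ − 2λC. The acceptability
curve is Φ(mean/SE) under a bivariate-normal approximation — consistent
with the normal-INB assumption the value-of-information analysis makes; a
within-site patient bootstrap (`ceac_bootstrap()`) is available to check
skew. Subgroups (urgency, surgical category, first-ten vs subsequent
recruits per site) reuse one global imputation and subset each completed
dataset, so subgroup contrasts are not distorted by subgroup-specific
imputation models; levels too small to support the pre-specified covariate
set fall back to age + sex + baseline EQ-5D with a warning.

## Lifetime extrapolation

High-risk surgical cohorts should not out-survive the general population,
and parametric fits to a 6-month window tend to predict implausibly low
long-term mortality. The base case therefore applies age-sex-matched
life-table death rates beyond the 6-month landmark, implemented as a
standardised-mortality-ratio multiplier on qx with SMR = 1 — so excess-rate
variants and the parametric sensitivity share one code path.
`fit_parametric()` fits exponential, Weibull, Gompertz, log-normal and
log-logistic models by maximum likelihood with right censoring;
`select_model()` ranks by AIC (= 2k − 2logL), breaks exact ties by the
fixed family order just given, and reports each family's predicted annual
death rates against the life-table rates at the cohort's age-sex mix — the
selection is surfaced, not silently automated.

Survivors' post-landmark utility starts at the arm-level mean 6-month
utility (the source uses the age-72 cohort mean; an arm-pooled option
exists), stays there to year 1, declines linearly to the age-referenced
population norm between years 1 and 2, and tracks the norm thereafter;
sensitivity `s5` freezes it for life. Annual cycles with half-cycle
correction are the default (the source states neither; both are exposed):
each cycle contributes the trapezoidal mean of its boundary survival
probabilities at the mid-cycle utility and discount factor. Discounting
(3.5%/year) starts at the landmark — within-trial QALYs are undiscounted —
with the first cycle discounted by half a cycle. No post-6-month costs are
modelled, so the lifetime incremental cost equals the 6-month one. Setting
the discount rate to 0 reproduces undiscounted sums exactly, zero
post-landmark survival reproduces the 6-month estimate exactly, and norms
equal to the 6-month mean make the frozen and interpolated paths identical
— these limits are asserted in the test suite.

## Value of information

With INB(λ) ~ N(μ, σ²), per-patient EVPI = σ[φ(z) − zΦ(−z)], z = |μ|/σ.
A 95% CI converts to σ via 1.959964 (the normal quantile, consistent with
the normality assumption). The effective population is either supplied
directly — the published figure of 270,503 eligible patients over 5 years
is consumed as given, since whether it is pre- or post-discounting is not
stated — or derived as Σ~t~ incidence/(1+r)^(t−1).

## The synthetic-trial generator

`generate_trial()` emulates the statistical structure the analysis assumes,
with exactly known ground truth:

* **Covariates** follow the trial's baseline table (age ~ N(71.7, 8.5²)
  truncated to [50, 95], 63% male, 97% elective, the four surgical
  categories, ASA mix, post-operative location, comorbidity rates).
* **Death** within 6 months is Bernoulli per arm (defaults 0.076 / 0.115)
  with truncated-exponential times — only the 6-month proportion is
  anchored, so the within-window shape is the simplest one.
* **Utilities** at the three assessments are multivariate normal with
  AR(1) correlation (default 0.5), residual SD 0.29, additive site
  intercepts and centred covariate effects, clipped to the value-set range
  [−0.594, 1]. The *true* baseline mean is common to both arms: in a
  randomised trial baseline distributions are equal by design, and building
  the baseline table's (noise-level) arm difference into the truth would
  leak into the baseline-adjusted treatment contrast. A constant
  post-randomisation shift in the intervention arm is solved numerically —
  through the clipping and the mortality contrast — so the true base-case
  QALY difference equals `true_delta_qaly` exactly for the realised
  covariates and sites.
* **Costs** are an itemised fixed part (adjusted surgery, monitor,
  dopexamine, fluids, blood — drawn to match the resource-use table) plus a
  gamma bed-day part with log-link covariate effects and additive site
  intercepts, whose arm means are calibrated so the totals differ by
  exactly `true_delta_cost`; the bed-day pounds are decomposed into
  level-2/3 critical-care and ward days at the unit-cost rates so the
  costing module reconstructs the generated totals exactly. The default
  gamma shape 0.75 was chosen once to reproduce total-cost SDs near the
  published 6304/7217 given the fixed components (the source reports no
  per-component SDs).
* **Missingness** of survivor questionnaires is missing-at-random by
  construction: its probability depends on arm and age only, never on the
  masked value (verifiable by regenerating without masking).

What passing tests show — and don't. Parameter recovery (500 replicates at
n = 734: bias within Monte-Carlo error, 93–97% CI coverage) validates the
estimation chain under the generator's assumptions: linear covariate
effects, gamma costs independent of utilities and of death, AR(1) utilities,
exponential death times, exchangeable site intercepts. Real trial data can
violate any of these — cost–outcome correlation at the patient level,
informative missingness, non-exchangeable sites — and the suite says
nothing about robustness to them beyond the cluster-robust fallback and the
bootstrap CEAC.

## Problem sizes and numerical choices

The test suite runs the recovery study at the trial's size (500 × 734) and
the oracle comparisons at 10^5 (CEAC Monte-Carlo) and 10^6 (EVPI
opportunity-loss) draws; the masking-recovery suite uses 100 replicates of
240 patients with 30% masking — sizes chosen so each check's Monte-Carlo
error is well below the effect it guards. QALY integration is exact
trapezoidal quadrature on the piecewise-linear curve (agreement with
fine-grid integration to 10⁻⁹ is asserted). Model selection ties break
deterministically; rank-deficient designs raise an error naming the
collinear terms rather than silently dropping them. The bundled life table
is a Gompertz–Makeham stand-in and the utility norms a linear-in-age
stand-in, both labelled synthetic; analyses of real data should supply the
published schedules.
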