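---
title: "Methods: a Markov cohort model of obesity-related complications"
author: "obesim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort model of obesity-related complications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(obesim)
```

## The model

`obesim` implements a deterministic, discrete-time, closed-cohort
state-transition (Markov) model for the complications of overweight and
obesity. A cohort enters with a shared mean cardiometabolic risk-factor
vector (age, BMI, SBP, lipids, smoking and medication shares, HbA1c and
diabetes duration for the diabetic stratum) and a baseline split across
glycemic strata. Each annual cycle, a row-stochastic transition matrix is
rebuilt from the current risk factors and the cohort's probability mass is
propagated through it. Cohort (rather than individual-level) simulation was
chosen deliberately: it is transparent, fast, and exactly reproducible,
at the price of simulating mean-level risk rather than individual
heterogeneity.

### State space

The enumeration is the constrained product of glycemic status
(NGT, prediabetes, T2D) and cardiovascular history (event-free, acute ACS
year, post-ACS, acute stroke year, post-stroke), plus three standalone
cancer states (colorectal, postmenopausal endometrial, postmenopausal
breast) and one absorbing death state — 19 mutually exclusive states in
all (`health_states()`). Acute event years are separate states so that
case fatality and recurrent-event risk can differ from later years.
`state_families()` collapses the acute/post distinction into the
single-or-combined comorbidity families used for reporting. Two
simplifications are worth stating plainly:

* the model tracks the **most recent** CV event type: a post-stroke
  cohort fraction that suffers an ACS is subsequently tracked as
  post-ACS, and vice versa;
* cancer states do not retain the glycemic/CV sub-classification.
  Because survival after these cancers is driven by the flat cancer
  mortality, the loss of glycemic detail there has little effect over
  the horizons simulated.

Knee replacement, bariatric surgery and sleep apnea are not states:
they can co-occur with every state, so the engine treats knee
replacement as a tallied overlay event and sleep apnea as a prevalent
attribute share with no mortality effect.

A severity partial order is enforced by construction and by
`validate_matrix()`: glycemic status never regresses
(T2D → prediabetes entries must be exactly zero), an acquired CV
history is never lost, cancer states are left only for death, and death
is absorbing. For CV history only "has a history" is ordered — moving
from a post-event state into a new acute event year is a progression,
not a regression.

### Competing transitions within a cycle

From each alive state the engine computes *marginal* annual
probabilities for every competing move (glycemic progression, first or
recurrent CV event split into ACS vs stroke, cancer onset), takes the
death probability from the mortality layer, and assigns the remaining
mass to staying put. If the marginal event probabilities ever exceeded
the surviving mass they would be rescaled proportionally to fit — the
standard cohort-model normalization; at realistic magnitudes the
rescaling never triggers. Only single-attribute moves are allowed per
cycle, except that a cohort fraction in an acute event year settles
deterministically into its post-event state (minus case fatality) and
defers other transitions for that one cycle. No half-cycle correction
is applied by default (`half_cycle = TRUE` enables one for
person-years); the validation statistics reported here were reproduced
without it.

## Risk engine

Risk equations enter through a registry of pluggable models
(`risk_registry()`), each mapping a risk-factor vector to a cumulative
K-year risk. Published equation families (QDiabetes / Framingham
Offspring for diabetes incidence; QRISK3 / Framingham for first CV
events in normoglycemia; UKPDS OM2 / NDR for diabetic cohorts;
Framingham recurrent-CHD for recurrence) are licensed and distributed
separately, so the package ships documented **toy logistic models**
(`example_registry()`) with plausible monotone gradients in BMI, age,
SBP and HbA1c. They exercise every code path and every qualitative
property (monotonicity, stratum ordering) but are synthetic: passing
tests demonstrates engine correctness, not calibration to any real
population. Coefficient files for real equations drop in via
`read_risk_model()`.

Three conversion rules are fixed and tested to closed form:

* **Annualization.** A K-year cumulative risk becomes an annual
  probability by the geometric (constant-rate) rule
  $p_1 = 1-(1-p_K)^{1/K}$, whose K-fold compounding is the exact
  inverse. Whether the original implementation annualized this way is
  not documented anywhere we could check; this is the standard choice
  and is stated rather than attributed.
* **Hazard ratios.** Applied on the complementary-log scale,
  $p' = 1-(1-p)^{\mathrm{HR}}$, which stays inside $[0,1]$ for any
  positive ratio and agrees with naive multiplication to well under
  $10^{-4}$ at annual-probability magnitudes.
* **Prediabetes.** Diabetes incidence for the prediabetic stratum is
  obtained by forcing the glycemic marker in the T2D equation to
  42 mmol/mol, taken as equivalent to 6.0% (the equivalence is used as
  conventionally stated even though the exact IFCC conversion differs
  slightly); the NGT stratum uses a normoglycemic 5.5%. Prediabetes has
  no CV equations of its own: first events borrow the NGT model,
  recurrent events the T2D model, reflecting the elevated recurrent
  risk in impaired glucose tolerance.

The composite CVD probability is split into ACS vs stroke by a
configurable proportion. The default, 3.4/7.8 ≈ 0.436, is calibrated
once from the observed normal-weight split of UA/MI vs stroke/TIA rates
in the packaged validation table; how a composite endpoint is
repartitioned visibly shifts its component predictions, which is why
the parameter is exposed.

BMI-graded complications (cancers, knee replacement, sleep apnea) use a
reference-stratum annual rate adjusted by a BMI-stratum hazard ratio.
The shipped reference rates and gradients (`default_baseline_rates()`,
`default_hr_tables()`) are placeholders in realistic ranges — the
sources behind the original parameterization are not reproduced here —
and are plainly flagged as user-configurable. Postmenopausal cancers
apply only to the female share of the cohort at or beyond the mean age
at menopause (default 51 years, the conventional population mean, which
the baseline table does not record).

## Mortality layer

Background mortality is an exact age lookup in a life table, mixing the
female and male columns by the cohort's female share. Event-year case
fatality replaces background mortality in the acute cycle (MI/unstable
angina 30.00% F / 32.00% M; stroke 24.70% F / 17.10% M; cancer onset
30.11% / 10.54% / 4.08% for colorectal / endometrial / breast, applied
on the transition into the cancer state). Post-onset years apply
relative risks to the life-table probability (1.30 post-ACS, 2.00
post-stroke) or a flat 4.31% annual cancer mortality; the adjusted
probability never falls below base mortality. The onset probabilities
are treated as first-cycle (annual) case fatality — whether their
sources report 30-day or first-year fatality is not recoverable, and
with annual cycles the first-cycle reading is the only consistent one.
When several triggers apply simultaneously (CV history plus cancer) the
maximum of the adjusted probabilities is used; multiplicative stacking
of the RRs is available (`stacking = "multiplicative"`) but is not the
default because compounding partially overlapping risks overstates
mortality. Knee replacement's 0.30% operative mortality is exposed in
`adjusted_mortality()` but not wired into the engine's death column:
as an overlay on annual incidence of a few per 1000 it contributes
~1e-5 to annual mortality, far below every other uncertainty. Sleep
apnea has no mortality effect, enforced.

Users supply national life tables as `age,sex,qx` CSV
(`read_life_table()`). For self-contained runs and tests,
`synthetic_life_table()` generates a Gompertz table
($q_x = 1-\exp[-(b/c)(e^{c(x+1)}-e^{cx})]$) whose defaults
($b_F = 2\times10^{-5}$, $b_M = 3\times10^{-5}$, $c = 0.095$) give
roughly 2 per 1000 annual mortality at age 50 rising to ~5% at 80 —
representative of a contemporary high-income population, and verified
in tests against the closed-form survivor function. Ages beyond the
table carry the last value forward, with a warning.

## Risk-factor dynamics

Fields are static (height, triglycerides, smoking, sex and
lipid-lowering shares, menopause age) or dynamic (age, BMI, SBP,
cholesterol, HbA1c, diabetes duration, antihypertensive share). A
treatment profile expresses on-treatment changes from baseline (BMI as
a percentage; SBP, HDL, total cholesterol absolutely; HbA1c in points).
After treatment stops, the induced deltas return **linearly** to zero
over the catch-up period — the sources describe regain "after a defined
period" without a shape, so the linear ramp is the package's choice,
with a step rebound recoverable by setting `catchup_years = 0`.
Afterwards natural drift applies (BMI upward until a stop age; HbA1c
upward in an all-diabetic cohort). The trajectory is a deterministic
function of the baseline vector and cycle index, so runs are exactly
reproducible. `freeze_bmi()` switches to the validation-mode
trajectory: every dynamic field held at baseline while age and diabetes
duration still advance.

The female share is treated as static; with sex-differential mortality
the true surviving share drifts slightly female, an approximation that
matters only at horizons long enough for substantial male excess
mortality. The NGT → prediabetes progression probability has no
published equation slot; it defaults to 0.02/year (a mid-range annual
progression figure for normoglycemic adults) and is exposed as
`ngt_to_prediabetes`.

## Validation workflow

`run_validation_study()` reproduces the comparative analysis: five BMI
groups (normal weight as reference) are simulated for 10 years with
100 individuals each, **keeping the reference group's baseline
characteristics and swapping in each group's mean BMI**, with BMI
frozen and no treatment. Event tallies become rates per 1000
patient-years by dividing cumulative events by undiscounted
person-years within the horizon (members alive at each cycle end).
Observed comparator rates are Cox-adjusted: the reference group's crude
rate multiplied by each stratum's proportional hazard ratio
(`cox_adjust()`).

The base scenario uses the reference group's recorded glycemic split
(95.3% / 2.0% / 2.7%); the `"hse-prediabetes"` scenario replaces it
with the survey-based split 71.4% / 25.9% / 2.7%, leaving T2D
prevalence unchanged — prediabetes prevalence from routine laboratory
records is known to be a substantial undercount.

Concordance is summarised by the zero-intercept least-squares line of
predicted (Y) on observed (X): slope $\sum o_i p_i / \sum o_i^2$, below
1 meaning underprediction. The $R^2$ convention for a forced-origin fit
is ambiguous; this package uses $1 - SS_{res}/SS_{tot}$ with residuals
about the fitted line and $SS_{tot}$ the sum of squares of the
*predicted* values about their own mean. This convention was selected
by brute force: among the candidate conventions (totals about the mean
of predicted, about the mean of observed, uncentered), only this one
recovers every published slope/$R^2$ pair from the packaged rate table,
including the strongly negative mortality values — negative because the
predictions are nearly flat across BMI groups while the forced-origin
line is steep, so the line explains the predictions far worse than
their own mean does. Slopes and $R^2$ are reported to 3 decimals, rates
to 1 decimal, matching the published precision. Two printed statistics
(mortality base-case slope and $R^2$) differ in the final digit from
what the rounded published inputs yield (0.444 vs 0.445; −26.839 vs
−26.840), as does one Cox-adjusted stroke cell (4.0 vs 4.1): those
published values were evidently computed from unrounded inputs that are
not recoverable, and the package reports what the printed inputs give.

## Problem sizes, tolerances and degenerate inputs

* Occupancy mass is validated to sum to 1 within $10^{-9}$ at every
  step; the engine itself conserves mass to machine precision.
* Validation runs use 5 cohorts × 10 annual cycles × 19 states
  (n = 100); engine property checks run 40-year horizons. All are
  sub-second; the full suite runs in well under a minute.
* `annual_probability(1, K)` returns exactly 1; `ols_zero_intercept()`
  rejects unequal lengths, all-zero observed vectors and constant
  predictions; `cox_adjust()` requires a hazard ratio for every
  stratum; BMI outside all hazard-ratio strata clamps to the nearest
  stratum with a warning; config errors name the offending field.

## Known limitations

The shipped risk models are synthetic stand-ins: absolute predicted
rates are illustrative until real coefficient sets are plugged in, and
engine-level tests establish structure (conservation, monotonicity,
ordering), not epidemiological calibration. Cost and quality-of-life
accumulation are deliberately out of scope (the state engine exposes
occupancy traces from which payload accumulation can be computed
externally). Bariatric surgery is named in the state overlay design but
not parameterized. Mortality underprediction at high BMI — visible in
the packaged validation table itself — is inherited from the modelled
mortality structure, in which BMI acts only through the complication
pathway.
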