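# obesim

A discrete-time **Markov closed-cohort model of obesity-related
complications** for health-economic decision analysis, with prediabetes
as an explicit glycemic risk stratum, plus the external-validation
workflow that compares model-predicted event rates with Cox-adjusted
observed rates.

It is aimed at modellers and HTA analysts who need a transparent,
scriptable cohort engine: the probability mass of a cohort moves
annually across 19 mutually exclusive health states — glycemic status
(NGT / prediabetes / T2D) crossed with cardiovascular history
(event-free / acute ACS year / post-ACS / acute stroke year /
post-stroke), three obesity-associated cancers, and death. Transition
probabilities come from a pluggable registry of cardiometabolic risk
equations; age- and sex-specific life-table mortality is layered with
event-year case fatality and post-event relative risks.

Key quantities, in the field's standard notation:

- annualization of a K-year cumulative risk: `p₁ = 1 − (1 − p_K)^(1/K)`;
- hazard-ratio application: `p' = 1 − (1 − p)^HR`;
- prediabetic T2D incidence: the T2D equation evaluated with HbA1c
  forced to 42 mmol/mol (6.0%);
- event rates: cumulative events ÷ person-years × 1000;
- Cox-adjusted observed rate: reference-group crude rate × stratum HR;
- concordance: zero-intercept OLS of predicted (Y) on observed (X),
  slope `Σoᵢpᵢ / Σoᵢ²` (<1 = underprediction), with `R² = 1 − SSres/SStot`,
  SStot about the mean of the predictions.

## Worked example

```r
library(obesim)

# Normal-weight reference cohort (packaged baseline table), 10 years,
# BMI held constant, toy risk-equation registry:
prof <- validation_cohort(group = 1, scenario = "base")
run  <- run_cohort(prof, horizon = 10, freeze = TRUE)
print(run)
#> Markov cohort run: n = 100, 10 annual cycles
#>   person-years 977.6 (life expectancy within horizon 9.78 y)
#>   deaths 4.75; T2D onsets 4.20; ACS 1.45; strokes 1.88

round(event_rate(run, "mortality"), 1)
#> [1] 4.9
```

`person-years 977.6` is the undiscounted time alive contributed by the
100-person cohort within the horizon; dividing the 4.75 expected deaths
by it gives the all-cause mortality rate of 4.9 per 1000 patient-years.

The concordance statistics on the packaged observed/predicted table:

```r
fit <- ols_zero_intercept(fixture_rates("cv_total", "observed"),
                          fixture_rates("cv_total", "com8_base"))
print(fit)
#> Zero-intercept OLS concordance: slope 1.091, R2 0.750
#>   (slope > 1: overprediction)
```

A slope of 1.091 says total CV event rates are overpredicted by ~9%
across the five BMI groups.

The full observed-vs-predicted study, under the survey-adjusted
baseline prediabetes prevalence:

```r
st <- run_validation_study(scenario = "hse-prediabetes")
print(st)   # rates per BMI group + slope/R2 per outcome
```

A thin command-line front end lives in `inst/cli/obesim.R`
(`simulate --config cfg.yaml`, `validate --scenario base|hse-prediabetes`,
`concordance --observed obs.csv --predicted pred.csv`).

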