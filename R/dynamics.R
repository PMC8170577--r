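# Cohort risk-factor vector, treatment effects, and per-cycle dynamics
# (treatment application, linear catch-up after stopping, natural drift).

#' Cohort-level cardiometabolic risk-factor vector
#'
#' Mean risk-factor values plus population shares, with fixed units:
#' age in years, BMI in kg/m^2, height in cm, SBP in mmHg, cholesterol
#' and triglycerides in mg/dL, HbA1c in % (describes the diabetic
#' stratum). Shares are proportions in \[0, 1\]. The baseline vector is
#' stored alongside so trajectories are reproducible.
#'
#' @param age,bmi Required; `bmi` must be positive.
#' @param height Height (cm).
#' @param sbp Systolic blood pressure (mmHg).
#' @param total_chol,hdl_chol Total and HDL cholesterol (mg/dL).
#' @param hba1c_pct HbA1c (%) in the T2D stratum.
#' @param t2d_duration Mean diabetes duration (years) in the T2D stratum.
#' @param triglycerides Triglycerides (mg/dL).
#' @param share_tg_ge_150,share_smokers,share_women,share_antihypertensive,share_lipid_lowering
#'   Proportions in \[0, 1\].
#' @param menopause_age Mean age at menopause (years).
#' @return Object of class `"risk_factors"`.
#' @export
risk_factors <- function(age, bmi, height = 168, sbp = 130,
                         total_chol = 200, hdl_chol = 55, hba1c_pct = 7.5,
                         t2d_duration = 5, triglycerides = 140,
                         share_tg_ge_150 = 0.3, share_smokers = 0.5,
                         share_women = 0.5, share_antihypertensive = 0.2,
                         share_lipid_lowering = 0.1, menopause_age = 51) {
  rf <- list(age = age, bmi = bmi, height = height, sbp = sbp,
             total_chol = total_chol, hdl_chol = hdl_chol,
             hba1c_pct = hba1c_pct, t2d_duration = t2d_duration,
             triglycerides = triglycerides, share_tg_ge_150 = share_tg_ge_150,
             share_smokers = share_smokers, share_women = share_women,
             share_antihypertensive = share_antihypertensive,
             share_lipid_lowering = share_lipid_lowering,
             menopause_age = menopause_age)
  if (rf$bmi <= 0) stop("bmi must be positive")
  if (rf$age < 0) stop("age must be non-negative")
  shares <- rf[grep("^share_", names(rf))]
  bad <- names(shares)[vapply(shares, function(x) x < 0 || x > 1, logical(1))]
  if (length(bad)) stop("proportions outside [0, 1]: ", paste(bad, collapse = ", "))
  out <- structure(rf, class = "risk_factors")
  attr(out, "baseline") <- rf
  attr(out, "frozen_bmi") <- FALSE
  out
}

#' @export
print.risk_factors <- function(x, ...) {
  cat(sprintf("Risk factors: age %.1f, BMI %.1f kg/m2, SBP %.1f mmHg, %.0f%% women%s\n",
              x$age, x$bmi, x$sbp, 100 * x$share_women,
              if (attr(x, "frozen_bmi")) " (BMI frozen)" else ""))
  invisible(x)
}

STATIC_FIELDS <- c("height", "triglycerides", "share_tg_ge_150",
                   "share_smokers", "share_women", "share_lipid_lowering",
                   "menopause_age")

#' Treatment effect on surrogate risk factors
#'
#' Effects are expressed as changes from baseline while on treatment:
#' BMI as a percentage change (a percentage weight change equals the
#' same percentage BMI change), SBP / HDL / total cholesterol as
#' absolute changes, HbA1c as a percentage-point change, plus an
#' optional change in the antihypertensive-medication share. After
#' `duration` years the treatment stops and the induced deltas return
#' linearly to zero over `catchup_years` (the catch-up period).
#'
#' @param bmi_pct_change BMI % change from baseline (negative = loss).
#' @param sbp_abs_change,hdl_abs_change,tc_abs_change Absolute changes.
#' @param hba1c_point_change HbA1c change in percentage points.
#' @param antihypertensive_share_change Change in treated share.
#' @param duration Years on treatment (>= 0).
#' @param catchup_years Catch-up period length (>= 0).
#' @return Object of class `"treatment_effect"`.
#' @export
treatment_effect <- function(bmi_pct_change = 0, sbp_abs_change = 0,
                             hdl_abs_change = 0, tc_abs_change = 0,
                             hba1c_point_change = 0,
                             antihypertensive_share_change = 0,
                             duration = 0, catchup_years = 0) {
  if (duration < 0 || catchup_years < 0)
    stop("duration and catchup_years must be non-negative")
  structure(list(bmi_pct_change = bmi_pct_change,
                 sbp_abs_change = sbp_abs_change,
                 hdl_abs_change = hdl_abs_change,
                 tc_abs_change = tc_abs_change,
                 hba1c_point_change = hba1c_point_change,
                 antihypertensive_share_change = antihypertensive_share_change,
                 duration = duration, catchup_years = catchup_years),
            class = "treatment_effect")
}

#' Natural-progression policy for dynamic risk factors
#'
#' Off treatment (and after any catch-up), BMI drifts upward by
#' `bmi_drift_per_year` until the cohort reaches `bmi_drift_stop_age`,
#' and HbA1c in an all-diabetic cohort drifts by
#' `hba1c_drift_per_year` percentage points.
#'
#' @param bmi_drift_per_year kg/m^2 per year (default 0).
#' @param bmi_drift_stop_age Age at which BMI drift stops.
#' @param hba1c_drift_per_year Percentage points per year.
#' @return Object of class `"trajectory_policy"`.
#' @export
trajectory_policy <- function(bmi_drift_per_year = 0,
                              bmi_drift_stop_age = Inf,
                              hba1c_drift_per_year = 0) {
  structure(list(bmi_drift_per_year = bmi_drift_per_year,
                 bmi_drift_stop_age = bmi_drift_stop_age,
                 hba1c_drift_per_year = hba1c_drift_per_year),
            class = "trajectory_policy")
}

# Fraction of the full treatment delta applying in year t since entry:
# 1 while on treatment, linear decay over the catch-up period, then 0.
delta_fraction <- function(t, effect) {
  if (is.null(effect) || t <= 0) return(0)
  if (t <= effect$duration) return(1)
  if (effect$catchup_years > 0 && t <= effect$duration + effect$catchup_years)
    return((effect$duration + effect$catchup_years - t) / effect$catchup_years)
  0
}

# Years of natural drift accumulated by year t (drift runs only after
# treatment + catch-up, and for BMI only below the stop age).
drift_years <- function(t, effect, stop_age = Inf, base_age = 0) {
  start <- if (is.null(effect)) 0 else effect$duration + effect$catchup_years
  yrs <- seq_len(t)
  sum(yrs > start & (base_age + yrs) <= stop_age)
}

#' Advance the cohort risk-factor vector by one annual cycle
#'
#' Age (and, in a diabetic cohort, diabetes duration) increase by one;
#' static fields never change; treated fields carry the treatment delta
#' scaled by the on-treatment / catch-up fraction for the new cycle;
#' after catch-up, natural drift applies. The trajectory is a
#' deterministic function of the stored baseline and the cycle index,
#' so repeated calls reproduce the same path.
#'
#' @param rf A [risk_factors()] vector at cycle `cycle`.
#' @param cycle Current cycle index (years since entry, >= 0).
#' @param effect A [treatment_effect()] or `NULL`.
#' @param policy A [trajectory_policy()].
#' @return The risk-factor vector at cycle `cycle + 1`.
#' @export
advance_risk_factors <- function(rf, cycle, effect = NULL,
                                 policy = trajectory_policy()) {
  stopifnot(inherits(rf, "risk_factors"), cycle >= 0)
  base <- attr(rf, "baseline")
  t <- cycle + 1L
  out <- rf
  out$age <- base$age + t
  out$t2d_duration <- base$t2d_duration + t
  for (f in STATIC_FIELDS) out[[f]] <- base[[f]]
  if (isTRUE(attr(rf, "frozen_bmi"))) {
    dyn <- c("bmi", "sbp", "total_chol", "hdl_chol", "hba1c_pct",
             "share_antihypertensive")
    for (f in dyn) out[[f]] <- base[[f]]
    return(out)
  }
  f <- delta_fraction(t, effect)
  db <- drift_years(t, effect, policy$bmi_drift_stop_age, base$age)
  dh <- drift_years(t, effect)
  e <- effect %||% treatment_effect()
  out$bmi <- base$bmi * (1 + f * e$bmi_pct_change / 100) +
    db * policy$bmi_drift_per_year
  out$sbp <- base$sbp + f * e$sbp_abs_change
  out$hdl_chol <- base$hdl_chol + f * e$hdl_abs_change
  out$total_chol <- base$total_chol + f * e$tc_abs_change
  out$hba1c_pct <- base$hba1c_pct + f * e$hba1c_point_change +
    dh * policy$hba1c_drift_per_year
  out$share_antihypertensive <-
    min(1, max(0, base$share_antihypertensive +
                 f * e$antihypertensive_share_change))
  out
}

#' Freeze BMI (validation-mode trajectory)
#'
#' Marks the vector so that [advance_risk_factors()] holds every
#' dynamic field at its baseline value while age and diabetes duration
#' still increment — the constant-BMI assumption used when comparing
#' predictions against observational rates.
#'
#' @param rf A [risk_factors()] vector.
#' @return The same vector flagged as frozen.
#' @export
freeze_bmi <- function(rf) {
  stopifnot(inherits(rf, "risk_factors"))
  attr(rf, "frozen_bmi") <- TRUE
  rf
}

#' Cohort profile: baseline risk factors plus strata shares
#'
#' @param n Cohort size (>= 1).
#' @param rf A [risk_factors()] vector.
#' @param share_ngt,share_prediabetes,share_t2d Glycemic split; must
#'   sum to 1 within 1e-9.
#' @param share_sleep_apnea Prevalent sleep-apnea share (overlay
#'   attribute, reported but without mortality effect).
#' @return Object of class `"cohort_profile"`.
#' @export
cohort_profile <- function(n = 100, rf, share_ngt, share_prediabetes,
                           share_t2d, share_sleep_apnea = 0) {
  stopifnot(inherits(rf, "risk_factors"))
  if (n < 1) stop("cohort size n must be >= 1")
  s <- c(share_ngt, share_prediabetes, share_t2d)
  if (any(s < 0)) stop("glycemic shares must be non-negative")
  if (abs(sum(s) - 1) > 1e-9)
    stop(sprintf("glycemic split sums to %.9f, expected 1", sum(s)))
  if (share_sleep_apnea < 0 || share_sleep_apnea > 1)
    stop("share_sleep_apnea must be in [0, 1]")
  structure(list(n = n, risk_factors = rf, share_ngt = share_ngt,
                 share_prediabetes = share_prediabetes, share_t2d = share_t2d,
                 share_sleep_apnea = share_sleep_apnea),
            class = "cohort_profile")
}

#' @export
print.cohort_profile <- function(x, ...) {
  cat(sprintf("Cohort of %d: %.1f%% NGT / %.1f%% prediabetes / %.1f%% T2D\n",
              x$n, 100 * x$share_ngt, 100 * x$share_prediabetes, 100 * x$share_t2d))
  print(x$risk_factors)
  invisible(x)
}
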