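# Risk engine: probability calculus, pluggable risk-model registry,
# hazard-ratio tables, and the prediabetes mapping rules.

#' Convert a cumulative K-year risk to a per-cycle (annual) probability
#'
#' Uses the constant-rate (geometric) annualization
#' `1 - (1 - cum_risk)^(1/K)`, whose K-fold compounding round-trips the
#' cumulative risk exactly; certainty is preserved (`cum_risk = 1`
#' returns 1).
#'
#' @param cum_risk Cumulative risk over `horizon` years, in \[0, 1\].
#' @param horizon Risk-equation horizon K in years (>= 1).
#' @return Annual probability in \[0, 1\].
#' @seealso [cumulative_probability()] for the inverse.
#' @examples
#' annual_probability(0.40, 10)  # 0.049787...
#' @export
annual_probability <- function(cum_risk, horizon) {
  if (any(horizon < 1)) stop("horizon must be >= 1 year")
  if (any(cum_risk < 0 | cum_risk > 1)) stop("cum_risk must be in [0, 1]")
  ifelse(cum_risk == 1, 1, 1 - (1 - cum_risk)^(1 / horizon))
}

#' Compound an annual probability over a horizon
#'
#' Inverse of [annual_probability()]: `1 - (1 - p)^K`.
#'
#' @param p Annual probability.
#' @param horizon Number of years K.
#' @return Cumulative probability over K years.
#' @export
cumulative_probability <- function(p, horizon) {
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]")
  1 - (1 - p)^horizon
}

#' Apply a hazard ratio to a per-cycle probability
#'
#' Applied on the complementary-log (constant-hazard) scale,
#' `1 - (1 - p)^hr`, which keeps the result in \[0, 1\] for any positive
#' ratio and agrees with naive multiplication to well under 1e-4 at the
#' annual-probability magnitudes involved here.
#'
#' @param p Per-cycle probability in \[0, 1\].
#' @param hr Hazard (relative-risk) ratio, > 0.
#' @return Adjusted per-cycle probability.
#' @examples
#' apply_hazard_ratio(0.30, 2)   # 1 - 0.7^2 = 0.51
#' @export
apply_hazard_ratio <- function(p, hr) {
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]")
  if (any(hr <= 0)) stop("hr must be positive")
  1 - (1 - p)^hr
}

#' Define a risk model
#'
#' A risk model maps a [risk_factors()] vector to a cumulative
#' `horizon_years`-year risk in \[0, 1\]. Published equations (QDiabetes,
#' Framingham, QRISK3, UKPDS OM2, NDR ...) plug into this interface via
#' their own `evaluate` functions or [read_risk_model()]; the package
#' ships documented toy logistic models (see [example_registry()]) so
#' the engine is fully testable offline.
#'
#' @param name Identifier.
#' @param evaluate Function of one argument (a risk-factor vector)
#'   returning a cumulative risk in \[0, 1\].
#' @param horizon_years Horizon K of the equation (>= 1).
#' @param population One of `"NGT"`, `"PREDIABETES"`, `"T2D"`, `"ANY"`.
#' @return Object of class `"risk_model"`.
#' @export
risk_model <- function(name, evaluate, horizon_years = 1L,
                       population = c("ANY", "NGT", "PREDIABETES", "T2D")) {
  population <- match.arg(population)
  stopifnot(is.function(evaluate), horizon_years >= 1)
  structure(list(name = name, evaluate = evaluate,
                 horizon_years = as.integer(horizon_years),
                 population = population),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("Risk model '%s' (%d-year horizon, population %s)\n",
              x$name, x$horizon_years, x$population))
  invisible(x)
}

#' Evaluate a risk model, enforcing the \[0, 1\] contract
#'
#' @param model A [risk_model()].
#' @param rf A [risk_factors()] vector.
#' @return Cumulative `horizon_years`-year risk.
#' @export
evaluate_risk <- function(model, rf) {
  r <- model$evaluate(rf)
  if (!is.finite(r) || r < 0 || r > 1)
    stop(sprintf("risk model '%s' returned %s outside [0, 1]", model$name, format(r)))
  r
}

#' Logistic-linear risk model
#'
#' Cumulative risk = `plogis(intercept + sum(coef * (value - center)))`
#' over the named risk-factor fields. This is the coefficient-driven
#' form used by the shipped toy models and by [read_risk_model()];
#' published linear-predictor equations can be expressed the same way.
#'
#' @param name Identifier.
#' @param intercept Intercept on the logit scale.
#' @param coefficients Named numeric vector; names are risk-factor
#'   fields (e.g. `bmi`, `age`, `sbp`, `hba1c_pct`).
#' @param centers Named numeric vector of centering constants (default
#'   0 for fields not listed).
#' @param horizon_years,population Passed to [risk_model()].
#' @return A `"risk_model"` whose `coefficients` are retrievable via
#'   `$terms`.
#' @export
logistic_risk_model <- function(name, intercept, coefficients,
                                centers = numeric(0),
                                horizon_years = 10L, population = "ANY") {
  stopifnot(length(names(coefficients)) == length(coefficients))
  cen <- stats::setNames(numeric(length(coefficients)), names(coefficients))
  cen[names(centers)] <- centers
  ev <- function(rf) {
    vals <- vapply(names(coefficients), function(f) {
      v <- rf[[f]]
      if (is.null(v) || is.na(v))
        stop(sprintf("risk model '%s' needs risk factor '%s'", name, f))
      as.numeric(v)
    }, numeric(1))
    stats::plogis(intercept + sum(coefficients * (vals - cen)))
  }
  m <- risk_model(name, ev, horizon_years = horizon_years, population = population)
  m$terms <- data.frame(term = c("(Intercept)", names(coefficients)),
                        coefficient = c(intercept, unname(coefficients)),
                        center = c(0, unname(cen)), stringsAsFactors = FALSE)
  m
}

#' Load a risk model from a coefficient file
#'
#' JSON schema: `{name, horizon_years, population, terms: [{term,
#' coefficient, center}]}` with an `"(Intercept)"` term. CSV schema:
#' columns `term, coefficient, center` (name/horizon/population given
#' as arguments).
#'
#' @param path File path (`.json`, or `.csv`).
#' @param name,horizon_years,population Used for CSV input only.
#' @return A `"risk_model"`.
#' @export
read_risk_model <- function(path, name = basename(path),
                            horizon_years = 10L, population = "ANY") {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    spec <- jsonlite::read_json(path, simplifyVector = TRUE)
    terms <- spec$terms
    name <- spec$name %||% name
    horizon_years <- spec$horizon_years %||% horizon_years
    population <- spec$population %||% population
  } else {
    terms <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("term", "coefficient")
  if (!all(need %in% names(terms)))
    stop("risk-model file needs columns: ", paste(need, collapse = ", "))
  if (is.null(terms$center)) terms$center <- 0
  ic <- terms$term == "(Intercept)"
  if (!any(ic)) stop("risk-model file has no (Intercept) term")
  co <- stats::setNames(terms$coefficient[!ic], terms$term[!ic])
  ce <- stats::setNames(terms$center[!ic], terms$term[!ic])
  logistic_risk_model(name, terms$coefficient[ic][1], co, ce,
                      horizon_years = horizon_years, population = population)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble a risk-model registry
#'
#' The registry slots the engine consumes: `t2d` (incidence equation,
#' evaluated with the glycemic marker forced per stratum), and the four
#' cardiovascular slots `cv_first_ngt`, `cv_first_t2d`,
#' `cv_recurrent_ngt`, `cv_recurrent_t2d`. Prediabetes maps onto these
#' by assumption: first events use the NGT model, recurrent events the
#' T2D model.
#'
#' @param t2d,cv_first_ngt,cv_first_t2d,cv_recurrent_ngt,cv_recurrent_t2d
#'   `"risk_model"` objects (slots may be omitted if never exercised).
#' @return Object of class `"risk_registry"`.
#' @export
risk_registry <- function(t2d = NULL, cv_first_ngt = NULL, cv_first_t2d = NULL,
                          cv_recurrent_ngt = NULL, cv_recurrent_t2d = NULL) {
  reg <- list(t2d = t2d, cv_first_ngt = cv_first_ngt,
              cv_first_t2d = cv_first_t2d,
              cv_recurrent_ngt = cv_recurrent_ngt,
              cv_recurrent_t2d = cv_recurrent_t2d)
  for (nm in names(reg))
    if (!is.null(reg[[nm]]) && !inherits(reg[[nm]], "risk_model"))
      stop("slot '", nm, "' is not a risk_model")
  structure(reg, class = "risk_registry")
}

registry_slot <- function(registry, slot) {
  m <- registry[[slot]]
  if (is.null(m)) stop("risk registry is missing slot '", slot, "'")
  m
}

#' Toy risk-model registry
#'
#' Documented logistic models with plausible cardiometabolic gradients,
#' monotone in BMI, age, SBP and HbA1c. They stand in for published
#' equations (whose full coefficient sets are licensed separately) so
#' that the engine, the prediabetes mechanism and the validation
#' workflow are exercisable offline; they are synthetic and make no
#' claim of calibration to any cohort.
#'
#' @return A [risk_registry()].
#' @export
example_registry <- function() {
  risk_registry(
    t2d = logistic_risk_model(
      "toy_t2d_10y", intercept = -2.8,
      coefficients = c(bmi = 0.16, age = 0.02, hba1c_pct = 1.0),
      centers = c(bmi = 25, age = 50, hba1c_pct = 5.5),
      horizon_years = 10L, population = "ANY"),
    cv_first_ngt = logistic_risk_model(
      "toy_cv_first_ngt_10y", intercept = -3.5,
      coefficients = c(bmi = 0.03, age = 0.05, sbp = 0.01),
      centers = c(bmi = 25, age = 50, sbp = 130),
      horizon_years = 10L, population = "NGT"),
    cv_first_t2d = logistic_risk_model(
      "toy_cv_first_t2d_10y", intercept = -2.8,
      coefficients = c(bmi = 0.03, age = 0.05, sbp = 0.01),
      centers = c(bmi = 25, age = 50, sbp = 130),
      horizon_years = 10L, population = "T2D"),
    cv_recurrent_ngt = logistic_risk_model(
      "toy_cv_recurrent_ngt_10y", intercept = -2.0,
      coefficients = c(age = 0.04, sbp = 0.008),
      centers = c(age = 50, sbp = 130),
      horizon_years = 10L, population = "NGT"),
    cv_recurrent_t2d = logistic_risk_model(
      "toy_cv_recurrent_t2d_10y", intercept = -1.6,
      coefficients = c(age = 0.04, sbp = 0.008),
      centers = c(age = 50, sbp = 130),
      horizon_years = 10L, population = "T2D"))
}

#' Registry with identically zero risks
#'
#' Useful as the no-event oracle: a cohort run under this registry has
#' only life-table mortality.
#'
#' @return A [risk_registry()].
#' @export
null_registry <- function() {
  zero <- function(nm, pop = "ANY")
    risk_model(nm, function(rf) 0, horizon_years = 10L, population = pop)
  risk_registry(t2d = zero("zero_t2d"),
                cv_first_ngt = zero("zero_cv_first_ngt", "NGT"),
                cv_first_t2d = zero("zero_cv_first_t2d", "T2D"),
                cv_recurrent_ngt = zero("zero_cv_recurrent_ngt", "NGT"),
                cv_recurrent_t2d = zero("zero_cv_recurrent_t2d", "T2D"))
}

#' Annual type 2 diabetes incidence for a glycemic stratum
#'
#' Evaluates the T2D risk equation with the cohort's glycemic marker
#' forced per stratum: 6.0% HbA1c (42 mmol/mol) for prediabetes, a
#' normoglycemic 5.5% for NGT. The cohort's own `hba1c_pct` field
#' describes its diabetic members and is not used here. The cumulative
#' risk is annualized with [annual_probability()].
#'
#' @param rf A [risk_factors()] vector.
#' @param stratum `"NGT"` or `"PREDIABETES"` (the T2D stratum is
#'   already diabetic and is rejected).
#' @param model The T2D incidence [risk_model()].
#' @param ngt_hba1c,prediabetes_hba1c Forced marker values (%).
#' @return Annual probability of developing T2D.
#' @export
t2d_incidence <- function(rf, stratum, model,
                          ngt_hba1c = 5.5, prediabetes_hba1c = 6.0) {
  if (!stratum %in% c("NGT", "PREDIABETES"))
    stop("stratum must be NGT or PREDIABETES (T2D is already diabetic)")
  if (!model$population %in% c("ANY", stratum) && model$population != "NGT")
    stop(sprintf("risk model '%s' targets population %s", model$name, model$population))
  rf2 <- rf
  rf2$hba1c_pct <- if (stratum == "PREDIABETES") prediabetes_hba1c else ngt_hba1c
  annual_probability(evaluate_risk(model, rf2), model$horizon_years)
}

#' Annual cardiovascular event probability, split into ACS and stroke
#'
#' Selects the registry slot by glycemic stratum and event history.
#' Prediabetes has no CV equations of its own: first events use the NGT
#' model and recurrent events the T2D model. The composite annual CVD
#' probability is partitioned into ACS vs stroke by a configurable
#' share (default 3.4/7.8 = 0.436, the observed reference-group split).
#'
#' @param rf A [risk_factors()] vector.
#' @param stratum Glycemic stratum (`"NGT"`, `"PREDIABETES"`, `"T2D"`).
#' @param history `"first"` or `"recurrent"`.
#' @param registry A [risk_registry()].
#' @param acs_share Proportion of composite CVD risk assigned to ACS.
#' @return Named numeric `c(acs = , stroke = )` of annual probabilities.
#' @export
cv_event_probability <- function(rf, stratum, history = c("first", "recurrent"),
                                 registry, acs_share = 3.4 / 7.8) {
  history <- match.arg(history)
  stopifnot(stratum %in% GLYCEMIC_LEVELS, acs_share >= 0, acs_share <= 1)
  slot <- if (history == "first") {
    if (stratum == "T2D") "cv_first_t2d" else "cv_first_ngt"
  } else {
    if (stratum == "NGT") "cv_recurrent_ngt" else "cv_recurrent_t2d"
  }
  model <- registry_slot(registry, slot)
  p <- annual_probability(evaluate_risk(model, rf), model$horizon_years)
  c(acs = p * acs_share, stroke = p * (1 - acs_share))
}

#' Hazard-ratio table over BMI strata
#'
#' @param outcome Outcome identifier.
#' @param bmi_low,bmi_high Half-open stratum bounds `[low, high)`.
#' @param hr Hazard ratios (> 0); the reference stratum has hr exactly 1.
#' @param ci_low,ci_high Optional confidence limits.
#' @return Data frame of class `"hazard_ratio_table"` ordered by
#'   `bmi_low`.
#' @export
hazard_ratio_table <- function(outcome, bmi_low, bmi_high, hr,
                               ci_low = NA_real_, ci_high = NA_real_) {
  stopifnot(length(bmi_low) == length(bmi_high), length(hr) == length(bmi_low))
  if (any(hr <= 0)) stop("hazard ratios must be positive")
  if (!any(hr == 1)) stop("a reference stratum with hr exactly 1 is required")
  df <- data.frame(outcome = outcome, bmi_low = bmi_low, bmi_high = bmi_high,
                   hr = hr, ci_low = ci_low, ci_high = ci_high,
                   stringsAsFactors = FALSE)
  df <- df[order(df$bmi_low), ]
  if (any(df$bmi_high[-nrow(df)] > df$bmi_low[-1] + 1e-12))
    stop("BMI strata must be non-overlapping")
  class(df) <- c("hazard_ratio_table", class(df))
  df
}

#' Look up the hazard ratio for a BMI value
#'
#' BMI values outside all strata are clamped to the nearest stratum
#' with a warning.
#'
#' @param hr_table A [hazard_ratio_table()].
#' @param bmi BMI in kg/m^2.
#' @return Scalar hazard ratio.
#' @export
hr_for_bmi <- function(hr_table, bmi) {
  hit <- which(bmi >= hr_table$bmi_low & bmi < hr_table$bmi_high)
  if (length(hit) == 1L) return(hr_table$hr[hit])
  i <- if (bmi < hr_table$bmi_low[1]) 1L else nrow(hr_table)
  warning(sprintf("BMI %.1f outside strata of '%s'; clamped to [%g, %g)",
                  bmi, hr_table$outcome[1], hr_table$bmi_low[i], hr_table$bmi_high[i]))
  hr_table$hr[i]
}

#' Annual probability of a BMI-graded complication
#'
#' Adjusts a reference-stratum annual rate by the cohort's BMI-stratum
#' hazard ratio on the complementary-log scale. Postmenopausal cancers
#' (`endometrial_pm`, `breast_pm`) apply only to the female share of a
#' cohort at or past the age at menopause and return 0 otherwise.
#'
#' @param rf A [risk_factors()] vector.
#' @param outcome One of `sleep_apnea`, `knee_replacement`,
#'   `colorectal`, `endometrial_pm`, `breast_pm`.
#' @param hr_table [hazard_ratio_table()] for the outcome.
#' @param baseline_rate Reference-stratum annual probability.
#' @return Annual probability for the cohort.
#' @export
complication_probability <- function(rf, outcome, hr_table, baseline_rate) {
  stopifnot(outcome %in% c("sleep_apnea", "knee_replacement", "colorectal",
                           "endometrial_pm", "breast_pm"))
  p <- apply_hazard_ratio(baseline_rate, hr_for_bmi(hr_table, rf$bmi))
  if (outcome %in% c("endometrial_pm", "breast_pm")) {
    if (rf$age < rf$menopause_age || rf$share_women == 0) return(0)
    p <- p * rf$share_women
  }
  p
}
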