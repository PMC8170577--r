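# Run configuration: schema-validated YAML/JSON describing the cohort,
# horizon, treatment, trajectory, life table and risk-model files.

cfg_stop <- function(field, msg) stop(sprintf("config field '%s': %s", field, msg),
                                      call. = FALSE)

#' Assemble a validated run configuration
#'
#' @param cohort A [cohort_profile()].
#' @param horizon_years Horizon in years (1 to 40).
#' @param treatment Optional [treatment_effect()].
#' @param trajectory A [trajectory_policy()].
#' @param life_table A [mortality_table()].
#' @param registry A [risk_registry()].
#' @param seed Optional integer seed recorded for stochastic extensions
#'   (the cohort engine itself is deterministic).
#' @param output_dir Output directory for the CLI.
#' @return Object of class `"run_config"`.
#' @export
run_config <- function(cohort, horizon_years = 40, treatment = NULL,
                       trajectory = trajectory_policy(),
                       life_table = synthetic_life_table(),
                       registry = example_registry(),
                       seed = NULL, output_dir = ".") {
  if (!inherits(cohort, "cohort_profile")) cfg_stop("cohort", "not a cohort profile")
  if (horizon_years < 1 || horizon_years > 40)
    cfg_stop("horizon_years", "must be between 1 and 40")
  if (!is.null(treatment) && !inherits(treatment, "treatment_effect"))
    cfg_stop("treatment", "not a treatment_effect")
  structure(list(cohort = cohort, horizon_years = horizon_years,
                 treatment = treatment, trajectory = trajectory,
                 life_table = life_table, registry = registry,
                 seed = seed, output_dir = output_dir),
            class = "run_config")
}

#' Load a run configuration from YAML or JSON
#'
#' Schema (fields in parentheses optional):
#' ```yaml
#' horizon_years: 10
#' cohort:
#'   n: 100
#'   glycemic_split: {ngt: 0.953, prediabetes: 0.020, t2d: 0.027}
#'   (share_sleep_apnea: 0.0)
#'   risk_factors: {age: 48.5, bmi: 22.5, ...}   # risk_factors() fields
#' (treatment: {bmi_pct_change: -10, duration: 3, catchup_years: 2, ...})
#' (trajectory: {bmi_drift_per_year: 0.1, bmi_drift_stop_age: 65, ...})
#' (life_table: path/to/life_table.csv)          # age,sex,qx CSV
#' (risk_models: {t2d: path.json, cv_first_ngt: path.json, ...})
#' (seed: 1)
#' (output_dir: results)
#' ```
#' Omitted optional blocks fall back to documented defaults (no
#' treatment, no drift, synthetic life table, toy registry), each
#' reported via a message. Validation failures name the offending
#' field.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [run_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(cfg$cohort)) cfg_stop("cohort", "missing")
  co <- cfg$cohort
  if (is.null(co$risk_factors)) cfg_stop("cohort.risk_factors", "missing")
  if (is.null(co$risk_factors$age) || is.null(co$risk_factors$bmi))
    cfg_stop("cohort.risk_factors", "age and bmi are required")
  rf <- do.call(risk_factors, co$risk_factors)
  gs <- co$glycemic_split
  if (is.null(gs)) cfg_stop("cohort.glycemic_split", "missing")
  s <- c(gs$ngt %||% 0, gs$prediabetes %||% 0, gs$t2d %||% 0)
  if (abs(sum(s) - 1) > 1e-9)
    cfg_stop("cohort.glycemic_split",
             sprintf("shares sum to %.3f, expected 1", sum(s)))
  cohort <- cohort_profile(co$n %||% 100, rf, s[1], s[2], s[3],
                           share_sleep_apnea = co$share_sleep_apnea %||% 0)
  horizon <- cfg$horizon_years %||% {
    message("config: horizon_years missing, defaulting to 40")
    40
  }
  treatment <- if (!is.null(cfg$treatment)) do.call(treatment_effect, cfg$treatment)
  trajectory <- if (!is.null(cfg$trajectory)) do.call(trajectory_policy, cfg$trajectory)
  else trajectory_policy()
  life_table <- if (!is.null(cfg$life_table)) {
    if (!file.exists(cfg$life_table))
      cfg_stop("life_table", paste("file not found:", cfg$life_table))
    read_life_table(cfg$life_table)
  } else {
    message("config: no life_table given, using the synthetic Gompertz table")
    synthetic_life_table()
  }
  registry <- if (!is.null(cfg$risk_models)) {
    paths <- cfg$risk_models
    for (nm in names(paths)) if (!file.exists(paths[[nm]]))
      cfg_stop(paste0("risk_models.", nm), paste("file not found:", paths[[nm]]))
    do.call(risk_registry, lapply(paths, read_risk_model))
  } else {
    message("config: no risk_models given, using the toy example registry")
    example_registry()
  }
  run_config(cohort, horizon, treatment, trajectory, life_table, registry,
             seed = cfg$seed, output_dir = cfg$output_dir %||% ".")
}

#' Execute a run configuration
#'
#' @param config A [run_config()].
#' @param ... Passed to [run_cohort()].
#' @return A `"cohort_run"`.
#' @export
run_from_config <- function(config, ...) {
  stopifnot(inherits(config, "run_config"))
  run_cohort(config$cohort, registry = config$registry,
             life_table = config$life_table, horizon = config$horizon_years,
             effect = config$treatment, policy = config$trajectory, ...)
}
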