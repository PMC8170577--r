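# Cohort engine: builds the per-cycle transition matrix from the risk
# and mortality layers, advances occupancy, and tallies events.

EVENT_TYPES <- c("t2d_onset", "acs", "stroke", "colorectal",
                 "endometrial_pm", "breast_pm", "knee_replacement")

#' Default BMI-stratum hazard-ratio tables for graded complications
#'
#' Placeholder gradients over the conventional BMI strata
#' (18.5-25, 25-30, 30-35, 35-40, 40-45 kg/m^2) with the normal-weight
#' stratum as reference. The literature sources for these outcomes are
#' not reproduced here; users substitute their own tables.
#'
#' @return Named list of [hazard_ratio_table()]s keyed by outcome.
#' @export
default_hr_tables <- function() {
  lo <- c(18.5, 25, 30, 35, 40); hi <- c(25, 30, 35, 40, 45)
  mk <- function(outcome, hr) hazard_ratio_table(outcome, lo, hi, hr)
  list(colorectal = mk("colorectal", c(1, 1.2, 1.5, 1.8, 2.0)),
       endometrial_pm = mk("endometrial_pm", c(1, 1.5, 2.5, 3.5, 4.5)),
       breast_pm = mk("breast_pm", c(1, 1.1, 1.3, 1.4, 1.5)),
       knee_replacement = mk("knee_replacement", c(1, 1.5, 3.0, 5.0, 7.0)),
       sleep_apnea = mk("sleep_apnea", c(1, 1.5, 2.5, 4.0, 6.0)))
}

#' Default reference-stratum annual rates for graded complications
#'
#' Placeholder annual probabilities in the normal-weight reference
#' stratum (user-configurable; the sources behind them are external).
#'
#' @return Named numeric vector.
#' @export
default_baseline_rates <- function() {
  c(colorectal = 5e-4, endometrial_pm = 3e-4, breast_pm = 1.5e-3,
    knee_replacement = 2e-3, sleep_apnea = 5e-3)
}

# Build the transition matrix and the per-state tallied-event
# probabilities for one cycle, from the current risk-factor vector.
build_cycle_matrix <- function(rf, registry, life_table,
                               adjustments = mortality_adjustments(),
                               hr_tables = default_hr_tables(),
                               baseline_rates = default_baseline_rates(),
                               acs_share = 3.4 / 7.8,
                               ngt_to_prediabetes = 0.02,
                               stacking = "max",
                               states = health_states()) {
  ids <- states$state
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  ev <- matrix(0, n, length(EVENT_TYPES), dimnames = list(ids, EVENT_TYPES))
  sw <- rf$share_women
  cancers <- c("colorectal", "endometrial_pm", "breast_pm")
  cancer_state <- c(colorectal = "CANCER_COLORECTAL",
                    endometrial_pm = "CANCER_ENDOMETRIAL_PM",
                    breast_pm = "CANCER_BREAST_PM")
  p_kr <- complication_probability(rf, "knee_replacement",
                                   hr_tables$knee_replacement,
                                   baseline_rates[["knee_replacement"]])
  p_ca <- vapply(cancers, function(o)
    complication_probability(rf, o, hr_tables[[o]], baseline_rates[[o]]),
    numeric(1))
  cf_ca <- vapply(cancers, function(o)
    sw * adjustments[[o]]$onset_f + (1 - sw) * adjustments[[o]]$onset_m,
    numeric(1))

  for (i in seq_len(n)) {
    st <- states[i, ]
    if (st$dead) { m[i, DEAD_STATE] <- 1; next }
    if (!is.na(st$cancer) && st$cancer != "NONE") {
      trig <- c(COLORECTAL = "colorectal", ENDOMETRIAL_PM = "endometrial_pm",
                BREAST_PM = "breast_pm")[[st$cancer]]
      q <- adjusted_mortality(trig, onset = FALSE, age = rf$age,
                              table = life_table, share_women = sw,
                              adjustments = adjustments, stacking = stacking)
      m[i, DEAD_STATE] <- q
      m[i, i] <- 1 - q
      next
    }
    g <- st$glycemic; cv <- st$cv
    if (cv %in% c("ACS_YEAR", "STROKE_YEAR")) {
      # acute cycle: case fatality, survivors settle into the post state
      trig <- if (cv == "ACS_YEAR") "acs_year" else "stroke_year"
      q <- adjusted_mortality(trig, onset = TRUE, age = rf$age,
                              table = life_table, share_women = sw,
                              adjustments = adjustments, stacking = stacking)
      post <- paste(g, if (cv == "ACS_YEAR") "POST_ACS" else "POST_STROKE",
                    sep = ".")
      m[i, DEAD_STATE] <- q
      m[i, post] <- 1 - q
      next
    }
    trig <- switch(cv, POST_ACS = "post_acs", POST_STROKE = "post_stroke", "none")
    q <- adjusted_mortality(trig, onset = FALSE, age = rf$age,
                            table = life_table, share_women = sw,
                            adjustments = adjustments, stacking = stacking)
    # competing marginal events from this state (single-attribute moves)
    dest <- character(0); prob <- numeric(0); kind <- character(0)
    add <- function(d, p, k) {
      dest <<- c(dest, d); prob <<- c(prob, p); kind <<- c(kind, k)
    }
    if (g == "NGT") {
      add(paste("PREDIABETES", cv, sep = "."), ngt_to_prediabetes, "pre")
      add(paste("T2D", cv, sep = "."),
          t2d_incidence(rf, "NGT", registry_slot(registry, "t2d")), "t2d_onset")
    } else if (g == "PREDIABETES") {
      add(paste("T2D", cv, sep = "."),
          t2d_incidence(rf, "PREDIABETES", registry_slot(registry, "t2d")),
          "t2d_onset")
    }
    hist <- if (cv == "EVENT_FREE") "first" else "recurrent"
    pcv <- cv_event_probability(rf, g, hist, registry, acs_share = acs_share)
    add(paste(g, "ACS_YEAR", sep = "."), pcv[["acs"]], "acs")
    add(paste(g, "STROKE_YEAR", sep = "."), pcv[["stroke"]], "stroke")
    for (o in cancers) add(cancer_state[[o]], p_ca[[o]], o)

    total <- sum(prob)
    scale <- if (total > 1 - q && total > 0) (1 - q) / total else 1
    prob <- prob * scale
    for (k in seq_along(dest)) {
      p <- prob[k]
      if (kind[k] %in% cancers) {
        # incident cancer mass splits into onset deaths and survivors
        cf <- cf_ca[[kind[k]]]
        m[i, dest[k]] <- m[i, dest[k]] + p * (1 - cf)
        m[i, DEAD_STATE] <- m[i, DEAD_STATE] + p * cf
      } else {
        m[i, dest[k]] <- m[i, dest[k]] + p
      }
      if (kind[k] != "pre") ev[i, kind[k]] <- ev[i, kind[k]] + p
    }
    m[i, DEAD_STATE] <- m[i, DEAD_STATE] + q
    m[i, i] <- m[i, i] + 1 - q - sum(prob)
    ev[i, "knee_replacement"] <- p_kr
  }
  list(matrix = transition_matrix(m, states), events = ev)
}

#' Run the Markov cohort simulation
#'
#' Advances the cohort one annual cycle at a time over the horizon.
#' Each cycle the risk-factor vector is updated
#' ([advance_risk_factors()]), the transition matrix is rebuilt from
#' the risk registry and mortality layer, occupancy is propagated, and
#' events are tallied (type 2 diabetes onsets, ACS and stroke events,
#' incident cancers, knee replacements as an overlay, deaths).
#' Person-years count cohort members alive at the end of each cycle;
#' no half-cycle correction is applied (available via `half_cycle`).
#'
#' @param profile A [cohort_profile()].
#' @param registry A [risk_registry()]; default [example_registry()].
#' @param life_table A [mortality_table()]; default
#'   [synthetic_life_table()].
#' @param horizon Number of annual cycles (1 to 40; default 40, a
#'   lifetime horizon for most entering cohorts).
#' @param effect Optional [treatment_effect()].
#' @param policy A [trajectory_policy()].
#' @param adjustments Mortality adjustments, see [mortality_adjustments()].
#' @param hr_tables,baseline_rates Complication gradients, see
#'   [default_hr_tables()] and [default_baseline_rates()].
#' @param acs_share ACS share of composite CVD risk.
#' @param ngt_to_prediabetes Annual NGT to prediabetes progression
#'   probability (no published equation; configurable).
#' @param freeze Freeze BMI and all other dynamics except age/duration
#'   (validation mode).
#' @param half_cycle Apply a half-cycle correction to person-years.
#' @param stacking Mortality stacking rule, `"max"` or `"multiplicative"`.
#' @param validate Validate each cycle's matrix (cheap; default TRUE).
#' @return Object of class `"cohort_run"` with the occupancy `trace`
#'   (cycles x states), per-cycle `events` (expected counts for a
#'   cohort of `n`), cumulative `totals`, `person_years` and
#'   `life_expectancy` within the horizon.
#' @export
run_cohort <- function(profile, registry = example_registry(),
                       life_table = synthetic_life_table(), horizon = 40,
                       effect = NULL, policy = trajectory_policy(),
                       adjustments = mortality_adjustments(),
                       hr_tables = default_hr_tables(),
                       baseline_rates = default_baseline_rates(),
                       acs_share = 3.4 / 7.8, ngt_to_prediabetes = 0.02,
                       freeze = FALSE, half_cycle = FALSE,
                       stacking = "max", validate = TRUE) {
  stopifnot(inherits(profile, "cohort_profile"))
  if (horizon < 1 || horizon > 40) stop("horizon must be between 1 and 40 years")
  states <- health_states()
  rf <- profile$risk_factors
  if (freeze) rf <- freeze_bmi(rf)
  occ <- state_occupancy(
    c(NGT.EVENT_FREE = profile$share_ngt,
      PREDIABETES.EVENT_FREE = profile$share_prediabetes,
      T2D.EVENT_FREE = profile$share_t2d),
    cycle = 0L, states = states)
  n_states <- nrow(states)
  trace <- matrix(NA_real_, horizon + 1L, n_states,
                  dimnames = list(0:horizon, states$state))
  trace[1L, ] <- occ$mass
  events <- matrix(0, horizon, length(c(EVENT_TYPES, "deaths")),
                   dimnames = list(1:horizon, c(EVENT_TYPES, "deaths")))
  alive_end <- numeric(horizon)
  for (t in seq_len(horizon)) {
    cyc <- build_cycle_matrix(rf, registry, life_table, adjustments,
                              hr_tables, baseline_rates, acs_share,
                              ngt_to_prediabetes, stacking, states)
    prev_dead <- occ$mass[[DEAD_STATE]]
    ev_t <- as.numeric(occ$mass %*% cyc$events)
    occ <- step_cohort(occ, cyc$matrix, validate = validate)
    events[t, EVENT_TYPES] <- ev_t * profile$n
    events[t, "deaths"] <- (occ$mass[[DEAD_STATE]] - prev_dead) * profile$n
    trace[t + 1L, ] <- occ$mass
    alive_end[t] <- 1 - occ$mass[[DEAD_STATE]]
    rf <- advance_risk_factors(rf, cycle = t - 1L, effect = effect,
                               policy = policy)
  }
  alive_start <- 1 - trace[seq_len(horizon), DEAD_STATE]
  py_per_n <- if (half_cycle) sum((alive_start + alive_end) / 2) else sum(alive_end)
  totals <- colSums(events)
  out <- list(trace = trace, events = as.data.frame(events), totals = totals,
              person_years = py_per_n * profile$n,
              life_expectancy = py_per_n, horizon = horizon,
              profile = profile, states = states,
              share_sleep_apnea = profile$share_sleep_apnea,
              half_cycle = half_cycle)
  class(out) <- "cohort_run"
  out
}

#' @export
print.cohort_run <- function(x, ...) {
  cat(sprintf("Markov cohort run: n = %d, %d annual cycles\n",
              x$profile$n, x$horizon))
  cat(sprintf("  person-years %.1f (life expectancy within horizon %.2f y)\n",
              x$person_years, x$life_expectancy))
  cat(sprintf("  deaths %.2f; T2D onsets %.2f; ACS %.2f; strokes %.2f\n",
              x$totals[["deaths"]], x$totals[["t2d_onset"]],
              x$totals[["acs"]], x$totals[["stroke"]]))
  invisible(x)
}

#' @export
summary.cohort_run <- function(object, ...) {
  rates <- vapply(c("t2d", "acs", "stroke", "cv_total", "mortality",
                    "colorectal", "endometrial_pm", "breast_pm",
                    "knee_replacement"),
                  function(o) event_rate(object, o), numeric(1))
  out <- list(run = object, rates = rates)
  class(out) <- "summary.cohort_run"
  out
}

#' @export
print.summary.cohort_run <- function(x, ...) {
  print(x$run)
  cat("Event rates per 1000 patient-years:\n")
  print(round(x$rates, 1))
  invisible(x)
}

#' @export
as.data.frame.cohort_run <- function(x, ...) {
  data.frame(cycle = as.integer(rownames(x$trace)), x$trace,
             check.names = FALSE)
}

#' Plot cohort occupancy by state family
#'
#' @param x A `"cohort_run"`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.cohort_run <- function(x, ...) {
  fams <- unique(x$states$family)
  agg <- sapply(fams, function(f)
    rowSums(x$trace[, x$states$state[x$states$family == f], drop = FALSE]))
  graphics::matplot(as.integer(rownames(x$trace)), agg, type = "l", lty = 1,
                    xlab = "cycle (years)", ylab = "occupancy",
                    col = grDevices::hcl.colors(length(fams), "Dark 3"), ...)
  graphics::legend("topright", legend = fams, lty = 1, cex = 0.6,
                   col = grDevices::hcl.colors(length(fams), "Dark 3"))
  invisible(x)
}

#' Write the occupancy trace as CSV
#'
#' One row per cycle, one column per state.
#'
#' @param run A `"cohort_run"`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_occupancy_csv <- function(run, path) {
  utils::write.csv(as.data.frame(run), path, row.names = FALSE)
  invisible(path)
}
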