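# Mortality layer: life-table lookup with sex mixing, event-year case
# fatality, post-event relative risks, and a synthetic Gompertz life table.

#' Construct a mortality (life) table
#'
#' @param age Integer ages (must be contiguous).
#' @param qx_f,qx_m Annual death probabilities for females and males.
#' @return Data frame of class `"mortality_table"`.
#' @seealso [read_life_table()], [synthetic_life_table()]
#' @export
mortality_table <- function(age, qx_f, qx_m) {
  stopifnot(length(age) == length(qx_f), length(age) == length(qx_m))
  if (length(age) == 0L) stop("mortality table is empty")
  o <- order(age)
  age <- age[o]; qx_f <- qx_f[o]; qx_m <- qx_m[o]
  if (any(diff(age) != 1L)) stop("ages must be contiguous")
  if (any(qx_f < 0 | qx_f > 1 | qx_m < 0 | qx_m > 1))
    stop("death probabilities must be in [0, 1]")
  structure(data.frame(age = age, qx_f = qx_f, qx_m = qx_m),
            class = c("mortality_table", "data.frame"))
}

#' Read / write a life table as long-format CSV
#'
#' Columns `age`, `sex` (`F`/`M`), `qx`.
#'
#' @param path File path.
#' @param table A [mortality_table()] (for writing).
#' @return `read_life_table` returns a `"mortality_table"`;
#'   `write_life_table` returns `path` invisibly.
#' @export
read_life_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age", "sex", "qx")
  if (!all(need %in% names(df)))
    stop("life table CSV needs columns: ", paste(need, collapse = ", "))
  f <- df[df$sex == "F", ]
  m <- df[df$sex == "M", ]
  if (!setequal(f$age, m$age)) stop("female and male ages differ")
  m <- m[match(f$age, m$age), ]
  mortality_table(f$age, f$qx, m$qx)
}

#' @rdname read_life_table
#' @export
write_life_table <- function(table, path) {
  df <- rbind(data.frame(age = table$age, sex = "F", qx = table$qx_f),
              data.frame(age = table$age, sex = "M", qx = table$qx_m))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Synthetic Gompertz life table
#'
#' Annual death probability from a Gompertz hazard
#' `h(a) = b * exp(shape * a)` integrated over the year of age:
#' `qx = 1 - exp(-(b/shape) * (exp(shape*(a+1)) - exp(shape*a)))`
#' (constant hazard `1 - exp(-b)` when `shape = 0`). The defaults give
#' adult mortality of roughly 2 per 1000 at age 50 rising to about 5%
#' at age 80, with a male excess, in line with contemporary
#' high-income-country life tables; they are a synthetic stand-in for
#' national statistics, which users supply via [read_life_table()].
#'
#' @param b_female,b_male Baseline hazards at age 0.
#' @param shape Log-hazard slope per year of age (>= 0).
#' @param ages Integer ages covered.
#' @return A [mortality_table()].
#' @export
synthetic_life_table <- function(b_female = 2e-5, b_male = 3e-5,
                                 shape = 0.095, ages = 0:109) {
  stopifnot(b_female > 0, b_male > 0, shape >= 0)
  qx <- function(b) {
    if (shape < 1e-12) rep(1 - exp(-b), length(ages))
    else pmin(1, 1 - exp(-(b / shape) * (exp(shape * (ages + 1)) - exp(shape * ages))))
  }
  mortality_table(ages, qx(b_female), qx(b_male))
}

#' Base (general-population) per-cycle mortality
#'
#' Exact life-table lookup; a mixed-sex cohort uses the female share to
#' mix the two columns. Ages above the table's range carry the last
#' tabulated value forward (with a warning); this is the documented
#' extrapolation rule.
#'
#' @param age Age in years.
#' @param table A [mortality_table()].
#' @param share_women Female share of the cohort, in \[0, 1\].
#' @return Annual death probability.
#' @export
base_mortality <- function(age, table, share_women = 1) {
  if (!inherits(table, "mortality_table") || nrow(table) == 0L)
    stop("a non-empty mortality_table is required")
  stopifnot(age >= 0, share_women >= 0, share_women <= 1)
  a <- floor(age)
  if (a > max(table$age)) {
    warning(sprintf("age %d beyond life table; carrying forward qx at age %d",
                    a, max(table$age)))
    a <- max(table$age)
  }
  if (a < min(table$age)) stop("age below the life-table range")
  i <- match(a, table$age)
  share_women * table$qx_f[i] + (1 - share_women) * table$qx_m[i]
}

#' Default mortality adjustments for events and health states
#'
#' Event-year (case-fatality) probabilities and post-onset adjustments:
#' MI and unstable angina 30.00% (F) / 32.00% (M) in the year of onset
#' then relative risk 1.30; stroke 24.70% (F) / 17.10% (M) then RR
#' 2.00; knee replacement 0.30% in the year of surgery; cancer onset
#' year 30.11% (colon), 10.54% (endometrial), 4.08% (breast), then a
#' flat 4.31% annually. Relative risks are applied to the age- and
#' sex-specific annual probability on the complementary-log scale via
#' [apply_hazard_ratio()]. Sleep apnea carries no mortality effect.
#'
#' @return Named list of adjustment descriptors keyed by trigger.
#' @export
mortality_adjustments <- function() {
  list(
    acs_year     = list(onset_f = 0.30, onset_m = 0.32),
    stroke_year  = list(onset_f = 0.247, onset_m = 0.171),
    post_acs     = list(rr = 1.30),
    post_stroke  = list(rr = 2.00),
    knee_replacement = list(onset_f = 0.003, onset_m = 0.003),
    colorectal     = list(onset_f = 0.3011, onset_m = 0.3011, post = 0.0431),
    endometrial_pm = list(onset_f = 0.1054, onset_m = 0.1054, post = 0.0431),
    breast_pm      = list(onset_f = 0.0408, onset_m = 0.0408, post = 0.0431),
    sleep_apnea  = list(rr = 1.0)
  )
}

#' Per-cycle mortality adjusted for events and health states
#'
#' In the year an acute event occurs the case-fatality probability
#' replaces background mortality (never dropping below it); in
#' post-onset years relative risks scale the life-table probability and
#' cancers use a flat annual probability. When several triggers apply
#' (e.g. a CV history plus cancer) the maximum of the adjusted
#' probabilities is taken by default; multiplicative stacking of the
#' relative risks is available as an option.
#'
#' @param trigger Character vector of trigger names (see
#'   [mortality_adjustments()]), or `"none"` / empty for base mortality.
#' @param onset Logical, whether this is the trigger's year of onset.
#' @param age Age in years.
#' @param table A [mortality_table()].
#' @param share_women Female share in \[0, 1\].
#' @param adjustments Adjustment list, default [mortality_adjustments()].
#' @param stacking `"max"` (default) or `"multiplicative"`.
#' @return Annual death probability, never below base mortality.
#' @export
adjusted_mortality <- function(trigger, onset = FALSE, age, table,
                               share_women = 1,
                               adjustments = mortality_adjustments(),
                               stacking = c("max", "multiplicative")) {
  stacking <- match.arg(stacking)
  q0 <- base_mortality(age, table, share_women)
  trigger <- setdiff(trigger, "none")
  if (length(trigger) == 0L) return(q0)
  unknown <- setdiff(trigger, names(adjustments))
  if (length(unknown))
    stop("unknown mortality trigger(s): ", paste(unknown, collapse = ", "))
  one <- function(tr) {
    adj <- adjustments[[tr]]
    if (onset && !is.null(adj$onset_f))
      return(share_women * adj$onset_f + (1 - share_women) * adj$onset_m)
    if (!is.null(adj$rr)) return(apply_hazard_ratio(q0, adj$rr))
    if (!is.null(adj$post)) return(adj$post)
    q0
  }
  qs <- vapply(trigger, one, numeric(1))
  q <- if (stacking == "max" || length(qs) == 1L) max(qs) else {
    rrs <- vapply(trigger, function(tr) adjustments[[tr]]$rr %||% 1, numeric(1))
    max(max(qs), apply_hazard_ratio(q0, prod(rrs)))
  }
  max(q, q0)
}
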