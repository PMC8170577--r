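# Packaged validation-study tables: baseline characteristics of the
# CPRD-HES BMI groups, Cox proportional hazard ratios, and the
# observed / predicted event-rate table. Shipped as plain CSV under
# extdata and verified against frozen checksums on load.

FIXTURE_MD5 <- c(
  cprd_hes_baseline.csv = "b69cc385513f7981fd4f83270b14ecb0",
  cox_hazard_ratios.csv = "91f9dcfae121e03337fe183b9e61fa8d",
  observed_predicted_rates.csv = "89dc92168ea6b17013475038c1ba3ed3"
)

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "obesim")
  if (p == "") stop("packaged table not found: ", file)
  p
}

#' Packaged validation-study tables
#'
#' Returns the three tables the comparative analysis consumes:
#' `baseline` (baseline characteristics of the five CPRD-HES BMI
#' groups), `hazard_ratios` (Cox proportional hazard ratios per BMI
#' stratum for UA/MI, stroke/TIA, T2D and all-cause mortality, with the
#' normal-weight stratum as reference) and `event_rates` (observed
#' crude rates per 1000 patient-years and the published model
#' predictions, long format). Each file's MD5 checksum is verified
#' against a frozen value; a mismatch raises an error.
#'
#' @return Named list of data frames `baseline`, `hazard_ratios`,
#'   `event_rates`.
#' @export
fixture_tables <- function() {
  for (f in names(FIXTURE_MD5)) {
    sum <- unname(tools::md5sum(fixture_path(f)))
    if (!identical(sum, unname(FIXTURE_MD5[[f]])))
      stop(sprintf("checksum mismatch for packaged table '%s' (%s)", f, sum))
  }
  list(
    baseline = utils::read.csv(fixture_path("cprd_hes_baseline.csv"),
                               stringsAsFactors = FALSE),
    hazard_ratios = utils::read.csv(fixture_path("cox_hazard_ratios.csv"),
                                    stringsAsFactors = FALSE),
    event_rates = utils::read.csv(fixture_path("observed_predicted_rates.csv"),
                                  stringsAsFactors = FALSE)
  )
}

#' Observed or published-predicted rate vector for one outcome
#'
#' Convenience accessors over the packaged event-rate table: rates per
#' 1000 patient-years across the five BMI groups, ordered from the
#' normal-weight reference upward.
#'
#' @param outcome One of `"cv_total"`, `"acs"`, `"stroke"`, `"t2d"`,
#'   `"mortality"`.
#' @param series One of `"observed"`, `"com8_base"`, `"com8_scenario"`,
#'   `"com6_base"`.
#' @param tables Result of [fixture_tables()].
#' @return Numeric vector of length 5 named by BMI group.
#' @export
fixture_rates <- function(outcome, series = "observed",
                          tables = fixture_tables()) {
  er <- tables$event_rates
  sel <- er[er$outcome == outcome & er$series == series, ]
  if (nrow(sel) == 0L)
    stop("no packaged rates for outcome '", outcome, "', series '", series, "'")
  stats::setNames(sel$rate, sel$bmi_group)
}
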