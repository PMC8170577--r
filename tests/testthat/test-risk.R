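test_that("annualization preserves endpoints and matches the geometric form", {
  expect_equal(annual_probability(0, 10), 0)
  expect_equal(annual_probability(1, 8), 1)
  # frozen from the closed form 1 - 0.6^(1/10), verified by compounding
  expect_equal(round(annual_probability(0.40, 10), 6), 0.049800)
  expect_error(annual_probability(1.2, 10), "\\[0, 1\\]")
  expect_error(annual_probability(0.5, 0.5), ">= 1")
})

test_that("annualization and compounding are mutually inverse on [0, 1)", {
  p <- seq(0, 0.999, by = 0.037)
  for (K in c(1, 5, 8, 10)) {
    expect_equal(cumulative_probability(annual_probability(p, K), K), p,
                 tolerance = 1e-9)
    # compounding the annual probability K times by hand returns cum risk
    a <- annual_probability(0.40, K)
    surv <- 1
    for (i in seq_len(K)) surv <- surv * (1 - a)
    expect_equal(1 - surv, 0.40, tolerance = 1e-9)
  }
})

test_that("hazard-ratio application is bounded, monotone and identity at 1", {
  expect_equal(apply_hazard_ratio(0.01, 1), 0.01)
  expect_equal(apply_hazard_ratio(0, 5), 0)
  expect_equal(apply_hazard_ratio(0.30, 2), 0.51)
  expect_error(apply_hazard_ratio(0.1, 0), "positive")
  p <- seq(0, 1, by = 0.1); hr <- c(0.5, 1, 2, 5, 20)
  for (h in hr) {
    out <- apply_hazard_ratio(p, h)
    expect_true(all(out >= 0 & out <= 1))
    expect_true(all(diff(out) >= 0))       # monotone in p
  }
  for (pp in p[p > 0 & p < 1])
    expect_true(all(diff(apply_hazard_ratio(pp, hr)) > 0))  # monotone in hr
})

test_that("T2D incidence forces the glycemic marker per stratum", {
  reg <- example_registry()
  rf <- test_rf()
  expect_equal(t2d_incidence(rf, "NGT", null_registry()$t2d), 0)
  expect_gte(t2d_incidence(rf, "PREDIABETES", reg$t2d),
             t2d_incidence(rf, "NGT", reg$t2d))
  expect_error(t2d_incidence(rf, "T2D", reg$t2d), "already diabetic")
  # the cohort's own (diabetic-stratum) HbA1c must not leak in
  rf2 <- test_rf(hba1c_pct = 12)
  expect_equal(t2d_incidence(rf2, "NGT", reg$t2d),
               t2d_incidence(rf, "NGT", reg$t2d))
})

test_that("toy T2D model matches an independent formula evaluation", {
  reg <- example_registry()
  # reference-group cohort, prediabetes stratum: marker forced to 6.0%
  rf <- test_rf(age = 48.5, bmi = 22.5)
  lp <- -2.8 + 0.16 * (22.5 - 25) + 0.02 * (48.5 - 50) + 1.0 * (6.0 - 5.5)
  expected <- 1 - (1 - 1 / (1 + exp(-lp)))^(1 / 10)
  expect_equal(t2d_incidence(rf, "PREDIABETES", reg$t2d), expected,
               tolerance = 1e-12)
})

test_that("prediabetes maps to NGT (first) and T2D (recurrent) CV models", {
  reg <- example_registry()
  rf <- test_rf()
  expect_equal(cv_event_probability(rf, "PREDIABETES", "first", reg),
               cv_event_probability(rf, "NGT", "first", reg))
  expect_equal(cv_event_probability(rf, "PREDIABETES", "recurrent", reg),
               cv_event_probability(rf, "T2D", "recurrent", reg))
  expect_equal(unname(cv_event_probability(rf, "NGT", "first", null_registry())),
               c(0, 0))
  partial <- risk_registry(t2d = reg$t2d)
  expect_error(cv_event_probability(rf, "NGT", "first", partial),
               "cv_first_ngt")
  # ACS/stroke partition respects the configured share
  p <- cv_event_probability(rf, "T2D", "first", reg, acs_share = 0.25)
  expect_equal(unname(p[["acs"]] / sum(p)), 0.25)
})

test_that("risk models enforce the [0, 1] contract and load from files", {
  bad <- risk_model("bad", function(rf) 1.5)
  expect_error(evaluate_risk(bad, test_rf()), "outside \\[0, 1\\]")

  m <- example_registry()$t2d
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(name = m$name, horizon_years = m$horizon_years,
                            population = m$population, terms = m$terms),
                       path, auto_unbox = TRUE, digits = NA)
  m2 <- read_risk_model(path)
  rf <- test_rf(hba1c_pct = 6.0)
  expect_equal(evaluate_risk(m2, rf), evaluate_risk(m, rf), tolerance = 1e-12)
})

test_that("BMI-graded complications adjust baseline rates per stratum", {
  tabs <- default_hr_tables()
  rf_ref <- test_rf(bmi = 22)
  expect_equal(complication_probability(rf_ref, "colorectal",
                                        tabs$colorectal, 0.001), 0.001)
  two <- hazard_ratio_table("colorectal", c(18.5, 25), c(25, 45), c(1, 2))
  expect_equal(complication_probability(test_rf(bmi = 30), "colorectal",
                                        two, 0.001), 1 - 0.999^2)
  # postmenopausal cancers: zero below menopause age or with no women
  expect_equal(complication_probability(test_rf(age = 45), "endometrial_pm",
                                        tabs$endometrial_pm, 0.001), 0)
  expect_equal(complication_probability(test_rf(age = 60, share_women = 0),
                                        "breast_pm", tabs$breast_pm, 0.001), 0)
  expect_gt(complication_probability(test_rf(age = 60), "breast_pm",
                                     tabs$breast_pm, 0.001), 0)
  expect_warning(
    complication_probability(test_rf(bmi = 55), "colorectal", tabs$colorectal,
                             0.001), "clamped")
})

test_that("returned probabilities stay in [0, 1] over randomized risk factors", {
  set.seed(11)
  reg <- example_registry()
  for (i in 1:25) {
    rf <- test_rf(age = runif(1, 25, 84), bmi = runif(1, 19, 44),
                  sbp = runif(1, 100, 180), share_women = runif(1))
    expect_true(t2d_incidence(rf, "NGT", reg$t2d) >= 0)
    expect_true(t2d_incidence(rf, "PREDIABETES", reg$t2d) <= 1)
    p <- cv_event_probability(rf, sample(c("NGT", "PREDIABETES", "T2D"), 1),
                              sample(c("first", "recurrent"), 1), reg)
    expect_true(all(p >= 0 & p <= 1))
  }
  # incidence non-decreasing in BMI for the BMI-monotone shipped model
  bmis <- seq(20, 44, by = 2)
  inc <- vapply(bmis, function(b)
    t2d_incidence(test_rf(bmi = b), "NGT", reg$t2d), numeric(1))
  expect_true(all(diff(inc) > 0))
})

test_that("hazard-ratio tables validate strata and reference", {
  expect_error(hazard_ratio_table("x", c(18.5, 25), c(25, 45), c(1.2, 2)),
               "reference")
  expect_error(hazard_ratio_table("x", c(18.5, 24), c(26, 45), c(1, 2)),
               "non-overlapping")
  tab <- hazard_ratio_table("x", c(18.5, 25), c(25, 45), c(1, 2))
  expect_equal(hr_for_bmi(tab, 24.999), 1)
  expect_equal(hr_for_bmi(tab, 25), 2)
})
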