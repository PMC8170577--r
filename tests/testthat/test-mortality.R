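test_that("base mortality looks up and mixes sexes by the female share", {
  flat <- flat_life_table(0.01)
  expect_equal(base_mortality(30, flat), 0.01)
  expect_equal(base_mortality(95, flat), 0.01)
  mixed <- sexed_life_table(0.02, 0.04)
  expect_equal(base_mortality(50, mixed, share_women = 1), 0.02)
  expect_equal(base_mortality(50, mixed, share_women = 0.5), 0.03)
  expect_equal(base_mortality(50, mixed, share_women = 0), 0.04)
  expect_error(base_mortality(50, data.frame()), "mortality_table")
  expect_warning(base_mortality(120, flat), "carrying forward")
})

test_that("event-year case fatality replaces background mortality", {
  flat <- flat_life_table(0.01)
  # MI/unstable angina: 30% female, 32% male in the year of onset
  expect_equal(adjusted_mortality("acs_year", onset = TRUE, age = 60,
                                  table = flat, share_women = 0), 0.32)
  expect_equal(adjusted_mortality("acs_year", onset = TRUE, age = 60,
                                  table = flat, share_women = 1), 0.30)
  expect_equal(adjusted_mortality("stroke_year", onset = TRUE, age = 60,
                                  table = flat, share_women = 1), 0.247)
  expect_equal(adjusted_mortality("stroke_year", onset = TRUE, age = 60,
                                  table = flat, share_women = 0), 0.171)
  # 50/50 mix is the linear blend
  expect_equal(adjusted_mortality("acs_year", onset = TRUE, age = 60,
                                  table = flat, share_women = 0.5), 0.31)
})

test_that("post-event years scale the life-table probability by the RR", {
  lt <- flat_life_table(0.02)
  expect_equal(adjusted_mortality("post_stroke", age = 70, table = lt), 0.0396)
  expect_equal(adjusted_mortality("post_acs", age = 70, table = lt),
               1 - 0.98^1.3)
  expect_equal(adjusted_mortality("none", age = 70, table = lt), 0.02)
  # cancers: flat annual post-onset probability, never below base
  expect_equal(adjusted_mortality("colorectal", age = 70, table = lt), 0.0431)
  hi <- flat_life_table(0.10)
  expect_equal(adjusted_mortality("colorectal", age = 70, table = hi), 0.10)
  expect_error(adjusted_mortality("gout", age = 70, table = lt), "unknown")
})

test_that("adjusted mortality never drops below base and stacks by maximum", {
  lt <- synthetic_life_table()
  for (a in c(40, 60, 80, 100)) {
    q0 <- base_mortality(a, lt, 0.5)
    for (tr in c("post_acs", "post_stroke", "colorectal", "sleep_apnea"))
      expect_gte(adjusted_mortality(tr, age = a, table = lt, share_women = 0.5), q0)
  }
  both <- adjusted_mortality(c("post_stroke", "colorectal"), age = 50,
                             table = flat_life_table(0.001))
  expect_equal(both, 0.0431)  # cancer flat dominates RR 2 on 0.001
  stacked <- adjusted_mortality(c("post_acs", "post_stroke"), age = 50,
                                table = flat_life_table(0.02),
                                stacking = "multiplicative")
  expect_equal(stacked, 1 - 0.98^(1.3 * 2))
})

test_that("sleep apnea carries no mortality effect", {
  lt <- flat_life_table(0.015)
  expect_equal(adjusted_mortality("sleep_apnea", age = 55, table = lt), 0.015)
})

test_that("synthetic Gompertz life table matches the analytic survivor function", {
  lt <- synthetic_life_table(b_female = 2e-5, b_male = 3e-5, shape = 0.095)
  expect_true(all(diff(lt$qx_f) >= 0))
  expect_true(all(diff(lt$qx_m) >= 0))
  expect_gte(base_mortality(80, lt), base_mortality(40, lt))
  # survival to age a from the table vs closed-form Gompertz survivor
  b <- 2e-5; c <- 0.095
  for (a in c(30, 60, 90)) {
    table_surv <- prod(1 - lt$qx_f[lt$age < a])
    closed <- exp(-(b / c) * (exp(c * a) - 1))
    expect_equal(table_surv, closed, tolerance = 1e-9)
  }
  flat <- synthetic_life_table(b_female = 0.01, b_male = 0.01, shape = 0)
  expect_equal(flat$qx_f, rep(1 - exp(-0.01), nrow(flat)))
})

test_that("life tables round-trip through long-format CSV", {
  lt <- synthetic_life_table(ages = 0:100)
  path <- withr::local_tempfile(fileext = ".csv")
  write_life_table(lt, path)
  lt2 <- read_life_table(path)
  expect_equal(lt2$qx_f, lt$qx_f, tolerance = 1e-12)
  expect_equal(lt2$qx_m, lt$qx_m, tolerance = 1e-12)
  expect_error(mortality_table(c(0, 2), c(0.1, 0.1), c(0.1, 0.1)), "contiguous")
  expect_error(mortality_table(integer(0), numeric(0), numeric(0)), "empty")
})
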