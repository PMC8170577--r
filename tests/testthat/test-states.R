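test_that("state enumeration is the documented 19-state constrained product", {
  st <- health_states()
  expect_equal(nrow(st), 19L)
  expect_equal(anyDuplicated(st$state), 0L)
  # exactly one absorbing death state, carrying no other attributes
  expect_equal(sum(st$dead), 1L)
  dead <- st[st$dead, ]
  expect_true(is.na(dead$glycemic) && is.na(dead$cv) && is.na(dead$cancer))
  # acute event-year states are distinct from their post-event states
  expect_true(all(c("ACS_YEAR", "POST_ACS", "STROKE_YEAR", "POST_STROKE") %in% st$cv))
  # no state combines two acute CV events
  expect_true(all(table(st$state, st$cv) <= 1))
  # deterministic ordering
  expect_identical(st$state, health_states()$state)
  # exhaustive product check: alive glycemic x cv states cover 3 x 5
  alive <- st[!st$dead & st$cancer == "NONE" & !is.na(st$cancer), ]
  expect_equal(nrow(alive), 15L)
  expect_setequal(unique(alive$glycemic), c("NGT", "PREDIABETES", "T2D"))
})

test_that("collapsing acute/post distinctions yields the single-or-combined families", {
  st <- health_states()
  fam <- state_families(st)
  # acute and post-event states of the same type share a family
  expect_equal(fam[st$state == "T2D.ACS_YEAR"], fam[st$state == "T2D.POST_ACS"])
  expect_equal(fam[st$state == "NGT.STROKE_YEAR"], fam[st$state == "NGT.POST_STROKE"])
  # 3 glycemic-only + 3x2 glycemic-CV combos + 3 cancers + death = 13 families
  expect_equal(length(unique(fam)), 13L)
})

test_that("validate_matrix reports row sums, negatives and severity violations", {
  expect_true(validate_matrix(matrix_with())$pass)

  short <- matrix_with(override_rows("NGT.EVENT_FREE", "NGT.EVENT_FREE", 0.99))
  d <- validate_matrix(short)
  expect_false(d$pass)
  expect_equal(names(which(abs(d$row_sum_dev) > 1e-9)), "NGT.EVENT_FREE")

  regress <- matrix_with(override_rows(
    c("T2D.EVENT_FREE", "T2D.EVENT_FREE"),
    c("PREDIABETES.EVENT_FREE", "T2D.EVENT_FREE"), c(0.1, 0.9)))
  d <- validate_matrix(regress)
  expect_false(d$pass)
  expect_equal(d$severity_violations$from_state, "T2D.EVENT_FREE")
  expect_equal(d$severity_violations$to_state, "PREDIABETES.EVENT_FREE")

  neg <- matrix_with(override_rows(
    c("NGT.EVENT_FREE", "NGT.EVENT_FREE"),
    c("T2D.EVENT_FREE", "NGT.EVENT_FREE"), c(-0.1, 1.1)))
  expect_gt(nrow(validate_matrix(neg)$negative), 0L)

  bad <- matrix(1, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(validate_matrix(bad), "state enumeration")
})

test_that("step_cohort propagates mass and increments the cycle", {
  occ <- state_occupancy(c(NGT.EVENT_FREE = 0.7, T2D.EVENT_FREE = 0.3))
  after <- step_cohort(occ, matrix_with())
  expect_equal(after$mass, occ$mass)
  expect_equal(after$cycle, 1L)

  dead <- state_occupancy(c(DEAD = 1))
  expect_equal(step_cohort(dead, matrix_with())$mass[["DEAD"]], 1)
})

test_that("two-state toy survival follows the closed form (1-q)^n", {
  q <- 0.1
  m <- matrix_with(override_rows(
    c("NGT.EVENT_FREE", "NGT.EVENT_FREE"), c("DEAD", "NGT.EVENT_FREE"),
    c(q, 1 - q)))
  occ <- state_occupancy(c(NGT.EVENT_FREE = 1))
  for (i in 1:5) occ <- step_cohort(occ, m)
  expect_equal(occ$mass[["NGT.EVENT_FREE"]], 0.9^5, tolerance = 1e-12)
  expect_equal(occ$mass[["NGT.EVENT_FREE"]], 0.59049)
})

test_that("n-step occupancy matches a brute-force matrix power oracle", {
  m <- matrix_with(rbind(
    override_rows(rep("NGT.EVENT_FREE", 3),
                  c("NGT.EVENT_FREE", "PREDIABETES.EVENT_FREE", "DEAD"),
                  c(0.7, 0.2, 0.1)),
    override_rows(rep("PREDIABETES.EVENT_FREE", 2),
                  c("PREDIABETES.EVENT_FREE", "DEAD"), c(0.85, 0.15))))
  occ0 <- c(NGT.EVENT_FREE = 1)
  occ <- state_occupancy(occ0)
  n <- 7
  for (i in seq_len(n)) occ <- step_cohort(occ, m)
  # independent oracle: explicit matrix power
  pow <- diag(nrow(m)); dimnames(pow) <- dimnames(m)
  for (i in seq_len(n)) pow <- pow %*% unclass(m)
  expect_equal(occ$mass, (state_occupancy(occ0)$mass %*% pow)[1, ],
               tolerance = 1e-12)
})

test_that("mass is conserved and death is monotone under random valid matrices", {
  set.seed(42)
  for (rep in 1:5) {
    m <- random_valid_matrix()
    occ <- state_occupancy(c(NGT.EVENT_FREE = 0.5, PREDIABETES.EVENT_FREE = 0.3,
                             T2D.EVENT_FREE = 0.2))
    dead_prev <- 0
    for (t in 1:40) {
      occ <- step_cohort(occ, m, validate = FALSE)
      expect_equal(sum(occ$mass), 1, tolerance = 1e-9)
      expect_true(all(occ$mass >= -1e-15))
      expect_gte(occ$mass[["DEAD"]], dead_prev)
      dead_prev <- occ$mass[["DEAD"]]
    }
  }
})

test_that("transition matrices round-trip through long-format CSV", {
  set.seed(7)
  m <- random_valid_matrix()
  path <- withr::local_tempfile(fileext = ".csv")
  write_transition_csv(m, path)
  m2 <- read_transition_csv(path)
  expect_equal(unclass(m2), unclass(m), tolerance = 1e-12)
  expect_error(transition_matrix(
    data.frame(from_state = "NOPE", to_state = "DEAD", probability = 1)),
    "unknown state")
})
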