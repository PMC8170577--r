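# Shared fixtures built in code: small life tables, degenerate
# registries and a convenience matrix builder.

flat_life_table <- function(q = 0.01, ages = 0:109)
  mortality_table(ages, rep(q, length(ages)), rep(q, length(ages)))

sexed_life_table <- function(qf = 0.02, qm = 0.04, ages = 0:109)
  mortality_table(ages, rep(qf, length(ages)), rep(qm, length(ages)))

# Identity-except rows: start from each state staying put, then
# override selected rows from a long data frame.
matrix_with <- function(overrides = NULL, states = health_states()) {
  ids <- states$state
  m <- diag(length(ids))
  dimnames(m) <- list(ids, ids)
  if (!is.null(overrides)) {
    for (k in seq_len(nrow(overrides))) {
      i <- overrides$from_state[k]
      if (!overrides$keep[k]) m[i, ] <- 0
    }
    m[cbind(overrides$from_state, overrides$to_state)] <- overrides$probability
  }
  transition_matrix(m, states)
}

override_rows <- function(from, to, probability, keep = FALSE)
  data.frame(from_state = from, to_state = to, probability = probability,
             keep = keep, stringsAsFactors = FALSE)

# Random admissible row-stochastic matrix under a fixed RNG state.
random_valid_matrix <- function(states = health_states()) {
  ok <- allowed_transitions(states)
  ids <- states$state
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_along(ids)) {
    w <- stats::runif(sum(ok[i, ]))
    m[i, ok[i, ]] <- w / sum(w)
  }
  transition_matrix(m, states)
}

test_rf <- function(...) {
  args <- list(age = 50, bmi = 32, sbp = 135, share_women = 0.6,
               menopause_age = 51)
  args[names(list(...))] <- list(...)
  do.call(risk_factors, args)
}
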