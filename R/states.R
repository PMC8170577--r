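# State-space engine: enumeration, severity ordering, transition matrices,
# and the one-cycle cohort update.

GLYCEMIC_LEVELS <- c("NGT", "PREDIABETES", "T2D")
CV_LEVELS <- c("EVENT_FREE", "ACS_YEAR", "POST_ACS", "STROKE_YEAR", "POST_STROKE")
CANCER_LEVELS <- c("COLORECTAL", "ENDOMETRIAL_PM", "BREAST_PM")
DEAD_STATE <- "DEAD"

#' Enumerate the model's health-state space
#'
#' The state space is the constrained product of glycemic status
#' (normal glucose tolerance, prediabetes, type 2 diabetes) and
#' cardiovascular history (event-free, acute ACS year, post-ACS,
#' acute stroke year, post-stroke), plus three standalone cancer
#' states (colorectal, postmenopausal endometrial, postmenopausal
#' breast) and a single absorbing death state: 3 x 5 + 3 + 1 = 19
#' mutually exclusive states. Acute event years are distinct from
#' their post-event states so that case fatality and recurrent-event
#' risk can differ. Sleep apnea, knee replacement and bariatric
#' surgery are modelled as tallied overlays on these states, not as
#' states of their own, because they can co-occur with any of them.
#'
#' @return A data frame with one row per state and columns `state`
#'   (unique identifier), `glycemic`, `cv`, `cancer` (`"NONE"` for
#'   non-cancer alive states, `NA` for death), `dead` (logical) and
#'   `family` (reporting family obtained by collapsing the acute/post
#'   distinction; see [state_families()]).
#' @seealso [state_families()], [transition_matrix()], [validate_matrix()]
#' @examples
#' st <- health_states()
#' nrow(st)            # 19
#' sum(st$dead)        # exactly one absorbing death state
#' @export
health_states <- function() {
  alive <- expand.grid(cv = CV_LEVELS, glycemic = GLYCEMIC_LEVELS,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  st <- data.frame(
    state = c(paste(alive$glycemic, alive$cv, sep = "."),
              paste0("CANCER_", CANCER_LEVELS),
              DEAD_STATE),
    glycemic = c(alive$glycemic, rep(NA_character_, length(CANCER_LEVELS) + 1L)),
    cv = c(alive$cv, rep(NA_character_, length(CANCER_LEVELS) + 1L)),
    cancer = c(rep("NONE", nrow(alive)), CANCER_LEVELS, NA_character_),
    dead = c(rep(FALSE, nrow(alive) + length(CANCER_LEVELS)), TRUE),
    stringsAsFactors = FALSE
  )
  st$family <- state_families(st)
  st
}

#' Map states to reporting families
#'
#' Collapses the acute-year/post-event distinction so that the 19
#' internal states aggregate to single-or-combined comorbidity
#' families (e.g. `"T2D+ACS"`), the three cancers and death.
#'
#' @param states A state data frame as returned by [health_states()].
#' @return Character vector of family labels, one per state row.
#' @export
state_families <- function(states = health_states()) {
  cvfam <- c(EVENT_FREE = "", ACS_YEAR = "+ACS", POST_ACS = "+ACS",
             STROKE_YEAR = "+STROKE", POST_STROKE = "+STROKE")
  fam <- ifelse(states$dead, "DEATH",
         ifelse(states$cancer != "NONE" & !is.na(states$cancer),
                paste0("CANCER_", states$cancer),
                paste0(states$glycemic, cvfam[states$cv])))
  unname(fam)
}

# Severity ranks used by the no-regression rule. Glycemic status is
# totally ordered; for CV history only "has a history" matters (recurrent
# acute events from post-event states are progressions, not regressions).
glycemic_rank <- function(g) match(g, GLYCEMIC_LEVELS) - 1L
cv_rank <- function(cv) ifelse(cv == "EVENT_FREE", 0L, 1L)

#' Logical matrix of severity-admissible transitions
#'
#' A transition is inadmissible ("cannot move to a less severe state")
#' when it lowers the glycemic rank (e.g. T2D to prediabetes), drops an
#' acquired cardiovascular history, leaves a cancer state for a
#' non-cancer state, or leaves death. Death is reachable from anywhere
#' and absorbing.
#'
#' @param states A state data frame as returned by [health_states()].
#' @return A square logical matrix with state identifiers as dimnames;
#'   `TRUE` where a nonzero transition probability is admissible.
#' @export
allowed_transitions <- function(states = health_states()) {
  n <- nrow(states)
  ok <- matrix(FALSE, n, n, dimnames = list(states$state, states$state))
  for (i in seq_len(n)) {
    from <- states[i, ]
    for (j in seq_len(n)) {
      to <- states[j, ]
      ok[i, j] <-
        if (from$dead) to$dead
        else if (to$dead) TRUE
        else if (!is.na(from$cancer) && from$cancer != "NONE") identical(from$state, to$state)
        else if (!is.na(to$cancer) && to$cancer != "NONE") TRUE
        else glycemic_rank(to$glycemic) >= glycemic_rank(from$glycemic) &&
             cv_rank(to$cv) >= cv_rank(from$cv)
    }
  }
  ok
}

#' Construct a transition matrix
#'
#' @param entries Either a square numeric matrix with state identifiers
#'   as dimnames, or a long-format data frame with columns
#'   `from_state`, `to_state`, `probability` (unlisted pairs get 0).
#' @param states State enumeration the matrix must cover.
#' @return A square numeric matrix of class `"transition_matrix"`,
#'   rows = from-state, columns = to-state.
#' @seealso [validate_matrix()], [read_transition_csv()]
#' @export
transition_matrix <- function(entries, states = health_states()) {
  ids <- states$state
  if (is.matrix(entries)) {
    if (is.null(dimnames(entries)) ||
        !setequal(rownames(entries), ids) || !setequal(colnames(entries), ids))
      stop("matrix dimnames must match the state enumeration")
    m <- entries[ids, ids, drop = FALSE]
  } else {
    need <- c("from_state", "to_state", "probability")
    if (!all(need %in% names(entries)))
      stop("long-format entries need columns: ", paste(need, collapse = ", "))
    bad <- setdiff(unique(c(entries$from_state, entries$to_state)), ids)
    if (length(bad))
      stop("unknown state reference(s): ", paste(bad, collapse = ", "))
    m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    m[cbind(entries$from_state, entries$to_state)] <- entries$probability
  }
  class(m) <- c("transition_matrix", class(m))
  m
}

#' Validate a transition matrix
#'
#' Checks that every row sums to one within tolerance, that no entry is
#' negative, that the death row is the identity on death (absorbing),
#' and that all entries violating the severity order are exactly zero.
#'
#' @param m A matrix as built by [transition_matrix()] (or any square
#'   numeric matrix with state dimnames).
#' @param states State enumeration.
#' @param tol Row-sum tolerance (default `1e-9`).
#' @return An object of class `"matrix_diagnostics"`: a list with
#'   `row_sum_dev` (named deviations from 1), `negative` and
#'   `severity_violations` (data frames of offending entries), and
#'   `pass` (logical).
#' @export
validate_matrix <- function(m, states = health_states(), tol = 1e-9) {
  ids <- states$state
  if (is.null(dimnames(m)) || !setequal(rownames(m), ids) || !setequal(colnames(m), ids))
    stop("matrix dimnames must match the state enumeration")
  m <- unclass(m)[ids, ids, drop = FALSE]
  dev <- rowSums(m) - 1
  neg <- which(m < 0, arr.ind = TRUE)
  negative <- data.frame(from_state = ids[neg[, 1]], to_state = ids[neg[, 2]],
                         probability = m[neg], stringsAsFactors = FALSE)
  ok <- allowed_transitions(states)
  viol <- which(!ok & m != 0, arr.ind = TRUE)
  severity_violations <- data.frame(from_state = ids[viol[, 1]],
                                    to_state = ids[viol[, 2]],
                                    probability = m[viol], stringsAsFactors = FALSE)
  out <- list(row_sum_dev = dev, negative = negative,
              severity_violations = severity_violations,
              tol = tol,
              pass = all(abs(dev) <= tol) && nrow(negative) == 0L &&
                nrow(severity_violations) == 0L)
  class(out) <- "matrix_diagnostics"
  out
}

#' @export
print.matrix_diagnostics <- function(x, ...) {
  cat("Transition-matrix diagnostics\n")
  bad <- names(x$row_sum_dev)[abs(x$row_sum_dev) > x$tol]
  cat("  rows off unit sum:", if (length(bad)) paste(bad, collapse = ", ") else "none", "\n")
  cat("  negative entries:", nrow(x$negative), "\n")
  cat("  severity-order violations:", nrow(x$severity_violations), "\n")
  cat(if (x$pass) "  PASS\n" else "  FAIL\n")
  invisible(x)
}

#' Cohort occupancy over the state space
#'
#' @param mass Named numeric vector of probability mass per state
#'   (names must cover the enumeration; omitted states get 0).
#' @param cycle Integer cycle index (years since model entry).
#' @param states State enumeration.
#' @return An object of class `"state_occupancy"`.
#' @export
state_occupancy <- function(mass, cycle = 0L, states = health_states()) {
  ids <- states$state
  full <- stats::setNames(numeric(length(ids)), ids)
  bad <- setdiff(names(mass), ids)
  if (length(bad)) stop("unknown state reference(s): ", paste(bad, collapse = ", "))
  full[names(mass)] <- mass
  if (any(full < 0)) stop("occupancy masses must be non-negative")
  if (abs(sum(full) - 1) > 1e-9)
    stop(sprintf("occupancy mass sums to %.12f, expected 1", sum(full)))
  structure(list(mass = full, cycle = as.integer(cycle)), class = "state_occupancy")
}

#' @export
print.state_occupancy <- function(x, ...) {
  cat("State occupancy at cycle", x$cycle, "\n")
  nz <- x$mass[x$mass > 0]
  print(round(nz, 6))
  invisible(x)
}

#' Advance cohort occupancy by one annual cycle
#'
#' @param occ A [state_occupancy()] object.
#' @param m A transition matrix (row-stochastic, from-state rows).
#' @param validate Validate `m` first and stop on failure (default TRUE).
#' @return The new occupancy with `cycle` incremented by one.
#' @export
step_cohort <- function(occ, m, validate = TRUE) {
  if (!inherits(occ, "state_occupancy")) stop("occ must be a state_occupancy")
  if (validate) {
    d <- validate_matrix(m)
    if (!d$pass) {
      print(d)
      stop("transition matrix failed validation")
    }
  }
  ids <- names(occ$mass)
  new_mass <- as.numeric(occ$mass %*% unclass(m)[ids, ids])
  names(new_mass) <- ids
  structure(list(mass = new_mass, cycle = occ$cycle + 1L),
            class = "state_occupancy")
}

#' Write / read a transition matrix as long-format CSV
#'
#' Columns `from_state`, `to_state`, `probability`; zero entries are
#' omitted on write and implied on read.
#'
#' @param m Transition matrix.
#' @param path File path.
#' @param states State enumeration.
#' @return `write_transition_csv` returns `path` invisibly;
#'   `read_transition_csv` returns a `"transition_matrix"`.
#' @export
write_transition_csv <- function(m, path, states = health_states()) {
  idx <- which(unclass(m) != 0, arr.ind = TRUE)
  df <- data.frame(from_state = rownames(m)[idx[, 1]],
                   to_state = colnames(m)[idx[, 2]],
                   probability = m[idx], stringsAsFactors = FALSE)
  df <- df[order(match(df$from_state, states$state),
                 match(df$to_state, states$state)), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_transition_csv
#' @export
read_transition_csv <- function(path, states = health_states()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  transition_matrix(df, states = states)
}
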