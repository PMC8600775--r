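#' The UK EQ-5D-3L time trade-off value set
#'
#' Returns the published UK TTO tariff as a list of scoring constants. A
#' health state is described by five dimensions (mobility, self-care, usual
#' activities, pain/discomfort, anxiety/depression), each at level 1 (no
#' problems), 2 (some problems) or 3 (extreme problems). The state 11111
#' scores exactly 1; any departure from full health triggers a fixed
#' constant decrement, per-dimension level decrements, and an additional
#' decrement ("N3") if any dimension is at level 3. The worst ("pits")
#' state 33333 scores -0.594 and the best state below full health, 11211,
#' scores 0.883 -- no state falls in the open interval (0.883, 1).
#'
#' The object is an ordinary list so that alternative tariffs with the same
#' shape could be supplied to the scoring functions, but only the UK 3L set
#' ships with the package.
#'
#' @return A list of class `eq5d_value_set` with elements `constant`,
#'   `level2` (named numeric, decrement for level 2 per dimension), `level3`
#'   (likewise for level 3), `n3` (any-level-3 decrement), `floor` (utility
#'   of 33333) and `ceiling_gap` (utility of the best non-full-health state).
#' @examples
#' vs <- uk3l_value_set()
#' score_state(c(3, 3, 3, 3, 3), vs) # -0.594
#' @export
uk3l_value_set <- function() {
  vs <- list(
    constant = 0.081,
    level2 = c(mobility = 0.069, self_care = 0.104, usual_activities = 0.036,
               pain_discomfort = 0.123, anxiety_depression = 0.071),
    level3 = c(mobility = 0.314, self_care = 0.214, usual_activities = 0.094,
               pain_discomfort = 0.386, anxiety_depression = 0.236),
    n3 = 0.269,
    floor = -0.594,
    ceiling_gap = 0.883
  )
  class(vs) <- "eq5d_value_set"
  vs
}

#' Names of the five EQ-5D dimensions, in scoring order
#' @return Character vector of length 5.
#' @export
eq5d_dimensions <- function() {
  c("mobility", "self_care", "usual_activities",
    "pain_discomfort", "anxiety_depression")
}

validate_state <- function(state) {
  state <- as.integer(round(as.numeric(state)))
  if (length(state) != 5L || anyNA(state) || any(!state %in% 1:3)) {
    stop("invalid EQ-5D-3L state: need 5 levels, each in {1, 2, 3}",
         call. = FALSE)
  }
  state
}

#' Score an EQ-5D-3L health state with a tariff
#'
#' @param state Integer vector of 5 levels (mobility, self-care, usual
#'   activities, pain/discomfort, anxiety/depression), each in 1..3, or a
#'   matrix/data frame with those five columns (one state per row).
#' @param value_set A tariff from [uk3l_value_set()].
#' @return Numeric utility (vectorised over rows): 1 for 11111, otherwise
#'   `1 - constant - level decrements - N3 decrement`, always in
#'   `[-0.594, 0.883]` for the UK set.
#' @examples
#' score_state(c(1, 1, 2, 1, 1)) # 0.883, best state short of full health
#' @export
score_state <- function(state, value_set = uk3l_value_set()) {
  if (is.data.frame(state)) state <- as.matrix(state)
  if (is.matrix(state)) {
    return(vapply(seq_len(nrow(state)),
                  function(i) score_state(state[i, ], value_set),
                  numeric(1)))
  }
  state <- validate_state(state)
  if (all(state == 1L)) return(1)
  dec2 <- sum(value_set$level2[state == 2L])
  dec3 <- sum(value_set$level3[state == 3L])
  n3 <- if (any(state == 3L)) value_set$n3 else 0
  1 - value_set$constant - dec2 - dec3 - n3
}

#' Enumerate all 243 EQ-5D-3L health states
#'
#' States are returned in deterministic lexicographic order with mobility
#' varying slowest, so the first row is 11111 and the last is 33333.
#'
#' @return A tibble with 243 rows and the five dimension columns plus
#'   `state` (the 5-digit label, e.g. "11211").
#' @export
enumerate_states <- function() {
  g <- expand.grid(
    anxiety_depression = 1:3, pain_discomfort = 1:3,
    usual_activities = 1:3, self_care = 1:3, mobility = 1:3,
    KEEP.OUT.ATTRS = FALSE
  )[, 5:1]
  tb <- tibble::as_tibble(g)
  tb$state <- apply(as.matrix(tb), 1L, paste0, collapse = "")
  tb
}

#' All feasible utilities of a tariff
#'
#' Scores the 243 states and returns the sorted unique utilities. For the
#' UK set the maximum is 1, the second-largest is 0.883 (the "gap" below
#' full health) and the minimum is -0.594.
#'
#' @inheritParams score_state
#' @return Sorted (increasing) numeric vector of distinct feasible utilities.
#' @export
feasible_utilities <- function(value_set = uk3l_value_set()) {
  states <- enumerate_states()
  u <- score_state(states[, eq5d_dimensions()], value_set)
  sort(unique(round(u, 10)))
}

#' Tabulate the full tariff
#'
#' @inheritParams score_state
#' @return A tibble of the 243 states with their `state` label and `utility`.
#' @export
tariff_table <- function(value_set = uk3l_value_set()) {
  states <- enumerate_states()
  states$utility <- score_state(states[, eq5d_dimensions()], value_set)
  states[, c("state", "utility")]
}

#' Check that utilities lie in the feasible EQ-5D-3L zone
#'
#' The feasible zone is `[floor, gap] U {1}`: nothing above 1, nothing below
#' the pits-state utility, and nothing in the open gap just below full
#' health.
#'
#' @param u Numeric vector of utilities.
#' @param value_set A tariff from [uk3l_value_set()].
#' @param tol Numerical slack at the zone edges.
#' @return Logical vector, `TRUE` where feasible.
#' @export
is_feasible_utility <- function(u, value_set = uk3l_value_set(), tol = 1e-9) {
  lo <- value_set$floor
  gap <- value_set$ceiling_gap
  in_band <- u >= lo - tol & u <= gap + tol
  at_one <- abs(u - 1) <= tol
  in_band | at_one
}
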