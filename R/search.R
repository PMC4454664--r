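#' Draw a meeting candidate under school-structured meeting
#'
#' Selects whom a seeking agent meets this step. The eligible pool contains
#' all opposite-gender agents of marriageable age except the seeker's
#' current partner; with probability `delta` the candidate is drawn
#' uniformly from the subset sharing the seeker's school enrolment status,
#' otherwise uniformly from the complementary subset. An empty chosen
#' subset falls back to the other; if both are empty no meeting occurs.
#'
#' This is the reference implementation of the meeting rule; the compiled
#' scheduler applies the same rule internally during a simulation run.
#'
#' @param seeker A one-row agent data frame (see [spawn_agent()]).
#' @param population An agent data frame including the seeker.
#' @param delta Structuring parameter in \[0, 1\].
#' @param a_marr Marriageable age in steps.
#' @return The candidate's row of `population`, or `NULL` if the pool is
#'   empty.
#' @export
select_partner_candidate <- function(seeker, population, delta,
                                     a_marr = 160) {
  stopifnot(nrow(seeker) == 1, delta >= 0, delta <= 1)
  if (seeker$age < a_marr) {
    stop("seeker must be of marriageable age", call. = FALSE)
  }
  pool <- population[population$gender != seeker$gender &
                       population$age >= a_marr, , drop = FALSE]
  if (!is.na(seeker$partner_id)) {
    pool <- pool[pool$id != seeker$partner_id, , drop = FALSE]
  }
  if (!nrow(pool)) return(NULL)
  same <- pool[pool$enrolment == seeker$enrolment, , drop = FALSE]
  diff <- pool[pool$enrolment != seeker$enrolment, , drop = FALSE]
  pick_same <- stats::runif(1) < delta
  chosen <- if (pick_same) same else diff
  if (!nrow(chosen)) chosen <- if (pick_same) diff else same
  if (!nrow(chosen)) return(NULL)
  chosen[sample.int(nrow(chosen), 1L), , drop = FALSE]
}
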