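#' Ideal partner age
#'
#' Male agents hold a fixed ideal partner age (24 years = 240 steps by
#' default), while a female agent's ideal partner age tracks her own age
#' plus a fixed offset (2.5 years = 25 steps by default) and is therefore
#' recomputed as she ages.
#'
#' @param gender Character vector, `"male"` or `"female"`.
#' @param age_steps Agent's own age in time steps.
#' @param prefs A [preference_params()] object.
#' @return Ideal partner age in time steps.
#' @examples
#' ideal_partner_age("male", 500)   # 240
#' ideal_partner_age("female", 300) # 325
#' @export
ideal_partner_age <- function(gender, age_steps, prefs = preference_params()) {
  g <- match_gender(gender)
  if (any(age_steps < 0 | age_steps > prefs$a_max)) {
    stop("`age_steps` must lie in [0, a_max]", call. = FALSE)
  }
  n <- max(length(g), length(age_steps))
  g <- rep_len(g, n); a <- rep_len(age_steps, n)
  switch(prefs$ideal_age_rule,
    fixed = rep_len(as.numeric(prefs$male_ideal_age), n),
    offset = a + prefs$female_ideal_offset,
    ifelse(g == 1L, prefs$male_ideal_age, a + prefs$female_ideal_offset)
  )
}

#' @keywords internal
match_gender <- function(gender) {
  if (is.numeric(gender)) {
    g <- as.integer(gender)
  } else {
    g <- match(as.character(gender), c("male", "female"))
  }
  if (anyNA(g) || any(g < 1L | g > 2L)) {
    stop("`gender` must be \"male\"/\"female\" (or 1/2)", call. = FALSE)
  }
  g
}

#' Mate value of a candidate in the eyes of an observer
#'
#' The attractiveness an observer perceives in an opposite-gender candidate,
#' a product of three power-weighted factors: similarity in ultimate
#' education, the candidate's earnings prospects, and the closeness of the
#' candidate's age to the observer's ideal partner age. Each factor's base
#' lies in \[0, 1\], so the value lies in \[0, 1\]; a zero weight
#' neutralises its factor entirely.
#'
#' @param observer,candidate Data frames (or single rows) with columns
#'   `gender`, `education`, `age`; the candidate additionally needs
#'   `earnings`. The observer's ideal partner age is derived from its
#'   current age via [ideal_partner_age()].
#' @param prefs A [preference_params()] object; the observer's
#'   gender-specific weights are used.
#' @return Numeric vector of mate values in \[0, 1\].
#' @examples
#' obs <- data.frame(gender = "male", education = 4L, age = 240)
#' cand <- data.frame(gender = "female", education = 2L, earnings = 3L,
#'                    age = 300)
#' mate_value(obs, cand,
#'            preference_params(w_s = 1, w_y = 1, w_a = 1)) # 0.2775
#' @export
mate_value <- function(observer, candidate, prefs = preference_params()) {
  g_i <- match_gender(observer$gender)
  g_j <- match_gender(candidate$gender)
  n <- max(length(g_i), length(g_j))
  g_i <- rep_len(g_i, n); g_j <- rep_len(g_j, n)
  if (any(g_i == g_j)) {
    stop("observer and candidate must be of opposite gender", call. = FALSE)
  }
  s_i <- rep_len(as.integer(observer$education), n)
  s_j <- rep_len(as.integer(candidate$education), n)
  y_j <- rep_len(as.integer(candidate$earnings), n)
  a_j <- rep_len(as.numeric(candidate$age), n)
  alpha_i <- ideal_partner_age(g_i, rep_len(as.numeric(observer$age), n),
                               prefs)
  cpp_mate_value(s_i, s_j, y_j, alpha_i, a_j,
                 unname(prefs$w_s[g_i]), unname(prefs$w_y[g_i]),
                 unname(prefs$w_a[g_i]),
                 prefs$s_max, prefs$y_max, prefs$a_max)
}

#' Probability of actively searching for a (new) partner
#'
#' Exponential decay `exp(-c * beta)` in the duration `c` of the current
#' relationship. Single agents (duration 0) always search.
#'
#' @param rel_duration Relationship duration in time steps (>= 0).
#' @param beta Commitment factor (>= 0).
#' @return Probability in \[0, 1\].
#' @examples
#' seek_probability(0, 0.015)   # 1
#' seek_probability(250, 0.015) # exp(-3.75)
#' @export
seek_probability <- function(rel_duration, beta) {
  if (any(rel_duration < 0) || any(beta < 0)) {
    stop("`rel_duration` and `beta` must be non-negative", call. = FALSE)
  }
  n <- max(length(rel_duration), length(beta))
  cpp_seek_probability(rep_len(as.numeric(rel_duration), n),
                       rep_len(as.numeric(beta), n))
}

#' Probability of being willing to date a candidate
#'
#' `(1 - exp(-a * v * sigma)) * exp(-c * beta)`: age pressure makes older
#' agents less selective, while commitment to a current partner attenuates
#' the willingness to start something new. For single agents the second
#' factor is 1.
#'
#' @param age Own age in steps.
#' @param v Candidate's mate value in \[0, 1\].
#' @param rel_duration Duration of the current relationship in steps.
#' @param sigma Age pressure factor.
#' @param beta Commitment factor.
#' @return Probability in \[0, 1\].
#' @examples
#' date_probability(200, 0.5, 0, 0.003, 0.015) # 1 - exp(-0.3)
#' @export
date_probability <- function(age, v, rel_duration, sigma, beta) {
  check_prob_args(age, v, rel_duration)
  n <- max(length(age), length(v), length(rel_duration), length(sigma),
           length(beta))
  cpp_date_probability(rep_len(as.numeric(age), n), rep_len(as.numeric(v), n),
                       rep_len(as.numeric(rel_duration), n),
                       rep_len(as.numeric(sigma), n),
                       rep_len(as.numeric(beta), n))
}

#' Probability of proposing to / accepting a proposal from the partner
#'
#' `(1 - exp(-a * v * sigma)) * (1 - exp(-c * beta))`: both the agent's age
#' and the accumulated relationship time push towards marriage. A freshly
#' formed couple (duration 0) can never propose.
#'
#' @inheritParams date_probability
#' @return Probability in \[0, 1\].
#' @examples
#' marry_probability(300, 1, 50, 0.003, 0.015)
#' @export
marry_probability <- function(age, v, rel_duration, sigma, beta) {
  check_prob_args(age, v, rel_duration)
  n <- max(length(age), length(v), length(rel_duration), length(sigma),
           length(beta))
  cpp_marry_probability(rep_len(as.numeric(age), n), rep_len(as.numeric(v), n),
                        rep_len(as.numeric(rel_duration), n),
                        rep_len(as.numeric(sigma), n),
                        rep_len(as.numeric(beta), n))
}

#' @keywords internal
check_prob_args <- function(age, v, rel_duration) {
  if (any(v < 0 | v > 1)) stop("`v` must lie in [0, 1]", call. = FALSE)
  if (any(age < 0) || any(rel_duration < 0)) {
    stop("`age` and `rel_duration` must be non-negative", call. = FALSE)
  }
  invisible(NULL)
}

#' Per-step death probability
#'
#' Convex age-specific mortality `0.1 * d * (a / a_max)^w_d` for ages up to
#' the ceiling `a_max`; the leading 0.1 spreads the maximal annual risk over
#' the ten steps of a simulation year. Agents reaching `a_max` are removed
#' from the population regardless of this draw.
#'
#' @param age Age in steps, in `[0, a_max]`.
#' @param mort A [mortality_params()] object.
#' @param gender `"male"` or `"female"` (mortality may be gender-specific).
#' @return Per-time-step death probability.
#' @examples
#' death_probability_step(800) # 0.01 per step, i.e. 10% per year
#' @export
death_probability_step <- function(age, mort = mortality_params(),
                                   gender = "male") {
  if (any(age < 0 | age > mort$a_max)) {
    stop("`age` must lie in [0, a_max]", call. = FALSE)
  }
  g <- match_gender(gender)
  n <- max(length(age), length(g))
  g <- rep_len(g, n)
  cpp_death_probability_step(rep_len(as.numeric(age), n),
                             unname(mort$d[g]), unname(mort$w_d[g]),
                             mort$a_max)
}

#' School enrolment status implied by age and ultimate education
#'
#' Deterministic mapping from age (steps) and ultimate educational
#' attainment to enrolment: primary school starts at age 6 (60 steps),
#' secondary at 10 (100), tertiary at 19 (190). Agents leave the system at
#' 6 (no education), 16 (primary, after some compulsory secondary years),
#' 19 (secondary) or 24 (tertiary).
#'
#' @param age Age in steps (>= 0).
#' @param education Ultimate education level 1 (none) to 4 (tertiary).
#' @return Integer enrolment code: 1 not yet enrolled, 2 in primary, 3 in
#'   secondary, 4 in tertiary, 5 finished.
#' @examples
#' enrolment_status(150, 2) # 3: still in (compulsory) secondary school
#' enrolment_status(250, 4) # 5: finished
#' @export
enrolment_status <- function(age, education) {
  if (any(age < 0)) stop("`age` must be non-negative", call. = FALSE)
  if (any(!education %in% 1:4)) {
    stop("`education` must be an integer in 1..4", call. = FALSE)
  }
  n <- max(length(age), length(education))
  cpp_enrolment_status(rep_len(as.numeric(age), n),
                       rep_len(as.integer(education), n))
}
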