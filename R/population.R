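#' Spawn newborn agents from cohort schedules
#'
#' Creates agents at age 0 in the single state, with ultimate education
#' sampled from the cohort schedule of their birth year and gender, and
#' earnings prospects sampled from the gender-by-education earnings
#' distribution. Vectorised over `birth_year` and `gender`.
#'
#' @param birth_year Integer vector of birth years.
#' @param gender Character vector, `"male"`/`"female"` (recycled).
#' @param schedules A [cohort_schedules()] object.
#' @param prefs A [preference_params()] object (for the ideal-age rule).
#' @return A data frame of agents with columns `id`, `gender`, `age`,
#'   `education`, `earnings`, `enrolment`, `rel_status`, `partner_id`,
#'   `rel_duration`, `ideal_partner_age`, `birth_year`, `proposed`.
#' @export
spawn_agent <- function(birth_year, gender, schedules,
                        prefs = preference_params()) {
  n <- max(length(birth_year), length(gender))
  birth_year <- rep_len(as.integer(birth_year), n)
  gender <- rep_len(as.character(gender), n)
  match_gender(gender)

  education <- integer(n)
  for (g in c("male", "female")) {
    sel <- which(gender == g)
    if (!length(sel)) next
    probs <- education_distribution(schedules, birth_year[sel], g)
    if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
    education[sel] <- vapply(seq_along(sel), function(k) {
      sample.int(4L, 1L, prob = probs[k, ])
    }, integer(1))
  }
  earnings <- integer(n)
  for (g in c("male", "female")) {
    for (s in 1:4) {
      sel <- which(gender == g & education == s)
      if (!length(sel)) next
      p <- earnings_distribution(schedules, g, s)
      earnings[sel] <- sample.int(5L, length(sel), replace = TRUE, prob = p)
    }
  }
  data.frame(
    id = seq_len(n),
    gender = gender,
    age = 0,
    education = education,
    earnings = earnings,
    enrolment = enrolment_status(0, education),
    rel_status = "single",
    partner_id = NA_integer_,
    rel_duration = 0,
    ideal_partner_age = ideal_partner_age(gender, 0, prefs),
    birth_year = birth_year,
    proposed = FALSE,
    stringsAsFactors = FALSE
  )
}

#' Build an initial agent population
#'
#' Constructs the burn-in population of a simulation run: `n_per_gender`
#' agents of each gender with ages drawn uniformly on `[0, a_max - 1]`
#' steps, birth years back-computed from age, and education/earnings
#' sampled from the (possibly fallback) schedule of each agent's birth
#' cohort. All agents start single.
#'
#' @param n_per_gender Number of agents of each gender.
#' @param start_year Calendar year at which the simulation starts.
#' @param schedules A [cohort_schedules()] object.
#' @param prefs A [preference_params()] object.
#' @param a_max Age ceiling in steps.
#' @param steps_per_year Time steps per year.
#' @return A data frame of agents (see [spawn_agent()]), with consistent
#'   `age`, `enrolment`, `ideal_partner_age` and `birth_year`.
#' @export
build_initial_population <- function(n_per_gender, start_year, schedules,
                                     prefs = preference_params(),
                                     a_max = 800, steps_per_year = 10) {
  stopifnot(n_per_gender > 0)
  n <- 2L * n_per_gender
  gender <- rep(c("male", "female"), each = n_per_gender)
  age <- sample.int(a_max, n, replace = TRUE) - 1L
  birth_year <- start_year - age %/% steps_per_year
  pop <- spawn_agent(birth_year, gender, schedules, prefs)
  pop$age <- as.numeric(age)
  pop$enrolment <- enrolment_status(pop$age, pop$education)
  pop$ideal_partner_age <- ideal_partner_age(gender, pop$age, prefs)
  pop
}
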