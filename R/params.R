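#' @keywords internal
check_gendered <- function(x, name, lo = 0, hi = Inf) {
  if (length(x) == 1L) x <- c(male = unname(x), female = unname(x))
  if (is.null(names(x))) names(x) <- c("male", "female")
  x <- x[c("male", "female")]
  if (anyNA(x) || any(x < lo) || any(x > hi)) {
    stop(sprintf("`%s` must lie in [%g, %g] for both genders", name, lo, hi),
         call. = FALSE)
  }
  x
}

#' Partner preference parameters
#'
#' Gender-specific weights of the mate-value function together with the
#' ideal-age rule and the attribute scales. The defaults are the calibrated
#' values of the full model: men weight educational similarity more than
#' women, women weight earnings and age more than men, men hold a fixed
#' ideal partner age of 24 years (240 steps) and women prefer partners about
#' 2.5 years (25 steps) older than themselves.
#'
#' @param w_s Education-similarity weight, scalar or named
#'   `c(male=, female=)` vector; admissible range 0--2.
#' @param w_y Earnings weight per gender; range 0--2.
#' @param w_a Age weight per gender; range 0--20.
#' @param male_ideal_age Fixed ideal partner age of male agents, in time
#'   steps (10 steps = 1 year).
#' @param female_ideal_offset Steps added to a female agent's own age to
#'   obtain her ideal partner age.
#' @param s_max,y_max,a_max Maxima of the education scale, the earnings
#'   scale and the age range (steps).
#' @param ideal_age_rule `"gendered"` (default: men fixed, women offset),
#'   or `"fixed"`/`"offset"` to apply one rule to both genders, e.g. for
#'   gender-symmetric parameterizations.
#' @return An object of class `preference_params`.
#' @seealso [mate_value()], [ideal_partner_age()], [experiment_preset()]
#' @export
preference_params <- function(w_s = c(male = 0.934, female = 0.385),
                              w_y = c(male = 1.025, female = 1.201),
                              w_a = c(male = 5.009, female = 10.833),
                              male_ideal_age = 240,
                              female_ideal_offset = 25,
                              s_max = 4, y_max = 5, a_max = 800,
                              ideal_age_rule = c("gendered", "fixed",
                                                 "offset")) {
  stopifnot(s_max > 0, y_max > 0, a_max > 0)
  out <- list(
    w_s = check_gendered(w_s, "w_s", 0, 2),
    w_y = check_gendered(w_y, "w_y", 0, 2),
    w_a = check_gendered(w_a, "w_a", 0, 20),
    male_ideal_age = male_ideal_age,
    female_ideal_offset = female_ideal_offset,
    s_max = s_max, y_max = y_max, a_max = a_max,
    ideal_age_rule = match.arg(ideal_age_rule)
  )
  structure(out, class = "preference_params")
}

#' Relationship dynamics parameters
#'
#' Commitment and age-pressure rates, and the degree to which the school
#' system structures meeting opportunities. `beta` suppresses further search
#' and builds marriage willingness as a relationship lasts; `sigma` raises
#' the willingness to date/marry with the agent's own age (women face
#' stronger age pressure by default); `delta` is the probability that a
#' meeting partner is drawn from agents with the same school enrolment
#' status.
#'
#' @param beta Commitment factor per gender (>= 0; 0 removes the
#'   commitment mechanism).
#' @param sigma Age pressure factor per gender (>= 0; 0 makes dating
#'   and marriage impossible).
#' @param delta Meeting structuring parameter in \[0, 1\].
#' @return An object of class `dynamics_params`.
#' @export
dynamics_params <- function(beta = c(male = 0.015, female = 0.015),
                            sigma = c(male = 0.0015, female = 0.0030),
                            delta = 0.9) {
  stopifnot(length(delta) == 1L, delta >= 0, delta <= 1)
  out <- list(
    beta = check_gendered(beta, "beta", 0, Inf),
    sigma = check_gendered(sigma, "sigma", 0, Inf),
    delta = delta
  )
  structure(out, class = "dynamics_params")
}

#' Mortality parameters
#'
#' Scale and shape of the convex age-specific per-step death probability,
#' plus the age ceiling and the marriageable age. With the defaults the
#' chance of dying within a simulation year reaches 10% at the age ceiling
#' of 80 years (800 steps).
#'
#' @param d Maximal step-level death scale per gender (0 < d <= 1).
#' @param w_d Shape of the age-specific death curve per gender (> 0).
#' @param a_max Age ceiling in steps; agents reaching it are removed.
#' @param a_marr Age (steps) at which agents become marriageable.
#' @return An object of class `mortality_params`.
#' @export
mortality_params <- function(d = c(male = 0.1, female = 0.1),
                             w_d = c(male = 6, female = 6),
                             a_max = 800, a_marr = 160) {
  stopifnot(a_marr < a_max)
  out <- list(
    d = check_gendered(d, "d", .Machine$double.xmin, 1),
    w_d = check_gendered(w_d, "w_d", .Machine$double.xmin, Inf),
    a_max = a_max, a_marr = a_marr
  )
  structure(out, class = "mortality_params")
}

#' Simulation run configuration
#'
#' Calendar range, population size, census timing and replication settings
#' of a simulation experiment. The defaults reproduce the study design:
#' cohorts born 1921--2012, 250 agents per gender, censuses pooled at the
#' end of the simulation years 2010 and 2012, 50 replicates.
#'
#' @param start_year,end_year Calendar range of the run.
#' @param steps_per_year Time steps per simulation year (10).
#' @param census_years Years at whose end a census of married couples is
#'   taken; must lie in `[start_year, end_year]`.
#' @param n_per_gender Number of male and of female agents.
#' @param n_replicates Number of independent replicate runs.
#' @param base_seed Seed of replicate 1; replicate r uses `base_seed + r - 1`.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(start_year = 1921, end_year = 2012,
                              steps_per_year = 10,
                              census_years = c(2010, 2012),
                              n_per_gender = 250,
                              n_replicates = 50, base_seed = 1) {
  stopifnot(steps_per_year > 0, end_year >= start_year, n_per_gender > 0,
            n_replicates >= 1)
  if (any(census_years < start_year | census_years > end_year)) {
    stop("`census_years` must lie within [start_year, end_year]",
         call. = FALSE)
  }
  structure(list(start_year = start_year, end_year = end_year,
                 steps_per_year = steps_per_year,
                 census_years = sort(unique(census_years)),
                 n_per_gender = n_per_gender,
                 n_replicates = n_replicates, base_seed = base_seed),
            class = "simulation_config")
}

#' Experiment presets: the calibrated full model and its knockouts
#'
#' Returns the parameter bundle for one of the five model versions compared
#' in the knockout experiments: the calibrated full model, and variants in
#' which one mechanism is turned off (no education preference, unstructured
#' meeting with `delta = 0.5`, no age preference, no earnings preference).
#'
#' @param name One of `"full"`, `"no_education_pref"`,
#'   `"unstructured_meeting"`, `"no_age_pref"`, `"no_earnings_pref"`.
#' @return A list with elements `name`, `prefs` ([preference_params()]),
#'   `dyn` ([dynamics_params()]) and `mort` ([mortality_params()]).
#' @export
experiment_preset <- function(name = c("full", "no_education_pref",
                                       "unstructured_meeting",
                                       "no_age_pref", "no_earnings_pref")) {
  name <- match.arg(name)
  prefs <- preference_params()
  dyn <- dynamics_params()
  switch(name,
    full = NULL,
    no_education_pref = { prefs$w_s[] <- 0 },
    unstructured_meeting = { dyn$delta <- 0.5 },
    no_age_pref = { prefs$w_a[] <- 0 },
    no_earnings_pref = { prefs$w_y[] <- 0 }
  )
  list(name = name, prefs = prefs, dyn = dyn, mort = mortality_params())
}

#' @export
print.preference_params <- function(x, ...) {
  cat("Partner preference parameters\n")
  cat(sprintf("  w_s: male %.3f, female %.3f\n", x$w_s[1], x$w_s[2]))
  cat(sprintf("  w_y: male %.3f, female %.3f\n", x$w_y[1], x$w_y[2]))
  cat(sprintf("  w_a: male %.3f, female %.3f\n", x$w_a[1], x$w_a[2]))
  cat(sprintf("  ideal age: male fixed %d steps, female own age + %d steps\n",
              x$male_ideal_age, x$female_ideal_offset))
  invisible(x)
}
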