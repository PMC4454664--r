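# Small in-code fixtures shared across the test files.

# A flat schedule: identical education distribution for every cohort and
# both genders, uniform-ish earnings within education.
flat_schedules <- function(edu = c(0.1, 0.3, 0.4, 0.2),
                           years = 1921:2012) {
  edu_rows <- do.call(rbind, lapply(c("male", "female"), function(g) {
    data.frame(birth_year = years, gender = g, p_none = edu[1],
               p_primary = edu[2], p_secondary = edu[3], p_tertiary = edu[4])
  }))
  earn_rows <- do.call(rbind, lapply(c("male", "female"), function(g) {
    out <- data.frame(gender = g, education = 1:4)
    out[paste0("p_y", 1:5)] <- 0.2
    out
  }))
  cohort_schedules(edu_rows, earn_rows)
}

# Fully gender-symmetric synthetic schedules (no tertiary gender gap, no
# male earnings advantage).
symmetric_schedules <- function(years = 1921:2012) {
  generate_synthetic_schedules(
    synthetic_scenario(gap_amplitude = 0, earnings_advantage = 1), years)
}

# A short, small run configuration for fast engine tests.
quick_config <- function(n_replicates = 2, ...) {
  simulation_config(start_year = 1921, end_year = 1960,
                    census_years = c(1958, 1960), n_per_gender = 60,
                    n_replicates = n_replicates, ...)
}
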