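#' Cohort schedules: education and earnings distributions
#'
#' Bundles the two input tables of the model: per birth year and gender a
#' probability distribution over the four education levels, and per gender
#' and education level a distribution over the five ordinal
#' earnings-prospect categories. Birth years before the first scheduled
#' year resolve to the first year's distribution (and years after the last
#' to the last year's).
#'
#' @param education Data frame with columns `birth_year`, `gender`
#'   (`"male"`/`"female"`), `p_none`, `p_primary`, `p_secondary`,
#'   `p_tertiary`; each row a probability vector summing to 1.
#' @param earnings Data frame with columns `gender`, `education` (1--4) and
#'   `p_y1` .. `p_y5`; each row a probability vector summing to 1.
#' @return An object of class `cohort_schedules`.
#' @seealso [generate_synthetic_schedules()], [read_schedules_csv()]
#' @export
cohort_schedules <- function(education, earnings) {
  edu_cols <- c("p_none", "p_primary", "p_secondary", "p_tertiary")
  earn_cols <- paste0("p_y", 1:5)
  need <- c("birth_year", "gender", edu_cols)
  if (!all(need %in% names(education))) {
    stop("education table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  need <- c("gender", "education", earn_cols)
  if (!all(need %in% names(earnings))) {
    stop("earnings table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  check_rows_sum1(as.matrix(education[edu_cols]), "education")
  check_rows_sum1(as.matrix(earnings[earn_cols]), "earnings")
  match_gender(education$gender)
  match_gender(earnings$gender)
  if (!all(earnings$education %in% 1:4)) {
    stop("earnings `education` must be 1..4", call. = FALSE)
  }
  for (g in c("male", "female")) {
    yrs <- sort(education$birth_year[education$gender == g])
    if (!identical(yrs, unique(yrs))) {
      stop("duplicate birth_year rows for gender ", g, call. = FALSE)
    }
    if (!setequal(earnings$education[earnings$gender == g], 1:4)) {
      stop("earnings table needs one row per education level 1..4 for ",
           g, call. = FALSE)
    }
  }
  yr <- range(education$birth_year)
  structure(list(education = education[order(education$gender,
                                             education$birth_year), ],
                 earnings = earnings[order(earnings$gender,
                                           earnings$education), ],
                 year_range = yr),
            class = "cohort_schedules")
}

#' @keywords internal
check_rows_sum1 <- function(m, what, tol = 1e-6) {
  if (any(m < 0)) {
    stop(sprintf("%s table row %d has a negative probability", what,
                 which(apply(m < 0, 1, any))[1]), call. = FALSE)
  }
  s <- rowSums(m)
  bad <- which(abs(s - 1) > tol)
  if (length(bad)) {
    stop(sprintf("%s table row %d does not sum to 1 (sum = %.6f)", what,
                 bad[1], s[bad[1]]), call. = FALSE)
  }
  invisible(NULL)
}

#' Resolve the education distribution for a birth year
#'
#' @param schedules A [cohort_schedules()] object.
#' @param birth_year Calendar birth year (any integer; out-of-range years
#'   fall back to the nearest scheduled year).
#' @param gender `"male"` or `"female"`.
#' @return Probability 4-vector over education levels.
#' @export
education_distribution <- function(schedules, birth_year, gender) {
  ed <- schedules$education
  yr <- pmin(pmax(birth_year, schedules$year_range[1]),
             schedules$year_range[2])
  rows <- ed[ed$gender == gender, ]
  idx <- match(yr, rows$birth_year)
  if (anyNA(idx)) {
    stop("no schedule row for birth year(s) ",
         paste(unique(yr[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(rows[idx, c("p_none", "p_primary", "p_secondary",
                             "p_tertiary")])
  dimnames(m) <- list(NULL, c("none", "primary", "secondary", "tertiary"))
  if (length(birth_year) == 1L) m[1, ] else m
}

#' Resolve the earnings distribution for a gender and education level
#'
#' @inheritParams education_distribution
#' @param education Education level 1--4.
#' @return Probability 5-vector over earnings categories.
#' @export
earnings_distribution <- function(schedules, gender, education) {
  ea <- schedules$earnings
  row <- ea[ea$gender == gender & ea$education == education, ]
  stats::setNames(as.numeric(row[1, paste0("p_y", 1:5)]), paste0("y", 1:5))
}

#' Synthetic cohort scenario
#'
#' Parameters of the built-in schedule generator, which emulates the two
#' stylised facts the model's inputs carry: the educational expansion of
#' the 20th century with a reversing gender gap in tertiary education
#' (female tertiary attainment overtakes male attainment at
#' `crossover_year`), and a male earnings advantage within every education
#' level. Trends are logistic in cohort birth year; the gender gap in
#' tertiary shares follows a smooth sign change centred on the crossover
#' cohort.
#'
#' @param tertiary_start,tertiary_end Male tertiary shares of the earliest
#'   and latest cohorts.
#' @param tertiary_midpoint,tertiary_steepness Midpoint year and steepness
#'   of the logistic male tertiary trend.
#' @param gap_amplitude Asymptotic female-minus-male tertiary share gap
#'   (negative before, positive after the crossover cohort).
#' @param gap_width Width (years) of the gap's sign change.
#' @param crossover_year Cohort birth year at which the female tertiary
#'   share overtakes the male share.
#' @param none_start,none_end,primary_start,primary_end Start and end
#'   shares of the 'no education' and 'primary' trends (before
#'   normalisation against the tertiary share).
#' @param low_midpoint,low_steepness Midpoint and steepness of the
#'   declining low-education trends.
#' @param earnings_advantage Target ratio of mean male to mean female
#'   earnings category within an education level (>= 1; 1 means identical
#'   distributions).
#' @return An object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(tertiary_start = 0.05, tertiary_end = 0.30,
                               tertiary_midpoint = 1955,
                               tertiary_steepness = 0.06,
                               gap_amplitude = 0.14, gap_width = 18,
                               crossover_year = 1965,
                               none_start = 0.12, none_end = 0.005,
                               primary_start = 0.50, primary_end = 0.06,
                               low_midpoint = 1950, low_steepness = 0.07,
                               earnings_advantage = 1.25) {
  shares <- c(tertiary_start, tertiary_end, none_start, none_end,
              primary_start, primary_end)
  if (any(shares < 0 | shares > 1)) {
    stop("scenario shares must lie in [0, 1]", call. = FALSE)
  }
  if (earnings_advantage < 1) {
    stop("`earnings_advantage` must be >= 1", call. = FALSE)
  }
  if (gap_amplitude < 0 || gap_width <= 0) {
    stop("`gap_amplitude` must be >= 0 and `gap_width` > 0", call. = FALSE)
  }
  structure(as.list(environment())[c(
    "tertiary_start", "tertiary_end", "tertiary_midpoint",
    "tertiary_steepness", "gap_amplitude", "gap_width", "crossover_year",
    "none_start", "none_end", "primary_start", "primary_end",
    "low_midpoint", "low_steepness", "earnings_advantage")],
    class = "synthetic_scenario")
}

#' @keywords internal
logistic_trend <- function(year, start, end, midpoint, steepness) {
  start + (end - start) * stats::plogis(steepness * (year - midpoint))
}

#' Generate synthetic cohort schedules
#'
#' Builds a [cohort_schedules()] object from a [synthetic_scenario()]: per
#' cohort and gender a smooth education distribution in which the female
#' tertiary share overtakes the male share at the scenario's crossover
#' cohort, and per gender and education level a binomial-shaped earnings
#' distribution in which the male mean category exceeds the female mean by
#' the scenario's advantage ratio (capped at the top category).
#'
#' @param scenario A [synthetic_scenario()] object.
#' @param years Integer vector of cohort birth years (default 1921--2012).
#' @return A [cohort_schedules()] object.
#' @export
generate_synthetic_schedules <- function(scenario = synthetic_scenario(),
                                         years = 1921:2012) {
  sc <- scenario
  tert_m <- logistic_trend(years, sc$tertiary_start, sc$tertiary_end,
                           sc$tertiary_midpoint, sc$tertiary_steepness)
  gap <- sc$gap_amplitude * tanh((years - sc$crossover_year) / sc$gap_width)
  tert_f <- pmin(pmax(tert_m + gap, 0.002), 0.95)

  none <- logistic_trend(years, sc$none_start, sc$none_end,
                         sc$low_midpoint, sc$low_steepness)
  prim <- logistic_trend(years, sc$primary_start, sc$primary_end,
                         sc$low_midpoint, sc$low_steepness)
  sec <- pmax(1 - none - prim - (sc$tertiary_start + sc$tertiary_end) / 2, 0.05)

  edu_rows <- function(gender, tert) {
    rest <- cbind(none, prim, sec)
    rest <- rest / rowSums(rest) * (1 - tert)
    data.frame(birth_year = years, gender = gender,
               p_none = rest[, 1], p_primary = rest[, 2],
               p_secondary = rest[, 3], p_tertiary = tert)
  }
  education <- rbind(edu_rows("male", tert_m), edu_rows("female", tert_f))

  # binomial(4, p) + 1 earnings categories; male mean category is the
  # female mean scaled by the advantage ratio, capped at 5
  female_p <- stats::plogis(-1.6 + 0.55 * (1:4))
  earn_rows <- function(gender) {
    p <- if (gender == "male") {
      mean_f <- 1 + 4 * female_p
      (pmin(sc$earnings_advantage * mean_f, 5) - 1) / 4
    } else {
      female_p
    }
    probs <- t(vapply(p, function(pp) stats::dbinom(0:4, 4, pp),
                      numeric(5)))
    out <- data.frame(gender = gender, education = 1:4)
    out[paste0("p_y", 1:5)] <- probs
    out
  }
  earnings <- rbind(earn_rows("male"), earn_rows("female"))
  cohort_schedules(education, earnings)
}

#' Merged 3-category education margins of a schedule cohort
#'
#' Collapses the 4-level education distribution of one birth cohort to the
#' merged 3-category scale used for outcome measures (low = none +
#' primary, secondary, tertiary).
#'
#' @inheritParams education_distribution
#' @return A list with probability 3-vectors `p_f` (women) and `p_m` (men).
#' @seealso [f_index()], [expected_random_shares()]
#' @export
schedule_margins <- function(schedules, birth_year) {
  collapse <- function(p) {
    stats::setNames(c(p[1] + p[2], p[3], p[4]), c("low", "secondary",
                                                  "tertiary"))
  }
  list(p_f = collapse(education_distribution(schedules, birth_year, "female")),
       p_m = collapse(education_distribution(schedules, birth_year, "male")))
}

#' Read / write cohort schedules as CSV
#'
#' Plain UTF-8 CSV with a header row and '.' decimal separator; the
#' education file has columns `birth_year, gender, p_none, p_primary,
#' p_secondary, p_tertiary` and the earnings file `gender, education,
#' p_y1..p_y5`. Validation failures name the offending row.
#'
#' @param education_path,earnings_path File paths.
#' @return `read_schedules_csv()` returns a [cohort_schedules()] object;
#'   `write_schedules_csv()` returns the paths invisibly.
#' @export
read_schedules_csv <- function(education_path, earnings_path) {
  education <- utils::read.csv(education_path, stringsAsFactors = FALSE)
  earnings <- utils::read.csv(earnings_path, stringsAsFactors = FALSE)
  cohort_schedules(education, earnings)
}

#' @rdname read_schedules_csv
#' @param schedules A [cohort_schedules()] object.
#' @export
write_schedules_csv <- function(schedules, education_path, earnings_path) {
  utils::write.csv(schedules$education, education_path, row.names = FALSE)
  utils::write.csv(schedules$earnings, earnings_path, row.names = FALSE)
  invisible(c(education_path, earnings_path))
}

#' @export
print.cohort_schedules <- function(x, ...) {
  cat(sprintf("Cohort schedules: birth years %d-%d\n", x$year_range[1],
              x$year_range[2]))
  last <- x$year_range[2]
  m <- schedule_margins(x, last)
  cat(sprintf("  last cohort tertiary share: male %.3f, female %.3f\n",
              m$p_m["tertiary"], m$p_f["tertiary"]))
  invisible(x)
}
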