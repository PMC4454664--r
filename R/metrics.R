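#' Classify a couple as hypergamic, homogamic or hypogamic
#'
#' Couples are classified on the merged 3-category education scale (levels
#' 1 and 2 are combined into 'low' because the 'no education' category is
#' nearly empty in the source data): hypergamic if the woman's merged level
#' is below the man's, homogamic if equal, hypogamic if above.
#'
#' @param male_education,female_education Education levels 1--4.
#' @return Factor with levels `hypergamic`, `homogamic`, `hypogamic`.
#' @examples
#' classify_couple(2, 1) # homogamic: both in the merged low category
#' classify_couple(3, 4) # hypogamic: the woman is more educated
#' @export
classify_couple <- function(male_education, female_education) {
  if (any(!c(male_education, female_education) %in% 1:4)) {
    stop("education levels must be integers in 1..4", call. = FALSE)
  }
  m <- merge_education(male_education)
  f <- merge_education(female_education)
  type <- ifelse(f < m, "hypergamic", ifelse(f > m, "hypogamic", "homogamic"))
  factor(type, levels = c("hypergamic", "homogamic", "hypogamic"))
}

#' Collapse 4-level education to the merged 3-category outcome scale
#'
#' @param education Education levels 1--4.
#' @return Integer 1 (low = none/primary), 2 (secondary) or 3 (tertiary).
#' @export
merge_education <- function(education) {
  pmax(as.integer(education) - 1L, 1L)
}

#' Couple-type shares by 10-year birth cohort
#'
#' Tabulates hypergamy/homogamy/hypogamy shares from pooled census records
#' in half-open decade bins of birth year. By default shares are
#' respondent-based (mirroring survey sampling of married individuals):
#' each married agent born inside a bin contributes one observation, so a
#' couple whose spouses were born in different decades contributes to both
#' bins. `unit = "couple"` instead bins each couple once by the male
#' spouse's birth year.
#'
#' @param records Census records (see [run_marriage_market()]); a
#'   `replicate` column, if present, is ignored (records are pooled).
#' @param breaks Increasing bin edges of birth year; bins are `(lo, hi]`.
#' @param unit `"respondent"` (default) or `"couple"`.
#' @return A data frame with one row per bin: `cohort_bin`, `n`
#'   (observations) and the share columns `hypergamic`, `homogamic`,
#'   `hypogamic` (each `NA` when `n = 0`, otherwise summing to 1).
#' @export
couple_shares <- function(records, breaks = seq(1940, 1980, by = 10),
                          unit = c("respondent", "couple")) {
  unit <- match.arg(unit)
  type <- classify_couple(records$male_education, records$female_education)
  if (unit == "respondent") {
    by <- c(records$male_birth_year, records$female_birth_year)
    type <- rep(type, 2)
  } else {
    by <- records$male_birth_year
  }
  bin <- cut(by, breaks = breaks, right = TRUE, dig.lab = 4)
  keep <- !is.na(bin)
  tab <- table(bin[keep], type[keep])
  n <- rowSums(tab)
  shares <- tab / ifelse(n > 0, n, NA_real_)
  out <- data.frame(cohort_bin = rownames(tab), n = as.integer(n))
  out$hypergamic <- as.numeric(shares[, "hypergamic"])
  out$homogamic <- as.numeric(shares[, "homogamic"])
  out$hypogamic <- as.numeric(shares[, "hypogamic"])
  rownames(out) <- NULL
  out
}

#' Pooled couple-type shares
#'
#' Shares of the three couple types among all observations falling in the
#' given birth-cohort range, pooled over bins (one number per type), using
#' the same counting rules as [couple_shares()].
#'
#' @inheritParams couple_shares
#' @return Named numeric vector `c(hypergamic=, homogamic=, hypogamic=)`.
#' @export
pooled_type_shares <- function(records, breaks = seq(1940, 1980, by = 10),
                               unit = c("respondent", "couple")) {
  unit <- match.arg(unit)
  type <- classify_couple(records$male_education, records$female_education)
  if (unit == "respondent") {
    by <- c(records$male_birth_year, records$female_birth_year)
    type <- rep(type, 2)
  } else {
    by <- records$male_birth_year
  }
  keep <- by > breaks[1] & by <= breaks[length(breaks)]
  prop.table(table(type[keep]))[c("hypergamic", "homogamic", "hypogamic")]
}

#' Index of female educational advantage (F)
#'
#' For merged 3-category education distributions of women (`p_f`) and men
#' (`p_m`), the probability that a randomly drawn woman is more educated
#' than a randomly drawn man, conditional on the two differing:
#' `F = (pf3(pm1+pm2) + pf2 pm1) / (1 - (pf1 pm1 + pf2 pm2 + pf3 pm3))`.
#' It equals 0 when every woman is less educated than any man, 0.5 when
#' the distributions are identical, and 1 when every woman is more
#' educated than any man.
#'
#' @param p_f,p_m Probability 3-vectors (low, secondary, tertiary).
#' @return The index, a number in \[0, 1\].
#' @examples
#' f_index(rep(1 / 3, 3), rep(1 / 3, 3)) # 0.5
#' f_index(c(0, 0, 1), c(1, 0, 0))       # 1
#' @export
f_index <- function(p_f, p_m) {
  check_simplex3(p_f, "p_f")
  check_simplex3(p_m, "p_m")
  num <- p_f[3] * (p_m[1] + p_m[2]) + p_f[2] * p_m[1]
  den <- 1 - (p_f[1] * p_m[1] + p_f[2] * p_m[2] + p_f[3] * p_m[3])
  if (den <= 0) {
    stop("F index undefined: both genders concentrated on one level",
         call. = FALSE)
  }
  unname(num / den)
}

#' @keywords internal
check_simplex3 <- function(p, name, tol = 1e-9) {
  if (length(p) != 3 || any(p < 0) || abs(sum(p) - 1) > tol) {
    stop(sprintf("`%s` must be a probability 3-vector summing to 1", name),
         call. = FALSE)
  }
  invisible(NULL)
}

#' Expected couple-type shares under random within-cohort mating
#'
#' The shares of hypergamic, homogamic and hypogamic couples expected if
#' every man married a woman drawn at random from the same cohort:
#' hypergamy `pm2 pf1 + pm3 pf1 + pm3 pf2`, homogamy
#' `pm1 pf1 + pm2 pf2 + pm3 pf3`, hypogamy `pf2 pm1 + pf3 pm1 + pf3 pm2`,
#' on the merged 3-category scale.
#'
#' @inheritParams f_index
#' @return Named numeric vector `c(hypergamic=, homogamic=, hypogamic=)`
#'   summing to 1.
#' @export
expected_random_shares <- function(p_f, p_m) {
  check_simplex3(p_f, "p_f")
  check_simplex3(p_m, "p_m")
  hyper <- p_m[2] * p_f[1] + p_m[3] * p_f[1] + p_m[3] * p_f[2]
  homo <- p_m[1] * p_f[1] + p_m[2] * p_f[2] + p_m[3] * p_f[3]
  hypo <- p_f[2] * p_m[1] + p_f[3] * p_m[1] + p_f[3] * p_m[2]
  stats::setNames(c(hyper, homo, hypo),
                  c("hypergamic", "homogamic", "hypogamic"))
}

#' Realized education margins of the married population
#'
#' Merged 3-category education distributions of married men and married
#' women in a set of census records, the margins against which simulated
#' couple-type shares can be compared with their random-mating expectation.
#'
#' @inheritParams couple_shares
#' @return A list with probability 3-vectors `p_f` and `p_m`.
#' @export
education_margins <- function(records) {
  tab3 <- function(x) {
    as.numeric(table(factor(merge_education(x), levels = 1:3))) / length(x)
  }
  list(p_f = tab3(records$female_education),
       p_m = tab3(records$male_education))
}

#' Mean within-couple age difference
#'
#' @inheritParams couple_shares
#' @param steps_per_year Steps per simulation year.
#' @return Mean of (male age - female age) in years.
#' @export
mean_age_difference <- function(records, steps_per_year = 10) {
  if (!nrow(records)) stop("no records", call. = FALSE)
  mean((records$male_age - records$female_age) / steps_per_year)
}

#' Aggregate couple-type shares across replicates
#'
#' Computes per-replicate shares by cohort bin and summarises them with the
#' unweighted mean and sample standard deviation across replicates. Bins
#' empty in some replicates are aggregated over the replicates in which
#' they are populated, with that count reported.
#'
#' @param records Census records with a `replicate` column, or a list of
#'   per-replicate [couple_shares()] tables.
#' @inheritParams couple_shares
#' @return A data frame with columns `cohort_bin`, `type`, `mean_share`,
#'   `sd_share` (`NA` with a single replicate) and `n_replicates`.
#' @export
aggregate_replicates <- function(records,
                                 breaks = seq(1940, 1980, by = 10),
                                 unit = c("respondent", "couple")) {
  unit <- match.arg(unit)
  if (is.data.frame(records)) {
    shares <- lapply(split(records, records$replicate), couple_shares,
                     breaks = breaks, unit = unit)
  } else {
    shares <- records
  }
  long <- dplyr::bind_rows(shares, .id = "replicate")
  long <- tidyr::pivot_longer(long, cols = c("hypergamic", "homogamic",
                                             "hypogamic"),
                              names_to = "type", values_to = "share")
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$cohort_bin, .data$type),
    mean_share = mean(.data$share[.data$n > 0]),
    sd_share = stats::sd(.data$share[.data$n > 0]),
    n_replicates = sum(.data$n > 0),
    .groups = "drop"
  )
  out$type <- factor(out$type, levels = c("hypergamic", "homogamic",
                                          "hypogamic"))
  as.data.frame(out[order(out$cohort_bin, out$type), ])
}
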