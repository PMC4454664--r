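test_that("couple classification merges the two lowest education levels", {
  expect_equal(as.character(classify_couple(3, 3)), "homogamic")
  expect_equal(as.character(classify_couple(2, 1)), "homogamic")
  expect_equal(as.character(classify_couple(3, 4)), "hypogamic")
  expect_equal(as.character(classify_couple(4, 2)), "hypergamic")
  expect_error(classify_couple(5, 1), "1..4")
})

test_that("classification is antisymmetric under spouse swap", {
  grid <- expand.grid(m = 1:4, f = 1:4)
  a <- classify_couple(grid$m, grid$f)
  b <- classify_couple(grid$f, grid$m)
  swap <- c(hypergamic = "hypogamic", homogamic = "homogamic",
            hypogamic = "hypergamic")
  expect_equal(as.character(b), unname(swap[as.character(a)]))
})

test_that("couple shares match a brute-force enumeration", {
  set.seed(11)
  n <- 200
  rec <- data.frame(
    census_year = 2010,
    male_education = sample(1:4, n, TRUE),
    female_education = sample(1:4, n, TRUE),
    male_birth_year = sample(1935:1985, n, TRUE),
    female_birth_year = sample(1935:1985, n, TRUE),
    male_age = 300, female_age = 300, rel_duration = 100
  )
  got <- couple_shares(rec)
  breaks <- seq(1940, 1980, by = 10)
  # independent enumeration over respondents
  for (b in seq_len(length(breaks) - 1)) {
    lo <- breaks[b]; hi <- breaks[b + 1]
    cnt <- c(hypergamic = 0, homogamic = 0, hypogamic = 0)
    for (i in seq_len(n)) {
      type <- as.character(classify_couple(rec$male_education[i],
                                           rec$female_education[i]))
      if (rec$male_birth_year[i] > lo && rec$male_birth_year[i] <= hi)
        cnt[type] <- cnt[type] + 1
      if (rec$female_birth_year[i] > lo && rec$female_birth_year[i] <= hi)
        cnt[type] <- cnt[type] + 1
    }
    expect_equal(got$n[b], unname(sum(cnt)))
    expect_equal(unlist(got[b, c("hypergamic", "homogamic", "hypogamic")]),
                 cnt / sum(cnt), ignore_attr = TRUE)
  }
  # every populated bin's triple sums to 1
  sums <- rowSums(got[got$n > 0, c("hypergamic", "homogamic", "hypogamic")])
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("spouses born in different decades contribute to both bins", {
  rec <- data.frame(census_year = 2010, male_education = 3,
                    female_education = 3, male_birth_year = 1949,
                    female_birth_year = 1951, male_age = 615,
                    female_age = 595, rel_duration = 300)
  got <- couple_shares(rec)
  expect_equal(got$n[got$cohort_bin == "(1940,1950]"], 1L)
  expect_equal(got$n[got$cohort_bin == "(1950,1960]"], 1L)
  # couple-based counting bins the couple once, by the male spouse
  gc <- couple_shares(rec, unit = "couple")
  expect_equal(gc$n[gc$cohort_bin == "(1940,1950]"], 1L)
  expect_equal(gc$n[gc$cohort_bin == "(1950,1960]"], 0L)
})

test_that("F index reproduces its defining boundary values", {
  expect_equal(f_index(rep(1, 3) / 3, rep(1, 3) / 3), 0.5)
  expect_equal(f_index(c(1, 0, 0), c(0, 0, 1)), 0)
  expect_equal(f_index(c(0, 0, 1), c(1, 0, 0)), 1)
  expect_error(f_index(c(1, 0, 0), c(1, 0, 0)), "undefined")
  expect_error(f_index(c(0.5, 0.2, 0.2), c(1, 0, 0)), "summing to 1")
})

test_that("F equals one half for any identical gender distributions", {
  set.seed(5)
  for (k in 1:50) {
    p <- as.numeric(stats::rgamma(3, 1)); p <- p / sum(p)
    expect_equal(f_index(p, p), 0.5, tolerance = 1e-12)
  }
})

test_that("expected random-mating shares follow the closed forms", {
  u <- rep(1, 3) / 3
  expect_equal(expected_random_shares(u, u),
               c(hypergamic = 1, homogamic = 1, hypogamic = 1) / 3)
  expect_equal(expected_random_shares(c(0, 0, 1), c(0, 0, 1)),
               c(hypergamic = 0, homogamic = 1, hypogamic = 0))
  set.seed(6)
  for (k in 1:50) {
    pf <- as.numeric(stats::rgamma(3, 1)); pf <- pf / sum(pf)
    pm <- as.numeric(stats::rgamma(3, 1)); pm <- pm / sum(pm)
    sh <- expected_random_shares(pf, pm)
    expect_equal(sum(sh), 1, tolerance = 1e-12)
    same <- expected_random_shares(pf, pf)
    expect_equal(same[["hypergamic"]], same[["hypogamic"]],
                 tolerance = 1e-12)
  }
})

test_that("mean age difference is in years", {
  rec <- data.frame(male_age = 320, female_age = 300)
  expect_equal(mean_age_difference(rec), 2)
  rec2 <- data.frame(male_age = c(300, 400), female_age = c(300, 400))
  expect_equal(mean_age_difference(rec2), 0)
  expect_error(mean_age_difference(rec[0, ]), "no records")
})

test_that("replicate aggregation gives mean and sample sd per bin/type", {
  one <- data.frame(cohort_bin = "(1950,1960]", n = 10L, hypergamic = 0.2,
                    homogamic = 0.6, hypogamic = 0.2)
  two <- one; two$homogamic <- 0.8; two$hypergamic <- 0.1; two$hypogamic <- 0.1
  agg <- aggregate_replicates(list(one, two))
  homo <- agg[agg$type == "homogamic", ]
  expect_equal(homo$mean_share, 0.7)
  expect_equal(homo$sd_share, sd(c(0.6, 0.8)), tolerance = 1e-12)
  expect_equal(homo$n_replicates, 2L)
  # identical replicates: sd 0; single replicate: sd undefined
  agg0 <- aggregate_replicates(list(one, one))
  expect_true(all(agg0$sd_share == 0))
  agg1 <- aggregate_replicates(list(one))
  expect_true(all(is.na(agg1$sd_share)))
})
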