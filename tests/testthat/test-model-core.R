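test_that("ideal partner age follows the gendered rule", {
  expect_equal(ideal_partner_age("male", 500), 240)
  expect_equal(ideal_partner_age("female", 300), 325)
  expect_equal(ideal_partner_age("female", 0), 25)
  expect_error(ideal_partner_age("other", 100), "gender")
  # symmetric rules apply one rule to both genders
  pf <- preference_params(ideal_age_rule = "fixed")
  po <- preference_params(ideal_age_rule = "offset")
  expect_equal(ideal_partner_age(c("male", "female"), 300, pf), c(240, 240))
  expect_equal(ideal_partner_age(c("male", "female"), 300, po), c(325, 325))
})

test_that("mate value matches its closed form and boundary cases", {
  p1 <- preference_params(w_s = 1, w_y = 1, w_a = 1)
  obs <- data.frame(gender = "male", education = 4L, age = 240)
  cand <- data.frame(gender = "female", education = 2L, earnings = 3L,
                     age = 300)
  # hand evaluation: 0.5 * 0.6 * 0.925
  expect_equal(mate_value(obs, cand, p1), 0.27750, tolerance = 1e-12)

  # perfect candidate: all factor bases are 1
  cand1 <- data.frame(gender = "female", education = 4L, earnings = 5L,
                      age = 240)
  expect_equal(mate_value(obs, cand1, p1), 1)
  # zero weights neutralise every factor
  p0 <- preference_params(w_s = 0, w_y = 0, w_a = 0)
  expect_equal(mate_value(obs, cand, p0), 1)
  expect_error(mate_value(obs, obs, p1), "opposite gender")
})

test_that("mate value is monotone in education distance and earnings", {
  p <- preference_params(w_s = c(male = 1.2, female = 0.5),
                         w_y = c(male = 0.8, female = 1.5))
  obs <- data.frame(gender = "female", education = 4L, age = 300)
  v_by_edu <- sapply(4:1, function(s) {
    mate_value(obs, data.frame(gender = "male", education = s,
                               earnings = 3L, age = 325), p)
  })
  expect_true(all(diff(v_by_edu) < 0))
  v_by_earn <- sapply(1:5, function(y) {
    mate_value(obs, data.frame(gender = "male", education = 4L,
                               earnings = y, age = 325), p)
  })
  expect_true(all(diff(v_by_earn) > 0))
})

test_that("seek probability decays with duration and is 1 for singles", {
  expect_equal(seek_probability(0, 0.015), 1)
  expect_equal(seek_probability(123, 0), 1)
  expect_equal(seek_probability(250, 0.015), exp(-3.75))
  expect_error(seek_probability(-1, 0.015), "non-negative")
})

test_that("date and marry probabilities match their closed forms", {
  expect_equal(date_probability(200, 0.5, 0, 0.003, 0.015),
               1 - exp(-0.3), tolerance = 1e-12)
  # sigma = 0 shuts down dating entirely
  expect_equal(date_probability(700, 1, 0, 0, 0.015), 0)
  # singles: the commitment factor is inert
  expect_equal(date_probability(340, 0.7, 0, 0.002, 0.015),
               1 - exp(-340 * 0.7 * 0.002))

  expect_equal(marry_probability(300, 1, 50, 0.003, 0.015),
               (1 - exp(-0.9)) * (1 - exp(-0.75)), tolerance = 1e-12)
  # a fresh couple can never propose
  expect_equal(marry_probability(500, 1, 0, 0.003, 0.015), 0)
  expect_equal(marry_probability(500, 1, 100, 0, 0.015), 0)
  expect_error(date_probability(200, 1.5, 0, 0.003, 0.015), "\\[0, 1\\]")
})

test_that("date and marry probabilities share their age-pressure factor", {
  set.seed(42)
  for (k in 1:20) {
    a <- runif(1, 160, 800); v <- runif(1); c <- runif(1, 1, 300)
    s <- runif(1, 1e-4, 0.01); b <- runif(1, 1e-3, 0.05)
    expect_equal(date_probability(a, v, c, s, b) / exp(-c * b),
                 marry_probability(a, v, c, s, b) / (1 - exp(-c * b)),
                 tolerance = 1e-9)
  }
})

test_that("all probability functions stay in [0, 1] on random inputs", {
  set.seed(7)
  n <- 500
  a <- runif(n, 0, 800); v <- runif(n); c <- runif(n, 0, 800)
  s <- runif(n, 0, 1); b <- runif(n, 0, 1)
  for (p in list(seek_probability(c, b), date_probability(a, v, c, s, b),
                 marry_probability(a, v, c, s, b),
                 death_probability_step(a))) {
    expect_true(all(p >= 0 & p <= 1))
  }
  obs <- data.frame(gender = "male", education = sample(1:4, n, TRUE),
                    age = a)
  cand <- data.frame(gender = "female", education = sample(1:4, n, TRUE),
                     earnings = sample(1:5, n, TRUE), age = runif(n, 0, 800))
  pr <- preference_params(w_s = runif(1, 0, 2), w_y = runif(1, 0, 2),
                          w_a = runif(1, 0, 20))
  vv <- mate_value(obs, cand, pr)
  expect_true(all(vv >= 0 & vv <= 1))
})

test_that("death probability is convex in age and hits its calibration", {
  expect_equal(death_probability_step(0), 0)
  expect_equal(death_probability_step(800), 0.01)
  expect_equal(death_probability_step(400), 0.1 * 0.1 * 0.5^6)
  expect_error(death_probability_step(900), "a_max")
  ages <- seq(0, 800, by = 40)
  p <- death_probability_step(ages)
  expect_true(all(diff(p) >= 0))
  expect_true(all(diff(diff(p)) > 0)) # convex increase
})

test_that("enrolment status is the documented piecewise mapping", {
  expect_equal(enrolment_status(50, 3), 1L)
  expect_equal(enrolment_status(150, 2), 3L)
  expect_equal(enrolment_status(250, 4), 5L)
  expect_equal(enrolment_status(60, 1), 5L)
  expect_equal(enrolment_status(200, 4), 4L)
  expect_error(enrolment_status(100, 5), "1..4")

  # piecewise-constant with breakpoints only in {60,100,160,190,240},
  # never decreasing along an agent's life
  for (s in 1:4) {
    r <- enrolment_status(0:800, s)
    jumps <- which(diff(r) != 0) # age after the jump = index
    expect_true(all(jumps %in% c(60, 100, 160, 190, 240)))
    expect_true(all(diff(r) >= 0))
  }
})
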