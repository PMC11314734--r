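test_that("the five parameters match a hand-evaluated ramp", {
  fe <- extract_features(hand_trial())
  # peak 50; threshold 40 first reached at t = 0.08; mean(40, 50) = 45;
  # 1 of 5 samples >= 45; RFD = 40 / 0.08
  expect_equal(fe$peak_force, 50)
  expect_equal(fe$rise_time, 0.08)
  expect_equal(fe$avg_after_threshold, 45)
  expect_equal(fe$pct_above_avg, 20)
  expect_equal(fe$rfd, 500)
  expect_length(fe$flags, 0)
})

test_that("a constant curve triggers the rise-time floor", {
  tr <- force_trial("const", seq(0.02, 0.10, by = 0.02), rep(10, 5), unit = "N")
  fe <- extract_features(tr)
  expect_equal(fe$peak_force, 10)
  expect_equal(fe$rise_time, 0.02)
  expect_equal(fe$avg_after_threshold, 10)
  expect_equal(fe$pct_above_avg, 100)
  expect_equal(fe$rfd, 8 / 0.02)
  expect_true("rise_floor" %in% fe$flags)
})

test_that("kg-to-N conversion scales by g and is idempotent", {
  tr <- force_trial("u", c(0.02, 0.04), c(1, 2), unit = "kg")
  n1 <- to_newtons(tr)
  expect_identical(n1$unit, "N")
  expect_equal(n1$force, c(9.80665, 19.6133))
  expect_identical(to_newtons(n1), n1)
  z <- to_newtons(force_trial("z", c(0.02, 0.04), c(0, 0), unit = "kg"))
  expect_equal(z$force, c(0, 0))
  # configurable constant
  expect_equal(to_newtons(tr, g = 9.81)$force[1], 9.81)
})

test_that("features are homogeneous of degree one in force", {
  set.seed(21)
  for (i in 1:50) {
    tr <- random_trial()
    c_ <- runif(1, 0.1, 12)
    tr2 <- tr
    tr2$force <- tr$force * c_
    a <- extract_features(tr)
    b <- extract_features(tr2)
    expect_equal(b$peak_force, c_ * a$peak_force)
    expect_equal(b$avg_after_threshold, c_ * a$avg_after_threshold)
    expect_equal(b$rfd, c_ * a$rfd)
    expect_equal(b$rise_time, a$rise_time)
    expect_equal(b$pct_above_avg, a$pct_above_avg)
  }
})

test_that("extraction commutes with unit conversion", {
  set.seed(22)
  for (i in 1:20) {
    tr <- random_trial()
    kg <- tr
    kg$unit <- "kg"
    kg$force <- tr$force / 9.80665
    a <- extract_features(to_newtons(kg))
    b <- extract_features(tr)
    expect_equal(a$peak_force, b$peak_force)
    expect_equal(a$rise_time, b$rise_time)
    expect_equal(a$rfd, b$rfd)
  }
})

test_that("implementation agrees with the literal-scan oracle", {
  set.seed(23)
  for (i in 1:100) {
    tr <- random_trial()
    fe <- extract_features(tr)
    or <- oracle_features(tr)
    expect_equal(fe$peak_force, or$peak_force, tolerance = 0)
    expect_equal(fe$rise_time, or$rise_time, tolerance = 0)
    expect_equal(fe$avg_after_threshold, or$avg_after_threshold, tolerance = 0)
    expect_equal(fe$pct_above_avg, or$pct_above_avg, tolerance = 0)
    expect_equal(fe$rfd, or$rfd, tolerance = 0)
  }
})

test_that("feature invariants hold on random trials", {
  set.seed(24)
  for (i in 1:50) {
    tr <- random_trial()
    fe <- extract_features(tr)
    expect_gt(fe$rise_time, 0)
    expect_lte(fe$rise_time, max(tr$time))
    expect_gte(fe$pct_above_avg, 0)
    expect_lte(fe$pct_above_avg, 100)
    expect_lte(fe$avg_after_threshold, fe$peak_force)
    expect_gte(fe$peak_force, max(tr$force))
    expect_equal(fe$rfd, 0.8 * fe$peak_force / fe$rise_time)
  }
})

test_that("appending sub-average samples cannot raise the above-average count", {
  set.seed(25)
  for (i in 1:20) {
    tr <- random_trial(n = 200)
    fe <- extract_features(tr)
    k <- 50
    low <- runif(k, 0, max(0.5 * fe$avg_after_threshold, 1e-6))
    ext <- force_trial(tr$subject_id,
                       c(tr$time, max(tr$time) + (1:k) / tr$sampling_hz),
                       c(tr$force, low), unit = "N",
                       sampling_hz = tr$sampling_hz)
    # against the same reference average, the appended sub-average samples
    # contribute nothing to the at-or-above count
    expect_identical(sum(ext$force >= fe$avg_after_threshold),
                     sum(tr$force >= fe$avg_after_threshold))
  }
})

test_that("the percent-above reference is switchable to the whole-trial mean", {
  tr <- hand_trial()
  fe <- extract_features(tr, pct_reference = "whole_trial")
  # whole-trial mean 24; samples >= 24: 40 and 50 -> 40%
  expect_equal(fe$pct_above_avg, 40)
})

test_that("degenerate trials raise rather than yield parameters", {
  z <- force_trial("zero", c(0.02, 0.04, 0.06), c(0, 0, 0), unit = "N")
  expect_error(extract_features(z), class = "degenerate_trial_error")
  neg <- force_trial("neg", c(0.02, 0.04), c(-1, -2), unit = "N")
  expect_error(extract_features(neg), class = "degenerate_trial_error")
  kg <- force_trial("kg", c(0.02, 0.04), c(1, 2), unit = "kg")
  expect_error(extract_features(kg), class = "trial_unit_error")
})

test_that("the feature table joins subjects and reports degenerates", {
  set.seed(26)
  co <- simulate_cohort(seed = 5)
  tab <- features_table(co$trials, co$subjects)
  expect_identical(nrow(tab), 31L)
  expect_true(all(c("peak_N", "rise_time_s", "avg_after80_N", "pct_above_avg",
                    "rfd_N_per_s", "age_group", "sex", "bmi",
                    "grip_strength_N") %in% names(tab)))
  # empty input gives an empty, well-formed table
  empty <- features_table(list(), co$subjects)
  expect_identical(nrow(empty), 0L)
  # unknown subject id is named in the error
  stray <- force_trial("GHOST", c(0.02, 0.04), c(1, 2), unit = "N")
  expect_error(features_table(list(stray), co$subjects), "GHOST",
               class = "unmatched_subject_error")
  # degenerate trials are listed, not dropped silently
  dead <- force_trial(co$subjects$subject_id[1], seq(0.02, 1, by = 0.02),
                      rep(0, 50), unit = "N")
  tab2 <- features_table(c(co$trials[-1], list(dead)), co$subjects)
  expect_identical(nrow(tab2), 30L)
  expect_identical(attr(tab2, "degenerate")$subject_id, co$subjects$subject_id[1])
})
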