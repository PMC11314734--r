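test_that("trial simulation is deterministic and respects its geometry", {
  a <- simulate_trial(50, 1, noise_cv = 0.05, seed = 99)
  b <- simulate_trial(50, 1, noise_cv = 0.05, seed = 99)
  expect_identical(a$force, b$force)
  expect_length(a$force, 500)
  expect_equal(a$time[1], 0.02)
  expect_equal(max(a$time), 10)
  c_ <- simulate_trial(50, 1, noise_cv = 0.05, seed = 100)
  expect_false(identical(a$force, c_$force))
  expect_error(simulate_trial(-1, 1), class = "synthetic_parameter_error")
  expect_error(simulate_trial(50, 0), class = "synthetic_parameter_error")
})

test_that("a noiseless curve is monotone with its peak at the final sample", {
  tr <- simulate_trial(50, 1, noise_cv = 0, seed = 1)
  expect_true(all(diff(tr$force) > 0))
  expect_equal(max(tr$force), tr$force[500])
  expect_lt(max(tr$force), 50)
  # longer windows approach the plateau
  long <- simulate_trial(50, 1, noise_cv = 0, seed = 1, duration = 60)
  expect_gt(max(long$force), max(tr$force))
  expect_equal(max(long$force), 50, tolerance = 1e-6)
})

test_that("the noiseless 80% crossing sits at tau*log(5) for short tau", {
  for (tau in c(0.3, 0.7, 1.0, 1.5)) {
    tr <- simulate_trial(60, tau, noise_cv = 0, seed = 1)
    fe <- extract_features(tr)
    expect_lt(abs(fe$rise_time - tau * log(5)), 0.02 + 1e-9)
  }
})

test_that("the finite-window crossing matches its closed form at 10 s", {
  # with a 10 s window the peak is plateau*(1-exp(-10/tau)), so the first
  # crossing solves 1-exp(-t/tau) = 0.8*(1-exp(-10/tau)) and the extracted
  # rise time is that root rounded up to the sampling grid
  for (tau in c(0.5, 1.5, 2.5, 3.5)) {
    tr <- simulate_trial(40, tau, noise_cv = 0, seed = 1)
    fe <- extract_features(tr)
    t_star <- -tau * log(1 - 0.8 * (1 - exp(-10 / tau)))
    expect_equal(fe$rise_time, ceiling(t_star / 0.02) * 0.02, tolerance = 1e-9)
  }
})

test_that("cohort generation reproduces the reference margins and is pure", {
  co <- simulate_cohort(seed = 3)
  expect_identical(nrow(co$subjects), 31L)
  expect_identical(sum(co$subjects$age_group == "older"), 17L)
  expect_identical(sum(co$subjects$age_group == "younger"), 14L)
  expect_identical(sum(co$subjects$sex == "male"), 9L)
  expect_identical(sum(co$subjects$sex == "female"), 22L)
  expect_identical(nrow(co$manifest), 31L)
  expect_true(all(co$manifest$true_plateau > 0))
  expect_true(all(co$manifest$true_tau > 0))
  expect_true(all(co$subjects$bmi > 0))
  # purity: same (profiles, seed) -> identical cohort
  co2 <- simulate_cohort(seed = 3)
  expect_identical(co$subjects, co2$subjects)
  expect_identical(lapply(co$trials, `[[`, "force"),
                   lapply(co2$trials, `[[`, "force"))
  # empty profiles give an empty cohort
  p0 <- default_group_profiles()
  p0 <- lapply(p0, function(p) { p$n <- 0L; p })
  e <- simulate_cohort(p0, seed = 1)
  expect_identical(nrow(e$subjects), 0L)
  expect_length(e$trials, 0)
})

test_that("a plateau contrast between profiles propagates to extracted peaks", {
  delta <- 25
  profs <- list(
    group_profile("younger", "male", 60, plateau_mean = 55 + delta,
                  plateau_sd = 5, tau_mean = 0.6, tau_sd = 0.05,
                  noise_cv = 0.02, grip_mean = 380, grip_sd = 50,
                  weight_mean = 77, weight_sd = 14,
                  height_mean = 1.78, height_sd = 0.09),
    group_profile("younger", "female", 60, plateau_mean = 55,
                  plateau_sd = 5, tau_mean = 0.6, tau_sd = 0.05,
                  noise_cv = 0.02, grip_mean = 220, grip_sd = 50,
                  weight_mean = 60, weight_sd = 10,
                  height_mean = 1.62, height_sd = 0.09))
  co <- simulate_cohort(profs, seed = 8)
  tab <- features_table(co$trials, co$subjects)
  obs <- mean(tab$peak_N[tab$sex == "male"]) -
    mean(tab$peak_N[tab$sex == "female"])
  se <- sqrt(2 * 25 / 60)   # plateau SD 5, n 60 per group
  expect_lt(abs(obs - delta), 4 * se + 2)  # allow for the small peak bias
})

test_that("induced correlations hit their target", {
  prof <- list(group_profile("younger", "female", 400, plateau_mean = 42.89,
                             plateau_sd = 15.47, tau_mean = 1, tau_sd = 0.5,
                             noise_cv = 0.02, grip_mean = 259.14,
                             grip_sd = 100.2, weight_mean = 65, weight_sd = 13,
                             height_mean = 1.67, height_sd = 0.1))
  co <- simulate_cohort(prof, seed = 12)
  # rho = 1: degenerate copy
  c1 <- induce_correlation(co, 1, seed = 1)
  expect_equal(cor(c1$subjects$grip_strength_N, c1$manifest$true_plateau), 1)
  # marginal moments preserved
  expect_equal(mean(c1$subjects$grip_strength_N),
               mean(co$subjects$grip_strength_N), tolerance = 1e-8)
  expect_equal(sd(c1$subjects$grip_strength_N),
               sd(co$subjects$grip_strength_N), tolerance = 1e-8)
  # rho = 0: near zero at n = 400 (|r| < 3/sqrt(n))
  c0 <- induce_correlation(co, 0, seed = 2)
  expect_lt(abs(cor(c0$subjects$grip_strength_N, c0$manifest$true_plateau)),
            3 / sqrt(400))
  # rho = 0.55: within the Fisher-z interval
  c5 <- induce_correlation(co, 0.55, seed = 3)
  r <- cor(c5$subjects$grip_strength_N, c5$manifest$true_plateau)
  z <- atanh(r) - atanh(0.55)
  expect_lt(abs(z), 3 / sqrt(400 - 3))
  expect_error(induce_correlation(co, 1.2), class = "synthetic_parameter_error")
})
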