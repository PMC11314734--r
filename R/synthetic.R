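#' Reference group summary statistics for toe extension strength
#'
#' Reference group means and standard deviations of the five curve
#' parameters and grip strength from a pilot cohort of 31 adults (17
#' older, 14 younger; 9 male, 22 female), stratified by age group and
#' sex.  These values calibrate the default synthetic-cohort profiles and
#' serve as inputs to [group_differences()]; they are summary statistics,
#' not raw data.
#'
#' @return A `data.frame` with columns `variable`, `age_stratum`
#'   (`total`/`older`/`younger`), `group` (`all`/`male`/`female`), `mean`
#'   and `sd`.
#' @export
pilot_reference_means <- function() {
  rows <- list(
    c("peak_N",          "total",   42.89, 15.47,  54.82, 13.06,  38.01, 13.82),
    c("peak_N",          "older",   39.32, 17.25,  58.02, 18.09,  33.57, 12.57),
    c("peak_N",          "younger", 47.22, 12.22,  52.26,  8.79,  44.42, 13.39),
    c("avg_after80_N",   "total",   34.78, 13.15,  42.45, 10.61,  31.64, 12.98),
    c("avg_after80_N",   "older",   31.58, 13.64,  44.42, 13.62,  27.63, 11.39),
    c("avg_after80_N",   "younger", 38.67, 11.84,  40.88,  8.88,  37.44, 13.55),
    c("rise_time_s",     "total",    2.29,  1.94,   1.02,  0.41,   2.82,  2.09),
    c("rise_time_s",     "older",    2.94,  2.22,   1.11,  0.62,   3.50,  2.23),
    c("rise_time_s",     "younger",  1.52,  1.21,   0.96,  0.17,   1.83,  1.44),
    c("rfd_N_per_s",     "total",   28.64, 21.80,  46.87, 14.76,  21.18, 19.89),
    c("rfd_N_per_s",     "older",   21.79, 20.09,  49.17, 19.59,  13.37, 12.21),
    c("rfd_N_per_s",     "younger", 36.95, 20.82,  45.02, 11.74,  32.47, 23.91),
    c("pct_above_avg",   "total",   42.59, 13.53,  50.22, 11.59,  39.48, 13.24),
    c("pct_above_avg",   "older",   36.15, 11.37,  42.45, 10.61,  34.21, 11.27),
    c("pct_above_avg",   "younger", 50.42, 11.96,  56.44,  8.69,  47.08, 12.63),
    c("grip_strength_N", "total",  259.14, 100.20, 374.85, 66.11, 211.81, 67.77),
    c("grip_strength_N", "older",  239.99,  93.56, 355.37, 89.58, 204.50, 67.76),
    c("grip_strength_N", "younger", 282.39, 103.26, 390.44, 45.17, 222.36, 70.39))
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(variable = r[1], age_stratum = r[2],
               group = c("all", "male", "female"),
               mean = as.numeric(r[c(3, 5, 7)]),
               sd = as.numeric(r[c(4, 6, 8)]))
  }))
  rownames(out) <- NULL
  out
}

#' Construct a synthetic group profile
#'
#' A `group_profile` describes one (age group, sex) stratum of a synthetic
#' cohort: how many subjects it contains and the between-subject
#' distributions of the force-curve parameters (plateau force and rise
#' time constant) and of the demographic covariates.
#'
#' @param age_group `"older"` or `"younger"`.
#' @param sex `"male"` or `"female"`.
#' @param n Number of subjects in the stratum.
#' @param plateau_mean,plateau_sd Between-subject distribution of the
#'   plateau (asymptotic) force in N.
#' @param tau_mean,tau_sd Between-subject distribution of the rise time
#'   constant tau in s (the 80% crossing of a saturating-exponential rise
#'   sits at `tau * log(5)`).
#' @param noise_cv Within-trial multiplicative noise, as a coefficient of
#'   variation.
#' @param grip_mean,grip_sd Grip strength distribution in N.
#' @param weight_mean,weight_sd Body weight distribution in kg.
#' @param height_mean,height_sd Height distribution in m.
#' @return A list of class `group_profile`.
#' @export
group_profile <- function(age_group, sex, n,
                          plateau_mean, plateau_sd, tau_mean, tau_sd,
                          noise_cv = 0.05,
                          grip_mean, grip_sd,
                          weight_mean, weight_sd,
                          height_mean, height_sd) {
  stopifnot(age_group %in% c("older", "younger"),
            sex %in% c("male", "female"),
            n >= 0, plateau_mean > 0, plateau_sd >= 0,
            tau_mean > 0, tau_sd >= 0, noise_cv >= 0,
            grip_mean > 0, weight_mean > 0, height_mean > 0)
  structure(list(age_group = age_group, sex = sex, n = as.integer(n),
                 plateau_mean = plateau_mean, plateau_sd = plateau_sd,
                 tau_mean = tau_mean, tau_sd = tau_sd, noise_cv = noise_cv,
                 grip_mean = grip_mean, grip_sd = grip_sd,
                 weight_mean = weight_mean, weight_sd = weight_sd,
                 height_mean = height_mean, height_sd = height_sd),
            class = "group_profile")
}

#' Default synthetic cohort profiles
#'
#' Four (age group, sex) profiles calibrated to the pilot reference
#' summaries ([pilot_reference_means()]): the plateau force of each
#' stratum is set to its observed mean (SD) peak force, and the rise time
#' constant is back-solved from the observed mean (SD) rise time as
#' `tau = rise_time / log(5)`, since the 80% crossing of a
#' saturating-exponential rise occurs at `tau * log(5)`.  Stratum sizes
#' (older males 4, younger males 5, older females 13, younger females 9)
#' reproduce the cohort margins of 17 older / 14 younger and 9 male / 22
#' female.  This is a calibration of a convenient generative shape to the
#' reference summaries, not a claim about the true data-generating
#' process.
#'
#' @param noise_cv Within-trial noise level applied to every profile.
#' @return A list of four [group_profile()] objects.
#' @export
default_group_profiles <- function(noise_cv = 0.05) {
  ln5 <- log(5)
  list(
    group_profile("older", "male", 4,
                  plateau_mean = 58.02, plateau_sd = 18.09,
                  tau_mean = 1.11 / ln5, tau_sd = 0.62 / ln5,
                  noise_cv = noise_cv,
                  grip_mean = 355.37, grip_sd = 89.58,
                  weight_mean = 77.06, weight_sd = 14.38,
                  height_mean = 1.78, height_sd = 0.09),
    group_profile("older", "female", 13,
                  plateau_mean = 33.57, plateau_sd = 12.57,
                  tau_mean = 3.50 / ln5, tau_sd = 2.23 / ln5,
                  noise_cv = noise_cv,
                  grip_mean = 204.50, grip_sd = 67.76,
                  weight_mean = 60.47, weight_sd = 10.13,
                  height_mean = 1.62, height_sd = 0.09),
    group_profile("younger", "male", 5,
                  plateau_mean = 52.26, plateau_sd = 8.79,
                  tau_mean = 0.96 / ln5, tau_sd = 0.17 / ln5,
                  noise_cv = noise_cv,
                  grip_mean = 390.44, grip_sd = 45.17,
                  weight_mean = 77.06, weight_sd = 14.38,
                  height_mean = 1.78, height_sd = 0.09),
    group_profile("younger", "female", 9,
                  plateau_mean = 44.42, plateau_sd = 13.39,
                  tau_mean = 1.83 / ln5, tau_sd = 1.44 / ln5,
                  noise_cv = noise_cv,
                  grip_mean = 222.36, grip_sd = 70.39,
                  weight_mean = 60.47, weight_sd = 10.13,
                  height_mean = 1.62, height_sd = 0.09))
}

#' Simulate one force trial
#'
#' Generates a synthetic isometric toe-extension trial: a saturating rise
#' to a plateau with multiplicative Gaussian sample noise,
#'
#' \deqn{F(t) = P (1 - e^{-t/\tau}) (1 + \epsilon_t), \quad
#'       \epsilon_t \sim N(0, \mathrm{noise\_cv}^2),}
#'
#' clipped at zero, sampled at `hz` over `duration` seconds with the first
#' sample at `1/hz`.  With `noise_cv = 0` the 80%-of-peak crossing of a
#' long trial sits at `tau * log(5)`.  A logistic rise is available as an
#' alternative shape.  The output is deterministic given `seed`.
#'
#' @param plateau Asymptotic force in N (> 0).
#' @param tau Rise time constant in s (> 0).
#' @param noise_cv Coefficient of variation of the per-sample noise.
#' @param seed Integer seed; same seed, same trial.
#' @param duration Trial length in s.
#' @param hz Sampling rate.
#' @param shape `"exponential"` (default) or `"logistic"` rise.
#' @param subject_id Identifier for the generated trial.
#' @return A [force_trial()] in newtons.
#' @export
simulate_trial <- function(plateau, tau, noise_cv = 0.05, seed = 1,
                           duration = 10, hz = 50,
                           shape = c("exponential", "logistic"),
                           subject_id = "sim") {
  shape <- match.arg(shape)
  if (!is.finite(plateau) || plateau <= 0) stop_toeforce("plateau must be > 0", "synthetic_parameter_error")
  if (!is.finite(tau) || tau <= 0) stop_toeforce("tau must be > 0", "synthetic_parameter_error")
  if (duration <= 0 || hz <= 0) stop_toeforce("duration and hz must be > 0", "synthetic_parameter_error")
  if (noise_cv < 0) stop_toeforce("noise_cv must be >= 0", "synthetic_parameter_error")
  n <- round(duration * hz)
  t <- seq_len(n) / hz
  mu <- switch(shape,
               exponential = plateau * (1 - exp(-t / tau)),
               logistic = plateau / (1 + exp(-(t - 2 * tau) / (tau / 2))))
  eps <- if (noise_cv > 0) with_seed(seed, stats::rnorm(n, 0, noise_cv)) else 0
  f <- pmax(mu * (1 + eps), 0)
  force_trial(subject_id, t, f, unit = "N", sampling_hz = hz)
}

#' Simulate a cohort of subjects and trials
#'
#' Draws `n` subjects per [group_profile()]: each subject's plateau force
#' and rise time constant come from the profile's truncated-normal
#' between-subject distributions (resampled until positive), weight and
#' height from the demographic distributions (BMI is derived as
#' weight/height^2), and grip strength from the profile's grip
#' distribution.  One trial per subject is generated with
#' [simulate_trial()].  A manifest records every subject's ground truth
#' for recovery testing.  The whole cohort is a pure function of
#' `(profiles, seed)`.
#'
#' @param profiles List of [group_profile()] objects.
#' @param seed Integer master seed.
#' @param duration,hz Trial geometry passed to [simulate_trial()].
#' @param shape Rise shape passed to [simulate_trial()].
#' @return A list of class `toe_cohort` with elements `trials` (list of
#'   [force_trial()]), `subjects` (data frame as from [read_subjects()])
#'   and `manifest` (data frame with `subject_id`, `age_group`, `sex`,
#'   `true_plateau`, `true_tau`, `noise_cv`, `seed`).
#' @export
simulate_cohort <- function(profiles = default_group_profiles(), seed = 1,
                            duration = 10, hz = 50, shape = "exponential") {
  stopifnot(is.list(profiles), length(profiles) > 0)
  if (!all(vapply(profiles, inherits, logical(1), "group_profile"))) {
    stop_toeforce("profiles must be a list of group_profile objects",
                  "synthetic_parameter_error")
  }
  n_total <- sum(vapply(profiles, function(p) p$n, integer(1)))
  subjects <- list()
  manifest <- list()
  draws <- with_seed(seed, {
    trial_seeds <- if (n_total > 0) sample.int(.Machine$integer.max - 1L, n_total) else integer()
    per_profile <- lapply(profiles, function(p) {
      if (p$n == 0L) return(NULL)
      list(plateau = rnorm_pos(p$n, p$plateau_mean, p$plateau_sd),
           tau = rnorm_pos(p$n, p$tau_mean, p$tau_sd),
           grip = rnorm_pos(p$n, p$grip_mean, p$grip_sd),
           weight = rnorm_pos(p$n, p$weight_mean, p$weight_sd),
           height = rnorm_pos(p$n, p$height_mean, p$height_sd))
    })
    list(trial_seeds = trial_seeds, per_profile = per_profile)
  })
  trials <- vector("list", n_total)
  k <- 0L
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    d <- draws$per_profile[[i]]
    if (p$n == 0L) next
    for (j in seq_len(p$n)) {
      k <- k + 1L
      sid <- sprintf("S%03d", k)
      trials[[k]] <- simulate_trial(d$plateau[j], d$tau[j], p$noise_cv,
                                    seed = draws$trial_seeds[k],
                                    duration = duration, hz = hz,
                                    shape = shape, subject_id = sid)
      subjects[[k]] <- data.frame(
        subject_id = sid, age_group = p$age_group, sex = p$sex,
        weight_kg = d$weight[j], height_m = d$height[j],
        bmi = d$weight[j] / d$height[j]^2,
        grip_strength_N = d$grip[j])
      manifest[[k]] <- data.frame(
        subject_id = sid, age_group = p$age_group, sex = p$sex,
        true_plateau = d$plateau[j], true_tau = d$tau[j],
        noise_cv = p$noise_cv, seed = draws$trial_seeds[k])
    }
  }
  empty_subjects <- data.frame(subject_id = character(), age_group = character(),
                               sex = character(), weight_kg = numeric(),
                               height_m = numeric(), bmi = numeric(),
                               grip_strength_N = numeric())
  structure(list(
    trials = trials,
    subjects = if (k > 0) do.call(rbind, subjects) else empty_subjects,
    manifest = if (k > 0) do.call(rbind, manifest) else
      data.frame(subject_id = character(), age_group = character(),
                 sex = character(), true_plateau = numeric(),
                 true_tau = numeric(), noise_cv = numeric(), seed = integer())),
    class = "toe_cohort")
}

#' @export
print.toe_cohort <- function(x, ...) {
  cat(sprintf("<toe_cohort> %d subjects (%d older, %d male)\n",
              nrow(x$subjects), sum(x$subjects$age_group == "older"),
              sum(x$subjects$sex == "male")))
  invisible(x)
}

#' Impose a target correlation between a covariate and true plateau force
#'
#' Regenerates one subject covariate as a Gaussian copy correlated at
#' `rho` with the per-subject true plateau from the cohort manifest, while
#' preserving the covariate's sample mean and SD.  This gives validation
#' tests a cohort whose population feature--covariate correlation is known
#' exactly.
#'
#' @param cohort A `toe_cohort` from [simulate_cohort()].
#' @param rho Target correlation in \[-1, 1\].
#' @param covariate Subject column to regenerate (default
#'   `"grip_strength_N"`).
#' @param seed Integer seed for the independent Gaussian component.
#' @return The cohort with the covariate column replaced.
#' @export
induce_correlation <- function(cohort, rho, covariate = "grip_strength_N",
                               seed = 1) {
  stopifnot(inherits(cohort, "toe_cohort"))
  if (!is.finite(rho) || abs(rho) > 1) {
    stop_toeforce("rho must lie in [-1, 1]", "synthetic_parameter_error")
  }
  if (!covariate %in% names(cohort$subjects)) {
    stop_toeforce(paste0("unknown covariate: ", covariate), "synthetic_parameter_error")
  }
  x <- cohort$manifest$true_plateau
  n <- length(x)
  if (n < 2L) return(cohort)
  old <- cohort$subjects[[covariate]]
  z <- as.numeric(scale(x))
  w <- with_seed(seed, stats::rnorm(n))
  y <- rho * z + sqrt(1 - rho^2) * w
  cohort$subjects[[covariate]] <- mean(old) + stats::sd(old) * y
  cohort
}
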