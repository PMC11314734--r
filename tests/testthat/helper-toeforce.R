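# Shared fixtures and independent oracles for the test suite.
# Oracles deliberately use literal element-by-element scans so they stay
# independent of the vectorised implementation paths they check.

# A random plausible trial on a regular 50 Hz grid: noisy saturating ramp,
# occasionally rounded to force ties at the peak/threshold.
random_trial <- function(n = sample(50:500, 1), hz = 50) {
  t <- seq_len(n) / hz
  plateau <- runif(1, 5, 80)
  tau <- runif(1, 0.1, 3)
  f <- plateau * (1 - exp(-t / tau)) * (1 + rnorm(n, 0, runif(1, 0, 0.1)))
  f <- pmax(f, 0)
  if (runif(1) < 0.3) f <- round(f, 1)   # induce ties
  force_trial(paste0("R", sample.int(1e6, 1)), t, f, unit = "N", sampling_hz = hz)
}

# Literal scan of the five curve-parameter definitions.
oracle_features <- function(trial) {
  force <- trial$force
  time <- trial$time
  n <- length(force)
  peak <- force[1]
  for (f in force) if (f > peak) peak <- f
  thr <- 0.8 * peak
  idx <- NA_integer_
  for (i in seq_len(n)) if (force[i] >= thr) { idx <- i; break }
  avg <- mean(force[idx:n])
  cnt <- 0L
  for (f in force) if (f >= avg) cnt <- cnt + 1L
  rise <- time[idx]
  if (idx == 1L) rise <- max(rise, 1 / trial$sampling_hz)
  list(peak_force = peak, rise_time = rise, avg_after_threshold = avg,
       pct_above_avg = 100 * cnt / n, rfd = thr / rise)
}

# Pairwise brute-force AUC: concordant pairs plus half the ties.
oracle_auc <- function(pos_scores, neg_scores) {
  s <- 0
  for (a in pos_scores) {
    for (b in neg_scores) {
      s <- s + (a > b) + 0.5 * (a == b)
    }
  }
  s / (length(pos_scores) * length(neg_scores))
}

# Small cohort of synthetic trials written to disk, for io round trips.
write_tmp_trial <- function(trial, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, paste0(trial$subject_id, ".txt"))
  write_trial(trial, path)
  path
}

# A deterministic ramp trial whose features are known by hand.
hand_trial <- function() {
  force_trial("hand", seq(0.02, 0.10, by = 0.02), c(0, 10, 20, 40, 50),
              unit = "N", sampling_hz = 50)
}

# Perfectly separable two-class curve dataset: Gaussian columns with the
# class means 10 SDs apart.
separable_trials <- function(n_per_class = 15, p = 500, delta = 10) {
  trials <- list()
  subjects <- list()
  for (i in seq_len(2 * n_per_class)) {
    cls <- if (i <= n_per_class) "female" else "male"
    mu <- if (cls == "male") delta else 0
    sid <- sprintf("P%03d", i)
    trials[[i]] <- force_trial(sid, seq_len(p) / 50, rnorm(p, mu, 1),
                               unit = "N", sampling_hz = 50)
    subjects[[i]] <- data.frame(subject_id = sid,
                                age_group = if (cls == "male") "younger" else "older",
                                sex = cls, weight_kg = 70, height_m = 1.7,
                                bmi = 24.2, grip_strength_N = 300)
  }
  list(trials = trials, subjects = do.call(rbind, subjects))
}
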