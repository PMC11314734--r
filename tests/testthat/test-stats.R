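make_feature_frame <- function(n = 40, seed = 31) {
  set.seed(seed)
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    age_group = rep(c("older", "younger"), length.out = n),
    sex = rep(c("male", "female", "female", "male"), length.out = n),
    peak_N = rnorm(n, 43, 15),
    avg_after80_N = rnorm(n, 35, 13),
    rise_time_s = rexp(n, 1 / 2.3),
    rfd_N_per_s = rnorm(n, 29, 20),
    pct_above_avg = runif(n, 20, 70),
    grip_strength_N = rnorm(n, 259, 100),
    bmi = rnorm(n, 23.3, 3.5))
}

test_that("descriptives give sample mean and n-1 SD per cell", {
  tab <- data.frame(subject_id = c("a", "b", "c"),
                    age_group = c("older", "older", "younger"),
                    sex = c("male", "female", "female"),
                    peak_N = c(1, 2, 3))
  d <- describe_groups(tab, variables = "peak_N")
  all_row <- d[d$grouping == "all", ]
  expect_equal(all_row$mean, 2)
  expect_equal(all_row$sd, 1)
  # single-observation cell: SD undefined and flagged
  y <- d[d$grouping == "age_group" & d$group == "younger", ]
  expect_identical(y$n, 1L)
  expect_true(is.na(y$sd))
  expect_identical(y$flag, "sd_undefined")
})

test_that("group cells carry the cohort margins", {
  co <- simulate_cohort(seed = 4)
  tab <- features_table(co$trials, co$subjects)
  d <- describe_groups(tab, variables = "peak_N", groupings = "sex")
  expect_setequal(d$n, c(9L, 22L))
})

test_that("identical groups give t = 0 and p = 1", {
  x <- rnorm(12, 40, 10)
  tab <- data.frame(v = c(x, x), g = rep(c("a", "b"), each = 12))
  r <- two_group_test(tab, "v", "g")
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  tiny <- data.frame(v = c(1, 2, 3), g = c("a", "a", "b"))
  expect_error(two_group_test(tiny, "v", "g"), class = "stats_grouping_error")
})

test_that("t, F and r are invariant to shifting and positive scaling", {
  tab <- make_feature_frame()
  base_t <- two_group_test(tab, "peak_N", "sex")
  base_a <- two_way_anova(tab, "peak_N")
  base_r <- cor.test(tab$peak_N, tab$grip_strength_N)
  tab2 <- tab
  tab2$peak_N <- 3.7 * tab$peak_N + 120
  r2 <- two_group_test(tab2, "peak_N", "sex")
  a2 <- two_way_anova(tab2, "peak_N")
  c2 <- cor.test(tab2$peak_N, tab2$grip_strength_N)
  expect_equal(r2$t, base_t$t)
  expect_equal(r2$p, base_t$p)
  expect_equal(a2$F, base_a$F)
  expect_equal(a2$p, base_a$p)
  expect_equal(unname(c2$estimate), unname(base_r$estimate))
})

test_that("type-II and type-I ANOVA agree on a balanced design", {
  set.seed(33)
  tab <- data.frame(age_group = rep(c("older", "younger"), each = 20),
                    sex = rep(c("male", "female"), times = 20),
                    peak_N = rnorm(40, 40, 10))
  t2 <- two_way_anova(tab, "peak_N", ss_type = 2)
  a1 <- anova(lm(peak_N ~ age_group * sex, data = tab))
  expect_equal(t2$F, a1[1:3, "F value"], tolerance = 1e-10)
  # a power check: a pure 2-SD sex effect is detected
  tab$peak_N <- tab$peak_N + ifelse(tab$sex == "male", 20, 0)
  t2b <- two_way_anova(tab, "peak_N")
  expect_lt(t2b$p[t2b$term == "sex"], 0.001)
  # empty cell is an explicit error
  bad <- tab[!(tab$age_group == "older" & tab$sex == "male"), ]
  expect_error(two_way_anova(bad, "peak_N"), class = "stats_design_error")
})

test_that("welch is the default and student is available", {
  tab <- make_feature_frame()
  w <- two_group_test(tab, "peak_N", "sex")
  s <- two_group_test(tab, "peak_N", "sex", var_equal = TRUE)
  expect_false(isTRUE(all.equal(w$df, s$df)))
  expect_equal(s$df, nrow(tab) - 2)
})

test_that("correlation matrices have a unit diagonal and flag non-normality", {
  tab <- make_feature_frame(n = 60)
  tab$rise_time_s <- exp(rnorm(60, 0, 1.2))   # clearly non-normal
  cr <- correlations(tab, by_group = FALSE)
  diag_rows <- cr$correlations[cr$correlations$var1 == cr$correlations$var2, ]
  expect_true(all(diag_rows$r == 1))
  nn <- cr$normality
  expect_false(nn$normal[nn$variable == "rise_time_s"])
  # perfectly linear pair
  tab$grip_strength_N <- 2 * tab$peak_N + 5
  cr2 <- correlations(tab, variables = c("peak_N", "grip_strength_N"),
                      by_group = FALSE)
  off <- cr2$correlations[cr2$correlations$var1 == "peak_N" &
                            cr2$correlations$var2 == "grip_strength_N", ]
  expect_equal(off$r, 1)
  # strata below n = 3 are refused
  expect_error(correlations(tab[1:2, ], by_group = FALSE),
               class = "stats_grouping_error")
})

test_that("significance marks mirror the alpha and trend thresholds", {
  tab <- make_feature_frame(n = 200, seed = 35)
  tab$peak_N <- tab$peak_N + ifelse(tab$sex == "male", 30, 0)
  r <- two_group_test(tab, "peak_N", "sex")
  expect_identical(r$mark, "*")
})

test_that("group differences use the stated sign conventions", {
  # on the bundled reference means
  d <- group_differences(pilot_reference_means())
  expect_equal(d$difference[d$variable == "peak_N" &
                              d$contrast == "male-female"], 16.81)
  expect_equal(d$difference[d$variable == "rfd_N_per_s" &
                              d$contrast == "younger-older"], 15.16)
  expect_equal(d$difference[d$variable == "rise_time_s" &
                              d$contrast == "female-male"], 1.80)
  # identical group means give zero
  tab <- data.frame(subject_id = sprintf("s%d", 1:8),
                    age_group = rep(c("older", "younger"), 4),
                    sex = rep(c("male", "female"), each = 4),
                    peak_N = rep(5, 8))
  dd <- group_differences(describe_groups(tab, variables = "peak_N"))
  expect_true(all(dd$difference == 0))
  # missing stratum errors
  one_sex <- describe_groups(tab[tab$sex == "male", ], variables = "peak_N")
  expect_error(group_differences(one_sex), class = "stats_grouping_error")
})

test_that("the bundled report assembles every section coherently", {
  co <- simulate_cohort(seed = 6)
  tab <- features_table(co$trials, co$subjects)
  rep_ <- group_stats_report(tab)
  expect_s3_class(rep_, "group_stats_report")
  expect_identical(rep_$n, 31L)
  expect_true(all(rep_$t_tests$p >= 0 & rep_$t_tests$p <= 1))
  expect_true(all(rep_$anova$F >= 0))
  cc <- rep_$correlations$correlations
  expect_true(all(cc$r >= -1 & cc$r <= 1))
  expect_true(all(cc$p >= 0 & cc$p <= 1, na.rm = TRUE))
  # group n's sum to the total
  d <- rep_$descriptives
  expect_identical(sum(d$n[d$variable == "peak_N" & d$grouping == "sex"]), 31L)
  expect_output(print(rep_), "Group statistics report")
})
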