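feature_variables <- c("peak_N", "avg_after80_N", "rise_time_s",
                       "rfd_N_per_s", "pct_above_avg")

# Significance marks used throughout the reports: '*' below alpha,
# '^' for a trend below the trend threshold.
significance_mark <- function(p, alpha = 0.05, trend = 0.10) {
  ifelse(is.na(p), "",
         ifelse(p < alpha, "*", ifelse(p < trend, "^", "")))
}

#' Group descriptives: mean (SD) per cell
#'
#' Computes the sample mean and SD (n-1 denominator) of each variable
#' within each level of each grouping, plus the ungrouped total.  Cells
#' with a single observation get an undefined SD and are flagged; empty
#' cells are reported as missing rather than zero.
#'
#' @param table Feature table as from [features_table()].
#' @param variables Numeric columns to summarise.
#' @param groupings Grouping columns (factors with their levels taken from
#'   the data); `"all"` denotes the ungrouped total.
#' @return A `data.frame` with columns `variable`, `grouping`, `group`,
#'   `n`, `mean`, `sd`, `flag`.
#' @export
describe_groups <- function(table, variables = feature_variables,
                            groupings = c("all", "age_group", "sex")) {
  stopifnot(all(variables %in% names(table)))
  out <- list()
  for (v in variables) {
    for (gcol in groupings) {
      groups <- if (gcol == "all") {
        list(all = seq_len(nrow(table)))
      } else {
        split(seq_len(nrow(table)), factor(table[[gcol]]))
      }
      for (gname in names(groups)) {
        idx <- groups[[gname]]
        x <- table[[v]][idx]
        n <- length(x)
        flag <- ""
        if (n == 0L) flag <- "empty"
        if (n == 1L) flag <- "sd_undefined"
        out[[length(out) + 1L]] <- data.frame(
          variable = v, grouping = gcol, group = gname, n = n,
          mean = if (n >= 1) mean(x) else NA_real_,
          sd = if (n >= 2) stats::sd(x) else NA_real_,
          flag = flag)
      }
    }
  }
  do.call(rbind, out)
}

#' Two-group location test
#'
#' Independent-samples t-test of `variable` between the two levels of
#' `grouping`.  Welch's unequal-variance form is the default since the
#' strata of interest (9 males vs 22 females) are far from balanced;
#' Student's pooled form is available via `var_equal = TRUE`.
#'
#' @param table Feature table.
#' @param variable Numeric column to test.
#' @param grouping Two-level grouping column (`"sex"` or `"age_group"`).
#' @param var_equal Use the pooled-variance (Student) form.
#' @return A `data.frame` row: `variable`, `grouping`, group labels and
#'   means, `t`, `df`, `p`, `mark`.
#' @export
two_group_test <- function(table, variable, grouping, var_equal = FALSE) {
  stopifnot(variable %in% names(table), grouping %in% names(table))
  g <- factor(table[[grouping]])
  if (nlevels(g) != 2L) {
    stop_toeforce(sprintf("grouping '%s' must have exactly 2 levels, found %d",
                          grouping, nlevels(g)), "stats_grouping_error")
  }
  x <- split(table[[variable]], g)
  if (any(vapply(x, length, integer(1)) < 2L)) {
    stop_toeforce("each group needs at least 2 observations", "stats_grouping_error")
  }
  tt <- stats::t.test(x[[1]], x[[2]], var.equal = var_equal)
  data.frame(variable = variable, grouping = grouping,
             group1 = levels(g)[1], group2 = levels(g)[2],
             mean1 = mean(x[[1]]), mean2 = mean(x[[2]]),
             t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, mark = significance_mark(tt$p.value))
}

#' Two-way ANOVA of a curve parameter on age group and sex
#'
#' Fits `variable ~ age_group * sex` and reports F and p for the two main
#' effects and the interaction using type-II sums of squares, which do not
#' depend on the order of unbalanced factors.
#'
#' @param table Feature table containing `age_group` and `sex`.
#' @param variable Numeric column to analyse.
#' @param ss_type Sum-of-squares type passed to [car::Anova()] (2 or 3).
#' @return A `data.frame` with one row per effect: `term`, `df`, `F`,
#'   `p`, `mark`.
#' @export
two_way_anova <- function(table, variable, ss_type = 2) {
  stopifnot(variable %in% names(table))
  dat <- data.frame(y = table[[variable]],
                    age_group = factor(table$age_group),
                    sex = factor(table$sex))
  if (nlevels(dat$age_group) != 2L || nlevels(dat$sex) != 2L) {
    stop_toeforce("both age_group and sex must have both levels present",
                  "stats_grouping_error")
  }
  cells <- table(dat$age_group, dat$sex)
  if (any(cells == 0L)) {
    stop_toeforce("empty cell in the age x sex design; two-way ANOVA undefined",
                  "stats_design_error")
  }
  fit <- stats::lm(y ~ age_group * sex, data = dat)
  an <- car::Anova(fit, type = ss_type)
  terms <- c("age_group", "sex", "age_group:sex")
  idx <- match(terms, rownames(an))
  p <- an[idx, "Pr(>F)"]
  data.frame(variable = variable, term = terms,
             df = an[idx, "Df"], F = an[idx, "F value"], p = p,
             mark = significance_mark(p))
}

#' Pairwise correlations with normality flags
#'
#' Pearson correlations (two-sided p) between every pair of variables,
#' computed for the whole sample and, when `by_group = TRUE`, within each
#' age group.  Each variable is additionally screened for normality with
#' a Shapiro-Wilk test in each stratum; non-normal variables are flagged
#' so that correlations involving them can be read with caution.
#' Significant correlations are marked `*` (p < 0.05) and trends `^`
#' (p < 0.10).  No multiple-testing correction is applied; the report
#' states this.
#'
#' @param table Feature table.
#' @param variables Numeric columns to correlate (default: the five curve
#'   parameters plus grip strength and BMI).
#' @param by_group Also compute within-age-group matrices.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A list of class `correlation_report`: `correlations` (long
#'   data frame with `stratum`, `var1`, `var2`, `n`, `r`, `p`, `mark`)
#'   and `normality` (`stratum`, `variable`, `shapiro_p`, `normal`).
#' @export
correlations <- function(table,
                         variables = c(feature_variables, "grip_strength_N", "bmi"),
                         by_group = TRUE, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  variables <- intersect(variables, names(table))
  strata <- list(whole_sample = seq_len(nrow(table)))
  if (by_group && "age_group" %in% names(table)) {
    strata <- c(strata, split(seq_len(nrow(table)), factor(table$age_group)))
  }
  cors <- list()
  norm <- list()
  for (s in names(strata)) {
    idx <- strata[[s]]
    if (length(idx) < 3L) {
      stop_toeforce(sprintf("stratum '%s' has n = %d < 3; correlations undefined",
                            s, length(idx)), "stats_grouping_error")
    }
    for (v in variables) {
      x <- table[[v]][idx]
      sw <- if (length(unique(x)) > 1L) stats::shapiro.test(x)$p.value else NA_real_
      norm[[length(norm) + 1L]] <- data.frame(
        stratum = s, variable = v, shapiro_p = sw,
        normal = is.na(sw) | sw >= 0.05)
    }
    for (i in seq_along(variables)) {
      for (j in seq_along(variables)) {
        v1 <- variables[i]; v2 <- variables[j]
        if (i == j) {
          cors[[length(cors) + 1L]] <- data.frame(
            stratum = s, var1 = v1, var2 = v2, n = length(idx),
            r = 1, p = NA_real_, mark = "")
          next
        }
        ct <- stats::cor.test(table[[v1]][idx], table[[v2]][idx],
                              method = method, exact = FALSE)
        cors[[length(cors) + 1L]] <- data.frame(
          stratum = s, var1 = v1, var2 = v2, n = length(idx),
          r = unname(ct$estimate), p = ct$p.value,
          mark = significance_mark(ct$p.value))
      }
    }
  }
  structure(list(correlations = do.call(rbind, cors),
                 normality = do.call(rbind, norm),
                 method = method,
                 note = "p-values are uncorrected for multiple testing"),
            class = "correlation_report")
}

#' Signed group mean differences
#'
#' Computes the between-group contrasts of per-variable means with a
#' stated sign convention: `male - female` for sex and
#' `younger - older` for age.  For rise time the reversed contrasts are
#' reported as well, since the slower group (females, older adults) has
#' the *longer* rise time and the field reports that direction.
#'
#' @param means A long means table with columns `variable`, `group` and
#'   `mean`, e.g. the output of [describe_groups()] or
#'   [pilot_reference_means()] (rows of other strata are ignored; when an
#'   `age_stratum` column is present, sex contrasts use the `total`
#'   stratum and age contrasts the per-age `all` rows).
#' @return A `data.frame` with columns `variable`, `contrast`,
#'   `difference`.
#' @export
group_differences <- function(means) {
  stopifnot(all(c("variable", "group", "mean") %in% names(means)))
  pick <- function(v, g, stratum = NULL) {
    rows <- means$variable == v & means$group == g
    if (!is.null(stratum) && "age_stratum" %in% names(means)) {
      rows <- rows & means$age_stratum == stratum
    }
    if ("grouping" %in% names(means)) {
      gcol <- if (g %in% c("male", "female")) "sex" else
        if (g %in% c("older", "younger")) "age_group" else "all"
      rows <- rows & means$grouping == gcol
    }
    m <- means$mean[rows]
    if (length(m) == 0L) return(NA_real_)
    m[1]
  }
  out <- list()
  for (v in unique(means$variable)) {
    male <- pick(v, "male", "total")
    female <- pick(v, "female", "total")
    if ("age_stratum" %in% names(means)) {
      younger <- pick(v, "all", "younger")
      older <- pick(v, "all", "older")
    } else {
      younger <- pick(v, "younger")
      older <- pick(v, "older")
    }
    if (is.na(male) || is.na(female) || is.na(younger) || is.na(older)) {
      stop_toeforce(sprintf("means table is missing a stratum for '%s'", v),
                    "stats_grouping_error")
    }
    out[[length(out) + 1L]] <- data.frame(
      variable = v,
      contrast = c("male-female", "younger-older"),
      difference = c(male - female, younger - older))
    if (v %in% c("rise_time_s", "rise_time")) {
      out[[length(out) + 1L]] <- data.frame(
        variable = v,
        contrast = c("female-male", "older-younger"),
        difference = c(female - male, older - younger))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Full traditional-analysis report for a feature table
#'
#' Bundles the descriptives, per-variable two-group tests by sex and by
#' age group, two-way ANOVAs, group mean differences, and the correlation
#' report into one object mirroring the usual presentation of toe
#' strength results.
#'
#' @param table Feature table from [features_table()].
#' @param var_equal Use Student rather than Welch t-tests.
#' @param ss_type ANOVA sum-of-squares type.
#' @param cor_method Correlation method.
#' @return A list of class `group_stats_report`.
#' @export
group_stats_report <- function(table, var_equal = FALSE, ss_type = 2,
                               cor_method = "pearson") {
  descr <- describe_groups(table)
  tts <- do.call(rbind, c(
    lapply(feature_variables, two_group_test, table = table, grouping = "sex",
           var_equal = var_equal),
    lapply(feature_variables, two_group_test, table = table,
           grouping = "age_group", var_equal = var_equal)))
  anovas <- do.call(rbind, lapply(feature_variables, two_way_anova,
                                  table = table, ss_type = ss_type))
  diffs <- group_differences(descr)
  cors <- correlations(table, method = cor_method)
  structure(list(n = nrow(table), descriptives = descr, t_tests = tts,
                 anova = anovas, differences = diffs, correlations = cors,
                 note = "p-values are uncorrected for multiple testing"),
            class = "group_stats_report")
}

#' @export
print.group_stats_report <- function(x, digits = 3, ...) {
  cat(sprintf("Group statistics report (n = %d)\n", x$n))
  cat("\nDescriptives: mean (SD) per group\n")
  d <- x$descriptives
  d$cell <- ifelse(is.na(d$mean), "--",
                   sprintf("%.2f (%s)", d$mean,
                           ifelse(is.na(d$sd), "NA", sprintf("%.2f", d$sd))))
  print(d[, c("variable", "grouping", "group", "n", "cell")], row.names = FALSE)
  cat("\nTwo-group tests (", ifelse(is.null(x$t_tests$df), "", "Welch"),
      " t):\n", sep = "")
  print(format(x$t_tests, digits = digits), row.names = FALSE)
  cat("\nTwo-way ANOVA (type-II SS):\n")
  print(format(x$anova, digits = digits), row.names = FALSE)
  cat("\nGroup mean differences:\n")
  print(format(x$differences, digits = digits), row.names = FALSE)
  cat("\nCorrelations (", x$correlations$method, "); ",
      x$correlations$note, "\n", sep = "")
  print(format(x$correlations$correlations, digits = digits), row.names = FALSE)
  nn <- x$correlations$normality
  bad <- nn[!nn$normal, , drop = FALSE]
  if (nrow(bad)) {
    cat("\nLack of normality (Shapiro-Wilk p < 0.05):\n")
    print(format(bad, digits = digits), row.names = FALSE)
  }
  invisible(x)
}
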