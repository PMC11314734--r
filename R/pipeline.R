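#' Pipeline configuration
#'
#' Validates and bundles every tunable of the analysis pipeline: ingestion
#' limits, the gravitational constant for unit conversion, the
#' percent-above-average reference, statistical test variants, the ML
#' model roster and evaluation schemes, and the synthetic cohort profiles.
#' All values are checked before any stage runs.
#'
#' @param expected_samples,sampling_hz,max_end_gap,hz_tol See
#'   [ingest_config()].
#' @param g Gravitational acceleration (m/s^2) for kg-to-N conversion.
#' @param pct_reference Reference average for the percent-above parameter
#'   (see [extract_features()]).
#' @param t_var_equal Use Student instead of Welch t-tests.
#' @param anova_ss_type ANOVA sum-of-squares type (2 or 3).
#' @param cor_method `"pearson"` or `"spearman"`.
#' @param ml_targets Classification targets to run.
#' @param ml_models List of [model_spec()]s.
#' @param ml_split Named train/validation/test fractions.
#' @param ml_cv_folds Cross-validation fold counts to run (subset of 3, 5).
#' @param standardize Standardize curve columns on training data.
#' @param profiles Synthetic cohort profiles for [make_fixtures()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(expected_samples = 500L, sampling_hz = 50,
                            max_end_gap = 10L, hz_tol = 0.01,
                            g = 9.80665,
                            pct_reference = c("post_threshold", "whole_trial"),
                            t_var_equal = FALSE,
                            anova_ss_type = 2,
                            cor_method = c("pearson", "spearman"),
                            ml_targets = c("age", "sex"),
                            ml_models = list(model_spec("knn", k = 5),
                                             model_spec("knn", k = 10),
                                             model_spec("svm"),
                                             model_spec("rf")),
                            ml_split = c(train = 0.45, validation = 0.25,
                                         test = 0.30),
                            ml_cv_folds = c(3, 5),
                            standardize = TRUE,
                            profiles = default_group_profiles()) {
  pct_reference <- match.arg(pct_reference)
  cor_method <- match.arg(cor_method)
  stopifnot(g > 0, anova_ss_type %in% c(2, 3),
            all(ml_targets %in% c("age", "sex")),
            all(ml_cv_folds %in% c(3, 5)),
            abs(sum(ml_split) - 1) < 1e-8,
            is.logical(t_var_equal), is.logical(standardize))
  if (!all(vapply(ml_models, inherits, logical(1), "toe_model_spec"))) {
    stop_toeforce("ml_models must be a list of model_spec objects", "config_error")
  }
  if (!all(vapply(profiles, inherits, logical(1), "group_profile"))) {
    stop_toeforce("profiles must be a list of group_profile objects", "config_error")
  }
  structure(list(expected_samples = as.integer(expected_samples),
                 sampling_hz = sampling_hz,
                 max_end_gap = as.integer(max_end_gap), hz_tol = hz_tol,
                 g = g, pct_reference = pct_reference,
                 t_var_equal = t_var_equal, anova_ss_type = anova_ss_type,
                 cor_method = cor_method, ml_targets = ml_targets,
                 ml_models = ml_models, ml_split = ml_split,
                 ml_cv_folds = ml_cv_folds, standardize = standardize,
                 profiles = profiles),
            class = "pipeline_config")
}

# Stamp every output file with the configuration hash and seed so runs
# are attributable and byte-reproducible.
output_header <- function(config, seed) {
  sprintf("toeforce %s; config %s; seed %d",
          as.character(utils::packageVersion("toeforce")),
          config_hash(config), seed)
}

write_stamped_csv <- function(df, path, config, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", output_header(config, seed)), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate synthetic fixture files
#'
#' Simulates a cohort from the configured profiles and writes it to disk
#' in the exact formats the ingestion stage reads: one two-column text
#' file per trial under `out_dir/trials/`, a subject CSV, and a
#' ground-truth manifest CSV.  Byte-reproducible given `(config, seed)`.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @param seed Integer seed.
#' @return Invisibly, a list with `trial_dir`, `subjects_csv`,
#'   `manifest_csv` and the generated `cohort`.
#' @export
make_fixtures <- function(out_dir, config = pipeline_config(), seed = 1) {
  trial_dir <- file.path(out_dir, "trials")
  ok <- dir.create(trial_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(trial_dir)) {
    stop_toeforce(paste0("cannot create directory ", trial_dir), "pipeline_io_error")
  }
  cohort <- simulate_cohort(config$profiles, seed = seed,
                            duration = config$expected_samples / config$sampling_hz,
                            hz = config$sampling_hz)
  for (tr in cohort$trials) {
    write_trial(tr, file.path(trial_dir, paste0(tr$subject_id, ".txt")))
  }
  subjects_csv <- file.path(out_dir, "subjects.csv")
  write_subjects(cohort$subjects, subjects_csv,
                 header_lines = output_header(config, seed))
  manifest_csv <- file.path(out_dir, "manifest.csv")
  write_stamped_csv(cohort$manifest, manifest_csv, config, seed)
  invisible(list(trial_dir = trial_dir, subjects_csv = subjects_csv,
                 manifest_csv = manifest_csv, cohort = cohort))
}

#' Run the full analysis pipeline
#'
#' Sequences the stages end to end: ingest every trial file in
#' `trial_dir`, convert to newtons, extract the five curve parameters and
#' join to the subject table, run the traditional group statistics, and
#' evaluate the configured classifiers on the raw curves under the single
#' split and each configured cross-validation scheme.  All outputs are
#' written under `out_dir` with a config-hash/seed stamp; given the same
#' `(config, seed)` and inputs the outputs are byte-identical.
#'
#' @param trial_dir Directory of trial text files (`*.txt`).
#' @param subjects_csv Subject metadata CSV.
#' @param out_dir Output directory.
#' @param config A [pipeline_config()].
#' @param seed Integer seed for the ML evaluations.
#' @return Invisibly, a list with the feature table, the
#'   `group_stats_report`, the ML report data frame, and the output file
#'   paths.
#' @export
run_pipeline <- function(trial_dir, subjects_csv, out_dir,
                         config = pipeline_config(), seed = 1) {
  stopifnot(inherits(config, "pipeline_config"))
  paths <- sort(list.files(trial_dir, pattern = "\\.txt$", full.names = TRUE))
  if (length(paths) == 0L) {
    stop_toeforce(paste0("ingestion: no trial files found in ", trial_dir),
                  "pipeline_io_error")
  }
  icfg <- ingest_config(config$expected_samples, config$sampling_hz,
                        config$max_end_gap, config$hz_tol)
  trials <- lapply(paths, read_trial, config = icfg)
  subjects <- read_subjects(subjects_csv)
  trials <- lapply(trials, to_newtons, g = config$g)

  feats <- features_table(trials, subjects, g = config$g,
                          pct_reference = config$pct_reference)
  stats_report <- group_stats_report(feats,
                                     var_equal = config$t_var_equal,
                                     ss_type = config$anova_ss_type,
                                     cor_method = config$cor_method)

  ml_rows <- list()
  for (target in config$ml_targets) {
    ds <- build_dataset(trials, subjects, target = target)
    for (spec in config$ml_models) {
      ml_rows[[length(ml_rows) + 1L]] <-
        evaluate_split(ds, spec, split = config$ml_split, seed = seed,
                       standardize = config$standardize)
      for (k in config$ml_cv_folds) {
        cv <- evaluate_cv(ds, spec, k_folds = k, seed = seed,
                          standardize = config$standardize)
        attr(cv, "fold_accuracy_pct") <- NULL
        ml_rows[[length(ml_rows) + 1L]] <- cv
      }
    }
  }
  ml_report <- do.call(rbind, lapply(ml_rows, function(r) {
    data.frame(model = r$model, target = r$target, scheme = r$scheme,
               validation_accuracy_pct = if ("validation_accuracy_pct" %in% names(r))
                 r$validation_accuracy_pct else NA_real_,
               test_accuracy_pct = if ("test_accuracy_pct" %in% names(r))
                 r$test_accuracy_pct else r$mean_accuracy_pct,
               auc = r$auc, seed = r$seed)
  }))

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list(
    features = write_stamped_csv(feats, file.path(out_dir, "features.csv"),
                                 config, seed),
    descriptives = write_stamped_csv(stats_report$descriptives,
                                     file.path(out_dir, "descriptives.csv"),
                                     config, seed),
    tests = write_stamped_csv(stats_report$t_tests,
                              file.path(out_dir, "t_tests.csv"), config, seed),
    anova = write_stamped_csv(stats_report$anova,
                              file.path(out_dir, "anova.csv"), config, seed),
    correlations = write_stamped_csv(stats_report$correlations$correlations,
                                     file.path(out_dir, "correlations.csv"),
                                     config, seed),
    ml = write_stamped_csv(ml_report, file.path(out_dir, "ml_report.csv"),
                           config, seed))
  json_path <- file.path(out_dir, "ml_report.json")
  jsonlite::write_json(ml_report, json_path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  files$ml_json <- json_path

  txt <- file.path(out_dir, "report.txt")
  con <- file(txt, "w")
  writeLines(paste0("# ", output_header(config, seed)), con)
  sink(con)
  print(stats_report)
  cat("\nClassifier report:\n")
  print(ml_report, row.names = FALSE)
  sink()
  close(con)
  files$report <- txt

  invisible(list(features = feats, stats = stats_report, ml = ml_report,
                 files = files))
}

#' Load a pipeline configuration from a YAML file
#'
#' Reads a YAML mapping of [pipeline_config()] arguments.  Model entries
#' under `ml_models` are lists of [model_spec()] arguments; profile
#' entries under `profiles` are lists of [group_profile()] arguments.
#' Unspecified fields keep their defaults.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw
  if (!is.null(raw$ml_models)) {
    args$ml_models <- lapply(raw$ml_models, function(m) do.call(model_spec, m))
  }
  if (!is.null(raw$profiles)) {
    args$profiles <- lapply(raw$profiles, function(p) do.call(group_profile, p))
  }
  if (!is.null(raw$ml_split)) args$ml_split <- unlist(raw$ml_split)
  do.call(pipeline_config, args)
}
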