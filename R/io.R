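#' Ingestion settings for device trial files
#'
#' Controls how raw toe-dynamometer trial files are parsed and repaired.
#' The device records force at 50 Hz for 10 s, so a complete trial holds
#' 500 samples.  Occasionally a trial file ends a few samples short; gaps
#' at the end of the trial are filled with the last recorded value, but
#' only when the gap is shorter than `max_end_gap` samples.  Gaps anywhere
#' else in the trial are treated as corruption and rejected.
#'
#' @param expected_samples Number of samples in a complete trial (500).
#' @param sampling_hz Nominal sampling rate in Hz (50).
#' @param max_end_gap Strict upper bound on the number of imputable trailing
#'   samples: a gap of `max_end_gap` or more is an error (default 10, so up
#'   to 9 samples may be imputed).
#' @param hz_tol Relative tolerance on the inferred sampling rate before a
#'   warning is raised (default 0.01, i.e. 1%).
#' @return A list of class `ingest_config`.
#' @export
ingest_config <- function(expected_samples = 500L, sampling_hz = 50,
                          max_end_gap = 10L, hz_tol = 0.01) {
  stopifnot(expected_samples >= 1, sampling_hz > 0,
            max_end_gap >= 1, hz_tol >= 0)
  structure(list(expected_samples = as.integer(expected_samples),
                 sampling_hz = sampling_hz,
                 max_end_gap = as.integer(max_end_gap),
                 hz_tol = hz_tol),
            class = "ingest_config")
}

#' Construct a force trial
#'
#' A `force_trial` is one subject's recorded force--time series together
#' with its sampling metadata: a strictly increasing time vector (seconds),
#' a force vector of the same length (kilograms as recorded by the device,
#' or newtons after conversion), and a count of trailing samples that were
#' imputed at ingestion.
#'
#' @param subject_id Subject identifier string.
#' @param time Strictly increasing numeric vector of sample times (s).
#' @param force Numeric vector of forces, same length as `time`.
#' @param unit `"kg"` (device native) or `"N"`.
#' @param sampling_hz Sampling rate in Hz; inferred from the median time
#'   step when `NULL`.
#' @param imputed_count Number of trailing samples filled by imputation.
#' @param flags Character vector of quality flags.
#' @return An object of class `force_trial`.
#' @seealso [read_trial()], [write_trial()], [to_newtons()]
#' @export
force_trial <- function(subject_id, time, force, unit = c("kg", "N"),
                        sampling_hz = NULL, imputed_count = 0L,
                        flags = character()) {
  unit <- match.arg(unit)
  time <- as.numeric(time)
  force <- as.numeric(force)
  if (length(time) != length(force)) {
    stop_toeforce("time and force must have equal length", "trial_structure_error")
  }
  if (length(time) < 2L) {
    stop_toeforce("a trial needs at least two samples", "trial_structure_error")
  }
  if (any(!is.finite(time)) || any(diff(time) <= 0)) {
    stop_toeforce("time must be finite and strictly increasing", "trial_structure_error")
  }
  if (any(!is.finite(force))) {
    stop_toeforce("all forces must be finite", "trial_structure_error")
  }
  if (is.null(sampling_hz)) sampling_hz <- 1 / stats::median(diff(time))
  structure(list(subject_id = as.character(subject_id),
                 time = time, force = force, unit = unit,
                 sampling_hz = sampling_hz,
                 expected_samples = length(force),
                 imputed_count = as.integer(imputed_count),
                 flags = flags),
            class = "force_trial")
}

#' @export
print.force_trial <- function(x, ...) {
  cat(sprintf("<force_trial> subject %s: %d samples @ %.3g Hz, unit %s",
              x$subject_id, length(x$force), x$sampling_hz, x$unit))
  if (x$imputed_count > 0) cat(sprintf(", %d imputed", x$imputed_count))
  if (length(x$flags)) cat(" [", paste(x$flags, collapse = ","), "]", sep = "")
  cat(sprintf("\n  force range [%.3g, %.3g]\n", min(x$force), max(x$force)))
  invisible(x)
}

#' Impute a short trailing gap with the last recorded value
#'
#' Device trials occasionally stop recording a few samples before the end
#' of the 10 s window.  When the gap is shorter than `max_end_gap` samples
#' it is filled by repeating the last available value, so that all trials
#' have the same number of samples; longer gaps are rejected.
#'
#' @param force Numeric vector of observed forces (the trial prefix).
#' @param expected_samples Target length after imputation.
#' @param max_end_gap Strict limit: the gap must be `< max_end_gap`.
#' @return A list with `force` (length `expected_samples`) and
#'   `imputed_count` (the gap size).
#' @examples
#' impute_tail(c(1, 2, 3), 5, 10)  # appends 3, 3
#' @export
impute_tail <- function(force, expected_samples, max_end_gap = 10L) {
  force <- as.numeric(force)
  if (length(force) == 0L) {
    stop_toeforce("cannot impute an empty trial", "trial_structure_error")
  }
  if (length(force) > expected_samples) {
    stop_toeforce(sprintf("trial has %d samples, more than the expected %d",
                          length(force), expected_samples),
                  "trial_structure_error")
  }
  gap <- expected_samples - length(force)
  if (gap >= max_end_gap) {
    stop_toeforce(sprintf(
      "end gap of %d samples reaches the imputation limit (%d); trial rejected",
      gap, max_end_gap), "end_gap_error")
  }
  list(force = c(force, rep(force[length(force)], gap)),
       imputed_count = as.integer(gap))
}

# Split one data line into numeric fields; `line_no` is the 1-based line
# number in the original file, used in parse-error messages.
parse_trial_line <- function(line, sep, line_no) {
  fields <- if (sep == ",") {
    trimws(strsplit(line, ",", fixed = TRUE)[[1]])
  } else {
    strsplit(trimws(line), "[ \t]+")[[1]]
  }
  fields <- fields[nzchar(fields)]
  vals <- suppressWarnings(as.numeric(fields))
  vals[toupper(fields) %in% c("NA", "NAN")] <- NA_real_
  if (length(vals) < 2L || any(is.na(vals[1:2]) & !toupper(fields[1:2]) %in% c("NA", "NAN"))) {
    stop_toeforce(sprintf("line %d: expected two numeric columns, got '%s'",
                          line_no, line), "trial_parse_error")
  }
  vals[1:2]
}

#' Read a device trial file
#'
#' Parses a plain-text trial file with two columns (time in seconds, force)
#' as written by portable toe dynamometers.  The delimiter (whitespace or
#' comma) is auto-detected, a single optional header line is skipped, and
#' lines starting with `#` are treated as comments.  The comments
#' `# subject: <id>` and `# unit: <kg|N>` are honoured when present;
#' otherwise the subject id is taken from the file name and the unit is
#' assumed to be the device-native kilograms.
#'
#' Trailing missing samples (a file shorter than `expected_samples`, or
#' non-finite values at the very end) are filled via [impute_tail()];
#' non-finite values anywhere else are rejected, as is a non-increasing
#' time column.  The sampling rate is inferred from the median time step
#' and a warning is raised when it deviates from the configured rate by
#' more than `hz_tol`.
#'
#' @param path Path to the trial file.
#' @param config An [ingest_config()].
#' @param subject_id Optional explicit subject id overriding file metadata.
#' @return A [force_trial()] with `expected_samples` samples.
#' @export
read_trial <- function(path, config = ingest_config(), subject_id = NULL) {
  if (!file.exists(path)) stop_toeforce(paste0("no such file: ", path), "trial_io_error")
  lines <- readLines(path, warn = FALSE)
  meta <- list()
  keep <- logical(length(lines))
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(\\S+)", ln))[[1]]
      if (length(m) == 3L) meta[[tolower(m[2])]] <- m[3]
      next
    }
    keep[i] <- TRUE
  }
  data_idx <- which(keep)
  if (length(data_idx) == 0L) stop_toeforce("file contains no data rows", "trial_parse_error")

  sep <- if (grepl(",", lines[data_idx[1]], fixed = TRUE)) "," else "ws"
  # optional single header line: first data line with a non-numeric token
  first_fields <- if (sep == ",") {
    trimws(strsplit(lines[data_idx[1]], ",", fixed = TRUE)[[1]])
  } else {
    strsplit(trimws(lines[data_idx[1]]), "[ \t]+")[[1]]
  }
  first_num <- suppressWarnings(as.numeric(first_fields))
  header <- any(is.na(first_num) & !toupper(first_fields) %in% c("NA", "NAN"))
  if (header) data_idx <- data_idx[-1]
  if (length(data_idx) == 0L) stop_toeforce("file contains no data rows", "trial_parse_error")

  rows <- vapply(data_idx, function(i) parse_trial_line(lines[i], sep, i),
                 numeric(2))
  time <- rows[1, ]
  force <- rows[2, ]

  if (any(!is.finite(time))) {
    stop_toeforce("non-finite values in the time column", "trial_structure_error")
  }
  if (any(diff(time) <= 0)) {
    stop_toeforce("time column is not strictly increasing", "trial_structure_error")
  }

  # trailing non-finite forces count as end-of-trial missingness
  n_obs <- length(force)
  last_ok <- n_obs
  while (last_ok >= 1L && !is.finite(force[last_ok])) last_ok <- last_ok - 1L
  if (last_ok == 0L) stop_toeforce("trial has no finite force values", "trial_structure_error")
  if (any(!is.finite(force[seq_len(last_ok)]))) {
    stop_toeforce(
      "non-finite force values in the interior of the trial; only end-of-trial gaps are imputable",
      "trial_gap_error")
  }
  force <- force[seq_len(last_ok)]
  time <- time[seq_len(last_ok)]

  imp <- impute_tail(force, config$expected_samples, config$max_end_gap)
  dt <- stats::median(diff(time))
  if (imp$imputed_count > 0) {
    time <- c(time, time[length(time)] + dt * seq_len(imp$imputed_count))
  }

  hz <- 1 / dt
  flags <- character()
  if (abs(hz - config$sampling_hz) / config$sampling_hz > config$hz_tol) {
    warning(sprintf("inferred sampling rate %.4g Hz deviates from the configured %g Hz",
                    hz, config$sampling_hz))
    flags <- c(flags, "sampling_rate_mismatch")
  }

  unit <- meta$unit %||% "kg"
  if (!unit %in% c("kg", "N")) {
    stop_toeforce(paste0("unknown force unit in file header: ", unit), "trial_parse_error")
  }
  sid <- subject_id %||% meta$subject %||% sub("\\.[^.]*$", "", basename(path))
  force_trial(sid, time, imp$force, unit = unit, sampling_hz = hz,
              imputed_count = imp$imputed_count, flags = flags)
}

#' Write a trial to a plain-text file
#'
#' Writes the two-column text format read by [read_trial()], with comment
#' headers recording the subject id and unit.  Values are written with
#' full double precision so that a write/read cycle reproduces the trial
#' exactly.
#'
#' @param trial A [force_trial()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "force_trial"))
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop_toeforce(paste0("cannot write to ", path), "trial_io_error")
  on.exit(close(con))
  writeLines(c(sprintf("# subject: %s", trial$subject_id),
               sprintf("# unit: %s", trial$unit),
               sprintf("time_s\tforce_%s", trial$unit),
               sprintf("%.17g\t%.17g", trial$time, trial$force)), con)
  invisible(path)
}

subject_columns <- c("subject_id", "age_group", "sex", "weight_kg",
                     "height_m", "bmi", "grip_strength_N")

#' Read and validate a subject metadata table
#'
#' Reads the cohort CSV with one row per participant: identifier, age
#' group (`older`/`younger`), sex (`male`/`female`), weight (kg), height
#' (m), BMI (kg/m^2) and grip strength (N).  Values outside the closed
#' vocabularies, duplicate ids, non-positive BMI or negative grip strength
#' are rejected.
#'
#' @param path Path to a CSV file with columns
#'   `subject_id, age_group, sex, weight_kg, height_m, bmi, grip_strength_N`.
#' @return A `data.frame` with one validated row per subject.
#' @export
read_subjects <- function(path) {
  if (!file.exists(path)) stop_toeforce(paste0("no such file: ", path), "subject_io_error")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  missing_cols <- setdiff(subject_columns, names(tab))
  if (length(missing_cols)) {
    stop_toeforce(paste0("subject table is missing required column(s): ",
                         paste(missing_cols, collapse = ", ")),
                  "subject_schema_error")
  }
  if (nrow(tab) == 0L) return(tab[, subject_columns, drop = FALSE])
  validate_subjects(tab[, subject_columns, drop = FALSE])
}

validate_subjects <- function(tab) {
  tab$subject_id <- as.character(tab$subject_id)
  if (anyDuplicated(tab$subject_id)) {
    stop_toeforce(paste0("duplicate subject_id: ",
                         paste(unique(tab$subject_id[duplicated(tab$subject_id)]),
                               collapse = ", ")),
                  "subject_schema_error")
  }
  bad_age <- !tab$age_group %in% c("older", "younger")
  if (any(bad_age)) {
    stop_toeforce(paste0("invalid age_group value(s): ",
                         paste(unique(tab$age_group[bad_age]), collapse = ", ")),
                  "subject_value_error")
  }
  bad_sex <- !tab$sex %in% c("male", "female")
  if (any(bad_sex)) {
    stop_toeforce(paste0("invalid sex value(s): ",
                         paste(unique(tab$sex[bad_sex]), collapse = ", ")),
                  "subject_value_error")
  }
  if (any(is.na(tab$bmi)) || any(tab$bmi <= 0)) {
    stop_toeforce("bmi must be present and > 0 for every subject", "subject_value_error")
  }
  if (any(is.na(tab$grip_strength_N)) || any(tab$grip_strength_N < 0)) {
    stop_toeforce("grip_strength_N must be present and >= 0", "subject_value_error")
  }
  tab
}

#' Write a subject metadata table
#'
#' @param subjects Data frame as returned by [read_subjects()].
#' @param path Output CSV path.
#' @param header_lines Optional comment lines written before the CSV header.
#' @return `path`, invisibly.
#' @export
write_subjects <- function(subjects, path, header_lines = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.csv(subjects, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
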