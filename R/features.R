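#' Convert a trial's forces from kilograms to newtons
#'
#' The device records force as an equivalent mass in kilograms; all
#' analyses are carried out in newtons.  Multiplies the force vector by
#' the gravitational acceleration `g`.  A trial already in newtons passes
#' through unchanged, so the operation is idempotent.
#'
#' @param trial A [force_trial()].
#' @param g Gravitational acceleration in m/s^2 (standard gravity by
#'   default).
#' @return The trial with `unit == "N"`.
#' @export
to_newtons <- function(trial, g = 9.80665) {
  stopifnot(inherits(trial, "force_trial"), g > 0)
  if (trial$unit == "N") return(trial)
  trial$force <- trial$force * g
  trial$unit <- "N"
  trial
}

#' Extract the five force-development-curve parameters
#'
#' Characterises one force--time curve by the five parameters used to
#' describe toe extension strength:
#'
#' * **peak force** -- the maximum sample (N);
#' * **rise time** -- the time of the first sample at or above 80% of the
#'   peak (s), measured from trial start;
#' * **average after threshold** -- the arithmetic mean of all samples from
#'   that first crossing (inclusive) to the end of the trial (N);
#' * **percent above average** -- the percentage of *all* samples in the
#'   trial at or above that average;
#' * **RFD** -- the rate of force development, defined as 80% of the peak
#'   divided by the rise time (N/s).
#'
#' The 80% cut-off standardises the rise-time measurement: near 80% of a
#' maximal voluntary contraction essentially all motor units of a muscle
#' group have been recruited, so the crossing marks the end of the
#' recruitment phase.  All comparisons use "at or above" (`>=`).
#'
#' If the very first sample already meets the threshold the rise time is
#' floored at one sampling interval (so the RFD stays finite) and the
#' trial is flagged `"rise_floor"`.  Trials with no strictly positive
#' sample carry no interpretable parameters and raise a
#' `degenerate_trial_error`.
#'
#' @param trial A [force_trial()] in newtons (convert with [to_newtons()]).
#' @param pct_reference Which average anchors the percent-above parameter:
#'   `"post_threshold"` (default) compares every sample against the
#'   post-crossing average; `"whole_trial"` compares against the mean of
#'   the full trial.
#' @return An object of class `curve_features`: a list with elements
#'   `peak_force`, `rise_time`, `avg_after_threshold`, `pct_above_avg`,
#'   `rfd`, `threshold`, `rise_index` and `flags`.
#' @examples
#' tr <- force_trial("ex", seq(0.02, 0.10, by = 0.02), c(0, 10, 20, 40, 50),
#'                   unit = "N")
#' extract_features(tr)
#' @export
extract_features <- function(trial,
                             pct_reference = c("post_threshold", "whole_trial")) {
  stopifnot(inherits(trial, "force_trial"))
  pct_reference <- match.arg(pct_reference)
  if (trial$unit != "N") {
    stop_toeforce("trial must be in newtons; apply to_newtons() first",
                  "trial_unit_error")
  }
  force <- trial$force
  time <- trial$time
  n <- length(force)
  if (all(force <= 0)) {
    stop_toeforce(sprintf("trial %s has no positive force sample; no curve parameters",
                          trial$subject_id),
                  "degenerate_trial_error")
  }

  peak <- max(force)
  threshold <- 0.8 * peak
  rise_index <- which(force >= threshold)[1L]

  flags <- character()
  dt <- 1 / trial$sampling_hz
  rise_time <- time[rise_index]
  if (rise_index == 1L) {      # first recorded sample already at threshold
    rise_time <- max(rise_time, dt)
    flags <- c(flags, "rise_floor")
  }

  avg_after <- mean(force[rise_index:n])
  reference <- switch(pct_reference,
                      post_threshold = avg_after,
                      whole_trial = mean(force))
  pct_above <- 100 * sum(force >= reference) / n
  rfd <- threshold / rise_time

  structure(list(peak_force = peak,
                 rise_time = rise_time,
                 avg_after_threshold = avg_after,
                 pct_above_avg = pct_above,
                 rfd = rfd,
                 threshold = threshold,
                 rise_index = rise_index,
                 pct_reference = pct_reference,
                 flags = flags),
            class = "curve_features")
}

#' @export
print.curve_features <- function(x, ...) {
  cat(sprintf(paste0("<curve_features> peak %.2f N, rise %.3f s, ",
                     "avg after 80%% %.2f N, %.1f%% >= avg, RFD %.2f N/s\n"),
              x$peak_force, x$rise_time, x$avg_after_threshold,
              x$pct_above_avg, x$rfd))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Build a per-subject feature table
#'
#' Extracts curve parameters from every trial and joins them to the
#' subject metadata.  Trials in kilograms are converted to newtons first.
#' Degenerate trials (no positive sample) are not silently dropped: they
#' are collected in the `"degenerate"` attribute of the result.
#'
#' @param trials List of [force_trial()] objects.
#' @param subjects Subject table as from [read_subjects()]; every trial's
#'   `subject_id` must appear in it.
#' @param g Gravitational acceleration used for unit conversion.
#' @param pct_reference Passed to [extract_features()].
#' @return A `data.frame` with one row per feature-bearing trial: columns
#'   `subject_id`, `peak_N`, `rise_time_s`, `avg_after80_N`,
#'   `pct_above_avg`, `rfd_N_per_s`, `flags`, plus the subject columns.
#'   Attribute `"degenerate"` lists excluded trials and the reason.
#' @export
features_table <- function(trials, subjects, g = 9.80665,
                           pct_reference = "post_threshold") {
  stopifnot(is.list(trials))
  ids <- vapply(trials, function(t) t$subject_id, character(1))
  unknown <- setdiff(ids, subjects$subject_id)
  if (length(unknown)) {
    stop_toeforce(paste0("trial subject id(s) not in subject table: ",
                         paste(unknown, collapse = ", ")),
                  "unmatched_subject_error")
  }
  rows <- list()
  degenerate <- data.frame(subject_id = character(), reason = character())
  for (tr in trials) {
    tr <- to_newtons(tr, g = g)
    fe <- tryCatch(extract_features(tr, pct_reference = pct_reference),
                   degenerate_trial_error = function(e) e)
    if (inherits(fe, "degenerate_trial_error")) {
      degenerate <- rbind(degenerate,
                          data.frame(subject_id = tr$subject_id,
                                     reason = conditionMessage(fe)))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = tr$subject_id,
      peak_N = fe$peak_force,
      rise_time_s = fe$rise_time,
      avg_after80_N = fe$avg_after_threshold,
      pct_above_avg = fe$pct_above_avg,
      rfd_N_per_s = fe$rfd,
      flags = paste(c(tr$flags, fe$flags), collapse = ";"))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character(), peak_N = numeric(),
               rise_time_s = numeric(), avg_after80_N = numeric(),
               pct_above_avg = numeric(), rfd_N_per_s = numeric(),
               flags = character())
  out <- merge(out, subjects, by = "subject_id", sort = TRUE)
  attr(out, "degenerate") <- degenerate
  out
}
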