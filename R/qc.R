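#' Drop the acclimation and final recording days
#'
#' The first recording day is treated as acclimation and the last as a day
#' of declining activity, so neither enters any analysis: both are removed
#' before rhythm or endpoint computation. Days are counted as consecutive
#' 24-h blocks from the first reading (recordings typically start mid-day);
#' a trailing partial block is removed together with the last complete day.
#' A 7-day series therefore yields 5 analysis days (7200 one-minute counts).
#'
#' @param series A [channel_series()] spanning at least 3 complete days.
#' @return The trimmed [channel_series()]; retained counts are untouched and
#'   `day_offset` is advanced so day labels stay aligned to recording days.
#' @export
trim_days <- function(series) {
  per_day <- 86400L %/% series$step
  n_days <- length(series$counts) %/% per_day
  if (n_days < 3L)
    stop(sprintf("series spans %d complete day(s); at least 3 are required to trim", n_days))
  keep <- (per_day + 1L):((n_days - 1L) * per_day)
  series$counts <- series$counts[keep]
  series$start <- series$start + per_day * series$step
  series$day_offset <- series$day_offset + 1L
  series
}

#' Flag an individual as dead
#'
#' An individual whose series contains 24 h of continuous inactivity (a run
#' of at least one full day of zero counts, 1440 consecutive zero minutes at
#' the 1-min step) is considered dead. The rule is evaluated on the full
#' untrimmed recording, so a death during the final day still flags the
#' individual.
#'
#' @param series A [channel_series()].
#' @return `TRUE` if a zero run of at least 24 h exists.
#' @export
flag_dead <- function(series) {
  need <- 86400L %/% series$step
  r <- rle(series$counts == 0L)
  any(r$values & r$lengths >= need)
}

#' Apply the cohort-level record filters
#'
#' Removes, in order: control tubes (empty tubes recording environmental
#' noise; a control tube with non-zero counts is additionally flagged as a
#' potential artifact), dead individuals per [flag_dead()], and individuals
#' from the inseminated arm whose post-hoc sperm check failed (i.e. females
#' that were not actually inseminated). Every removal is appended to the
#' cohort's QC log. The filter is idempotent.
#'
#' @param cohort A [cohort_table()].
#' @return The filtered [cohort_table()] with an extended `qc_log`.
#' @export
apply_cohort_filters <- function(cohort) {
  keep <- rep(TRUE, length(cohort$series))
  for (i in seq_along(cohort$series)) {
    s <- cohort$series[[i]]
    if (isTRUE(s$meta$is_control_tube)) {
      reason <- if (sum(s$counts) > 0)
        "control tube (non-zero counts: potential artifact)" else "control tube"
      cohort <- log_qc(cohort, s$individual_id, "removed", reason)
      keep[i] <- FALSE
    } else if (flag_dead(s)) {
      cohort <- log_qc(cohort, s$individual_id, "removed",
                       "dead: >= 24 h of continuous inactivity")
      keep[i] <- FALSE
    } else if (identical(s$meta$insemination, "inseminated") &&
               identical(s$meta$sperm_check, "failed")) {
      cohort <- log_qc(cohort, s$individual_id, "removed",
                       "sperm check failed: not inseminated")
      keep[i] <- FALSE
    }
  }
  cohort$series <- cohort$series[keep]
  cohort
}

#' Trim every series of a cohort
#'
#' @param cohort A [cohort_table()].
#' @return The cohort with [trim_days()] applied to each series.
#' @export
trim_cohort <- function(cohort) {
  cohort$series <- lapply(cohort$series, trim_days)
  cohort
}

#' Write the QC log as CSV
#'
#' @param cohort A [cohort_table()].
#' @param path Output CSV path.
#' @export
write_qc_log <- function(cohort, path) {
  utils::write.csv(cohort$qc_log, path, row.names = FALSE)
  invisible(path)
}
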