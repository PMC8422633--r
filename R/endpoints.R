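#' @keywords internal
# calendar dates (UTC) covered by a series
series_first_date <- function(series) {
  as.Date(format(series$start, "%Y-%m-%d", tz = "UTC"))
}

# indices into series$counts that fall in [date_d start_clock, date_d+k end_clock)
# where the window may cross midnight (end <= start means next day)
clock_window_indices <- function(series, day, start_clock, end_clock) {
  d0 <- series_first_date(series)
  start_h <- parse_clock(start_clock)
  end_h <- parse_clock(end_clock)
  w_start <- as.POSIXct(paste(d0 + (day - 1L)), tz = "UTC") + start_h * 3600
  w_end <- as.POSIXct(paste(d0 + (day - 1L) + (end_h <= start_h)), tz = "UTC") +
    end_h * 3600
  t0 <- as.numeric(series$start)
  i_start <- floor((as.numeric(w_start) - t0) / series$step) + 1
  i_end <- ceiling((as.numeric(w_end) - t0) / series$step)
  if (i_start < 1 || i_end > length(series$counts)) return(NULL)  # partial window
  seq.int(i_start, i_end)
}

# number of whole windows of that clock span contained in the series
n_clock_windows <- function(series, start_clock, end_clock) {
  n <- 0L
  repeat {
    if (is.null(clock_window_indices(series, n + 1L, start_clock, end_clock)))
      break
    n <- n + 1L
  }
  n
}

#' Format a minute of day as "HH:MM"
#'
#' @param min_of_day Numeric minute(s) of day (0-1439), NA allowed.
#' @return Character "HH:MM" (NA preserved).
#' @export
fmt_clock <- function(min_of_day) {
  ifelse(is.na(min_of_day), NA_character_,
         sprintf("%02d:%02d", as.integer(min_of_day) %/% 60L,
                 as.integer(min_of_day) %% 60L))
}

#' Select series of a cohort by metadata
#'
#' @param cohort A [cohort_table()].
#' @param ... Named metadata filters, e.g. `meal = "blood"`, `regimen = "LD"`.
#' @return A [cohort_table()] with the matching series.
#' @export
subset_cohort <- function(cohort, ...) {
  filters <- list(...)
  keep <- vapply(cohort$series, function(s)
    all(vapply(names(filters), function(k)
      identical(s$meta[[k]], filters[[k]]), logical(1))), logical(1))
  cohort_table(cohort$series[keep], cohort$schedule, cohort$qc_log)
}

#' Mean activity profile of a group
#'
#' Pointwise mean activity score across a group's individuals, by recording
#' day and clock minute — the quantity plotted in group actograms.
#'
#' @param cohort A trimmed [cohort_table()]; all series must share the time
#'   grid.
#' @param ... Optional metadata filters passed to [subset_cohort()].
#' @return Data frame with columns `day` (within-series day), `clock_min`
#'   (minute of day, 0-1439) and `mean_count`.
#' @export
mean_activity_profile <- function(cohort, ...) {
  co <- if (...length()) subset_cohort(cohort, ...) else cohort
  if (!length(co$series)) stop("empty group: no series match the filters")
  lens <- unique(vapply(co$series, function(s) length(s$counts), integer(1)))
  starts <- unique(vapply(co$series, function(s) as.numeric(s$start), numeric(1)))
  if (length(lens) > 1 || length(starts) > 1)
    stop("profile requires series on a common time grid")
  m <- Reduce(`+`, lapply(co$series, function(s) as.numeric(s$counts))) /
    length(co$series)
  s1 <- co$series[[1]]
  ts <- s1$start + (seq_along(m) - 1L) * s1$step
  per_day <- 86400L %/% s1$step
  data.frame(day = (seq_along(m) - 1L) %/% per_day + 1L,
             clock_min = minute_of_day(ts),
             mean_count = m)
}

#' Nightly activity in 5-minute bins
#'
#' Sums the 1-min activity scores of each analysis night into 5-min bins
#' over the night window 16:00 to 07:00 next day (180 bins, spanning ZT10
#' to ZT1 under the default schedule). Nights not fully covered by the
#' series are omitted and listed in the `omitted` attribute.
#'
#' @param series A trimmed [channel_series()] at 60-s step.
#' @param schedule A [light_schedule()] (window is clock-anchored; kept for
#'   interface symmetry).
#' @param night_window Clock window `c(start, end)` (default 16:00-07:00).
#' @param bin_min Bin width in minutes (default 5).
#' @return Integer matrix, one row per complete night (rownames = night
#'   labels, offset by `day_offset`), `(15*60)/bin_min` columns.
#' @export
nightly_activity <- function(series, schedule,
                             night_window = c("16:00", "07:00"), bin_min = 5) {
  stopifnot(series$step == 60L)
  span_min <- as.integer(((parse_clock(night_window[2]) -
                             parse_clock(night_window[1])) %% 24) * 60)
  n_bins <- span_min %/% bin_min
  rows <- list()
  omitted <- integer(0)
  d0 <- series_first_date(series)
  n_cal_days <- as.integer(ceiling(length(series$counts) * series$step / 86400)) + 1L
  for (d in seq_len(n_cal_days)) {
    idx <- clock_window_indices(series, d, night_window[1], night_window[2])
    if (is.null(idx)) {
      # distinguish "window would start inside coverage" -> partial, log it
      w_start <- as.POSIXct(paste(d0 + (d - 1L)), tz = "UTC") +
        parse_clock(night_window[1]) * 3600
      end_ts <- series$start + length(series$counts) * series$step
      if (w_start >= series$start && w_start < end_ts)
        omitted <- c(omitted, d + series$day_offset)
      next
    }
    x <- series$counts[idx]
    rows[[as.character(d + series$day_offset)]] <-
      as.integer(rowsum(x, rep(seq_len(n_bins), each = bin_min)))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- matrix(integer(0), nrow = 0, ncol = n_bins)
  attr(out, "omitted") <- omitted
  attr(out, "bin_min") <- bin_min
  out
}

#' Onset of sustained activity at dusk
#'
#' The onset of activity is the first minute of the dusk search window from
#' which the individual produces at least 1 beam break per minute for 3
#' consecutive minutes; the run must lie entirely inside the window.
#' Returns the clock minute of that first minute, or NA when no such run
#' exists.
#'
#' @param series A [channel_series()] at 60-s step.
#' @param day Within-series day (1-based; labels shift by `day_offset`).
#' @param schedule A [light_schedule()].
#' @param window Clock search window (default 17:00-19:30: start of the
#'   artificial dusk ramp through the end of the peak window).
#' @param run_min Required run length in minutes (default 3).
#' @return Minute of day (0-1439) of onset, or NA.
#' @export
onset_time <- function(series, day, schedule, window = c("17:00", "19:30"),
                       run_min = 3L) {
  stopifnot(series$step == 60L)
  idx <- clock_window_indices(series, day, window[1], window[2])
  if (is.null(idx)) return(NA_real_)
  x <- series$counts[idx] >= 1L
  if (length(x) < run_min) return(NA_real_)
  run <- stats::filter(as.numeric(x), rep(1, run_min), sides = 1)
  hit <- which(run == run_min)[1]
  if (is.na(hit)) return(NA_real_)
  m <- idx[hit - run_min + 1L]
  ts <- series$start + (m - 1L) * series$step
  minute_of_day(ts)
}

#' Time of peak dusk activity
#'
#' Clock time of the maximum 1-min activity score within the dusk peak
#' window: 17:30-19:30 under LD and 16:30-19:30 under DD (the free-running
#' dusk peak drifts earlier). Ties resolve to the earliest time; an
#' all-zero window yields NA.
#'
#' @param series A [channel_series()] at 60-s step.
#' @param day Within-series day (1-based).
#' @param schedule A [light_schedule()].
#' @param window Clock window override; default depends on the series'
#'   regimen (falling back to the schedule's).
#' @return Minute of day (0-1439) of the peak, or NA.
#' @export
peak_time <- function(series, day, schedule, window = NULL) {
  stopifnot(series$step == 60L)
  if (is.null(window)) {
    regimen <- series$meta$regimen
    if (is.na(regimen)) regimen <- schedule$regimen
    window <- if (identical(regimen, "DD")) c("16:30", "19:30")
              else c("17:30", "19:30")
  }
  idx <- clock_window_indices(series, day, window[1], window[2])
  if (is.null(idx)) return(NA_real_)
  x <- series$counts[idx]
  if (all(x == 0L)) return(NA_real_)
  m <- idx[which.max(x)]  # which.max takes the earliest maximum
  minute_of_day(series$start + (m - 1L) * series$step)
}

#' Per-individual, per-day endpoint table
#'
#' @param cohort A trimmed, QC-filtered [cohort_table()].
#' @param onset_window Clock window for [onset_time()].
#' @return Data frame: `individual_id`, treatment factors, `day` (recording
#'   day label), `onset_min`, `onset_clock`, `peak_min`, `peak_clock`,
#'   `nightly_total`.
#' @export
endpoint_table <- function(cohort, onset_window = c("17:00", "19:30")) {
  rows <- lapply(cohort$series, function(s) {
    nights <- nightly_activity(s, cohort$schedule)
    n_days <- n_clock_windows(s, onset_window[1], onset_window[2])
    if (!n_days) return(NULL)
    dd <- seq_len(n_days)
    onset <- vapply(dd, function(d) onset_time(s, d, cohort$schedule,
                                               window = onset_window), numeric(1))
    peak <- vapply(dd, function(d) peak_time(s, d, cohort$schedule), numeric(1))
    labels <- dd + s$day_offset
    tot <- rowSums(nights)[as.character(labels)]
    data.frame(individual_id = s$individual_id,
               insemination = s$meta$insemination, meal = s$meta$meal,
               regimen = s$meta$regimen, day = labels,
               onset_min = onset, onset_clock = fmt_clock(onset),
               peak_min = peak, peak_clock = fmt_clock(peak),
               nightly_total = unname(tot),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Long-format nightly 5-min counts for modelling
#'
#' @param cohort A trimmed, QC-filtered [cohort_table()].
#' @param ... Passed to [nightly_activity()].
#' @return Data frame: `individual_id`, treatment factors, `night`, `bin`,
#'   `count` (per 5 min).
#' @export
nightly_table <- function(cohort, ...) {
  rows <- lapply(cohort$series, function(s) {
    m <- nightly_activity(s, cohort$schedule, ...)
    if (!nrow(m)) return(NULL)
    data.frame(individual_id = s$individual_id,
               insemination = s$meta$insemination, meal = s$meta$meal,
               regimen = s$meta$regimen,
               night = rep(as.integer(rownames(m)), each = ncol(m)),
               bin = rep(seq_len(ncol(m)), times = nrow(m)),
               count = as.integer(t(m)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
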