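#' One individual's beam-break count series
#'
#' The elementary record of the pipeline: a regular-grid series of
#' non-negative beam-break counts ("activity scores") for one individual in
#' one monitor channel, together with its treatment metadata.
#'
#' @param individual_id Unique individual identifier.
#' @param monitor_id Monitor (file) identifier.
#' @param channel Channel number, 1-32.
#' @param start POSIXct timestamp (UTC) of the first reading.
#' @param counts Integer vector of beam-break counts, one per time step.
#' @param step Sampling step in seconds; must divide 86400 (default 60).
#' @param meta Named list of treatment metadata: `insemination` ("virgin" or
#'   "inseminated"), `meal` ("glucose" or "blood"), `regimen` ("LD" or "DD"),
#'   `is_control_tube` (logical), optionally `sperm_check` ("passed"/"failed").
#' @param day_offset Number of recording days preceding the first retained
#'   day (set by [trim_days()]); used only for day labelling.
#' @return An object of class `channel_series`.
#' @export
channel_series <- function(individual_id, monitor_id, channel, start, counts,
                           step = 60L, meta = list(), day_offset = 0L) {
  counts <- as.integer(counts)
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative integers")
  if (86400L %% as.integer(step) != 0L)
    stop("step must divide 86400 seconds")
  if (!(is.numeric(channel) && channel >= 1 && channel <= 32))
    stop("channel must be in 1..32")
  start <- as.POSIXct(start, tz = "UTC")
  meta <- utils::modifyList(
    list(insemination = NA_character_, meal = NA_character_,
         regimen = NA_character_, is_control_tube = FALSE,
         sperm_check = NA_character_),
    meta)
  structure(
    list(individual_id = as.character(individual_id),
         monitor_id = as.character(monitor_id),
         channel = as.integer(channel),
         start = start, step = as.integer(step),
         counts = counts, meta = meta,
         day_offset = as.integer(day_offset)),
    class = "channel_series")
}

#' @export
print.channel_series <- function(x, ...) {
  cat(sprintf("<channel_series> %s (monitor %s ch %d): %d counts @ %ds from %s; %s/%s/%s%s\n",
              x$individual_id, x$monitor_id, x$channel, length(x$counts),
              x$step, format(x$start, "%Y-%m-%d %H:%M", tz = "UTC"),
              x$meta$insemination, x$meta$meal, x$meta$regimen,
              if (isTRUE(x$meta$is_control_tube)) " [control]" else ""))
  invisible(x)
}

#' A cohort of channel series with its schedule and QC log
#'
#' @param series List of [channel_series()] objects; individual ids must be
#'   unique and all series must share the sampling step.
#' @param schedule A [light_schedule()].
#' @param qc_log Data frame with columns `individual_id`, `action`, `reason`
#'   recording removals and notes; grown by the QC filters.
#' @return An object of class `cohort_table`.
#' @export
cohort_table <- function(series, schedule, qc_log = empty_qc_log()) {
  stopifnot(inherits(schedule, "light_schedule"))
  ids <- vapply(series, `[[`, character(1), "individual_id")
  if (anyDuplicated(ids)) stop("individual ids must be unique within a cohort")
  steps <- vapply(series, `[[`, integer(1), "step")
  if (length(series) && length(unique(steps)) != 1L)
    stop("all series in a cohort must share the sampling step")
  names(series) <- ids
  structure(list(series = series, schedule = schedule, qc_log = qc_log),
            class = "cohort_table")
}

empty_qc_log <- function() {
  data.frame(individual_id = character(), action = character(),
             reason = character(), stringsAsFactors = FALSE)
}

log_qc <- function(cohort, individual_id, action, reason) {
  cohort$qc_log <- rbind(cohort$qc_log,
                         data.frame(individual_id = individual_id,
                                    action = action, reason = reason,
                                    stringsAsFactors = FALSE))
  cohort
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d series (%s), %d QC log entries\n",
              length(x$series), x$schedule$regimen, nrow(x$qc_log)))
  invisible(x)
}

#' @export
length.cohort_table <- function(x) length(x$series)

# locale-proof month handling for the monitor-file date field
.MONTHS <- c("Jan", "Feb", "Mar", "Apr", "May", "Jun",
             "Jul", "Aug", "Sep", "Oct", "Nov", "Dec")

format_monitor_date <- function(ts) {
  lt <- as.POSIXlt(ts, tz = "UTC")
  sprintf("%d %s %02d", lt$mday, .MONTHS[lt$mon + 1L], lt$year %% 100L)
}

parse_monitor_timestamp <- function(date_str, time_str) {
  dp <- strsplit(date_str, " ", fixed = TRUE)
  bad <- vapply(dp, length, integer(1)) != 3L
  if (any(bad)) stop("malformed date field: ", date_str[bad][1])
  day <- as.integer(vapply(dp, `[`, character(1), 1))
  mon <- match(vapply(dp, `[`, character(1), 2), .MONTHS)
  yy <- as.integer(vapply(dp, `[`, character(1), 3))
  if (any(is.na(day)) || any(is.na(mon)) || any(is.na(yy)))
    stop("malformed date field")
  year <- ifelse(yy < 70, 2000L + yy, 1900L + yy)
  as.POSIXct(sprintf("%04d-%02d-%02d %s", year, mon, day, time_str),
             tz = "UTC")
}

#' Read a tab-delimited activity-monitor file
#'
#' Parses the TriKinetics-style "Monitor" dialect: one row per reading with
#' a reading index, a date (`d Mon yy`), a time (`HH:MM:SS`), one or more
#' status fields, and 32 integer channel-count columns. The 32 counts are
#' taken from the last 32 tab-separated fields of each row, so firmware
#' variants that insert extra status columns are tolerated (a note is
#' emitted when extra columns are present). Readings must form a gap-free
#' regular grid at `step` seconds in file order.
#'
#' @param path Path to the monitor file.
#' @param channel_meta Data frame mapping channels to individuals, with
#'   columns `monitor_id`, `channel`, `individual_id`, `insemination`,
#'   `meal`, `regimen`, `is_control_tube` and optionally `sperm_check`.
#' @param schedule A [light_schedule()].
#' @param monitor_id Monitor identifier used to look up `channel_meta`;
#'   defaults to the file name without extension.
#' @param step Expected sampling step in seconds (default 60).
#' @return A [cohort_table()] with one series per mapped channel (control
#'   tubes included, flagged via `is_control_tube`). Unmapped channels are
#'   skipped with a warning.
#' @export
read_monitor_file <- function(path, channel_meta, schedule,
                              monitor_id = sub("\\.[^.]*$", "", basename(path)),
                              step = 60L) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(cohort_table(list(), schedule))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, integer(1))
  if (any(nf < 36L))
    stop(sprintf("parse error at line %d: expected >= 36 tab-separated fields, got %d",
                 which(nf < 36L)[1], nf[nf < 36L][1]))
  if (any(nf > 36L))
    message(sprintf("note [%s]: %d extra status column(s) ignored",
                    monitor_id, max(nf) - 36L))
  n <- length(fields)
  date_str <- vapply(fields, `[`, character(1), 2)
  time_str <- vapply(fields, `[`, character(1), 3)
  ts <- parse_monitor_timestamp(date_str, time_str)
  if (anyNA(ts)) stop(sprintf("parse error at line %d: bad timestamp", which(is.na(ts))[1]))
  d <- diff(as.numeric(ts))
  if (any(d == 0))
    stop(sprintf("duplicate timestamp at %s",
                 format(ts[which(d == 0)[1] + 1L], "%Y-%m-%d %H:%M:%S", tz = "UTC")))
  if (any(d != step)) {
    i <- which(d != step)[1]
    stop(sprintf("gap in time grid: missing reading(s) after %s",
                 format(ts[i], "%Y-%m-%d %H:%M:%S", tz = "UTC")))
  }
  counts <- matrix(NA_integer_, nrow = n, ncol = 32L)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    v <- suppressWarnings(as.integer(f[(length(f) - 31L):length(f)]))
    if (anyNA(v) || any(v < 0))
      stop(sprintf("parse error at line %d: channel counts must be non-negative integers", i))
    counts[i, ] <- v
  }
  cm <- channel_meta[channel_meta$monitor_id == monitor_id, , drop = FALSE]
  mapped <- intersect(seq_len(32L), cm$channel)
  unmapped_active <- setdiff(which(colSums(counts) > 0), mapped)
  if (length(unmapped_active))
    warning(sprintf("monitor %s: skipping unmapped channel(s) with activity: %s",
                    monitor_id, paste(unmapped_active, collapse = ", ")))
  series <- list()
  for (ch in mapped) {
    row <- cm[cm$channel == ch, , drop = FALSE][1, ]
    meta <- list(insemination = as.character(row$insemination),
                 meal = as.character(row$meal),
                 regimen = as.character(row$regimen),
                 is_control_tube = as.logical(row$is_control_tube))
    if ("sperm_check" %in% names(row))
      meta$sperm_check <- as.character(row$sperm_check)
    series[[length(series) + 1L]] <-
      channel_series(row$individual_id, monitor_id, ch, ts[1], counts[, ch],
                     step = step, meta = meta)
  }
  cohort_table(series, schedule)
}

#' Write a cohort back to the monitor-file dialect
#'
#' Serialises all series of one monitor to the same tab-delimited dialect
#' read by [read_monitor_file()] (reading index, date, time, a status column
#' of 1, then 32 channel counts; unassigned channels are written as zeros).
#' Reading a written file recovers the counts exactly.
#'
#' @param cohort A [cohort_table()] whose series belong to a single monitor
#'   and share the same time grid.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_monitor_file <- function(cohort, path) {
  if (!length(cohort$series)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  mons <- unique(vapply(cohort$series, `[[`, character(1), "monitor_id"))
  if (length(mons) > 1)
    stop("write_monitor_file() writes one monitor; use write_cohort_files() for several")
  chans <- vapply(cohort$series, `[[`, integer(1), "channel")
  if (length(chans) > 32L || anyDuplicated(chans))
    stop("a monitor holds at most 32 channels, each assigned once")
  starts <- unique(vapply(cohort$series, function(s) as.numeric(s$start), numeric(1)))
  lens <- unique(vapply(cohort$series, function(s) length(s$counts), integer(1)))
  if (length(starts) > 1 || length(lens) > 1)
    stop("all series must share the same time grid")
  n <- lens[1]
  step <- cohort$series[[1]]$step
  ts <- cohort$series[[1]]$start + (seq_len(n) - 1L) * step
  counts <- matrix(0L, nrow = n, ncol = 32L)
  for (s in cohort$series) counts[, s$channel] <- s$counts
  rows <- paste(seq_len(n),
                format_monitor_date(ts),
                format(ts, "%H:%M:%S", tz = "UTC"),
                1L,
                apply(counts, 1, paste, collapse = "\t"),
                sep = "\t")
  writeLines(rows, path)
  invisible(path)
}

#' Write a multi-monitor cohort as monitor files plus channel metadata
#'
#' @param cohort A [cohort_table()].
#' @param dir Output directory (created if needed).
#' @return Named list with `monitor_files` and `channel_meta` paths.
#' @export
write_cohort_files <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mons <- unique(vapply(cohort$series, `[[`, character(1), "monitor_id"))
  files <- character(0)
  for (m in mons) {
    keep <- vapply(cohort$series, function(s) s$monitor_id == m, logical(1))
    sub <- cohort_table(cohort$series[keep], cohort$schedule)
    f <- file.path(dir, paste0(m, ".txt"))
    write_monitor_file(sub, f)
    files[m] <- f
  }
  meta <- channel_meta_table(cohort)
  meta_path <- file.path(dir, "channel_meta.csv")
  utils::write.csv(meta, meta_path, row.names = FALSE)
  invisible(list(monitor_files = files, channel_meta = meta_path))
}

#' Channel metadata table of a cohort
#'
#' @param cohort A [cohort_table()].
#' @return Data frame in the layout expected by [read_monitor_file()].
#' @export
channel_meta_table <- function(cohort) {
  do.call(rbind, lapply(cohort$series, function(s) {
    data.frame(monitor_id = s$monitor_id, channel = s$channel,
               individual_id = s$individual_id,
               insemination = s$meta$insemination, meal = s$meta$meal,
               regimen = s$meta$regimen,
               is_control_tube = s$meta$is_control_tube,
               sperm_check = s$meta$sperm_check %||% NA_character_,
               stringsAsFactors = FALSE)
  }))
}

#' Read a multi-monitor cohort written by [write_cohort_files()]
#'
#' @param dir Directory holding `<monitor_id>.txt` files and `channel_meta.csv`.
#' @param schedule A [light_schedule()].
#' @param step Sampling step in seconds.
#' @return A combined [cohort_table()].
#' @export
read_cohort_files <- function(dir, schedule, step = 60L) {
  meta <- utils::read.csv(file.path(dir, "channel_meta.csv"),
                          stringsAsFactors = FALSE)
  series <- list()
  for (m in unique(meta$monitor_id)) {
    co <- read_monitor_file(file.path(dir, paste0(m, ".txt")), meta, schedule,
                            monitor_id = m, step = step)
    series <- c(series, co$series)
  }
  cohort_table(series, schedule)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
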