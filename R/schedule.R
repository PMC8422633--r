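#' Light schedule for an activity-monitor experiment
#'
#' Describes the photic regimen of a recording run: an LD (light:dark 12:12)
#' cycle with linear twilight ramps, or DD (constant darkness), which keeps
#' the same nominal clock anchors so that "subjective" dusk and dawn remain
#' defined. The default schedule has lights off at 18:00 preceded by a 1-h
#' linear dusk ramp (17:00-18:00) and lights on at 06:00 preceded by a 1-h
#' dawn ramp (05:00-06:00), i.e. 11 h full light, 11 h full darkness and two
#' 1-h twilights.
#'
#' Reference time (Zeitgeber time under LD, circadian time under DD) is
#' anchored at lights off by default, so 18:00 is ZT0 and 06:00 is ZT12.
#' Set `zt0_anchor = "lights_on"` for the alternative convention that puts
#' ZT0 at lights on.
#'
#' @param regimen "LD" or "DD".
#' @param lights_off Clock time of lights off, "HH:MM" (default "18:00").
#' @param lights_on Clock time of lights on, "HH:MM" (default "06:00").
#' @param dusk_ramp_min Length of the linear dusk ramp ending at lights off,
#'   minutes (default 60).
#' @param dawn_ramp_min Length of the linear dawn ramp ending at lights on,
#'   minutes (default 60).
#' @param zt0_anchor Which light transition defines reference time zero,
#'   "lights_off" (default) or "lights_on".
#' @return An object of class `light_schedule`.
#' @examples
#' sch <- light_schedule("LD")
#' to_reference_time("18:00", sch)  # 0
#' to_reference_time("06:00", sch)  # 12
#' @export
light_schedule <- function(regimen = c("LD", "DD"),
                           lights_off = "18:00",
                           lights_on = "06:00",
                           dusk_ramp_min = 60,
                           dawn_ramp_min = 60,
                           zt0_anchor = c("lights_off", "lights_on")) {
  regimen <- match.arg(regimen)
  zt0_anchor <- match.arg(zt0_anchor)
  off_h <- parse_clock(lights_off)
  on_h <- parse_clock(lights_on)
  if (dusk_ramp_min < 0 || dawn_ramp_min < 0)
    stop("twilight ramps must be non-negative")
  if (isTRUE(all.equal(off_h, on_h)))
    stop("lights_off and lights_on must differ")
  scoto_h <- (on_h - off_h) %% 24   # lights-off -> lights-on span
  photo_h <- 24 - scoto_h
  if (dusk_ramp_min / 60 >= photo_h)
    stop("dusk ramp longer than the photophase")
  if (dawn_ramp_min / 60 >= scoto_h)
    stop("dawn ramp longer than the scotophase")
  structure(
    list(regimen = regimen,
         lights_off = lights_off, lights_on = lights_on,
         lights_off_h = off_h, lights_on_h = on_h,
         dusk_ramp_min = dusk_ramp_min, dawn_ramp_min = dawn_ramp_min,
         zt0_anchor = zt0_anchor),
    class = "light_schedule")
}

#' @export
print.light_schedule <- function(x, ...) {
  cat(sprintf("<light_schedule> %s; lights off %s (dusk ramp %d min), lights on %s (dawn ramp %d min); ZT0 at %s\n",
              x$regimen, x$lights_off, x$dusk_ramp_min,
              x$lights_on, x$dawn_ramp_min, x$zt0_anchor))
  invisible(x)
}

# "HH:MM[:SS]" -> decimal hours; numeric input passes through modulo 24
parse_clock <- function(x) {
  if (is.numeric(x)) return(x %% 24)
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    p <- suppressWarnings(as.numeric(p))
    if (any(is.na(p)) || length(p) < 2 || length(p) > 3)
      stop("clock times must be 'HH:MM' or 'HH:MM:SS'")
    (p[1] + p[2] / 60 + if (length(p) == 3) p[3] / 3600 else 0) %% 24
  }, numeric(1))
}

#' Convert clock time to reference time (ZT or CT)
#'
#' Maps wall-clock time onto Zeitgeber time (LD) or circadian time (DD)
#' hours in `[0, 24)`, with hour 0 at the schedule's anchor transition
#' (lights off by default, so 18:00 -> 0 and 06:00 -> 12).
#'
#' @param clock A POSIXct timestamp, an "HH:MM[:SS]" string, or numeric
#'   hours of day; vectors allowed.
#' @param schedule A [light_schedule()].
#' @return Numeric reference hours in `[0, 24)`.
#' @export
to_reference_time <- function(clock, schedule) {
  stopifnot(inherits(schedule, "light_schedule"))
  h <- clock_hours(clock)
  anchor <- if (schedule$zt0_anchor == "lights_off") schedule$lights_off_h
            else schedule$lights_on_h
  (h - anchor) %% 24
}

# any clock-like input -> decimal hours of day
clock_hours <- function(clock) {
  if (inherits(clock, "POSIXt")) {
    lt <- as.POSIXlt(clock, tz = "UTC")
    lt$hour + lt$min / 60 + lt$sec / 3600
  } else if (is.character(clock)) {
    parse_clock(clock)
  } else if (is.numeric(clock)) {
    clock %% 24
  } else stop("unsupported clock representation")
}

# minute of day (0..1439) for a POSIXct vector
minute_of_day <- function(ts) {
  lt <- as.POSIXlt(ts, tz = "UTC")
  lt$hour * 60L + lt$min
}
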