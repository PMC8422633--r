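#' Simulation parameters for one treatment group
#'
#' Generative parameters of the synthetic actogram model. The expected
#' activity (counts per minute) of a rhythmic individual is
#'
#'   lambda(t) = baseline * (1 + dusk_amp * exp(-dt_dusk/dusk_decay)
#'                             + dawn_amp * 1[LD] * exp(-dt_dawn/dusk_decay)
#'                             + (night_plateau - 1) * 1[scotophase])
#'                        * suppression(t)
#'
#' where dt_dusk is the time since the most recent (possibly delayed) dusk
#' anchor. Under LD the anchors recur every 24 h at the schedule's clock
#' times; under DD they recur every tau hours, so the dusk burst drifts
#' earlier each subjective day when tau < 24, and the dawn burst is absent.
#' Blood-fed individuals have activity multiplied by `blood_suppression`
#' until `recovery_h` hours after recording start, then linearly recover to
#' 1 over `recovery_ramp_h`. Arrhythmic individuals emit flat baseline
#' activity. Counts are negative-binomially distributed around lambda.
#'
#' @param baseline_rate Baseline (daytime) expected counts/min (default
#'   0.05; daytime activity is near-nil in this system).
#' @param dusk_amp Dusk burst multiplier (default 60, making the dusk peak
#'   the dominant actogram feature).
#' @param dusk_decay_min Exponential decay constant of the bursts, minutes
#'   (default 30, giving a 1-2 h visible burst).
#' @param dawn_amp Dawn burst multiplier, LD only (default 30).
#' @param night_plateau Multiplicative activity level during (subjective)
#'   night (default 10, i.e. 0.5 counts/min of sustained night activity).
#' @param tau_h Free-running period in DD, hours (default 23; LD individuals
#'   are entrained to 24 h regardless).
#' @param tau_sd_h Between-individual SD of tau in DD (default 0.3),
#'   truncated to 21-25 h.
#' @param onset_delay_min Delay delta of the dusk anchor, minutes (default 0).
#' @param blood_suppression Activity multiplier after a blood meal
#'   (default 1 = no suppression; blood-fed groups use 0.2).
#' @param recovery_h Hours of full suppression after recording start
#'   (default 72).
#' @param recovery_ramp_h Hours over which suppression then ramps back to 1
#'   (default 24).
#' @param p_arrhythmic Probability an individual is arrhythmic (default 0.03).
#' @param nb_dispersion Negative-binomial size parameter (default 2;
#'   `Inf` gives Poisson counts).
#' @param n_per_group Individuals per group (default 25).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(baseline_rate = 0.05, dusk_amp = 60, dusk_decay_min = 30,
                       dawn_amp = 30, night_plateau = 10, tau_h = 23,
                       tau_sd_h = 0.3, onset_delay_min = 0,
                       blood_suppression = 1, recovery_h = 72,
                       recovery_ramp_h = 24, p_arrhythmic = 0.03,
                       nb_dispersion = 2, n_per_group = 25) {
  cfg <- as.list(environment())
  stopifnot(baseline_rate >= 0, dusk_amp >= 0, dawn_amp >= 0,
            night_plateau >= 0, blood_suppression >= 0,
            p_arrhythmic >= 0, p_arrhythmic <= 1, nb_dispersion > 0)
  structure(cfg, class = "sim_config")
}

#' Expected activity rate of the simulator
#'
#' @param t_min Minutes since recording start (vector).
#' @param params A [sim_config()].
#' @param schedule A [light_schedule()].
#' @param regimen "LD" or "DD" for this individual.
#' @param start_clock_min Clock minute of day at recording start.
#' @param tau_h Individual free-running period (defaults to `params$tau_h`).
#' @param arrhythmic If TRUE, the rate is flat baseline.
#' @return Expected counts/min at each `t_min`.
#' @export
intensity_function <- function(t_min, params, schedule, regimen = schedule$regimen,
                               start_clock_min = 780,
                               tau_h = params$tau_h, arrhythmic = FALSE) {
  if (arrhythmic) return(rep(params$baseline_rate, length(t_min)))
  dusk_clock <- schedule$lights_off_h * 60 + params$onset_delay_min
  dawn_clock <- schedule$lights_on_h * 60
  if (identical(regimen, "LD")) {
    clock <- (start_clock_min + t_min) %% 1440
    dt_dusk <- (clock - dusk_clock) %% 1440
    dt_dawn <- (clock - dawn_clock) %% 1440
    scoto <- ((clock - schedule$lights_off_h * 60) %% 1440) <
      ((schedule$lights_on_h * 60 - schedule$lights_off_h * 60) %% 1440)
    dawn_term <- params$dawn_amp * exp(-dt_dawn / params$dusk_decay_min)
  } else {
    period <- tau_h * 60
    u0 <- dusk_clock - start_clock_min  # first dusk anchor relative to start
    dt_dusk <- (t_min - u0) %% period
    scoto <- dt_dusk < period / 2
    dawn_term <- 0
  }
  lam <- params$baseline_rate *
    (1 + params$dusk_amp * exp(-dt_dusk / params$dusk_decay_min) +
       dawn_term + (params$night_plateau - 1) * scoto)
  if (params$blood_suppression < 1) {
    rec <- params$recovery_h * 60
    ramp <- params$recovery_ramp_h * 60
    s <- ifelse(t_min < rec, params$blood_suppression,
                pmin(1, params$blood_suppression +
                       (1 - params$blood_suppression) * (t_min - rec) / ramp))
    lam <- lam * s
  }
  lam
}

draw_counts <- function(lam, dispersion) {
  if (is.infinite(dispersion)) stats::rpois(length(lam), lam)
  else stats::rnbinom(length(lam), size = dispersion, mu = lam)
}

#' Simulate one individual's recording
#'
#' Draws arrhythmicity and (in DD) an individual free-running period, then
#' generates `days` days of 1-min negative-binomial counts around the
#' intensity function.
#'
#' @param params A [sim_config()].
#' @param schedule A [light_schedule()].
#' @param seed Optional RNG seed (same seed, same series).
#' @param days Recording length in days (default 7).
#' @param start Recording start timestamp (default mid-day, 13:00, as
#'   recordings begin about an hour after animals are loaded).
#' @param individual_id,monitor_id,channel Identifiers for the series.
#' @param meta Metadata list (insemination, meal, regimen, ...).
#' @return List with `series` (a [channel_series()]) and `truth` (a one-row
#'   data frame: `individual_id`, `is_arrhythmic`, `tau_h`,
#'   `onset_delay_min`).
#' @export
simulate_individual <- function(params, schedule, seed = NULL, days = 7,
                                start = "2026-01-05 13:00:00",
                                individual_id = "ind1", monitor_id = "M01",
                                channel = 1, meta = list()) {
  if (!is.null(seed)) set.seed(seed)
  start <- as.POSIXct(start, tz = "UTC")
  regimen <- meta$regimen %||% schedule$regimen
  n <- as.integer(days * 1440)
  arr <- stats::runif(1) < params$p_arrhythmic
  tau <- if (identical(regimen, "DD")) {
    min(25, max(21, stats::rnorm(1, params$tau_h, params$tau_sd_h)))
  } else 24
  lam <- intensity_function(0:(n - 1L), params, schedule, regimen = regimen,
                            start_clock_min = clock_hours(start) * 60,
                            tau_h = tau, arrhythmic = arr)
  counts <- draw_counts(lam, params$nb_dispersion)
  meta$regimen <- regimen
  series <- channel_series(individual_id, monitor_id, channel, start, counts,
                           step = 60L, meta = meta)
  truth <- data.frame(individual_id = individual_id, is_arrhythmic = arr,
                      tau_h = if (arr) NA_real_ else tau,
                      onset_delay_min = params$onset_delay_min,
                      stringsAsFactors = FALSE)
  list(series = series, truth = truth)
}

#' Default 8-group study design
#'
#' The factorial design of the emulated experiment: insemination status
#' (virgin, inseminated) x meal (glucose, blood) x light regimen (LD, DD).
#' Blood-fed groups activity is suppressed (x0.2) with a 72-h recovery;
#' inseminated groups have their dusk onset delayed by 4 min; inseminated
#' DD groups have an elevated arrhythmic fraction (0.25 vs 0.03); DD groups
#' free-run at tau ~ 23 h.
#'
#' @param n_per_group Individuals per group (default 25).
#' @return List of group descriptors (`insemination`, `meal`, `regimen`,
#'   `params`), usable as the `study` argument of [simulate_cohort()].
#' @export
default_study <- function(n_per_group = 25) {
  grid <- expand.grid(insemination = c("virgin", "inseminated"),
                      meal = c("glucose", "blood"),
                      regimen = c("LD", "DD"),
                      stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    list(insemination = g$insemination, meal = g$meal, regimen = g$regimen,
         params = sim_config(
           n_per_group = n_per_group,
           blood_suppression = if (g$meal == "blood") 0.2 else 1,
           onset_delay_min = if (g$insemination == "inseminated") 4 else 0,
           p_arrhythmic = if (g$insemination == "inseminated" &&
                                g$regimen == "DD") 0.25 else 0.03))
  })
}

#' Simulate a full cohort with ground truth
#'
#' Generates every individual of a study design, packs them into monitors
#' of up to 30 experimental channels plus 2 all-zero control tubes
#' (channels 31 and 32; monitors never mix light regimens), and optionally
#' writes the whole study to disk in the monitor-file dialect together
#' with the channel metadata, the ground truth, and the study configuration
#' for exact re-runs.
#'
#' @param study List of group descriptors, e.g. from [default_study()].
#' @param schedule A [light_schedule()] (clock anchors shared by LD and DD).
#' @param seed RNG seed for the whole cohort.
#' @param days Recording length in days (default 7).
#' @param start Recording start timestamp.
#' @param dir Optional output directory.
#' @return List with `cohort` (a [cohort_table()] including controls),
#'   `truth` (data frame with group columns) and, when `dir` is given,
#'   `files`.
#' @export
simulate_cohort <- function(study = default_study(), schedule = light_schedule("LD"),
                            seed = 1, days = 7,
                            start = "2026-01-05 13:00:00", dir = NULL) {
  set.seed(seed)
  series <- list()
  truth <- list()
  # lay out individuals per regimen so monitors are single-regimen
  per_regimen <- split(study, vapply(study, `[[`, character(1), "regimen"))
  mon_counter <- 0L
  for (reg in names(per_regimen)) {
    slot <- 0L
    mon_id <- NULL
    mon_of <- function() sprintf("M%02d", mon_counter)
    for (grp in per_regimen[[reg]]) {
      n <- grp$params$n_per_group
      if (n < 1) next
      for (k in seq_len(n)) {
        if (slot == 0L) {  # open a new monitor with its two control tubes
          mon_counter <- mon_counter + 1L
          mon_id <- mon_of()
          for (cc in c(31L, 32L)) {
            ctrl_id <- sprintf("%s_ctrl%02d", mon_id, cc)
            series[[ctrl_id]] <- channel_series(
              ctrl_id, mon_id, cc, start, integer(days * 1440),
              meta = list(regimen = reg, is_control_tube = TRUE))
          }
        }
        slot <- slot + 1L
        id <- sprintf("%s_%s_%s_%02d", substr(grp$insemination, 1, 3),
                      substr(grp$meal, 1, 3), reg, k)
        sim <- simulate_individual(
          grp$params, schedule, seed = NULL, days = days, start = start,
          individual_id = id, monitor_id = mon_id, channel = slot,
          meta = list(insemination = grp$insemination, meal = grp$meal,
                      regimen = reg))
        series[[id]] <- sim$series
        tr <- sim$truth
        tr$insemination <- grp$insemination
        tr$meal <- grp$meal
        tr$regimen <- reg
        truth[[id]] <- tr
        if (slot == 30L) slot <- 0L
      }
    }
  }
  cohort <- cohort_table(series, schedule)
  truth <- if (length(truth))
    do.call(rbind, c(truth, list(make.row.names = FALSE)))
  else data.frame(individual_id = character(), is_arrhythmic = logical(),
                  tau_h = numeric(), onset_delay_min = numeric(),
                  insemination = character(), meal = character(),
                  regimen = character(), stringsAsFactors = FALSE)
  out <- list(cohort = cohort, truth = truth)
  if (!is.null(dir)) {
    files <- write_cohort_files(cohort, dir)
    utils::write.csv(truth, file.path(dir, "ground_truth.csv"),
                     row.names = FALSE)
    cfg <- lapply(study, function(g)
      c(g[c("insemination", "meal", "regimen")],
        list(params = unclass(g$params))))
    yaml::write_yaml(list(seed = seed, days = days,
                          start = format(as.POSIXct(start, tz = "UTC"),
                                         "%Y-%m-%d %H:%M:%S"),
                          study = cfg),
                     file.path(dir, "study_config.yaml"))
    out$files <- files
  }
  out
}
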