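test_that("the intensity function has the stated shape", {
  flat <- sim_config(dusk_amp = 0, dawn_amp = 0, night_plateau = 1)
  lam <- intensity_function(0:2879, flat, LD, regimen = "LD")
  expect_true(all(lam == flat$baseline_rate))
  # LD: exactly two local maxima per 24 h (dusk and dawn bursts)
  cfg <- sim_config()
  lam <- intensity_function(0:(3 * 1440 - 1), cfg, LD, regimen = "LD",
                            start_clock_min = 0)
  day2 <- lam[1441:2880]
  is_max <- vapply(seq_along(day2), function(i) {
    prev <- day2[ifelse(i == 1, 1440, i - 1)]
    nxt <- day2[ifelse(i == 1440, 1, i + 1)]
    day2[i] > prev && day2[i] >= nxt
  }, logical(1))
  expect_equal(sum(is_max), 2)
  # DD with tau = 23: the dusk maximum comes 60 min earlier each subjective day
  cfg23 <- sim_config(tau_h = 23)
  lam <- intensity_function(0:(4 * 1440 - 1), cfg23, DD, regimen = "DD",
                            start_clock_min = 0)
  p1 <- which.max(lam[1:1440])
  p2 <- which.max(lam[1441:2880])
  expect_equal(p2 + 1440 - p1, 23 * 60)
  # arrhythmic individuals are flat regardless of amplitudes
  expect_true(all(intensity_function(0:999, cfg, LD, arrhythmic = TRUE) ==
                    cfg$baseline_rate))
  # blood suppression: x0.2 before recovery_h, then ramping back to 1
  cfgb <- sim_config(dusk_amp = 0, dawn_amp = 0, night_plateau = 1,
                     blood_suppression = 0.2, recovery_h = 72,
                     recovery_ramp_h = 24)
  lam <- intensity_function(c(0, 71 * 60, 72 * 60, 84 * 60, 96 * 60, 200 * 60),
                            cfgb, LD, regimen = "LD")
  expect_equal(lam / cfgb$baseline_rate, c(0.2, 0.2, 0.2, 0.6, 1, 1))
})

test_that("individual simulation is seeded, mean-accurate and edge-safe", {
  cfg <- sim_config()
  a <- simulate_individual(cfg, LD, seed = 77, days = 2)
  b <- simulate_individual(cfg, LD, seed = 77, days = 2)
  expect_identical(a$series$counts, b$series$counts)
  expect_identical(a$truth, b$truth)
  # zero baseline -> all-zero series (flagged dead downstream)
  z <- simulate_individual(sim_config(baseline_rate = 0), LD, seed = 1, days = 2)
  expect_true(all(z$series$counts == 0L))
  expect_true(flag_dead(z$series))
  # Monte-Carlo check: the simulated mean at fixed minutes matches lambda
  cfg0 <- sim_config(p_arrhythmic = 0)
  lam <- intensity_function(0:(2 * 1440 - 1), cfg0, LD, regimen = "LD",
                            start_clock_min = 13 * 60)
  pick <- c(300, 1080 - 13 * 60 + 1441, 2000)  # day, dusk burst, night
  set.seed(123)
  draws <- vapply(1:200, function(i)
    simulate_individual(cfg0, LD, days = 2)$series$counts[pick], numeric(3))
  for (j in 1:3) {
    m <- mean(draws[j, ])
    se <- sd(draws[j, ]) / sqrt(ncol(draws))
    expect_lt(abs(m - lam[pick[j]]), 3 * se + 1e-9)
  }
})

test_that("cohort simulation is pipeline-consumable with clean QC", {
  sim <- simulate_cohort(default_study(n_per_group = 3), seed = 5, days = 3)
  # 8 groups x 3 + 2 controls per monitor
  expect_equal(sum(vapply(sim$cohort$series, function(s)
    isTRUE(s$meta$is_control_tube), logical(1))), 4)  # one LD + one DD monitor
  expect_equal(nrow(sim$truth), 24)
  filtered <- apply_cohort_filters(sim$cohort)
  # only controls removed: no QC surprises
  expect_setequal(filtered$qc_log$reason, "control tube")
  expect_equal(length(filtered$series), 24)
  # monitors never mix regimens
  regs <- vapply(sim$cohort$series, function(s) s$meta$regimen, character(1))
  mons <- vapply(sim$cohort$series, function(s) s$monitor_id, character(1))
  expect_true(all(vapply(split(regs, mons), function(r)
    length(unique(r)) == 1, logical(1))))
  # empty study -> valid empty outputs
  empty <- simulate_cohort(lapply(default_study(0), identity), seed = 1, days = 3)
  expect_length(empty$cohort$series, 0)
  expect_equal(nrow(empty$truth), 0)
})

test_that("an all-arrhythmic group is classified as such after analysis", {
  study <- list(list(insemination = "virgin", meal = "glucose", regimen = "DD",
                     params = sim_config(p_arrhythmic = 1, n_per_group = 10)))
  sim <- simulate_cohort(study, seed = 9, days = 7)
  co <- trim_cohort(apply_cohort_filters(sim$cohort))
  rhythms <- analyse_rhythms(co)
  calls <- rhythm_call_table(rhythms, co)
  expect_gte(mean(!calls$is_rhythmic), 0.9)
})

test_that("LD mean profiles are bimodal where DD profiles lack the dawn peak", {
  study <- list(
    list(insemination = "virgin", meal = "glucose", regimen = "LD",
         params = sim_config(n_per_group = 8, p_arrhythmic = 0)),
    list(insemination = "virgin", meal = "glucose", regimen = "DD",
         params = sim_config(n_per_group = 8, p_arrhythmic = 0, tau_sd_h = 0)))
  sim <- simulate_cohort(study, seed = 13, days = 4)
  co <- trim_cohort(apply_cohort_filters(sim$cohort))
  dawn <- function(p) mean(p$mean_count[p$clock_min >= 6 * 60 & p$clock_min < 6.5 * 60])
  midday <- function(p) mean(p$mean_count[p$clock_min >= 10 * 60 & p$clock_min < 14 * 60])
  pLD <- mean_activity_profile(co, regimen = "LD")
  pDD <- mean_activity_profile(co, regimen = "DD")
  expect_gt(dawn(pLD) / midday(pLD), 3)   # clear dawn peak in LD
  expect_lt(dawn(pDD), dawn(pLD) / 3)     # absent (or drifted away) in DD
})

test_that("simulated studies round-trip through disk with ground truth", {
  d <- withr::local_tempdir()
  sim <- simulate_cohort(default_study(n_per_group = 2)[c(1, 3)], seed = 4,
                         days = 3, dir = d)
  expect_true(file.exists(file.path(d, "channel_meta.csv")))
  expect_true(file.exists(file.path(d, "ground_truth.csv")))
  expect_true(file.exists(file.path(d, "study_config.yaml")))
  back <- read_cohort_files(d, LD)
  expect_setequal(names(back$series), names(sim$cohort$series))
  truth <- read.csv(file.path(d, "ground_truth.csv"))
  expect_setequal(truth$individual_id,
                  sim$truth$individual_id)
})
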