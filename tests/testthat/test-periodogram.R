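test_that("Qp equals the brute-force statistic, including a perfect repeat", {
  # perfect 4-bin repeat over 12 bins: between-bin variance exhausts the total,
  # so Qp = number of bins used (here 12)
  x <- rep(c(1, 3, 2, 0), 3)
  expect_equal(qp_naive(x, 4), 12)
  s <- mk_series(x, step = 300L)  # 5-min bins stored directly
  pg <- chi_square_periodogram(s, bin_min = 5, period_range_h = c(10 / 60, 30 / 60))
  expect_equal(pg$qp[pg$period_h == 4 * 5 / 60], 12)
  # random series against the double-loop oracle
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(20:100, 1)
    x <- rpois(n, sample(1:5, 1))
    if (var(x) == 0) next
    s <- mk_series(x, step = 60L)
    pg <- chi_square_periodogram(s, bin_min = 1,
                                 period_range_h = c(2 / 60, (n %/% 2) / 60))
    oracle <- vapply(round(pg$period_h * 60), function(K) qp_naive(x, K),
                     numeric(1))
    expect_equal(pg$qp, oracle, tolerance = 1e-12)
  }
})

test_that("Qp is invariant under count shifts and positive scaling", {
  set.seed(7)
  x <- rpois(600, 2)
  pg0 <- chi_square_periodogram(mk_series(x), bin_min = 5,
                                period_range_h = c(1, 4))
  pg_shift <- chi_square_periodogram(mk_series(x + 3L), bin_min = 5,
                                     period_range_h = c(1, 4))
  pg_scale <- chi_square_periodogram(mk_series(x * 4L), bin_min = 5,
                                     period_range_h = c(1, 4))
  expect_equal(pg_shift$qp, pg0$qp, tolerance = 1e-9)
  expect_equal(pg_scale$qp, pg0$qp, tolerance = 1e-9)
})

test_that("a noiseless 24-h square wave puts the top significant period at 24 h", {
  onoff <- rep(c(0L, 20L), each = 720)  # 24-h square wave at 1-min step
  s <- mk_series(rep(onoff, 5))         # 5 days
  pg <- chi_square_periodogram(s, bin_min = 5)
  expect_false(pg$degenerate)
  top <- pg$period_h[which.max(pg$qp - pg$threshold)]
  expect_identical(top, 24)
  expect_true(24 %in% find_significant_peaks(pg))
  # argmax equals the true period on pure periodic signals (16-h wave too)
  onoff16 <- rep(c(0L, 20L), each = 480)
  pg16 <- chi_square_periodogram(mk_series(rep(onoff16, 7)), bin_min = 5)
  expect_equal(pg16$period_h[which.max(pg16$qp - pg16$threshold)], 16)
})

test_that("constant series are degenerate with no significant periods", {
  pg <- chi_square_periodogram(mk_series(rep(3L, 7200)), bin_min = 5)
  expect_true(pg$degenerate)
  expect_true(all(pg$qp == 0))
  expect_length(find_significant_peaks(pg), 0)
  call <- classify_rhythmicity(pg)
  expect_false(call$is_rhythmic)
})

test_that("each super-threshold run yields one peak at its maximum margin", {
  grid <- seq(20, 26, by = 0.2)
  thr <- rep(10, length(grid))
  qp <- rep(1, length(grid))
  expect_length(find_significant_peaks(mk_pg(grid, qp, thr)), 0)
  # one run spanning 23-25 h with its margin maximum at 23.8
  qp[grid >= 23 & grid <= 25] <- 12
  qp[abs(grid - 23.8) < 0.01] <- 20
  expect_equal(find_significant_peaks(mk_pg(grid, qp, thr)), 23.8)
  # a bimodal signal (fundamental + first harmonic) gives two disjoint runs
  t <- seq_len(7200) - 1
  x <- as.integer(round(20 + 10 * cos(2 * pi * t / 1440) +
                          8 * cos(2 * pi * t / 720)))
  pg <- chi_square_periodogram(mk_series(x), bin_min = 5)
  pk <- find_significant_peaks(pg)
  expect_true(any(abs(pk - 24) <= 0.1) && any(abs(pk - 12) <= 0.1))
})

test_that("rhythmicity calls pick the fundamental and flag atypical periods", {
  grid <- seq(5, 32, by = 0.25)
  thr <- rep(10, length(grid))
  base <- rep(0, length(grid))
  # single circadian peak at 22.5
  qp <- base; qp[grid == 22.5] <- 15
  call <- classify_rhythmicity(mk_pg(grid, qp, thr))
  expect_true(call$is_rhythmic)
  expect_equal(call$fundamental_period_h, 22.5)
  expect_false(call$atypical)
  # only peak at 27.5: rhythmic but atypical, no fundamental
  qp <- base; qp[grid == 27.5] <- 15
  call <- classify_rhythmicity(mk_pg(grid, qp, thr))
  expect_true(call$is_rhythmic)
  expect_true(is.na(call$fundamental_period_h))
  expect_true(call$atypical)
  # an ultradian-only individual (12 h) is rhythmic but neither fundamental
  # nor atypical
  qp <- base; qp[grid == 12] <- 15
  call <- classify_rhythmicity(mk_pg(grid, qp, thr))
  expect_true(call$is_rhythmic)
  expect_true(is.na(call$fundamental_period_h))
  expect_false(call$atypical)
  # two circadian peaks: largest margin wins, tie broken to the shorter
  qp <- base; qp[grid == 22] <- 15; qp[grid == 24] <- 18
  expect_equal(classify_rhythmicity(mk_pg(grid, qp, thr))$fundamental_period_h, 24)
  qp <- base; qp[grid == 22] <- 18; qp[grid == 24] <- 18
  expect_equal(classify_rhythmicity(mk_pg(grid, qp, thr))$fundamental_period_h, 22)
})

test_that("canonical-period mapping is nearest-with-tolerance, ties to shorter", {
  f <- map_to_canonical(c(12.2, 23.9))
  expect_true(f[["12"]])
  expect_false(any(f[setdiff(names(f), "12")]))  # 23.9 is fundamental territory
  expect_false(any(map_to_canonical(numeric(0))))
  # 7.0 h is equidistant from 6 and 8: assigned to the shorter
  f <- map_to_canonical(7.0, tolerance_h = 1)
  expect_true(f[["6"]])
  expect_false(f[["8"]])
  # outside tolerance -> absent
  expect_false(any(map_to_canonical(7.0, tolerance_h = 0.5)))
})

test_that("i.i.d. noise is rarely called rhythmic at the corrected threshold", {
  # small-n check; the full 500-individual calibration runs in the
  # acceptance suite
  set.seed(99)
  calls <- vapply(1:60, function(i) {
    s <- mk_series(rpois(7200, 0.5))
    classify_rhythmicity(chi_square_periodogram(s))$is_rhythmic
  }, logical(1))
  expect_lte(mean(calls), 0.1)
})
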