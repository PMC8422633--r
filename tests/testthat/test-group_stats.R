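test_that("Williams-corrected G matches the brute-force formulas", {
  # rhythmic/arrhythmic x LD/DD counts from the worked-example dataset
  counts <- coluzzii_rhythm_counts()
  tab <- rbind(colSums(counts[counts$regimen == "LD", 4:5]),
               colSums(counts[counts$regimen == "DD", 4:5]))
  g <- williams_g_test(tab)
  expect_equal(g$G, 5.57, tolerance = 0.005)
  expect_equal(g$df, 1)
  expect_lt(g$p.value, 0.05)
  # independence -> zero
  expect_equal(williams_g_test(matrix(10, 2, 2))$G, 0)
  # perfect association: G = 40 log 2, q = 1.075
  g <- williams_g_test(matrix(c(10, 0, 0, 10), 2))
  expect_equal(g$G_uncorrected, 40 * log(2))
  expect_equal(g$q, 1.075)
  expect_equal(g$G, 40 * log(2) / 1.075, tolerance = 1e-9)
  # random tables against the naive oracle; permutation invariance
  set.seed(21)
  for (i in 1:20) {
    O <- matrix(rpois(6, 8) + 1, 2, 3)
    g <- williams_g_test(O)
    o <- g_naive(O)
    expect_equal(g$G, o$G, tolerance = 1e-9)
    expect_equal(g$q, o$q, tolerance = 1e-12)
    perm <- O[sample(2), sample(3)]
    expect_equal(williams_g_test(perm)$G, g$G, tolerance = 1e-9)
  }
  expect_error(williams_g_test(matrix(c(0, 0, 1, 2), 2)), "positive")
})

test_that("Williams' q tends to 1 as n grows with fixed margin proportions", {
  qs <- vapply(c(1, 10, 100, 1000), function(m)
    williams_g_test(m * matrix(c(3, 1, 2, 2), 2))$q, numeric(1))
  expect_true(all(diff(qs) < 0))
  expect_equal(qs[4], 1, tolerance = 1e-2)
})

# build a nightly-format table from per-individual Poisson rates
mk_nightly <- function(rates_by_group, night = 2, bins = 180) {
  rows <- list()
  for (g in names(rates_by_group)) {
    rates <- rates_by_group[[g]]
    for (i in seq_along(rates)) {
      rows[[paste(g, i)]] <- data.frame(
        individual_id = paste0(g, "_", i), insemination = "virgin", meal = g,
        regimen = "LD", night = night, bin = seq_len(bins),
        count = rpois(bins, rates[i]), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

test_that("rate ratios recover truth and behave on degenerate input", {
  set.seed(31)
  nightly <- mk_nightly(list(a = rep(2, 30), b = rep(2, 30)))
  rr <- rate_ratio_nightly(nightly, c("a", "b"), night = 2, group_by = "meal",
                           B = 300, seed = 1)
  expect_equal(rr$estimate, 1, tolerance = 0.1)
  expect_lte(rr$ci_low, 1.02)  # CI sits around 1 up to Monte-Carlo tolerance
  expect_gte(rr$ci_high, 0.98)
  # true rates 2:1 -> estimate within [1.8, 2.2]
  set.seed(32)
  nightly <- mk_nightly(list(a = rep(2, 30), b = rep(1, 30)))
  rr <- rate_ratio_nightly(nightly, c("a", "b"), night = 2, group_by = "meal",
                           B = 300, seed = 1)
  expect_gt(rr$estimate, 1.8)
  expect_lt(rr$estimate, 2.2)
  # scale consistency: multiplying all rates leaves RR unchanged in expectation
  set.seed(33)
  nightly10 <- mk_nightly(list(a = rep(20, 30), b = rep(10, 30)))
  rr10 <- rate_ratio_nightly(nightly10, c("a", "b"), night = 2,
                             group_by = "meal", B = 300, seed = 1)
  expect_equal(rr10$estimate, rr$estimate, tolerance = 0.15)
  # all-zero group is an error with a diagnostic
  set.seed(34)
  nightly <- mk_nightly(list(a = rep(2, 5), b = rep(0, 5)))
  expect_error(rate_ratio_nightly(nightly, c("a", "b"), night = 2,
                                  group_by = "meal", B = 10),
               "all-zero")
  expect_error(rate_ratio_nightly(mk_nightly(list(a = 2, b = 2)),
                                  c("a", "b"), night = 2, group_by = "meal"),
               "at least 2")
})

test_that("period contrasts reduce to differences of cell means", {
  mk_periods <- function(taus, ins, meal)
    data.frame(fundamental_period_h = taus, insemination = ins, meal = meal,
               stringsAsFactors = FALSE)
  # two groups: MD equals the difference of sample means exactly
  p <- mk_periods(c(23.1, 23.3, 23.2, 22.9, 22.7, 22.8),
                  rep(c("virgin", "inseminated"), each = 3), "glucose")
  suppressWarnings(out <- compare_periods(p))
  expect_equal(nrow(out), 1)
  expect_equal(out$estimate, mean(c(22.9, 22.7, 22.8)) - mean(c(23.1, 23.3, 23.2)))
  # all groups equal in mean: no rejections
  set.seed(41)
  grid <- expand.grid(ins = c("virgin", "inseminated"),
                      meal = c("glucose", "blood"))
  p <- do.call(rbind, lapply(seq_len(4), function(i)
    mk_periods(23 + rnorm(10, 0, 0.2), grid$ins[i], grid$meal[i])))
  out <- compare_periods(p)
  expect_equal(nrow(out), 6)
  expect_true(all(out$p_adj > 0.05))
  expect_true(all(abs(out$estimate) < 0.3))
  # one group shifted +0.3 h is recovered
  set.seed(42)
  p <- do.call(rbind, lapply(seq_len(4), function(i)
    mk_periods(23 + (i == 1) * 0.3 + rnorm(25, 0, 0.2), grid$ins[i], grid$meal[i])))
  out <- compare_periods(p)
  hit <- out[out$group_a == "virgin.glucose" | out$group_b == "virgin.glucose", ]
  expect_equal(mean(abs(hit$estimate)), 0.3, tolerance = 0.15)
  expect_error(compare_periods(mk_periods(23, "virgin", "glucose")), "at least 2")
})

test_that("onset contrasts are two-stage and fail without observed onsets", {
  mk_ep <- function(onsets, grp, ids) data.frame(
    individual_id = ids, insemination = grp, onset_min = onsets,
    stringsAsFactors = FALSE)
  set.seed(51)
  ids <- rep(sprintf("i%02d", 1:20), each = 5)
  a <- mk_ep(1080 + rnorm(100, 0, 2), "inseminated", ids)
  b <- mk_ep(1080 + rnorm(100, 0, 2), "virgin", paste0("v", ids))
  res <- compare_onset(rbind(a, b), c("inseminated", "virgin"), B = 300, seed = 1)
  expect_equal(res$estimate, 0, tolerance = 1.5)
  expect_true(res$ci_low <= 0 && res$ci_high >= 0)
  # a group with no observed onsets is an error
  b$onset_min <- NA_real_
  expect_error(compare_onset(rbind(a, b), c("inseminated", "virgin"), B = 10),
               "fewer than 2")
})
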