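# shared fixtures and independent oracles

LD <- light_schedule("LD")
DD <- light_schedule("DD")

# quick series constructor; start defaults to midnight for easy indexing
mk_series <- function(counts, step = 60L, start = "2026-01-05 00:00:00",
                      meta = list(), id = "ind1", monitor = "M01", channel = 1) {
  channel_series(id, monitor, channel, start, counts, step = step, meta = meta)
}

# naive double-loop Sokolove-Bushell statistic for one trial period of K bins
qp_naive <- function(x, K) {
  N <- length(x) %/% K
  xx <- x[seq_len(N * K)]
  Mbar <- mean(xx)
  M_h <- numeric(K)
  for (h in seq_len(K)) {
    acc <- 0
    for (cyc in seq_len(N)) acc <- acc + xx[(cyc - 1) * K + h]
    M_h[h] <- acc / N
  }
  num <- 0
  for (h in seq_len(K)) num <- num + (M_h[h] - Mbar)^2
  den <- 0
  for (i in seq_len(N * K)) den <- den + (xx[i] - Mbar)^2
  N^2 * K * num / den
}

# naive Williams-corrected G oracle, written straight from the formulas
g_naive <- function(O) {
  n <- sum(O); r <- rowSums(O); cl <- colSums(O)
  G <- 0
  for (i in seq_len(nrow(O))) for (j in seq_len(ncol(O))) {
    E <- r[i] * cl[j] / n
    if (O[i, j] > 0) G <- G + O[i, j] * log(O[i, j] / E)
  }
  G <- 2 * G
  df <- (nrow(O) - 1) * (ncol(O) - 1)
  q <- 1 + (n * sum(1 / r) - 1) * (n * sum(1 / cl) - 1) / (6 * n * df)
  list(G = G / q, G_uncorrected = G, q = q, df = df)
}

# fabricate a minimal periodogram object for classification unit tests
mk_pg <- function(period_h, qp, threshold, degenerate = FALSE) {
  structure(list(period_h = period_h, qp = qp,
                 df = rep(10L, length(period_h)), threshold = threshold,
                 alpha = 0.05, correction = "none", bin_min = 5,
                 degenerate = degenerate),
            class = "periodogram")
}

# fabricate a rhythm call
mk_call <- function(rhythmic = TRUE, fundamental = 23, peaks = fundamental,
                    atypical = FALSE) {
  structure(list(is_rhythmic = rhythmic,
                 fundamental_period_h = if (rhythmic) fundamental else NA_real_,
                 significant_periods_h = if (rhythmic) peaks else numeric(0),
                 atypical = atypical),
            class = "rhythm_call")
}

no_canonical <- stats::setNames(rep(FALSE, 7),
                                c("6", "8", "12", "16", "18", "20", "30"))
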