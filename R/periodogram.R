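#' Chi-square periodogram of an activity series
#'
#' Computes the Sokolove-Bushell chi-square periodogram. Counts are first
#' re-binned to `bin_min`-minute bins. For each trial period P = K bins the
#' first N*K bins (N = floor(T/K) complete cycles) are folded into an N x K
#' array with column (phase-bin) means M_h and grand mean M; the statistic
#' is
#'
#'   Qp = N^2 * K * sum_h (M_h - M)^2 / sum_i (x_i - M)^2
#'
#' which is asymptotically chi-square with K - 1 degrees of freedom under
#' the null of no rhythm at P. The incomplete final cycle is discarded.
#' Each trial period is compared with the upper-`alpha` chi-square quantile
#' at K - 1 df; with `correction = "bonferroni"` (the default) `alpha` is
#' divided by the number of trial periods scanned, guarding the family-wise
#' error rate across the period grid.
#'
#' A constant (zero-variance) series has no defined statistic; it is
#' returned with Qp = 0 everywhere and the `degenerate` flag set.
#'
#' @param series A [channel_series()], normally trimmed with [trim_days()].
#' @param bin_min Bin width in minutes (default 5); must be a multiple of
#'   the recording step.
#' @param period_range_h Range of trial periods in hours (default 5-32);
#'   the grid steps by one bin.
#' @param alpha Significance level before correction (default 0.05).
#' @param correction "bonferroni" (default) or "none".
#' @return An object of class `periodogram`: a list with vectors
#'   `period_h`, `qp`, `df`, `threshold`, plus `alpha`, `correction`,
#'   `bin_min` and the `degenerate` flag.
#' @export
chi_square_periodogram <- function(series, bin_min = 5, period_range_h = c(5, 32),
                                   alpha = 0.05,
                                   correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  x <- rebin_counts(series$counts, series$step, bin_min)
  qp_periodogram(x, bin_min, period_range_h, alpha, correction)
}

# core statistic on an already-binned vector; shared with simulation tests
qp_periodogram <- function(x, bin_min, period_range_h, alpha, correction) {
  total <- length(x)
  k_min <- max(2L, as.integer(ceiling(period_range_h[1] * 60 / bin_min)))
  k_max <- as.integer(floor(period_range_h[2] * 60 / bin_min))
  k_max <- min(k_max, total %/% 2L)  # need at least 2 complete cycles
  if (k_max < k_min) stop("series too short for the requested period range")
  ks <- k_min:k_max
  n_trial <- length(ks)
  alpha_eff <- if (correction == "bonferroni") alpha / n_trial else alpha
  qp <- numeric(n_trial)
  degenerate <- stats::var(x) == 0
  if (!degenerate) {
    for (j in seq_along(ks)) {
      K <- ks[j]
      N <- total %/% K
      xx <- x[seq_len(N * K)]
      M_h <- colMeans(matrix(xx, nrow = N, ncol = K, byrow = TRUE))
      Mbar <- mean(xx)
      denom <- sum((xx - Mbar)^2)
      qp[j] <- if (denom > 0) N^2 * K * sum((M_h - Mbar)^2) / denom else 0
    }
  }
  structure(
    list(period_h = ks * bin_min / 60,
         qp = qp,
         df = ks - 1L,
         threshold = stats::qchisq(1 - alpha_eff, df = ks - 1L),
         alpha = alpha, correction = correction, bin_min = bin_min,
         degenerate = degenerate),
    class = "periodogram")
}

# sum 1-min (or step-s) counts into bin_min-minute bins; partial tail dropped
rebin_counts <- function(counts, step, bin_min) {
  per_bin <- as.integer(bin_min * 60) %/% as.integer(step)
  if ((bin_min * 60) %% step != 0 || per_bin < 1L)
    stop("bin_min must be a multiple of the recording step")
  if (per_bin == 1L) return(as.numeric(counts))
  nb <- length(counts) %/% per_bin
  as.numeric(rowsum(counts[seq_len(nb * per_bin)],
                    rep(seq_len(nb), each = per_bin)))
}

#' @export
print.periodogram <- function(x, ...) {
  cat(sprintf("<periodogram> %d trial periods %.2f-%.2f h, %g-min bins, alpha %g (%s)%s\n",
              length(x$period_h), min(x$period_h), max(x$period_h),
              x$bin_min, x$alpha, x$correction,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' @export
as.data.frame.periodogram <- function(x, ...) {
  data.frame(period_h = x$period_h, qp = x$qp, df = x$df,
             threshold = x$threshold)
}

#' Significant peaks of a periodogram
#'
#' A significant peak is the maximum of `qp - threshold` within one
#' contiguous run of trial periods exceeding their chi-square threshold;
#' each super-threshold run contributes exactly one peak.
#'
#' @param pg A [chi_square_periodogram()] result.
#' @return Numeric vector of peak periods (hours), possibly empty.
#' @export
find_significant_peaks <- function(pg) {
  if (pg$degenerate) return(numeric(0))
  over <- pg$qp > pg$threshold
  if (!any(over)) return(numeric(0))
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  peaks <- numeric(0)
  for (i in which(r$values)) {
    idx <- starts[i]:ends[i]
    margin <- pg$qp[idx] - pg$threshold[idx]
    peaks <- c(peaks, pg$period_h[idx[which.max(margin)]])
  }
  peaks
}

#' Classify an individual's rhythmicity from its periodogram
#'
#' An individual is arrhythmic when no trial period anywhere in the scanned
#' range reaches significance. Among significant peaks, the fundamental
#' (free-running) period tau is the peak inside the circadian acceptance
#' window (default 21-25 h, i.e. 23 +/- 2 h) with the largest margin
#' `qp - threshold`; ties go to the shorter period. A rhythmic individual
#' whose circadian-band peaks all fall outside the acceptance window (e.g.
#' a lone 27.5-h peak) is flagged `atypical` and carries no fundamental;
#' such individuals are excluded from period-length analyses.
#'
#' @param pg A [chi_square_periodogram()] result for one individual.
#' @param fundamental_range_h Acceptance window for tau, hours
#'   (default `c(21, 25)`).
#' @param circadian_band_h Band within which a non-canonical peak counts as
#'   circadian for the `atypical` flag (default `c(19, 29)`).
#' @param canonical_periods_h Canonical secondary periods used by
#'   [map_to_canonical()]; peaks mapping to these are never `atypical`.
#' @param canonical_tol_h Tolerance for that mapping (default 0.5 h).
#' @return An object of class `rhythm_call`: list with `is_rhythmic`,
#'   `fundamental_period_h` (NA when absent), `significant_periods_h`,
#'   `atypical`.
#' @export
classify_rhythmicity <- function(pg, fundamental_range_h = c(21, 25),
                                 circadian_band_h = c(19, 29),
                                 canonical_periods_h = c(6, 8, 12, 16, 18, 20, 30),
                                 canonical_tol_h = 0.5) {
  peaks <- find_significant_peaks(pg)
  if (!length(peaks)) {
    return(structure(list(is_rhythmic = FALSE, fundamental_period_h = NA_real_,
                          significant_periods_h = numeric(0), atypical = FALSE),
                     class = "rhythm_call"))
  }
  in_window <- peaks >= fundamental_range_h[1] & peaks <= fundamental_range_h[2]
  fundamental <- NA_real_
  if (any(in_window)) {
    cand <- peaks[in_window]
    margins <- vapply(cand, function(p) {
      i <- which.min(abs(pg$period_h - p))
      pg$qp[i] - pg$threshold[i]
    }, numeric(1))
    best <- margins == max(margins)
    fundamental <- min(cand[best])  # tie -> shorter period
  }
  atypical <- FALSE
  if (is.na(fundamental)) {
    out_band <- peaks[peaks >= circadian_band_h[1] & peaks <= circadian_band_h[2]]
    out_band <- out_band[!vapply(out_band, function(p)
      any(abs(p - canonical_periods_h) <= canonical_tol_h), logical(1))]
    atypical <- length(out_band) > 0
  }
  structure(list(is_rhythmic = TRUE, fundamental_period_h = fundamental,
                 significant_periods_h = peaks, atypical = atypical),
            class = "rhythm_call")
}

#' @export
print.rhythm_call <- function(x, ...) {
  if (!x$is_rhythmic) cat("<rhythm_call> arrhythmic\n")
  else cat(sprintf("<rhythm_call> rhythmic; tau = %s h; peaks: %s%s\n",
                   ifelse(is.na(x$fundamental_period_h), "none",
                          format(x$fundamental_period_h, digits = 4)),
                   paste(format(x$significant_periods_h, digits = 4),
                         collapse = ", "),
                   if (x$atypical) " [atypical]" else ""))
  invisible(x)
}

#' Map significant peaks onto the canonical secondary periods
#'
#' Besides the circadian fundamental, activity signals commonly carry
#' significant ultradian/infradian components at 6, 8, 12, 16, 18, 20 and
#' 30 h. Each significant peak is assigned to its nearest canonical period
#' (ties between two equidistant canonical periods go to the shorter one)
#' and the canonical period is flagged present when the peak lies within
#' `tolerance_h` of it. Peaks inside the fundamental window are handled by
#' [classify_rhythmicity()] and never map to a canonical period.
#'
#' @param peaks Numeric vector of significant peak periods (hours).
#' @param canonical_periods_h Canonical period set (hours).
#' @param tolerance_h Half-width of the assignment window (default 0.5 h).
#' @param fundamental_range_h Window reserved for the fundamental.
#' @return Named logical vector, one flag per canonical period.
#' @export
map_to_canonical <- function(peaks,
                             canonical_periods_h = c(6, 8, 12, 16, 18, 20, 30),
                             tolerance_h = 0.5,
                             fundamental_range_h = c(21, 25)) {
  flags <- stats::setNames(rep(FALSE, length(canonical_periods_h)),
                           as.character(canonical_periods_h))
  peaks <- peaks[peaks < fundamental_range_h[1] | peaks > fundamental_range_h[2]]
  for (p in peaks) {
    d <- abs(p - canonical_periods_h)
    nearest <- which(d == min(d))
    nearest <- nearest[which.min(canonical_periods_h[nearest])]  # tie -> shorter
    if (d[nearest] <= tolerance_h) flags[nearest] <- TRUE
  }
  flags
}

#' Run the rhythm analysis over a cohort
#'
#' Convenience wrapper: per retained individual, computes the chi-square
#' periodogram, the rhythmicity call and the canonical-period flags.
#'
#' @param cohort A trimmed, QC-filtered [cohort_table()].
#' @param ... Passed to [chi_square_periodogram()].
#' @param keep_periodograms Keep each full periodogram in the result
#'   (default FALSE to save memory).
#' @return Named list (by individual) of lists with elements `call`,
#'   `canonical`, and optionally `periodogram`.
#' @export
analyse_rhythms <- function(cohort, ..., keep_periodograms = FALSE) {
  lapply(cohort$series, function(s) {
    pg <- chi_square_periodogram(s, ...)
    call <- classify_rhythmicity(pg)
    out <- list(call = call,
                canonical = map_to_canonical(call$significant_periods_h))
    if (keep_periodograms) out$periodogram <- pg
    out
  })
}

#' Tabulate rhythm calls
#'
#' @param rhythms Result of [analyse_rhythms()].
#' @param cohort The matching [cohort_table()] (for metadata columns).
#' @return Data frame with one row per individual: treatment factors,
#'   `is_rhythmic`, `fundamental_period_h`, `atypical`.
#' @export
rhythm_call_table <- function(rhythms, cohort) {
  do.call(rbind, lapply(names(rhythms), function(id) {
    s <- cohort$series[[id]]
    r <- rhythms[[id]]$call
    data.frame(individual_id = id,
               insemination = s$meta$insemination, meal = s$meta$meal,
               regimen = s$meta$regimen,
               is_rhythmic = r$is_rhythmic,
               fundamental_period_h = r$fundamental_period_h,
               atypical = r$atypical,
               stringsAsFactors = FALSE)
  }))
}
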