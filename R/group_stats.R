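#' G test of independence with Williams' correction
#'
#' Likelihood-ratio G statistic for an r x c contingency table,
#' G = 2 * sum O * ln(O/E) with expected counts E from the product of the
#' margins (cells with O = 0 contribute 0), divided by Williams' correction
#' q = 1 + (n*sum(1/r_i) - 1)(n*sum(1/c_j) - 1) / (6n(r-1)(c-1)).
#' The corrected statistic is referred to the chi-square distribution with
#' (r-1)(c-1) degrees of freedom.
#'
#' @param tab Matrix (or table) of non-negative integer counts, at least
#'   2 x 2, with all row and column sums positive.
#' @return List with `G` (corrected), `G_uncorrected`, `q`, `df`, `p.value`.
#' @examples
#' # rhythmic/arrhythmic individuals by light regimen
#' williams_g_test(matrix(c(112, 4, 51, 8), 2, byrow = TRUE))
#' @export
williams_g_test <- function(tab) {
  O <- as.matrix(tab)
  if (nrow(O) < 2 || ncol(O) < 2) stop("table must be at least 2 x 2")
  if (any(O < 0)) stop("counts must be non-negative")
  r <- rowSums(O); cl <- colSums(O); n <- sum(O)
  if (any(r == 0) || any(cl == 0))
    stop("all row and column sums must be positive")
  E <- outer(r, cl) / n
  terms <- ifelse(O > 0, O * log(O / E), 0)
  G <- 2 * sum(terms)
  df <- (nrow(O) - 1) * (ncol(O) - 1)
  q <- 1 + (n * sum(1 / r) - 1) * (n * sum(1 / cl) - 1) / (6 * n * df)
  G_adj <- G / q
  list(G = G_adj, G_uncorrected = G, q = q, df = df,
       p.value = stats::pchisq(G_adj, df, lower.tail = FALSE))
}

group_key <- function(df, group_by) {
  do.call(paste, c(unname(df[group_by]), list(sep = ".")))
}

# ratio of group mean counts == single-factor log-link NB/Poisson MLE of RR
ratio_of_means <- function(count, grp, A, B) {
  mA <- mean(count[grp == A]); mB <- mean(count[grp == B])
  if (mB == 0 || mA == 0) return(NA_real_)
  mA / mB
}

#' Nightly-activity rate ratio between two groups
#'
#' Estimates how much less (RR < 1) or more (RR > 1) active group A is than
#' group B on a given night, from per-5-min counts. The point estimate is a
#' log-link negative-binomial regression of count on group (dispersion by
#' maximum likelihood, falling back to Poisson when the dispersion estimate
#' diverges); the 95% CI comes from a cluster bootstrap that resamples
#' individuals within group, respecting the repeated-measures structure.
#'
#' @param nightly Long table from [nightly_table()].
#' @param contrast Character `c(A, B)` of group keys; RR = rate(A)/rate(B).
#' @param night Which night (recording-day label) to analyse.
#' @param group_by Columns of `nightly` whose `.`-joined values form the
#'   group key (default insemination and meal).
#' @param B Bootstrap replicates (default 1000).
#' @param seed Optional RNG seed.
#' @param conf Confidence level (default 0.95).
#' @return List of class `comparison_result`: `estimate` (RR), `ci_low`,
#'   `ci_high`, `p_value`, `method`, `B`, `seed`, `n` (individuals per group).
#' @export
rate_ratio_nightly <- function(nightly, contrast, night,
                               group_by = c("insemination", "meal"),
                               B = 1000, seed = NULL, conf = 0.95) {
  if (!is.null(seed)) set.seed(seed)
  dat <- nightly[nightly$night == night, , drop = FALSE]
  dat$grp <- group_key(dat, group_by)
  dat <- dat[dat$grp %in% contrast, , drop = FALSE]
  A <- contrast[1]; Bk <- contrast[2]
  n_ind <- tapply(dat$individual_id, dat$grp, function(x) length(unique(x)))
  if (any(is.na(n_ind[contrast])) || any(n_ind[contrast] < 2))
    stop("each group needs at least 2 individuals observed on that night")
  tot <- tapply(dat$count, dat$grp, sum)
  if (any(tot[contrast] == 0))
    stop(sprintf("group '%s' has all-zero counts on night %s: rate ratio undefined",
                 contrast[which(tot[contrast] == 0)[1]], night))
  dat$grp <- factor(dat$grp, levels = c(Bk, A))
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(count ~ grp, data = dat)),
    error = function(e) NULL)
  method <- "negative binomial GLM + cluster bootstrap"
  if (is.null(fit)) {
    fit <- stats::glm(count ~ grp, family = stats::poisson(), data = dat)
    method <- "Poisson GLM (NB dispersion diverged) + cluster bootstrap"
  }
  rr <- unname(exp(stats::coef(fit)[2]))
  # cluster bootstrap over individuals within group
  split_A <- split(dat$count[dat$grp == A], dat$individual_id[dat$grp == A])
  split_B <- split(dat$count[dat$grp == Bk], dat$individual_id[dat$grp == Bk])
  boot <- vapply(seq_len(B), function(b) {
    xa <- unlist(split_A[sample.int(length(split_A), replace = TRUE)])
    xb <- unlist(split_B[sample.int(length(split_B), replace = TRUE)])
    if (mean(xb) == 0 || mean(xa) == 0) NA_real_ else mean(xa) / mean(xb)
  }, numeric(1))
  boot <- boot[!is.na(boot)]
  al <- (1 - conf) / 2
  ci <- stats::quantile(boot, c(al, 1 - al), names = FALSE)
  sd_log <- stats::sd(log(boot))
  p <- if (is.finite(sd_log) && sd_log > 0)
    2 * stats::pnorm(-abs(log(rr)) / sd_log) else NA_real_
  structure(list(estimate = rr, ci_low = ci[1], ci_high = ci[2],
                 p_value = p, method = method, B = B, seed = seed,
                 n = as.list(n_ind[contrast]), night = night,
                 contrast = contrast),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison> %s: estimate %.4g, 95%% CI (%.4g, %.4g), p = %.3g [%s]\n",
              paste(x$contrast, collapse = " vs "),
              x$estimate, x$ci_low, x$ci_high, x$p_value, x$method))
  invisible(x)
}

#' Compare free-running period lengths between treatment groups
#'
#' Least-squares fit of the fundamental period tau on the meal x
#' insemination cells (LD and DD are analysed separately by the caller),
#' followed by all pairwise group mean differences with t-based confidence
#' intervals and Holm adjustment of the p-values. With a full interaction
#' the model is the cell-means model, so each mean difference equals the
#' difference of sample means; empty cells simply drop out (with a
#' warning).
#'
#' @param periods Data frame with columns `fundamental_period_h` (or
#'   `tau_h`), `meal`, `insemination`; NA periods are dropped.
#' @param conf Confidence level (default 0.95).
#' @return Data frame of class `period_comparison`: one row per pair with
#'   `estimate` (mean difference, hours), `ci_low`, `ci_high`, `p_value`,
#'   `p_adj`, `method`.
#' @export
compare_periods <- function(periods, conf = 0.95) {
  tau_col <- if ("fundamental_period_h" %in% names(periods))
    "fundamental_period_h" else "tau_h"
  dat <- periods[!is.na(periods[[tau_col]]), , drop = FALSE]
  dat$grp <- factor(group_key(dat, c("insemination", "meal")))
  sizes <- table(dat$grp)
  if (length(sizes) < 2) stop("need at least 2 groups with period values")
  if (any(sizes < 2)) stop("each group needs at least 2 period values")
  if (length(sizes) < 4)
    warning("empty treatment cell(s): interaction not estimable, comparing available groups")
  fit <- stats::lm(stats::reformulate("0 + grp", response = tau_col), data = dat)
  cf <- stats::coef(fit)
  V <- diag(stats::vcov(fit))
  lv <- levels(dat$grp)
  pairs <- utils::combn(seq_along(lv), 2)
  dfres <- stats::df.residual(fit)
  rows <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    md <- cf[i] - cf[j]
    se <- sqrt(V[i] + V[j])
    tcrit <- stats::qt(1 - (1 - conf) / 2, dfres)
    data.frame(group_a = lv[i], group_b = lv[j],
               estimate = unname(md), ci_low = unname(md - tcrit * se),
               ci_high = unname(md + tcrit * se),
               p_value = 2 * stats::pt(-abs(md / se), dfres),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_value, method = "holm")
  out$method <- "lm cell means, t CIs, Holm-adjusted p"
  rownames(out) <- NULL
  class(out) <- c("period_comparison", "data.frame")
  out
}

#' Compare onset of activity between two groups
#'
#' Two-stage estimate of the onset delay: each individual is summarised by
#' its mean onset time across analysis days (missing onsets dropped), then
#' the groups are contrasted on those means; positive estimates mean group
#' A starts later (is delayed) relative to group B. The confidence interval
#' is a percentile bootstrap over individuals.
#'
#' @param endpoints Data frame from [endpoint_table()] (needs
#'   `individual_id`, `onset_min`, the grouping columns).
#' @param contrast Character `c(A, B)` of group keys.
#' @param group_by Columns forming the group key (default insemination).
#' @param B Bootstrap replicates (default 1000).
#' @param seed Optional RNG seed.
#' @param conf Confidence level.
#' @return A `comparison_result` with `estimate` = delay of A vs B in
#'   minutes.
#' @export
compare_onset <- function(endpoints, contrast, group_by = "insemination",
                          B = 1000, seed = NULL, conf = 0.95) {
  if (!is.null(seed)) set.seed(seed)
  endpoints$grp <- group_key(endpoints, group_by)
  dat <- endpoints[endpoints$grp %in% contrast, , drop = FALSE]
  ind <- stats::aggregate(onset_min ~ individual_id + grp, data = dat,
                          FUN = mean, na.rm = TRUE, na.action = stats::na.omit)
  for (g in contrast) {
    if (sum(ind$grp == g & is.finite(ind$onset_min)) < 2)
      stop(sprintf("group '%s' has fewer than 2 individuals with an observed onset", g))
  }
  A <- ind$onset_min[ind$grp == contrast[1]]
  Bv <- ind$onset_min[ind$grp == contrast[2]]
  est <- mean(A) - mean(Bv)
  boot <- vapply(seq_len(B), function(b)
    mean(A[sample.int(length(A), replace = TRUE)]) -
      mean(Bv[sample.int(length(Bv), replace = TRUE)]), numeric(1))
  al <- (1 - conf) / 2
  ci <- stats::quantile(boot, c(al, 1 - al), names = FALSE)
  sdb <- stats::sd(boot)
  p <- if (sdb > 0) 2 * stats::pnorm(-abs(est) / sdb) else NA_real_
  structure(list(estimate = est, ci_low = ci[1], ci_high = ci[2],
                 p_value = p,
                 method = "two-stage mean onset + percentile bootstrap",
                 B = B, seed = seed,
                 n = list(length(A), length(Bv)), contrast = contrast),
            class = "comparison_result")
}

#' Rhythmic/arrhythmic counts by light regimen
#'
#' Collapses a rhythm-call table into the 2 x 2 contingency table of
#' rhythmicity by regimen (rows LD, DD; columns rhythmic, arrhythmic) for
#' [williams_g_test()].
#'
#' @param calls Data frame from [rhythm_call_table()].
#' @return 2 x 2 integer matrix.
#' @export
rhythmicity_by_regimen <- function(calls) {
  t(table(factor(ifelse(calls$is_rhythmic, "rhythmic", "arrhythmic"),
                 levels = c("rhythmic", "arrhythmic")),
          factor(calls$regimen, levels = c("LD", "DD"))))
}
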