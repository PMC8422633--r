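#' Chronotype barcode of an individual
#'
#' Encodes which of the eight periodic components an individual expresses as
#' an ordered binary vector: seven canonical secondary periods (6, 8, 12,
#' 16, 18, 20, 30 h, ascending) followed by presence of the circadian
#' fundamental. Arrhythmic individuals carry the all-zero barcode.
#'
#' @param call A [classify_rhythmicity()] result.
#' @param canonical_flags Presence flags from [map_to_canonical()] for the
#'   same individual.
#' @return Named integer vector of 0/1 of length 8, class `barcode`.
#' @export
make_barcode <- function(call, canonical_flags) {
  periods <- sort(as.numeric(names(canonical_flags)))
  bits <- as.integer(canonical_flags[as.character(periods)])
  fundamental <- as.integer(isTRUE(call$is_rhythmic) &&
                              !is.na(call$fundamental_period_h))
  if (!call$is_rhythmic) {
    bits[] <- 0L
    fundamental <- 0L
  }
  structure(stats::setNames(c(bits, fundamental),
                            c(as.character(periods), "fundamental")),
            class = "barcode")
}

#' @export
print.barcode <- function(x, ...) {
  cat("<barcode>", paste(unclass(x), collapse = ""), "\n")
  invisible(x)
}

barcode_key <- function(b) paste(unclass(b), collapse = "")

#' Shannon diversity of chronotype barcodes
#'
#' H = -sum_k p_k log(p_k) over the empirical frequencies p_k of the
#' distinct barcodes in a group. Diversity is computed over barcode
#' combinations (not per-period marginals): a low H indicates that a few
#' combinations of periodic components dominate the group, a high H that
#' individuals differ widely in which periods they express. Natural
#' logarithms (nats) by default.
#'
#' @param barcodes A list of [make_barcode()] vectors, or a character vector
#'   of barcode keys.
#' @param base Logarithm base (default `exp(1)` for nats).
#' @return The Shannon index H (non-negative scalar).
#' @export
shannon_diversity <- function(barcodes, base = exp(1)) {
  if (!length(barcodes)) stop("cannot compute diversity of an empty group")
  keys <- if (is.character(barcodes)) barcodes
          else vapply(barcodes, barcode_key, character(1))
  p <- as.numeric(table(keys)) / length(keys)
  -sum(p * log(p, base = base))
}

#' Per-group Shannon diversity table
#'
#' Computes H for every (insemination x meal x regimen) group of a cohort,
#' with arrhythmic individuals included as the all-zero barcode class.
#' Empty groups are omitted (with a note). With `margins = TRUE`, pooled
#' rows over insemination status within each regimen are appended.
#'
#' @param cohort A QC-filtered [cohort_table()].
#' @param rhythms Result of [analyse_rhythms()] on the same cohort.
#' @param base Logarithm base for H.
#' @param margins Append pooled insemination margins (default FALSE).
#' @return Data frame with columns `insemination`, `meal`, `regimen`, `n`,
#'   `n_barcodes`, `H`.
#' @export
diversity_table <- function(cohort, rhythms, base = exp(1), margins = FALSE) {
  ids <- names(cohort$series)
  if (!all(ids %in% names(rhythms)))
    stop("every retained individual needs a rhythm call")
  keys <- vapply(ids, function(id)
    barcode_key(make_barcode(rhythms[[id]]$call, rhythms[[id]]$canonical)),
    character(1))
  meta <- data.frame(
    insemination = vapply(cohort$series, function(s) s$meta$insemination, character(1)),
    meal = vapply(cohort$series, function(s) s$meta$meal, character(1)),
    regimen = vapply(cohort$series, function(s) s$meta$regimen, character(1)),
    key = keys, stringsAsFactors = FALSE)
  grp <- interaction(meta$insemination, meta$meal, meta$regimen, drop = TRUE)
  rows <- lapply(levels(grp), function(g) {
    sub <- meta[grp == g, , drop = FALSE]
    data.frame(insemination = sub$insemination[1], meal = sub$meal[1],
               regimen = sub$regimen[1], n = nrow(sub),
               n_barcodes = length(unique(sub$key)),
               H = shannon_diversity(sub$key, base = base),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (margins) {
    mg <- interaction(meta$insemination, meta$regimen, drop = TRUE)
    mrows <- lapply(levels(mg), function(g) {
      sub <- meta[mg == g, , drop = FALSE]
      data.frame(insemination = sub$insemination[1], meal = "(pooled)",
                 regimen = sub$regimen[1], n = nrow(sub),
                 n_barcodes = length(unique(sub$key)),
                 H = shannon_diversity(sub$key, base = base),
                 stringsAsFactors = FALSE)
    })
    out <- rbind(out, do.call(rbind, mrows))
  }
  rownames(out) <- NULL
  out
}

#' Barcode table of a cohort
#'
#' @param cohort A QC-filtered [cohort_table()].
#' @param rhythms Result of [analyse_rhythms()].
#' @return Data frame: one row per individual, treatment factors, the eight
#'   barcode bits and the barcode key string.
#' @export
barcode_table <- function(cohort, rhythms) {
  do.call(rbind, lapply(names(cohort$series), function(id) {
    s <- cohort$series[[id]]
    b <- make_barcode(rhythms[[id]]$call, rhythms[[id]]$canonical)
    cbind(data.frame(individual_id = id,
                     insemination = s$meta$insemination, meal = s$meta$meal,
                     regimen = s$meta$regimen, stringsAsFactors = FALSE),
          as.data.frame(t(unclass(b))),
          data.frame(barcode = barcode_key(b), stringsAsFactors = FALSE))
  }))
}
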