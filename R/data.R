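#' Rhythmicity classification counts from a laboratory study
#'
#' Counts of rhythmic and arrhythmic *Anopheles coluzzii* females by
#' treatment (insemination status x food source) and light regimen, as
#' classified by chi-square periodograms in a week-long locomotor-activity
#' experiment (200 females; first/last days and dead individuals excluded).
#' Useful as a worked example for [williams_g_test()]: collapsing over
#' treatments gives the 2 x 2 rhythmicity-by-regimen table.
#'
#' @return Data frame with columns `insemination`, `meal`, `regimen`,
#'   `n_rhythmic`, `n_arrhythmic`.
#' @examples
#' counts <- coluzzii_rhythm_counts()
#' tab <- rbind(LD = colSums(counts[counts$regimen == "LD", 4:5]),
#'              DD = colSums(counts[counts$regimen == "DD", 4:5]))
#' williams_g_test(tab)
#' @export
coluzzii_rhythm_counts <- function() {
  data.frame(
    insemination = c("virgin", "virgin", "inseminated", "inseminated",
                     "inseminated", "inseminated", "virgin", "virgin"),
    meal = c("glucose", "glucose", "glucose", "glucose",
             "blood", "blood", "blood", "blood"),
    regimen = c("LD", "DD", "LD", "DD", "LD", "DD", "LD", "DD"),
    n_rhythmic = c(32L, 15L, 24L, 11L, 21L, 11L, 35L, 14L),
    n_arrhythmic = c(1L, 0L, 1L, 4L, 1L, 3L, 1L, 1L),
    stringsAsFactors = FALSE)
}
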