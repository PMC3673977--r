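#' Published co-occurrence count tables from the 15-fetus longitudinal study
#'
#' Observed numbers of co-occurrence events per ordinal complexity category,
#' pooled over the 15 healthy fetuses of the original 4-D ultrasound study, by
#' nominal gestational age. These are the printed reference tables the
#' tabulation and simulation defaults are calibrated against: the
#' all-movements scheme counts events by distinct facial movements involved
#' (six categories, "sextuple or more" on top); the gestalt scheme counts only
#' the six pain/distress-gestalt movements (five categories).
#'
#' @param scheme `"all"` or `"gestalt"`.
#' @return A count table tibble with columns `age_weeks`, `cat_1` ... `cat_K`
#'   and `total`, one row per nominal age (24/28/32/36 weeks).
#' @examples
#' reference_counts("gestalt")
#' row_percentages(reference_counts("all"))
#' @export
reference_counts <- function(scheme = c("all", "gestalt")) {
  scheme <- match.arg(scheme)
  if (scheme == "all") {
    out <- tibble::tribble(
      ~age_weeks, ~cat_1, ~cat_2, ~cat_3, ~cat_4, ~cat_5, ~cat_6,
      24,  482L, 251L,  93L,  37L,  5L,  1L,
      28,  336L, 319L, 240L, 107L, 24L, 11L,
      32,  145L, 245L, 235L, 130L, 28L, 10L,
      36,   35L, 151L, 236L, 186L, 44L,  3L
    )
  } else {
    out <- tibble::tribble(
      ~age_weeks, ~cat_1, ~cat_2, ~cat_3, ~cat_4, ~cat_5,
      24,  448L,  96L,  29L,   2L,  0L,
      28,  391L, 230L,  76L,  15L,  0L,
      32,  201L, 241L,  93L,  10L,  2L,
      36,  100L, 192L,  82L,  11L,  2L
    )
  }
  out$total <- as.integer(rowSums(out[grep("^cat_", names(out))]))
  out
}

#' Published row percentages of the reference count tables
#'
#' The percentage rows as printed alongside [reference_counts()] (one
#' decimal, half-up). Useful as a fixed expectation when checking
#' [row_percentages()].
#'
#' @inheritParams reference_counts
#' @return A tibble shaped like [reference_counts()] with percentages in the
#'   `cat_*` columns.
#' @export
reference_percentages <- function(scheme = c("all", "gestalt")) {
  scheme <- match.arg(scheme)
  if (scheme == "all") {
    out <- tibble::tribble(
      ~age_weeks, ~cat_1, ~cat_2, ~cat_3, ~cat_4, ~cat_5, ~cat_6,
      24, 55.5, 28.9, 10.7,  4.3, 0.6, 0.1,
      28, 32.4, 30.8, 23.1, 10.3, 2.3, 1.1,
      32, 18.3, 30.9, 29.6, 16.4, 3.5, 1.3,
      36,  5.3, 23.1, 36.0, 28.4, 6.7, 0.5
    )
  } else {
    out <- tibble::tribble(
      ~age_weeks, ~cat_1, ~cat_2, ~cat_3, ~cat_4, ~cat_5,
      24, 77.9, 16.7,  5.0, 0.3, 0.0,
      28, 54.9, 32.3, 10.7, 2.1, 0.0,
      32, 36.7, 44.1, 17.0, 1.8, 0.4,
      36, 25.8, 49.6, 21.2, 2.8, 0.5
    )
  }
  out$total <- reference_counts(scheme)$total
  out
}
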