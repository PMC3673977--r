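#' Read and validate a facial-movement annotation stream
#'
#' An annotation stream is the unit the human coders produce: one row per
#' timestamped onset of one of the 19 coded facial movements within an
#' observation session. Onset times are expressed in seconds on the
#' accumulated-codable-time axis (coding pauses while the face is not visible,
#' so the clock only advances while the face is codable; see
#' [rebase_onsets()] for streams recorded in raw scan time).
#'
#' @param path Path to a UTF-8 CSV file with header columns
#'   `fetus_id,session_id,gestational_age_weeks,sex,onset_s,code_id` and an
#'   optional `coder_id` column (dual-coded reliability streams).
#' @return A validated annotation tibble, sorted by session and onset. An empty
#'   file body yields an empty tibble with a warning.
#' @seealso [validate_annotations()], [cluster_events()]
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("annotation file does not exist: %s", path))
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0) {
    warn(sprintf("annotation file %s contains no rows", basename(path)))
  }
  validate_annotations(df)
}

#' Validate an annotation tibble
#'
#' Checks the column schema, that every `code_id` is one of the 19 registered
#' movement codes, that onsets are non-negative and that sex labels are
#' `"female"`/`"male"`. Rows are sorted by fetus, session and onset (ties kept
#' in input order).
#'
#' @param annotations A data frame of annotations (see [read_annotations()]
#'   for the schema).
#' @return The annotation tibble, validated and sorted.
#' @export
validate_annotations <- function(annotations) {
  required <- c("fetus_id", "session_id", "gestational_age_weeks", "sex",
                "onset_s", "code_id")
  assert_columns(annotations, required, "annotation stream")
  df <- tibble::as_tibble(annotations)
  if (nrow(df) == 0) {
    return(dplyr::select(df, dplyr::any_of(c(required, "coder_id"))))
  }

  bad_code <- which(!(df$code_id %in% movement_codes()$code_id))
  if (length(bad_code) > 0) {
    abort(sprintf(
      "unknown movement code id(s) %s at row(s) %s (valid ids are 1-19)",
      paste(unique(df$code_id[bad_code]), collapse = ", "),
      paste(utils::head(bad_code, 5), collapse = ", ")
    ))
  }
  bad_onset <- which(df$onset_s < 0 | !is.finite(df$onset_s))
  if (length(bad_onset) > 0) {
    abort(sprintf(
      "negative or non-finite onset_s at row(s) %s",
      paste(utils::head(bad_onset, 5), collapse = ", ")
    ))
  }
  bad_sex <- which(!(df$sex %in% c("female", "male")))
  if (length(bad_sex) > 0) {
    abort(sprintf(
      "sex must be \"female\" or \"male\"; offending row(s) %s",
      paste(utils::head(bad_sex, 5), collapse = ", ")
    ))
  }
  bad_age <- which(df$gestational_age_weeks < 20 | df$gestational_age_weeks > 42)
  if (length(bad_age) > 0) {
    abort(sprintf(
      "gestational_age_weeks outside [20, 42] at row(s) %s",
      paste(utils::head(bad_age, 5), collapse = ", ")
    ))
  }
  df$code_id <- as.integer(df$code_id)
  dplyr::arrange(df, .data$fetus_id, .data$session_id, .data$onset_s)
}

#' Rebase raw-scan-time onsets onto the accumulated-codable-time axis
#'
#' When a stream was annotated in raw recording time, pauses (face not
#' visible) must be removed before event clustering, otherwise a pause could
#' artificially split a co-occurrence event. Given the visible segments of
#' each session, onsets are mapped to cumulative codable seconds: an onset at
#' raw time `t` inside a segment becomes (time elapsed within earlier
#' segments) + (t - segment start).
#'
#' @param annotations Annotation tibble with `onset_s` in raw recording time.
#' @param segments Tibble of visible windows with columns
#'   `fetus_id,session_id,start_s,end_s` (non-overlapping within a session).
#' @return The annotation tibble with `onset_s` rebased. Annotations falling
#'   outside every visible segment raise an error.
#' @export
rebase_onsets <- function(annotations, segments) {
  assert_columns(segments, c("fetus_id", "session_id", "start_s", "end_s"),
                 "segment table")
  df <- tibble::as_tibble(annotations)
  seg <- dplyr::arrange(tibble::as_tibble(segments),
                        .data$fetus_id, .data$session_id, .data$start_s)
  seg <- dplyr::group_by(seg, .data$fetus_id, .data$session_id)
  seg <- dplyr::mutate(
    seg,
    codable_before = cumsum(dplyr::lag(.data$end_s - .data$start_s, default = 0))
  )
  seg <- dplyr::ungroup(seg)

  joined <- dplyr::inner_join(
    df, seg,
    by = c("fetus_id", "session_id"),
    relationship = "many-to-many"
  )
  joined <- dplyr::filter(joined, .data$onset_s >= .data$start_s,
                          .data$onset_s <= .data$end_s)
  if (nrow(joined) < nrow(df)) {
    abort("some annotations fall outside every visible segment of their session")
  }
  joined$onset_s <- joined$codable_before + (joined$onset_s - joined$start_s)
  out <- dplyr::select(joined, -"start_s", -"end_s", -"codable_before")
  dplyr::arrange(out, .data$fetus_id, .data$session_id, .data$onset_s)
}
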