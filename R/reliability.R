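#' Align two coders' annotation streams into per-code confusion counts
#'
#' The session timeline is partitioned into bins of `bin_s` seconds; for each
#' movement code, each bin is scored present/absent for each coder, giving a
#' 2x2 confusion table per code: `a` both present, `b` coder A only, `c`
#' coder B only, `d` both absent. The bin width defaults to the 1-second
#' co-occurrence window of the event coding.
#'
#' @param stream_a,stream_b Annotation tibbles for the same session (same
#'   `fetus_id` and `session_id`), one per coder.
#' @param bin_s Bin width in seconds.
#' @param duration_s Codable session duration; defaults to 600 s, the study's
#'   accumulated codable time per observation period (extended if an onset
#'   exceeds it).
#' @param codes Which code ids to tally; by default the codes observed by at
#'   least one coder (codes never observed have undefined kappa).
#' @return A tibble with columns `code_id,a,b,c,d,bin_s`; `a+b+c+d` equals the
#'   number of bins for every code.
#' @export
align_coders <- function(stream_a, stream_b, bin_s = 1.0, duration_s = 600,
                         codes = NULL) {
  a_df <- tibble::as_tibble(stream_a)
  b_df <- tibble::as_tibble(stream_b)
  key <- function(d) unique(d[c("fetus_id", "session_id")])
  if (nrow(a_df) > 0 && nrow(b_df) > 0) {
    ka <- key(a_df); kb <- key(b_df)
    if (nrow(ka) != 1 || nrow(kb) != 1 || !identical(ka, kb)) {
      abort("both streams must cover exactly one common (fetus_id, session_id)")
    }
  }
  max_onset <- suppressWarnings(max(c(a_df$onset_s, b_df$onset_s, 0)))
  n_bins <- max(ceiling(duration_s / bin_s), floor(max_onset / bin_s) + 1)
  if (is.null(codes)) codes <- sort(unique(c(a_df$code_id, b_df$code_id)))

  bins_of <- function(d, code) {
    unique(pmin(floor(d$onset_s[d$code_id == code] / bin_s) + 1, n_bins))
  }
  purrr::map_dfr(codes, function(code) {
    in_a <- bins_of(a_df, code)
    in_b <- bins_of(b_df, code)
    a <- length(intersect(in_a, in_b))
    tibble::tibble(
      code_id = as.integer(code),
      a = a,
      b = length(in_a) - a,
      c = length(in_b) - a,
      d = n_bins - length(union(in_a, in_b)),
      bin_s = bin_s
    )
  })
}

#' Cohen's kappa from a 2x2 confusion table
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with observed
#' agreement `p_o = (a + d) / n` and chance agreement
#' `p_e = ((a+b)(a+c) + (c+d)(b+d)) / n^2`. Vectorised over rows.
#'
#' @param a,b,c,d Confusion counts: both present, first coder only, second
#'   coder only, both absent.
#' @return Kappa in \[-1, 1\]. Degenerate marginals (`p_e = 1`, e.g. a code
#'   marked in every bin by both coders) are an error: agreement beyond chance
#'   is then undefined.
#' @examples
#' cohen_kappa(40, 10, 10, 40) # 0.6
#' @export
cohen_kappa <- function(a, b, c, d) {
  n <- a + b + c + d
  if (any(n <= 0)) abort("confusion table is empty (a+b+c+d must be > 0)")
  if (any(c(a, b, c, d) < 0)) abort("confusion counts must be non-negative")
  p_o <- (a + d) / n
  p_e <- ((a + b) * (a + c) + (c + d) * (b + d)) / n^2
  if (any(abs(1 - p_e) < 1e-12)) {
    abort("kappa undefined: chance agreement p_e = 1 (degenerate marginals)")
  }
  (p_o - p_e) / (1 - p_e)
}

#' Per-code kappa and gestalt/overall reliability summaries
#'
#' `kappa_by_code()` appends a `kappa` column to an [align_coders()] table.
#' `summarise_kappa()` reports the unweighted mean and range of the per-code
#' kappas, separately for all coded movements and for the six
#' pain/distress-gestalt movements. Codes never marked by either coder are
#' excluded before averaging (their kappa is undefined).
#'
#' @param confusion A confusion tibble from [align_coders()].
#' @return `kappa_by_code()`: the confusion tibble plus `kappa`.
#'   `summarise_kappa()`: a tibble with one row per subset
#'   (`"all"`, `"gestalt"`) and columns `n_codes,mean_kappa,min_kappa,max_kappa`.
#' @export
kappa_by_code <- function(confusion) {
  assert_columns(confusion, c("code_id", "a", "b", "c", "d"), "confusion table")
  conf <- dplyr::filter(tibble::as_tibble(confusion),
                        .data$a + .data$b + .data$c > 0)
  dropped <- setdiff(confusion$code_id, conf$code_id)
  if (length(dropped) > 0) {
    warn(sprintf("code(s) %s never observed by either coder; kappa undefined, dropped",
                 paste(dropped, collapse = ", ")))
  }
  dplyr::mutate(conf, kappa = cohen_kappa(.data$a, .data$b, .data$c, .data$d))
}

#' @rdname kappa_by_code
#' @export
summarise_kappa <- function(confusion) {
  per_code <- if ("kappa" %in% names(confusion)) {
    tibble::as_tibble(confusion)
  } else {
    kappa_by_code(confusion)
  }
  if (nrow(per_code) == 0) abort("no codes with observations; kappa undefined")
  one <- function(d, label) {
    tibble::tibble(
      subset = label, n_codes = nrow(d),
      mean_kappa = mean(d$kappa),
      min_kappa = min(d$kappa), max_kappa = max(d$kappa)
    )
  }
  gest <- dplyr::filter(per_code, .data$code_id %in% gestalt_code_ids())
  out <- one(per_code, "all")
  if (nrow(gest) > 0) out <- dplyr::bind_rows(out, one(gest, "gestalt"))
  out
}
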