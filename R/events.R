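#' Cluster annotations into co-occurrence events
#'
#' Co-occurring facial movements are movements whose onsets lie within one
#' second of one another. Under the default `"chain"` rule this is read as
#' single-linkage chaining: two annotations belong to the same event whenever
#' they are connected by a chain of consecutive onset gaps each at most
#' `window_s` (the transitive closure of the pairwise relation). The
#' alternative `"anchor"` rule closes an event `window_s` after its first
#' member's onset. Comparisons use an absolute tolerance of 1e-9 so that a gap
#' of exactly one second never flips with floating-point representation.
#'
#' @param annotations Annotation tibble (see [read_annotations()]); onsets
#'   must be sorted within session, as [validate_annotations()] guarantees.
#' @param window_s Co-occurrence window in seconds (default 1.0).
#' @param rule `"chain"` (single-linkage, default) or `"anchor"` (fixed window
#'   from the first movement of the event).
#' @return The annotation tibble with an integer `event` column numbering
#'   events in temporal order within each session. Every annotation belongs to
#'   exactly one event.
#' @examples
#' ann <- tibble::tibble(
#'   fetus_id = "f1", session_id = "s1", gestational_age_weeks = 24,
#'   sex = "female", onset_s = c(0, 0.5, 3), code_id = c(3L, 5L, 3L)
#' )
#' cluster_events(ann)
#' @export
cluster_events <- function(annotations, window_s = 1.0,
                           rule = c("chain", "anchor")) {
  rule <- match.arg(rule)
  df <- tibble::as_tibble(annotations)
  if (nrow(df) == 0) {
    df$event <- integer(0)
    return(df)
  }
  df <- dplyr::group_by(df, .data$fetus_id, .data$session_id)
  df <- dplyr::mutate(df, event = assign_events(.data$onset_s, window_s, rule))
  dplyr::ungroup(df)
}

# event ids for one session's sorted onset vector
assign_events <- function(onset, window_s, rule, tol = 1e-9) {
  n <- length(onset)
  if (n == 0) return(integer(0))
  if (rule == "chain") {
    new_event <- c(TRUE, diff(onset) > window_s + tol)
  } else {
    new_event <- logical(n)
    anchor <- onset[1]
    new_event[1] <- TRUE
    for (i in seq_len(n)[-1]) {
      if (onset[i] - anchor > window_s + tol) {
        new_event[i] <- TRUE
        anchor <- onset[i]
      }
    }
  }
  cumsum(new_event)
}

#' Summarise clustered annotations into one row per co-occurrence event
#'
#' Event complexity is the number of *distinct* movement codes among the
#' event's members (a repeated occurrence of one code within an event counts
#' once): `complexity_all` over all 19 codes, `complexity_gestalt` over the 6
#' pain/distress-gestalt codes only.
#'
#' @param clustered Output of [cluster_events()].
#' @return A tibble with one row per event: session identifiers, event number,
#'   first onset, member count, `complexity_all` and `complexity_gestalt`.
#' @export
summarise_events <- function(clustered) {
  assert_columns(clustered, "event", "clustered annotations")
  gestalt <- gestalt_code_ids()
  out <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(clustered),
                    .data$fetus_id, .data$session_id,
                    .data$gestational_age_weeks, .data$sex, .data$event),
    onset_first_s = min(.data$onset_s),
    n_members = dplyr::n(),
    complexity_all = dplyr::n_distinct(.data$code_id),
    complexity_gestalt = dplyr::n_distinct(.data$code_id[.data$code_id %in% gestalt]),
    .groups = "drop"
  )
  dplyr::arrange(out, .data$fetus_id, .data$session_id, .data$onset_first_s)
}

#' Complexity of one event's member codes
#'
#' The number of distinct movement codes among an event's members, optionally
#' restricted to the pain/distress-gestalt subset. Repeated occurrences of a
#' code count once. This is the per-event scalar behind the
#' `complexity_all` / `complexity_gestalt` columns of [summarise_events()].
#'
#' @param codes Integer vector of movement code ids of one event's members.
#' @param subset `"all"` or `"gestalt"`.
#' @return A non-negative integer (0 is possible under `"gestalt"` when no
#'   member belongs to the gestalt).
#' @examples
#' event_complexity(c(3, 5, 17), "gestalt") # 3
#' event_complexity(c(3, 3, 5), "all")      # distinct codes: 2
#' @export
event_complexity <- function(codes, subset = c("all", "gestalt")) {
  subset <- match.arg(subset)
  if (length(codes) == 0) abort("an event must have at least one member")
  if (subset == "gestalt") codes <- codes[codes %in% gestalt_code_ids()]
  length(unique(codes))
}

#' Map an event complexity to its ordinal response category
#'
#' The ordinal response pools rare high complexities into a top category:
#' single, double, triple, quadruple, quintuple and "sextuple or more" for the
#' all-movements scheme (6 categories), and single through "quintuple or more"
#' for the gestalt scheme (5 categories).
#'
#' @param complexity Integer vector of event complexities (all >= 1; events
#'   with zero gestalt movements are excluded upstream, not categorised).
#' @param scheme `"all"` (6 categories) or `"gestalt"` (5 categories).
#' @return Integer category indices.
#' @export
to_ordinal_category <- function(complexity, scheme = c("all", "gestalt")) {
  scheme <- match.arg(scheme)
  if (any(complexity < 1)) {
    abort("complexity must be >= 1; zero-complexity events are excluded upstream")
  }
  pmin(as.integer(complexity), n_categories(scheme))
}

n_categories <- function(scheme = c("all", "gestalt")) {
  if (match.arg(scheme) == "all") 6L else 5L
}

#' Tabulate co-occurrence events into ordinal category counts
#'
#' Events are clustered over *all* annotations; under the gestalt scheme each
#' event's complexity is the number of distinct gestalt codes inside it, and
#' events containing no gestalt movement are dropped before counting (which is
#' why gestalt totals are smaller than all-movements totals).
#'
#' @param annotations Annotation tibble.
#' @param scheme `"all"` or `"gestalt"`.
#' @param by `"age_bin"` pools fetuses within the nominal observation week
#'   (24/28/32/36; sessions further than 2 weeks from every nominal age are an
#'   error), `"session"` keeps one row per session for modelling.
#' @param window_s,rule Passed to [cluster_events()].
#' @return A count table tibble: grouping columns, `cat_1` ... `cat_K` and
#'   `total`. `K` is 6 (`"all"`) or 5 (`"gestalt"`).
#' @examples
#' design <- simulation_design(seed = 1)
#' ann <- simulate_annotations(design)$annotations
#' tabulate_counts(ann, scheme = "gestalt", by = "age_bin")
#' @export
tabulate_counts <- function(annotations, scheme = c("all", "gestalt"),
                            by = c("age_bin", "session"),
                            window_s = 1.0, rule = c("chain", "anchor")) {
  scheme <- match.arg(scheme)
  by <- match.arg(by)
  rule <- match.arg(rule)
  K <- n_categories(scheme)
  cat_cols <- paste0("cat_", seq_len(K))

  df <- tibble::as_tibble(annotations)
  if (nrow(df) == 0) {
    empty <- tibble::tibble(!!!setNames(
      rep(list(integer(0)), K + 1), c(cat_cols, "total")))
    key <- if (by == "age_bin") {
      tibble::tibble(age_weeks = numeric(0))
    } else {
      tibble::tibble(fetus_id = character(0), session_id = character(0),
                     gestational_age_weeks = numeric(0), sex = character(0))
    }
    return(dplyr::bind_cols(key, empty))
  }

  ev <- summarise_events(cluster_events(df, window_s = window_s, rule = rule))
  ev$complexity <- if (scheme == "all") ev$complexity_all else ev$complexity_gestalt
  ev <- dplyr::filter(ev, .data$complexity >= 1)
  ev$category <- to_ordinal_category(ev$complexity, scheme)

  if (by == "age_bin") {
    ev$age_weeks <- bin_age(ev$gestational_age_weeks)
    keys <- "age_weeks"
  } else {
    keys <- c("fetus_id", "session_id", "gestational_age_weeks", "sex")
  }

  counts <- dplyr::count(ev, dplyr::across(dplyr::all_of(keys)), .data$category)
  wide <- tidyr::pivot_wider(
    counts,
    names_from = "category", values_from = "n",
    names_prefix = "cat_", values_fill = 0L
  )
  for (col in setdiff(cat_cols, names(wide))) wide[[col]] <- 0L
  wide <- dplyr::select(wide, dplyr::all_of(keys), dplyr::all_of(cat_cols))
  wide$total <- as.integer(rowSums(wide[cat_cols]))
  dplyr::arrange(wide, dplyr::across(dplyr::all_of(keys)))
}

# snap recorded gestational ages to the nearest nominal observation week
bin_age <- function(age_weeks, tolerance_weeks = 2) {
  nominal <- nominal_ages()
  idx <- vapply(age_weeks, function(a) which.min(abs(nominal - a)), integer(1))
  off <- abs(age_weeks - nominal[idx])
  if (any(off > tolerance_weeks)) {
    abort(sprintf(
      "gestational age(s) %s not within %.1f weeks of any nominal age (%s)",
      paste(unique(age_weeks[off > tolerance_weeks]), collapse = ", "),
      tolerance_weeks, paste(nominal, collapse = "/")
    ))
  }
  nominal[idx]
}

#' Convert a count table to row percentages
#'
#' Percentages are `100 * count / total` rounded half-up to one decimal, the
#' convention of the published tables; rounded rows need not sum to exactly
#' 100.
#'
#' @param counts A count table from [tabulate_counts()] (or any tibble with
#'   `cat_*` columns and a positive `total`).
#' @return The tibble with each `cat_*` column replaced by its row percentage
#'   and `total` retained.
#' @examples
#' tab <- tibble::tibble(cat_1 = 482L, cat_2 = 251L, cat_3 = 93L,
#'                       cat_4 = 37L, cat_5 = 5L, cat_6 = 1L, total = 869L)
#' row_percentages(tab)
#' @export
row_percentages <- function(counts) {
  cat_cols <- grep("^cat_", names(counts), value = TRUE)
  if (length(cat_cols) == 0) abort("no cat_* columns found")
  assert_columns(counts, "total", "count table")
  if (any(counts$total <= 0)) {
    abort("row percentages are undefined for a zero total")
  }
  out <- tibble::as_tibble(counts)
  for (col in cat_cols) {
    out[[col]] <- round_half_up(100 * out[[col]] / out$total, 1)
  }
  out
}
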