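#' Describe a synthetic longitudinal observation design
#'
#' Encodes the study conditions the generator emulates: 15 healthy fetuses
#' (8 girls, 7 boys) each observed at nominal gestational ages 24, 28, 32 and
#' 36 weeks, with 600 seconds of codable scan per session. Default events per
#' session are the published pooled event totals per age divided by the 15
#' fetuses (gestalt scheme 38/47/36/26; all-movements 58/69/53/44), and the
#' default true parameters are the published fitted values for the chosen
#' scheme with cutpoints calibrated to the pooled observed category marginals
#' (see [default_true_params()]).
#'
#' @param n_fetuses Number of fetuses.
#' @param ages_weeks Nominal observation ages (weeks).
#' @param n_female Number of female fetuses (the rest are male).
#' @param scheme `"gestalt"` or `"all"`; sets category count, default event
#'   rates and default true parameters.
#' @param events_per_session Integer vector, one entry per age: events
#'   generated in each session at that age.
#' @param true_params An [ordinal_params()] object used as the generative
#'   truth.
#' @param codable_duration_s Codable seconds per session.
#' @param seed Integer seed; all generator output is a pure function of the
#'   design including this seed.
#' @return A `simulation_design` list.
#' @examples
#' simulation_design(seed = 42)
#' @export
simulation_design <- function(n_fetuses = 15,
                              ages_weeks = c(24, 28, 32, 36),
                              n_female = 8,
                              scheme = c("gestalt", "all"),
                              events_per_session = NULL,
                              true_params = NULL,
                              codable_duration_s = 600,
                              seed = 1) {
  scheme <- match.arg(scheme)
  if (is.null(events_per_session)) {
    totals <- reference_counts(scheme)$total
    if (length(totals) != length(ages_weeks)) {
      abort("supply events_per_session when ages_weeks is not the 4-age default")
    }
    events_per_session <- round(totals / 15)
  }
  if (length(events_per_session) == 1) {
    events_per_session <- rep(events_per_session, length(ages_weeks))
  }
  if (length(events_per_session) != length(ages_weeks)) {
    abort("events_per_session must have one entry per age")
  }
  if (any(events_per_session <= 0)) abort("events_per_session must be positive")
  if (n_female > n_fetuses || n_female < 0) abort("invalid n_female")
  if (is.null(true_params)) true_params <- default_true_params(scheme)
  structure(
    list(
      n_fetuses = n_fetuses, ages_weeks = ages_weeks, n_female = n_female,
      scheme = scheme, events_per_session = as.integer(events_per_session),
      true_params = true_params, codable_duration_s = codable_duration_s,
      seed = as.integer(seed)
    ),
    class = "simulation_design"
  )
}

#' Default generative truth for a complexity scheme
#'
#' The published fitted age slope and random-intercept variance for the
#' scheme (gestalt: beta_age 0.1965, sigma2 0.392; all movements: 0.2283,
#' 0.417), with cutpoints calibrated so that the model at the mid-study age
#' (30 weeks, u = 0) reproduces the pooled observed category marginals:
#' `alpha_j = logit(pooled cumulative proportion_j) + beta_age * 30`.
#'
#' @inheritParams simulation_design
#' @return An [ordinal_params()] object.
#' @export
default_true_params <- function(scheme = c("gestalt", "all")) {
  scheme <- match.arg(scheme)
  beta_age <- if (scheme == "gestalt") 0.1965 else 0.2283
  sigma2 <- if (scheme == "gestalt") 0.392 else 0.417
  ref <- reference_counts(scheme)
  tot <- colSums(ref[grep("^cat_", names(ref))])
  cum <- cumsum(tot) / sum(tot)
  alpha <- qlogis(pmin(cum[-length(cum)], 1 - 1e-6)) + beta_age * 30
  ordinal_params(unname(alpha), beta_age = beta_age, sigma2 = sigma2)
}

# deterministic sex assignment: first n_female fetuses female
design_fetuses <- function(design) {
  tibble::tibble(
    fetus_id = sprintf("f%02d", seq_len(design$n_fetuses)),
    sex = rep(c("female", "male"),
              c(design$n_female, design$n_fetuses - design$n_female))
  )
}

#' Simulate per-session ordinal category counts from the model
#'
#' Draws one random intercept per fetus from N(0, sigma2), then for every
#' (fetus, age) session draws the design's number of events multinomially
#' from the model's category probabilities at that fetus's covariates and
#' random effect. This is the generative direction of the fitted model, so
#' [fit_clmm()] applied to the output is a parameter-recovery experiment.
#'
#' @param design A [simulation_design()].
#' @param seed Optional override of `design$seed`.
#' @return A list: `counts` (per-session tibble ready for [fit_clmm()]),
#'   `fetuses` (sex and true random intercept `u` per fetus) and the design.
#' @export
simulate_counts <- function(design, seed = NULL) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(seed %||% design$seed)
  fet <- design_fetuses(design)
  fet$u <- rnorm(design$n_fetuses, 0, sqrt(design$true_params$sigma2))
  J <- length(design$true_params$cutpoints) + 1

  grid <- tidyr::expand_grid(
    fetus_id = fet$fetus_id,
    age_idx = seq_along(design$ages_weeks)
  )
  grid <- dplyr::left_join(grid, fet, by = "fetus_id")
  grid$gestational_age_weeks <- design$ages_weeks[grid$age_idx]
  grid$session_id <- sprintf("%s_w%02d", grid$fetus_id, grid$gestational_age_weeks)
  grid$n_events <- design$events_per_session[grid$age_idx]

  probs <- category_probs(design$true_params,
                          age = grid$gestational_age_weeks,
                          male = as.numeric(grid$sex == "male"),
                          u = grid$u)
  pmat <- as.matrix(probs[paste0("cat_", seq_len(J))])
  counts <- t(vapply(
    seq_len(nrow(grid)),
    function(i) rmultinom(1, grid$n_events[i], pmat[i, ])[, 1],
    integer(J)
  ))
  colnames(counts) <- paste0("cat_", seq_len(J))

  out <- dplyr::bind_cols(
    dplyr::select(grid, "fetus_id", "session_id", "gestational_age_weeks", "sex"),
    tibble::as_tibble(counts)
  )
  out$total <- as.integer(rowSums(counts))
  list(counts = out, fetuses = fet, design = design)
}

#' Reconstruct an annotation stream realising given category counts
#'
#' The inverse of event coding, used for round-trip testing: for each event
#' of ordinal category k, k distinct movement codes are drawn (gestalt codes
#' under the gestalt scheme, any of the 19 otherwise), member onsets are
#' chained 0.3 s apart (every within-event gap <= 1 s) and consecutive events
#' are separated by 1.5 s (> the 1 s window), so
#' `tabulate_counts(cluster_events(stream))` returns exactly the input
#' counts.
#'
#' @param session_counts Integer vector of events per category
#'   (`cat_1` ... `cat_K`) for one session.
#' @param scheme `"gestalt"` or `"all"`.
#' @param fetus_id,session_id,gestational_age_weeks,sex Session identity.
#' @param codable_duration_s Available codable time; an infeasible packing
#'   (too many events for the duration) is an error.
#' @param shuffle Randomise event order along the timeline.
#' @return An annotation tibble.
#' @export
simulate_stream <- function(session_counts, scheme = c("gestalt", "all"),
                            fetus_id = "f01", session_id = "s1",
                            gestational_age_weeks = 24, sex = "female",
                            codable_duration_s = 600, shuffle = TRUE) {
  scheme <- match.arg(scheme)
  K <- n_categories(scheme)
  if (length(session_counts) != K) {
    abort(sprintf("session_counts must have %d categories for the %s scheme",
                  K, scheme))
  }
  if (any(session_counts < 0)) abort("counts must be non-negative")
  complexities <- rep(seq_len(K), times = session_counts)
  if (length(complexities) == 0) {
    return(validate_annotations(tibble::tibble(
      fetus_id = character(0), session_id = character(0),
      gestational_age_weeks = numeric(0), sex = character(0),
      onset_s = numeric(0), code_id = integer(0)
    )))
  }
  if (shuffle) complexities <- sample(complexities)
  within_gap <- 0.3; between_gap <- 1.5
  need <- sum((complexities - 1) * within_gap) +
    (length(complexities) - 1) * between_gap
  if (need > codable_duration_s) {
    abort(sprintf("infeasible packing: %d events need %.0f s > %.0f s codable",
                  length(complexities), need, codable_duration_s))
  }
  pool <- if (scheme == "gestalt") gestalt_code_ids() else movement_codes()$code_id

  t0 <- 0
  rows <- purrr::map(complexities, function(k) {
    onsets <- t0 + within_gap * (seq_len(k) - 1)
    codes <- sample(pool, k)
    t0 <<- max(onsets) + between_gap
    tibble::tibble(onset_s = onsets, code_id = as.integer(codes))
  })
  ann <- dplyr::bind_rows(rows)
  ann <- dplyr::mutate(ann,
    fetus_id = fetus_id, session_id = session_id,
    gestational_age_weeks = gestational_age_weeks, sex = sex,
    .before = 1
  )
  validate_annotations(ann)
}

#' Simulate a full multi-session annotation bundle
#'
#' Draws session category counts with [simulate_counts()] and realises each
#' session as an annotation stream with [simulate_stream()], giving a
#' complete synthetic study that exercises the whole pipeline (reading,
#' clustering, tabulation, modelling) with known truth.
#'
#' @inheritParams simulate_counts
#' @return A list: `annotations` (one tibble over all sessions), `counts`,
#'   `fetuses`, `design`.
#' @export
simulate_annotations <- function(design, seed = NULL) {
  sim <- simulate_counts(design, seed = seed)
  cat_cols <- grep("^cat_", names(sim$counts), value = TRUE)
  ann <- purrr::pmap_dfr(
    sim$counts,
    function(fetus_id, session_id, gestational_age_weeks, sex, ...) {
      cnt <- unlist(list(...))[cat_cols]
      simulate_stream(
        as.integer(cnt), scheme = design$scheme,
        fetus_id = fetus_id, session_id = session_id,
        gestational_age_weeks = gestational_age_weeks, sex = sex,
        codable_duration_s = design$codable_duration_s
      )
    }
  )
  c(list(annotations = ann), sim)
}

#' Simulate an independent re-coding of a stream
#'
#' Fixture generator for the reliability module: a second coder who misses
#' each annotation independently with probability `miss_rate` and marks onset
#' times with uniform jitter in (-`jitter_s`, `jitter_s`), truncated at 0.
#'
#' @param stream An annotation tibble (one session).
#' @param miss_rate Per-annotation miss probability in \[0, 1).
#' @param jitter_s Half-width of the onset jitter in seconds.
#' @param seed Optional seed.
#' @return The re-coded annotation tibble.
#' @export
simulate_dual_coding <- function(stream, miss_rate = 0.05, jitter_s = 0.2,
                                 seed = NULL) {
  if (miss_rate < 0 || miss_rate >= 1) abort("miss_rate must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  df <- tibble::as_tibble(stream)
  keep <- runif(nrow(df)) >= miss_rate
  df <- df[keep, , drop = FALSE]
  if (nrow(df) > 0 && jitter_s > 0) {
    df$onset_s <- pmax(0, df$onset_s + runif(nrow(df), -jitter_s, jitter_s))
  }
  dplyr::arrange(df, .data$fetus_id, .data$session_id, .data$onset_s)
}
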