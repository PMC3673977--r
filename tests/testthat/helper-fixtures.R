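# shared fixture builders -- everything is generated in code, no stored data

# minimal annotation tibble for one session
make_annotations <- function(onsets, codes,
                             fetus_id = "f1", session_id = "s1",
                             age = 24, sex = "female") {
  tibble::tibble(
    fetus_id = fetus_id, session_id = session_id,
    gestational_age_weeks = age, sex = sex,
    onset_s = onsets, code_id = as.integer(codes)
  )
}

# brute-force transitive-closure clustering: pairwise |gap| <= window builds
# a graph; connected components are events (independent oracle for
# cluster_events under the chain rule)
brute_force_events <- function(onsets, window_s = 1.0, tol = 1e-9) {
  n <- length(onsets)
  if (n == 0) return(integer(0))
  adj <- abs(outer(onsets, onsets, `-`)) <= window_s + tol
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      linked <- which(adj[i, ])
      m <- min(comp[linked])
      if (any(comp[linked] != m)) {
        comp[linked] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp[order(onsets)]))
}

# brute-force marginal log-likelihood by dense trapezoid integration over u
# (independent oracle for marginal_loglik)
trapezoid_loglik <- function(params, counts, n_grid = 1e5) {
  cat_cols <- grep("^cat_", names(counts), value = TRUE)
  N <- as.matrix(counts[cat_cols])
  eta <- params$beta_age * counts$gestational_age_weeks +
    params$beta_male * as.numeric(counts$sex == "male")
  sigma <- sqrt(params$sigma2)
  # generous range: the posterior can sit far from the prior's centre when
  # the covariate pattern and counts disagree
  hw <- 10 * sigma + 25
  us <- seq(-hw, hw, length.out = n_grid)
  total <- 0
  for (f in unique(counts$fetus_id)) {
    rows <- which(counts$fetus_id == f)
    lh <- stats::dnorm(us, 0, sigma, log = TRUE)
    for (r in rows) {
      cum <- stats::plogis(outer(-(eta[r] + us), params$cutpoints, `+`))
      pr <- pmax(cbind(cum, 1) - cbind(0, cum), 1e-300)
      lh <- lh + drop(log(pr) %*% N[r, ])
    }
    m <- max(lh)
    total <- total + m + log(sum(exp(lh - m)) * (us[2] - us[1]))
  }
  total
}

# small random per-session count dataset for likelihood oracle checks
random_small_counts <- function(n_fetuses = 3, J = 4, max_events = 12) {
  counts <- matrix(
    sample(0:max_events, n_fetuses * 2 * J, replace = TRUE), ncol = J)
  out <- tibble::tibble(
    fetus_id = rep(sprintf("f%d", seq_len(n_fetuses)), each = 2),
    gestational_age_weeks = rep(c(24, 36), n_fetuses),
    sex = rep(sample(c("female", "male"), n_fetuses, replace = TRUE), each = 2)
  )
  colnames(counts) <- paste0("cat_", seq_len(J))
  dplyr::bind_cols(out, tibble::as_tibble(counts))
}

random_increasing_cutpoints <- function(J) {
  sort(stats::rnorm(J - 1, sd = 2)) + cumsum(c(0, rep(0.2, J - 2)))
}
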