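#' Parameters of the random-intercept proportional-odds model
#'
#' The model for the ordinal complexity category Y of a co-occurrence event of
#' fetus i at session t is the cumulative logit
#' \deqn{\mathrm{logit}\, P(Y_{it} \le j) = \alpha_j - (\beta_1 x_{it} +
#'   \beta_2\, male_i + u_i),}
#' with strictly increasing cutpoints \eqn{\alpha_j} (j = 1..J-1), gestational
#' age \eqn{x_{it}} in weeks, male indicator (female is the baseline), and a
#' per-fetus random intercept \eqn{u_i \sim N(0, \sigma^2)} capturing early
#' versus late developers. A positive \eqn{\beta_1} shifts probability mass
#' toward higher complexity categories as the fetus matures; the larger it is,
#' the faster the developmental progression.
#'
#' @param cutpoints Strictly increasing numeric vector \eqn{\alpha_1 <
#'   \ldots < \alpha_{J-1}}.
#' @param beta_age Age slope per gestational week.
#' @param beta_male Male contrast (0 when sex is excluded).
#' @param sigma2 Random-intercept variance, >= 0.
#' @return An object of class `ordinal_params`.
#' @examples
#' ordinal_params(c(-1, 1), beta_age = 0.2)
#' @export
ordinal_params <- function(cutpoints, beta_age = 0, beta_male = 0, sigma2 = 0) {
  cutpoints <- as.numeric(cutpoints)
  if (length(cutpoints) < 1 || any(!is.finite(cutpoints))) {
    abort("cutpoints must be a finite numeric vector")
  }
  if (length(cutpoints) > 1 && any(diff(cutpoints) <= 0)) {
    abort("cutpoints must be strictly increasing")
  }
  if (sigma2 < 0) abort("sigma2 must be >= 0")
  structure(
    list(cutpoints = cutpoints, beta_age = beta_age,
         beta_male = beta_male, sigma2 = sigma2),
    class = "ordinal_params"
  )
}

#' @export
print.ordinal_params <- function(x, ...) {
  cat("Proportional-odds parameters (J =", length(x$cutpoints) + 1, "categories)\n")
  cat("  cutpoints:", paste(format(x$cutpoints, digits = 4), collapse = " "), "\n")
  cat("  beta_age: ", format(x$beta_age, digits = 4),
      "  beta_male:", format(x$beta_male, digits = 4),
      "  sigma2:", format(x$sigma2, digits = 4), "\n")
  invisible(x)
}

# J-column matrix of category probabilities for a vector of linear predictors
# eta = beta_age * x + beta_male * male + u; rows sum to 1 by construction.
cat_prob_matrix <- function(cutpoints, eta) {
  cum <- plogis(outer(-eta, cutpoints, `+`)) # P(Y <= j), n x (J-1)
  cbind(cum, 1)[, , drop = FALSE] - cbind(0, cum)
}

#' Category probabilities at given covariates
#'
#' Evaluates the model's category probabilities \eqn{P(Y = j)} as adjacent
#' differences of the cumulative logistic probabilities. Vectorised over
#' `age`, `male` and `u` (recycled to a common length).
#'
#' @param params An [ordinal_params()] object.
#' @param age Gestational age(s) in weeks.
#' @param male Male indicator(s) (0 female, 1 male).
#' @param u Random-effect value(s); 0 is the "typical fetus".
#' @return A tibble with `age`, `male`, `u` and probability columns
#'   `cat_1` ... `cat_J` (each row sums to 1).
#' @examples
#' p <- ordinal_params(c(0, 2), beta_age = 0.1)
#' category_probs(p, age = 10, u = 0.5)
#' @export
category_probs <- function(params, age, male = 0, u = 0) {
  stopifnot(inherits(params, "ordinal_params"))
  n <- max(length(age), length(male), length(u))
  age <- rep_len(age, n); male <- rep_len(male, n); u <- rep_len(u, n)
  eta <- params$beta_age * age + params$beta_male * male + u
  pr <- cat_prob_matrix(params$cutpoints, eta)
  colnames(pr) <- paste0("cat_", seq_len(ncol(pr)))
  dplyr::bind_cols(tibble::tibble(age = age, male = male, u = u),
                   tibble::as_tibble(pr))
}

# --- internal data marshalling -------------------------------------------

# Per-session count data -> matrices the likelihood consumes. Accepts the
# output of tabulate_counts(by = "session") or any tibble with fetus_id,
# cat_* count columns and either sex ("female"/"male") or a 0/1 male column,
# and either gestational_age_weeks or age_weeks.
model_frame <- function(data) {
  df <- tibble::as_tibble(data)
  assert_columns(df, "fetus_id", "model data")
  cat_cols <- grep("^cat_[0-9]+$", names(df), value = TRUE)
  cat_cols <- cat_cols[order(as.integer(sub("cat_", "", cat_cols)))]
  if (length(cat_cols) < 2) abort("model data needs >= 2 cat_* count columns")
  age <- df[["gestational_age_weeks"]] %||% df[["age_weeks"]]
  if (is.null(age)) abort("model data needs gestational_age_weeks or age_weeks")
  male <- df[["male"]]
  if (is.null(male)) {
    male <- if ("sex" %in% names(df)) as.numeric(df$sex == "male") else rep(0, nrow(df))
  }
  N <- as.matrix(df[cat_cols])
  if (any(N < 0)) abort("category counts must be non-negative")
  list(
    N = N, age = as.numeric(age), male = as.numeric(male),
    fetus = factor(df$fetus_id), J = length(cat_cols),
    n_events = sum(N)
  )
}

# --- marginal likelihood --------------------------------------------------

# per-row log multinomial kernel sum_j n_j log pi_j at row-specific total
# linear predictors; optionally with first and second derivatives in u
# (logistic algebra: d/du P(Y<=j) = -F_j(1-F_j)).
row_kernel <- function(cutpoints, N, eta_total, derivs = FALSE) {
  Fm <- plogis(outer(-eta_total, cutpoints, `+`)) # n x (J-1), P(Y <= j)
  pr <- cbind(Fm, 1) - cbind(0, Fm)
  pr <- pmax(pr, 1e-300)
  k0 <- rowSums(N * log(pr))
  if (!derivs) return(list(k0 = k0))
  g <- Fm * (1 - Fm)
  gb <- cbind(0, g, 0)
  cb <- cbind(0, (1 - 2 * Fm) * g, 0)
  J <- ncol(N)
  dpi <- gb[, 1:J, drop = FALSE] - gb[, 2:(J + 1), drop = FALSE]
  d2pi <- cb[, 2:(J + 1), drop = FALSE] - cb[, 1:J, drop = FALSE]
  r1 <- dpi / pr
  r2 <- d2pi / pr
  list(
    k0 = k0,
    k1 = rowSums(N * r1),
    k2 = rowSums(N * (r2 - r1^2))
  )
}

# kernel plus the complete-data score pieces: A[, j] = dK/d alpha_j and
# k1 = dK/d eta (k1 = -rowSums(A) by the telescoping of the logistic density)
kernel_score <- function(cutpoints, N, eta_total, score = TRUE) {
  Fm <- plogis(outer(-eta_total, cutpoints, `+`))
  pr <- pmax(cbind(Fm, 1) - cbind(0, Fm), 1e-300)
  k0 <- rowSums(N * log(pr))
  if (!score) return(list(k0 = k0))
  g <- Fm * (1 - Fm)
  J <- ncol(N)
  R <- N / pr
  A <- g * (R[, seq_len(J - 1), drop = FALSE] - R[, 2:J, drop = FALSE])
  list(k0 = k0, A = A, k1 = -rowSums(A))
}

# per-fetus posterior modes and curvatures of
# h_i(u) = sum_rows kernel + log phi(u; 0, sigma2), by damped Newton,
# vectorised over fetuses. `start` allows warm starts across optimizer steps.
fetus_modes <- function(cutpoints, N, eta, fetus, sigma2, start = NULL) {
  nf <- nlevels(fetus)
  u <- start %||% numeric(nf)
  idx <- as.integer(fetus)
  for (iter in 1:50) {
    kd <- row_kernel(cutpoints, N, eta + u[idx], derivs = TRUE)
    h1 <- rowsum(kd$k1, fetus)[, 1] - u / sigma2
    h2 <- rowsum(kd$k2, fetus)[, 1] - 1 / sigma2
    h2 <- pmin(h2, -1e-10)
    step <- h1 / h2
    step[!is.finite(step)] <- 0
    # cap steps: the posterior mode lies within a few prior sds of zero
    step <- pmin(pmax(step, -2 * sqrt(sigma2) - 1), 2 * sqrt(sigma2) + 1)
    u <- u - step
    if (max(abs(step)) < 1e-10) break
  }
  kd <- row_kernel(cutpoints, N, eta + u[idx], derivs = TRUE)
  h2 <- pmin(rowsum(kd$k2, fetus)[, 1] - 1 / sigma2, -1e-10)
  list(mode = u, curv = h2)
}

#' Marginal log-likelihood of the random-intercept model
#'
#' For each fetus, the multinomial likelihood of all its session count vectors
#' is integrated over the random intercept \eqn{u \sim N(0, \sigma^2)} by
#' Gauss-Hermite quadrature -- by default adaptive, i.e. centred and scaled at
#' each fetus's posterior mode and curvature -- and the per-fetus log
#' integrals are summed. All products are taken in log space, so counts in the
#' hundreds do
#' not underflow. The multinomial coefficient is omitted: the value equals the
#' log-likelihood of the individual events, matching a fixed-effects ordinal
#' fit on the expanded data when `sigma2 = 0`. There is no residual scale
#' parameter -- within-fetus variability is fixed by the multinomial.
#'
#' @param params An [ordinal_params()] object (its `sigma2` is used as the
#'   mixing variance).
#' @param data Per-session count data (see [fit_clmm()] for the schema).
#' @param nodes Number of Gauss-Hermite nodes (>= 7; 21 is ample for a single
#'   scalar random effect).
#' @param adaptive Centre and rescale the quadrature grid at each fetus's
#'   posterior mode and curvature (default). The non-adaptive grid
#'   (`FALSE`) spaces nodes on the prior N(0, sigma2) scale, which loses
#'   accuracy once a fetus contributes many events and its posterior is much
#'   narrower than the prior.
#' @return The marginal log-likelihood (a scalar).
#' @export
marginal_loglik <- function(params, data, nodes = 21, adaptive = TRUE) {
  stopifnot(inherits(params, "ordinal_params"))
  if (nodes < 7) abort("use at least 7 quadrature nodes")
  mf <- if (is.list(data) && !is.data.frame(data) && !is.null(data$N)) data else model_frame(data)
  if (mf$J != length(params$cutpoints) + 1) {
    abort(sprintf("params have %d categories but data have %d",
                  length(params$cutpoints) + 1, mf$J))
  }
  marginal_loglik_mf(params, mf, nodes = nodes, adaptive = adaptive)
}

# internal core working on a prepared model frame; all node evaluations are
# flattened into one matrix pass (rows x nodes) to keep the optimizer cheap.
# With `grad = TRUE` (adaptive only) also returns the score with respect to
# (alpha_1..alpha_{J-1}, beta_age, beta_male, log sigma): the gradient of the
# marginal log-likelihood is the posterior-weighted expectation of the
# complete-data score over the quadrature grid.
marginal_loglik_mf <- function(params, mf, nodes = 21, adaptive = TRUE,
                               grad = FALSE) {
  eta <- params$beta_age * mf$age + params$beta_male * mf$male
  sigma2 <- params$sigma2
  idx <- as.integer(mf$fetus)
  n <- length(eta)
  J <- mf$J

  # degenerate mixing distribution: exactly the fixed-effects likelihood
  if (sigma2 < 1e-12) {
    kd <- kernel_score(params$cutpoints, mf$N, eta)
    if (!grad) return(sum(kd$k0))
    return(list(
      loglik = sum(kd$k0),
      score = unname(c(colSums(kd$A), sum(kd$k1 * mf$age),
                       sum(kd$k1 * mf$male), NA_real_))
    ))
  }

  gh <- pracma::gaussHermite(nodes)
  log_w <- log(gh$w)
  Nrep <- mf$N[rep(seq_len(n), times = nodes), , drop = FALSE]

  if (adaptive) {
    m <- fetus_modes(params$cutpoints, mf$N, eta, mf$fetus, sigma2)
    tau <- 1 / sqrt(-m$curv)
    U <- m$mode + sqrt(2) * outer(tau, gh$x) # fetuses x nodes
  } else {
    if (grad) abort("analytic score requires adaptive quadrature")
    U <- matrix(sqrt(2 * sigma2) * gh$x, nlevels(mf$fetus), nodes, byrow = TRUE)
  }

  eta_flat <- rep(eta, times = nodes) + as.vector(U[idx, , drop = FALSE])
  kd <- kernel_score(params$cutpoints, Nrep, eta_flat, score = grad)
  per <- rowsum(matrix(kd$k0, n, nodes), mf$fetus) # fetuses x nodes

  if (!adaptive) {
    return(sum(log_sum_exp_rows(sweep(per, 2, log_w - 0.5 * log(pi), `+`))))
  }

  # integral_i = sqrt2 tau_i sum_k w_k e^{x_k^2} e^{h_i(mode_i + sqrt2 tau_i x_k)}
  per <- per + dnorm(U, 0, sqrt(sigma2), log = TRUE) +
    matrix(log_w + gh$x^2, nrow(per), nodes, byrow = TRUE)
  lse <- log_sum_exp_rows(per)
  ll <- sum(0.5 * log(2) + log(tau) + lse)
  if (!grad) return(ll)

  omega <- exp(per - lse)            # posterior node weights per fetus
  W <- omega[idx, , drop = FALSE]    # broadcast to rows x nodes
  w_flat <- as.vector(W)
  g_alpha <- colSums(kd$A * w_flat)
  g_eta_rows <- rowSums(matrix(kd$k1, n, nodes) * W)
  g_lsig <- sum(omega * (U^2 / sigma2 - 1))
  list(
    loglik = ll,
    score = unname(c(g_alpha, sum(g_eta_rows * mf$age),
                     sum(g_eta_rows * mf$male), g_lsig))
  )
}

# --- fitting --------------------------------------------------------------

# theta packing: (alpha_1, log diff alpha_2.., [beta_age], [beta_male], [log sigma])
unpack_theta <- function(theta, J, include_age, include_gender, est_sigma,
                         sigma2_fixed) {
  n_alpha <- J - 1
  alpha <- cumsum(c(theta[1], exp(theta[seq_len(n_alpha - 1) + 1])))
  i <- n_alpha + 1
  beta_age <- if (include_age) { v <- theta[i]; i <- i + 1; v } else 0
  beta_male <- if (include_gender) { v <- theta[i]; i <- i + 1; v } else 0
  sigma2 <- if (est_sigma) exp(2 * theta[i]) else sigma2_fixed
  ordinal_params(alpha, beta_age, beta_male, sigma2)
}

# pooled empirical cumulative logits as deterministic cutpoint start values
start_cutpoints <- function(N) {
  tot <- colSums(N)
  cum <- cumsum(tot) / sum(tot)
  cum <- pmin(pmax(cum[-length(cum)], 1e-4), 1 - 1e-4)
  alpha <- unname(qlogis(cum))
  # enforce strict increase for degenerate (empty-category) starts
  for (j in seq_along(alpha)[-1]) {
    if (alpha[j] <= alpha[j - 1]) alpha[j] <- alpha[j - 1] + 1e-3
  }
  alpha
}

#' Fit the random-intercept proportional-odds model by maximum likelihood
#'
#' Maximises [marginal_loglik()] over the cutpoints (via an increasing
#' reparametrisation: first cutpoint plus log-gaps), the age slope, optionally
#' the male contrast, and log sigma, by BFGS quasi-Newton iteration from a
#' deterministic start (cutpoints at the pooled empirical cumulative logits,
#' slopes 0, sigma2 = 0.1). Standard errors come from the central-difference
#' Hessian of the marginal log-likelihood at the optimum, on the scale
#' (cutpoints, slopes, log sigma), with sigma2's error delta-transformed.
#'
#' @param data Per-session ordinal count data: one row per observation
#'   session with columns `fetus_id`, `gestational_age_weeks` (or `age_weeks`),
#'   `sex` (or a 0/1 `male` column) and counts `cat_1` ... `cat_J`. This is
#'   exactly the shape of `tabulate_counts(..., by = "session")`. Unbalanced
#'   designs (a fetus missing a session) contribute naturally.
#' @param include_age Include the gestational-age slope `beta_age`? Set
#'   `FALSE` for the no-covariate null model of the age LRT.
#' @param include_gender Include the male contrast `beta_male`?
#' @param nodes Gauss-Hermite nodes for the marginal likelihood.
#' @param sigma2 `NULL` (default) to estimate the random-intercept variance,
#'   or a fixed non-negative value (0 gives the plain fixed-effects
#'   proportional-odds fit).
#' @param adaptive Use adaptive quadrature (see [marginal_loglik()]).
#' @param max_iter BFGS iteration cap.
#' @return An object of class `clmm_fit`: parameter estimates
#'   (`$params`), log-likelihood, standard errors (`$se`), covariance matrix,
#'   event and fetus counts, convergence flag and quadrature size. Supports
#'   [tidy()], [glance()], `print()`, [fitted_trajectory()] and [autoplot()].
#' @examples
#' design <- simulation_design(seed = 7)
#' sim <- simulate_counts(design)
#' fit <- fit_clmm(sim$counts)
#' glance(fit)
#' @export
fit_clmm <- function(data, include_age = TRUE, include_gender = FALSE,
                     nodes = 21, sigma2 = NULL, adaptive = TRUE,
                     max_iter = 500) {
  mf <- model_frame(data)
  if (nlevels(mf$fetus) < 2) abort("need >= 2 fetuses to fit the model")
  if (length(unique(mf$age)) < 2) abort("need >= 2 distinct ages to fit the model")
  empty <- colSums(mf$N) == 0
  if (any(empty)) {
    warn(sprintf(
      "category(ies) %s have zero total count; the adjacent cutpoints are weakly identified",
      paste(which(empty), collapse = ", ")
    ))
  }
  est_sigma <- is.null(sigma2)
  sigma2_fixed <- if (est_sigma) NA_real_ else sigma2
  if (!est_sigma && sigma2_fixed < 0) abort("fixed sigma2 must be >= 0")
  J <- mf$J

  alpha0 <- start_cutpoints(mf$N)
  theta0 <- c(alpha0[1], log(diff(alpha0)))
  if (include_age) theta0 <- c(theta0, 0)
  if (include_gender) theta0 <- c(theta0, 0)
  if (est_sigma) theta0 <- c(theta0, 0.5 * log(0.1))

  # function and analytic gradient share one evaluation per theta
  ev <- new.env(parent = emptyenv())
  compute <- function(theta) {
    p <- tryCatch(
      unpack_theta(theta, J, include_age, include_gender, est_sigma,
                   sigma2_fixed),
      error = function(e) NULL
    )
    if (is.null(p)) return(list(loglik = -1e10, score = NULL))
    res <- if (adaptive) {
      marginal_loglik_mf(p, mf, nodes = nodes, adaptive = TRUE, grad = TRUE)
    } else {
      list(loglik = marginal_loglik_mf(p, mf, nodes = nodes,
                                       adaptive = FALSE), score = NULL)
    }
    if (!is.finite(res$loglik)) res <- list(loglik = -1e10, score = NULL)
    res
  }
  get_res <- function(theta) {
    if (is.null(ev$theta) || !identical(theta, ev$theta)) {
      ev$res <- compute(theta)
      ev$theta <- theta
    }
    ev$res
  }
  nll <- function(theta) -get_res(theta)$loglik
  # chain rule from the natural score (alpha, beta1, beta2, log sigma) to the
  # optimised parametrisation (alpha_1, log cutpoint gaps, slopes, log sigma)
  theta_grad <- function(theta) {
    res <- get_res(theta)
    if (is.null(res$score)) return(numeric(length(theta)))
    s <- res$score
    s_alpha <- s[seq_len(J - 1)]
    delta <- if (J > 2) exp(theta[2:(J - 1)]) else numeric(0)
    g <- sum(s_alpha)
    if (J > 2) {
      g <- c(g, delta * rev(cumsum(rev(s_alpha[-1]))))
    }
    if (include_age) g <- c(g, s[J])
    if (include_gender) g <- c(g, s[J + 1])
    if (est_sigma) g <- c(g, s[J + 2])
    g[!is.finite(g)] <- 0
    -g
  }
  use_analytic <- adaptive
  opt <- optim(theta0, nll,
               gr = if (use_analytic) theta_grad else NULL,
               method = "BFGS",
               control = list(maxit = max_iter, reltol = 1e-10,
                              ndeps = rep(1e-6, length(theta0))))
  params <- unpack_theta(opt$par, J, include_age, include_gender, est_sigma,
                         sigma2_fixed)
  loglik <- -opt$value

  # convergence is judged on the natural-scale score, ignoring cutpoints next
  # to empty categories: their MLE is at infinity and the likelihood is flat
  # there (already warned about above)
  if (use_analytic) {
    s <- marginal_loglik_mf(params, mf, nodes = nodes, adaptive = TRUE,
                            grad = TRUE)$score
    tot <- colSums(mf$N)
    keep_alpha <- vapply(seq_len(J - 1), function(j)
      tot[j] > 0 && tot[j + 1] > 0, logical(1))
    keep <- c(keep_alpha, include_age, include_gender, est_sigma)
    grad <- s[keep]
    grad[is.na(grad)] <- 0
  } else {
    grad <- num_grad(nll, opt$par)
  }
  spread <- diff(range(params$cutpoints))
  diverged <- abs(params$beta_age) > 50 || abs(params$beta_male) > 50 ||
    (length(params$cutpoints) > 1 && spread > 100)
  converged <- opt$convergence == 0 && !diverged &&
    max(abs(grad)) < 1e-2 * (1 + abs(loglik) / 100)
  if (diverged) {
    warn("fit diverged (separation?); partial result returned with converged = FALSE")
  }

  # natural-scale parametrisation for the Hessian: alphas, slopes, log sigma
  nat <- c(params$cutpoints,
           if (include_age) params$beta_age,
           if (include_gender) params$beta_male,
           if (est_sigma) 0.5 * log(max(params$sigma2, 1e-12)))
  nat_names <- c(paste0("alpha_", seq_len(J - 1)),
                 if (include_age) "beta_age",
                 if (include_gender) "beta_male",
                 if (est_sigma) "log_sigma")
  nll_nat <- function(phi) {
    a <- phi[seq_len(J - 1)]
    if (any(diff(a) <= 0)) return(NA_real_)
    i <- J
    b1 <- if (include_age) { v <- phi[i]; i <- i + 1; v } else 0
    b2 <- if (include_gender) { v <- phi[i]; i <- i + 1; v } else 0
    s2 <- if (est_sigma) exp(2 * phi[i]) else sigma2_fixed
    -marginal_loglik_mf(ordinal_params(a, b1, b2, s2), mf, nodes = nodes,
                        adaptive = adaptive)
  }
  H <- tryCatch(num_hessian(nll_nat, nat), error = function(e) NULL)
  vcov <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  se <- rep(NA_real_, length(nat))
  if (!is.null(vcov)) {
    dv <- diag(vcov)
    se[dv > 0] <- sqrt(dv[dv > 0])
    dimnames(vcov) <- list(nat_names, nat_names)
  }
  names(se) <- nat_names

  structure(
    list(
      params = params, loglik = loglik, se = se, vcov = vcov,
      estimate_age = include_age,
      estimate_gender = include_gender, estimate_sigma = est_sigma,
      n_obs = mf$n_events, n_sessions = nrow(mf$N),
      n_fetuses = nlevels(mf$fetus), J = J,
      n_par = length(opt$par), quadrature_nodes = nodes,
      converged = converged, grad_max = max(abs(grad)),
      optim_counts = opt$counts
    ),
    class = "clmm_fit"
  )
}

num_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h * (1 + abs(x[i]))
    (f(x + e) - f(x - e)) / (2 * e[i])
  }, numeric(1))
}

num_hessian <- function(f, x, h = 1e-4) {
  p <- length(x)
  hh <- h * (1 + abs(x))
  H <- matrix(NA_real_, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    for (j in i:p) {
      ei <- numeric(p); ei[i] <- hh[i]
      ej <- numeric(p); ej[j] <- hh[j]
      if (i == j) {
        H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / hh[i]^2
      } else {
        H[i, j] <- H[j, i] <-
          (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
          (4 * hh[i] * hh[j])
      }
    }
  }
  H
}

#' Likelihood-ratio test between nested model fits
#'
#' Twice the log-likelihood difference between a full and a nested fit on the
#' same data, referred to the upper tail of a chi-square with degrees of
#' freedom equal to the parameter-count difference. This is how the age and
#' sex effects are assessed: age + sex versus age, and age versus the
#' no-covariate model.
#'
#' @param full,nested `clmm_fit` objects on the same data, nested parameters.
#' @return A one-row tibble with `statistic`, `df` and `p_value`.
#' @export
lrt <- function(full, nested) {
  stopifnot(inherits(full, "clmm_fit"), inherits(nested, "clmm_fit"))
  if (full$n_obs != nested$n_obs || full$J != nested$J) {
    abort("fits do not appear to be on the same data")
  }
  df <- full$n_par - nested$n_par
  if (df <= 0) abort("`full` must have more free parameters than `nested`")
  stat <- 2 * (full$loglik - nested$loglik)
  if (stat < -1e-6) {
    abort("full-model log-likelihood below nested model's: optimizer failure")
  }
  stat <- max(stat, 0)
  tibble::tibble(statistic = stat, df = df,
                 p_value = pchisq(stat, df, lower.tail = FALSE))
}

#' Fitted complexity trajectory of a typical fetus
#'
#' Category probabilities across a grid of gestational ages for a fetus with
#' random effect zero (and female baseline), i.e. the population-typical
#' developmental trajectory implied by the fitted model.
#'
#' @param fit A converged `clmm_fit`.
#' @param ages Gestational-age grid in weeks.
#' @return A tibble `age`, `cat_1` ... `cat_J` (probabilities).
#' @export
fitted_trajectory <- function(fit, ages = seq(24, 36, by = 0.5)) {
  stopifnot(inherits(fit, "clmm_fit"))
  if (!fit$converged) warn("fit did not converge; trajectory may be unreliable")
  dplyr::select(category_probs(fit$params, age = ages, male = 0, u = 0),
                -"male", -"u")
}
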