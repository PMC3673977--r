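test_that("category probabilities follow the cumulative logit algebra", {
  # symmetric logistic at the cutpoint
  p2 <- ordinal_params(0, beta_age = 0, sigma2 = 0)
  expect_equal(unlist(category_probs(p2, age = 0)[, c("cat_1", "cat_2")],
                      use.names = FALSE), c(0.5, 0.5))

  # hand evaluation: logistic CDF at -1.5 and 0.5
  p3 <- ordinal_params(c(0, 2), beta_age = 0.1)
  got <- category_probs(p3, age = 10, u = 0.5)
  expect_equal(unlist(got[, c("cat_1", "cat_2", "cat_3")], use.names = FALSE),
               c(plogis(-1.5), plogis(0.5) - plogis(-1.5), 1 - plogis(0.5)),
               tolerance = 1e-12)
  expect_equal(round(unlist(got[, c("cat_1", "cat_2", "cat_3")],
                            use.names = FALSE), 5),
               c(0.18243, 0.44003, 0.37754))

  # probabilities sum to one and cumulative sums are monotone in j
  set.seed(8)
  for (i in 1:20) {
    J <- sample(3:6, 1)
    pars <- ordinal_params(random_increasing_cutpoints(J + 1)[1:(J - 1)],
                           beta_age = rnorm(1, 0, 0.3),
                           beta_male = rnorm(1, 0, 0.3))
    pr <- as.matrix(category_probs(pars, age = runif(1, 20, 40),
                                   male = sample(0:1, 1),
                                   u = rnorm(1))[, -(1:3)])
    expect_equal(sum(pr), 1, tolerance = 1e-12)
    expect_true(all(pr >= 0))
    expect_true(all(diff(cumsum(pr[1, ])) >= -1e-12))
  }

  # positive age slope moves mass up the categories
  lo <- category_probs(p3, age = 0)$cat_1
  hi <- category_probs(p3, age = 30)$cat_1
  expect_lt(hi, lo)

  expect_error(ordinal_params(c(2, 1)), "increasing")
})

test_that("marginal likelihood reduces to fixed effects at sigma2 = 0", {
  d <- random_small_counts(n_fetuses = 4, J = 4)
  pars <- ordinal_params(c(-1, 0.5, 2), beta_age = 0.05, sigma2 = 0)
  cat_cols <- paste0("cat_", 1:4)
  direct <- sum(as.matrix(d[cat_cols]) *
                  log(as.matrix(category_probs(pars, d$gestational_age_weeks,
                                               as.numeric(d$sex == "male"))[, cat_cols])))
  expect_equal(marginal_loglik(pars, d), direct, tolerance = 1e-10)
})

test_that("one binary event under a unit normal intercept integrates to 1/2", {
  d <- tibble::tibble(fetus_id = "f1", gestational_age_weeks = 24,
                      sex = "female", cat_1 = 1L, cat_2 = 0L)
  pars <- ordinal_params(0, beta_age = 0, sigma2 = 1)
  # E[expit(-u)] = 1/2 by the symmetry of logistic and centred normal
  expect_equal(marginal_loglik(pars, d, nodes = 41), log(0.5), tolerance = 1e-8)
})

test_that("quadrature matches dense trapezoid integration on random data", {
  set.seed(123)
  for (i in 1:20) {
    J <- sample(3:5, 1)
    d <- random_small_counts(n_fetuses = sample(2:4, 1), J = J)
    pars <- ordinal_params(
      sort(rnorm(J - 1, 0, 2)) + seq(0, 0.3, length.out = J - 1),
      beta_age = rnorm(1, 0, 0.1), beta_male = rnorm(1, 0, 0.2),
      sigma2 = runif(1, 0.05, 1.5)
    )
    gh <- marginal_loglik(pars, d, nodes = 21)
    brute <- trapezoid_loglik(pars, d, n_grid = 1e5)
    expect_equal(gh, brute, tolerance = 1e-6)
  }
})

test_that("the likelihood is stable in the number of quadrature nodes", {
  sim <- simulate_counts(simulation_design(scheme = "gestalt", seed = 61))
  pars <- simulation_design(scheme = "gestalt")$true_params
  ll21 <- marginal_loglik(pars, sim$counts, nodes = 21)
  ll41 <- marginal_loglik(pars, sim$counts, nodes = 41)
  expect_lt(abs(ll21 - ll41) / abs(ll21), 1e-6)
})

test_that("the analytic score matches a numerical gradient", {
  set.seed(77)
  d <- random_small_counts(n_fetuses = 4, J = 4)
  mf <- fetalface:::model_frame(d)
  v0 <- c(-1, 0.4, 1.9, 0.12, -0.2, 0.5 * log(0.6))
  f <- function(v) {
    fetalface:::marginal_loglik_mf(
      ordinal_params(v[1:3], v[4], v[5], exp(2 * v[6])), mf, 21, TRUE)
  }
  analytic <- fetalface:::marginal_loglik_mf(
    ordinal_params(v0[1:3], v0[4], v0[5], exp(2 * v0[6])), mf, 21, TRUE,
    grad = TRUE)$score
  expect_equal(analytic, fetalface:::num_grad(f, v0), tolerance = 1e-5)
})

test_that("sigma2 = 0 fit agrees with an independent proportional-odds fit", {
  skip_if_not_installed("MASS")
  sim <- simulate_counts(simulation_design(scheme = "gestalt", seed = 13))
  fit0 <- fit_clmm(sim$counts, sigma2 = 0)
  cat_cols <- paste0("cat_", 1:5)
  # expand counts to one row per event for polr
  n_per <- rowSums(sim$counts[cat_cols])
  long <- sim$counts[rep(seq_len(nrow(sim$counts)), n_per), ]
  y <- unlist(apply(sim$counts[cat_cols], 1, function(r) rep(1:5, r)))
  pol <- MASS::polr(factor(y) ~ long$gestational_age_weeks)
  expect_lt(abs(fit0$loglik - as.numeric(stats::logLik(pol))), 1e-4)
  expect_equal(fit0$params$beta_age, unname(stats::coef(pol)), tolerance = 1e-4)
  expect_equal(fit0$params$cutpoints, unname(pol$zeta), tolerance = 1e-3)
})

test_that("a null age effect is estimated near zero", {
  set.seed(19)
  pars <- ordinal_params(c(0.2, 1.8, 3.6, 5.5), beta_age = 0, sigma2 = 0.3)
  betas <- vapply(1:10, function(r) {
    d <- simulation_design(scheme = "gestalt", true_params = pars,
                           seed = 400 + r)
    fit_clmm(simulate_counts(d)$counts)$params$beta_age
  }, numeric(1))
  expect_lt(abs(mean(betas)), 0.02)
})

test_that("fit recovers generating parameters on one large draw", {
  sim <- simulate_counts(simulation_design(scheme = "gestalt", seed = 11))
  fit <- fit_clmm(sim$counts)
  expect_true(fit$converged)
  truth <- simulation_design(scheme = "gestalt")$true_params
  expect_equal(fit$params$beta_age, truth$beta_age, tolerance = 0.05)
  se <- unname(fit$se["beta_age"])
  expect_gt(se, 0)
  expect_lt(abs(fit$params$beta_age - truth$beta_age), 4 * se)
})

test_that("likelihood-ratio tests are well-formed", {
  sim <- simulate_counts(simulation_design(scheme = "gestalt", seed = 23))
  fit_age <- fit_clmm(sim$counts)
  fit_null <- fit_clmm(sim$counts, include_age = FALSE)
  fit_both <- fit_clmm(sim$counts, include_gender = TRUE)

  res <- lrt(fit_age, fit_null)
  expect_gte(res$statistic, 0)
  expect_equal(res$df, 1)
  expect_lt(res$p_value, 0.001) # age effect is overwhelming at study scale

  res2 <- lrt(fit_both, fit_age)
  expect_gte(res2$statistic, -1e-6)
  expect_equal(res2$df, 1)

  expect_error(lrt(fit_age, fit_age), "more free parameters")
})

test_that("fitted trajectories are monotone where the model says so", {
  sim <- simulate_counts(simulation_design(scheme = "gestalt", seed = 29))
  fit <- fit_clmm(sim$counts)
  traj <- fitted_trajectory(fit, ages = seq(24, 40, by = 1))
  expect_true(all(diff(traj$cat_1) < 0)) # single events decline with age
  expect_equal(rowSums(as.matrix(traj[, -1])), rep(1, nrow(traj)),
               tolerance = 1e-12)
  # single-movement probability lower at 36 than at 24 weeks
  expect_lt(traj$cat_1[traj$age == 36], traj$cat_1[traj$age == 24])

  # flat when beta = 0
  flat_pars <- ordinal_params(c(0, 2, 4, 6), beta_age = 0, sigma2 = 0.2)
  flat_fit <- fit_clmm(simulate_counts(simulation_design(
    scheme = "gestalt", true_params = flat_pars, seed = 3))$counts)
  ftraj <- fitted_trajectory(flat_fit, ages = c(24, 36))
  expect_lt(abs(ftraj$cat_1[2] - ftraj$cat_1[1]), 0.05)
})

test_that("tidy and glance expose the fit in broom shape", {
  sim <- simulate_counts(simulation_design(scheme = "gestalt", seed = 37))
  fit <- fit_clmm(sim$counts, include_gender = TRUE)
  td <- tidy(fit)
  expect_setequal(td$term, c(paste0("alpha_", 1:4), "beta_age", "beta_male",
                             "sigma2"))
  expect_true(all(td$std.error > 0, na.rm = TRUE))
  gl <- glance(fit)
  expect_equal(gl$nobs, sum(sim$counts$total))
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("fit handles unbalanced sessions (a missing scan)", {
  sim <- simulate_counts(simulation_design(scheme = "gestalt", seed = 41))
  counts59 <- dplyr::filter(sim$counts,
                            !(fetus_id == "f01" & gestational_age_weeks == 24))
  fit <- fit_clmm(counts59)
  expect_true(fit$converged)
  expect_equal(fit$n_sessions, 59)
})
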