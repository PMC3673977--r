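#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' @export
print.clmm_fit <- function(x, digits = 4, ...) {
  cat("Random-intercept proportional-odds fit (", x$J, " categories)\n", sep = "")
  cat(sprintf("  %d events in %d sessions from %d fetuses; %d GH nodes\n",
              x$n_obs, x$n_sessions, x$n_fetuses, x$quadrature_nodes))
  cat(sprintf("  log-likelihood %.3f  (%sconverged)\n",
              x$loglik, if (x$converged) "" else "NOT "))
  print(as.data.frame(tidy(x)), digits = digits, row.names = FALSE)
  if (x$estimate_sigma) {
    cat(sprintf("  random-intercept variance sigma2 = %.*f\n", digits,
                x$params$sigma2))
  } else {
    cat(sprintf("  sigma2 fixed at %.*f\n", digits, x$params$sigma2))
  }
  invisible(x)
}

#' Tidy and glance methods for proportional-odds fits
#'
#' `tidy()` returns one row per estimated parameter (cutpoints, slopes and
#' the random-intercept variance) with Wald standard errors; z statistics and
#' two-sided Wald p-values are given for the regression slopes. `glance()`
#' returns a one-row model summary.
#'
#' @param x A `clmm_fit` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.clmm_fit <- function(x, ...) {
  p <- x$params
  terms <- paste0("alpha_", seq_along(p$cutpoints))
  est <- p$cutpoints
  if (x$estimate_age) {
    terms <- c(terms, "beta_age"); est <- c(est, p$beta_age)
  }
  if (x$estimate_gender) {
    terms <- c(terms, "beta_male"); est <- c(est, p$beta_male)
  }
  se <- unname(x$se[terms])
  stat <- ifelse(grepl("^beta_", terms), est / se, NA_real_)
  out <- tibble::tibble(
    term = terms, estimate = est, std.error = se,
    statistic = stat,
    p.value = ifelse(is.na(stat), NA_real_, 2 * stats::pnorm(-abs(stat)))
  )
  if (x$estimate_sigma) {
    # delta method from log sigma: se(sigma2) = 2 * sigma2 * se(log sigma)
    se_s2 <- 2 * p$sigma2 * unname(x$se["log_sigma"])
    out <- dplyr::bind_rows(out, tibble::tibble(
      term = "sigma2", estimate = p$sigma2, std.error = se_s2,
      statistic = NA_real_, p.value = NA_real_
    ))
  }
  out
}

#' @rdname tidy.clmm_fit
#' @export
glance.clmm_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, df = x$n_par,
    AIC = -2 * x$loglik + 2 * x$n_par,
    nobs = x$n_obs, n_fetuses = x$n_fetuses,
    sigma2 = x$params$sigma2, beta_age = x$params$beta_age,
    converged = x$converged, quadrature_nodes = x$quadrature_nodes
  )
}

#' Plot the typical-fetus complexity trajectory
#'
#' Line plot of fitted category probabilities against gestational age for a
#' fetus with random effect zero, one line per ordinal complexity category.
#'
#' @param object A `clmm_fit`.
#' @param ages Age grid in weeks.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.clmm_fit <- function(object, ages = seq(24, 36, by = 0.25), ...) {
  traj <- fitted_trajectory(object, ages)
  long <- tidyr::pivot_longer(traj, dplyr::starts_with("cat_"),
                              names_to = "category", values_to = "probability")
  long$category <- factor(
    long$category,
    levels = paste0("cat_", seq_len(object$J)),
    labels = category_labels(object$J)
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$age, .data$probability,
                                     colour = .data$category)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(
      x = "Gestational age (weeks)",
      y = "Fitted probability (typical fetus, u = 0)",
      colour = "Co-occurring\nmovements"
    ) +
    ggplot2::theme_minimal()
}

category_labels <- function(J) {
  base <- c("single", "double", "triple", "quadruple", "quintuple", "sextuple")
  c(base[seq_len(J - 1)], paste0(base[J], " or more"))
}

#' Plot observed complexity proportions by gestational age
#'
#' Companion to [autoplot.clmm_fit()]: shows the observed proportion of
#' events in each ordinal category per nominal age bin, as points joined by
#' lines.
#'
#' @param counts An age-binned count table (see [tabulate_counts()] with
#'   `by = "age_bin"`, or [reference_counts()]).
#' @return A ggplot object.
#' @export
plot_observed_proportions <- function(counts) {
  cat_cols <- grep("^cat_", names(counts), value = TRUE)
  long <- tidyr::pivot_longer(counts, dplyr::all_of(cat_cols),
                              names_to = "category", values_to = "n")
  long$proportion <- long$n / long$total
  long$category <- factor(long$category, levels = cat_cols,
                          labels = category_labels(length(cat_cols)))
  ggplot2::ggplot(long, ggplot2::aes(.data$age_weeks, .data$proportion,
                                     colour = .data$category)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Gestational age (weeks)", y = "Observed proportion",
                  colour = "Co-occurring\nmovements") +
    ggplot2::theme_minimal()
}
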