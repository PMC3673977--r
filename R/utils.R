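#' @importFrom rlang .data abort warn .env
#' @importFrom stats plogis qlogis optim pchisq rnorm rmultinom runif dnorm setNames
NULL

# round half away from zero at `digits` decimals (printed tables use half-up,
# whereas base round() rounds half to even)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# numerically stable log(sum(exp(x))) along rows of a matrix
log_sum_exp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}
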