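# Descriptive summaries and logistic risk modelling.

#' Mean with a t-based confidence interval
#'
#' @param values numeric vector; `NA`s are dropped with a message.
#' @param level confidence level.
#' @return List with `n`, `mean`, `sd`, `ci_low`, `ci_high`, `level`.
#'   With fewer than two values the CI is `NA` and the mean is still
#'   reported.
#' @export
summarise_numeric <- function(values, level = 0.95) {
  if (!is.numeric(values)) abort_arg("values must be numeric")
  if (anyNA(values)) {
    message(sum(is.na(values)), " missing value(s) dropped from summary")
    values <- values[!is.na(values)]
  }
  n <- length(values)
  if (n == 0L) abort_arg("no non-missing values to summarise")
  m <- mean(values)
  if (n < 2L) {
    return(list(n = n, mean = m, sd = NA_real_,
                ci_low = NA_real_, ci_high = NA_real_, level = level))
  }
  s <- stats::sd(values)
  half <- stats::qt(1 - (1 - level) / 2, df = n - 1) * s / sqrt(n)
  list(n = n, mean = m, sd = s, ci_low = m - half, ci_high = m + half, level = level)
}

#' Sample Pearson correlation coefficient
#'
#' Thin validated wrapper around [stats::cor()]: equal-length inputs of at
#' least three pairs, complete pairs only, and an explicit error for
#' zero-variance input rather than a silent `NA`.
#'
#' @param x,y numeric vectors of equal length.
#' @return Single correlation in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) abort_arg("x and y must have equal length")
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) abort_arg("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_arg("correlation undefined: an input has zero variance")
  }
  stats::cor(x, y)
}

#' Binary logistic regression with Wald intervals on the odds-ratio scale
#'
#' Fits `outcome ~ predictors` by maximum likelihood (IRLS via
#' [stats::glm()]) and reports coefficients with Wald confidence intervals,
#' exponentiated to odds ratios. Non-convergence and (quasi-)complete
#' separation are detected and flagged: a separated fit carries no usable
#' Wald intervals and `separation = TRUE`, rather than silently huge
#' estimates.
#'
#' @param outcome binary vector (0/1 or logical), one element per subject.
#' @param predictors numeric matrix or data frame of predictors (columns are
#'   model terms; an intercept is always added).
#' @param level confidence level for the Wald intervals.
#' @return Object of class `"logistic_fit"`: list with `coefficients`
#'   (log-odds), `se`, `ci_low`, `ci_high` (log scale), `or`, `or_ci_low`,
#'   `or_ci_high`, `p_value` (Wald), `converged`, `separation`, `n`, `level`.
#' @export
fit_logistic <- function(outcome, predictors, level = 0.95) {
  y <- as.integer(outcome)
  if (any(is.na(y)) || !all(y %in% c(0L, 1L))) abort_arg("outcome must be binary 0/1")
  if (length(unique(y)) < 2L) abort_arg("outcome must contain both classes")
  X <- as.data.frame(predictors)
  if (nrow(X) != length(y)) abort_arg("predictors and outcome lengths differ")
  if (any(vapply(X, function(col) stats::var(as.numeric(col)) == 0, logical(1)))) {
    abort_arg("constant predictor column duplicates the intercept")
  }
  dat <- cbind(.y = y, X)
  fit <- suppressWarnings(stats::glm(.y ~ ., data = dat, family = stats::binomial()))
  eps <- 1e-08
  separation <- any(fit$fitted.values < eps | fit$fitted.values > 1 - eps) ||
    any(abs(stats::coef(fit)) > 15)
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(
    list(coefficients = cf, se = se,
         ci_low = cf - z * se, ci_high = cf + z * se,
         or = exp(cf), or_ci_low = exp(cf - z * se), or_ci_high = exp(cf + z * se),
         p_value = 2 * stats::pnorm(-abs(cf / se)),
         converged = fit$converged, separation = separation,
         n = length(y), level = level),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, digits = 3, ...) {
  if (x$separation) cat("warning: (quasi-)complete separation detected; Wald intervals unreliable\n")
  if (!x$converged) cat("warning: IRLS did not converge\n")
  out <- data.frame(
    log_odds = round(x$coefficients, digits),
    OR = round(x$or, digits),
    or_ci_low = round(x$or_ci_low, digits),
    or_ci_high = round(x$or_ci_high, digits),
    p = signif(x$p_value, 2)
  )
  print(out)
  invisible(x)
}
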