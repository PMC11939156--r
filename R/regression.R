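#' Descriptive statistics of a numeric variable
#'
#' Mean, median (midpoint of the two central order statistics for even n),
#' sample standard deviation (divisor n - 1), minimum and maximum. For a
#' single observation the standard deviation is reported as 0 with
#' `sd_defined = FALSE`.
#'
#' @param values Numeric vector, length >= 1, no missing values.
#' @return List of class `descriptive_stats`: `n`, `mean`, `median`, `sd`,
#'   `min`, `max`, `sd_defined`.
#' @export
descriptive_stats <- function(values) {
  if (length(values) == 0) {
    stop("descriptive_stats requires at least one value", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("descriptive_stats requires finite values", call. = FALSE)
  }
  n <- length(values)
  structure(list(n = n,
                 mean = mean(values),
                 median = stats::median(values),
                 sd = if (n > 1) stats::sd(values) else 0,
                 min = min(values),
                 max = max(values),
                 sd_defined = n > 1),
            class = "descriptive_stats")
}

#' @export
print.descriptive_stats <- function(x, ...) {
  cat(sprintf(
    "n = %d  mean = %.4f  median = %.4f  sd = %.5f  min = %.2f  max = %.2f\n",
    x$n, x$mean, x$median, x$sd, x$min, x$max))
  invisible(x)
}

#' Two-sided p-value from the central t distribution
#'
#' `2 P(T_df >= |t|)`; monotone decreasing in `|t|`.
#'
#' @param t Observed t statistic.
#' @param df Degrees of freedom (>= 1).
#' @return p-value in `[0, 1]`.
#' @export
two_sided_p <- function(t, df) {
  if (any(df < 1)) stop("degrees of freedom must be >= 1", call. = FALSE)
  2 * stats::pt(-abs(t), df)
}

#' Simple linear regression with full ANOVA decomposition
#'
#' Ordinary least squares of `y` on a single predictor `x`, reported the way
#' clinical statistics packages print it: coefficients with standard errors,
#' t statistics and two-sided p-values; the regression/residual/total sum of
#' squares with degrees of freedom, mean squares, F and its p-value; the
#' standardized slope (`b1 sd(x) / sd(y)`, equal to the Pearson correlation);
#' and R-squared. The fit itself is delegated to [stats::lm()].
#'
#' @param x Predictor vector.
#' @param y Response vector, same length, n >= 3.
#' @return List of class `ols_report` with fields `n`, `b0`, `b1`, `se_b0`,
#'   `se_b1`, `t_b0`, `t_b1`, `p_b0`, `p_b1`, `ss_regression`,
#'   `ss_residual`, `ss_total`, `df_regression`, `df_residual`, `df_total`,
#'   `ms_regression`, `ms_residual`, `f_stat`, `p_f`, `standardized_beta`,
#'   `r_squared`.
#' @examples
#' fit_simple_ols(1:5, 2 * (1:5) + 1)  # exact line: b0 = 1, b1 = 2
#' @export
fit_simple_ols <- function(x, y) {
  if (length(x) != length(y)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  n <- length(x)
  if (n < 3) stop("simple regression requires n >= 3", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("x and y must be finite", call. = FALSE)
  }
  if (stats::var(x) == 0) {
    stop("degenerate predictor: x is constant", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  cf <- summary(fit)$coefficients
  an <- stats::anova(fit)
  ss_reg <- an["x", "Sum Sq"]
  ss_res <- an["Residuals", "Sum Sq"]
  ss_tot <- ss_reg + ss_res
  b1 <- unname(stats::coef(fit)[2])
  structure(list(
    n = n,
    b0 = unname(stats::coef(fit)[1]),
    b1 = b1,
    se_b0 = cf[1, 2], se_b1 = cf[2, 2],
    t_b0 = cf[1, 3], t_b1 = cf[2, 3],
    p_b0 = cf[1, 4], p_b1 = cf[2, 4],
    ss_regression = ss_reg,
    ss_residual = ss_res,
    ss_total = ss_tot,
    df_regression = 1L,
    df_residual = n - 2L,
    df_total = n - 1L,
    ms_regression = ss_reg / 1,
    ms_residual = ss_res / (n - 2),
    f_stat = an["x", "F value"],
    p_f = an["x", "Pr(>F)"],
    standardized_beta = b1 * stats::sd(x) / stats::sd(y),
    r_squared = summary(fit)$r.squared),
    class = "ols_report")
}

#' @export
print.ols_report <- function(x, ...) {
  cat(sprintf("y = %.3f + %.3f x   (n = %d)\n", x$b0, x$b1, x$n))
  cat(sprintf("  slope:     se = %.3f  beta = %.3f  t = %.3f  p = %.4f\n",
              x$se_b1, x$standardized_beta, x$t_b1, x$p_b1))
  cat(sprintf("  intercept: se = %.3f  t = %.3f  p = %.4f\n",
              x$se_b0, x$t_b0, x$p_b0))
  cat(sprintf("  ANOVA: SSreg = %.3f  SSres = %.3f (df %d)  F = %.3f  p = %.4f\n",
              x$ss_regression, x$ss_residual, x$df_residual, x$f_stat,
              x$p_f))
  cat(sprintf("  R-squared = %.4f\n", x$r_squared))
  invisible(x)
}

#' Validation report: risk score against periodontal pocket counts
#'
#' Reproduces the statistical stage of the risk model's validation on a
#' scored cohort: descriptive statistics of the cumulative risk score
#' (PCRisk) and of the pocket count (nrPP), the simple OLS of nrPP on
#' PCRisk with its ANOVA table, and whether the slope is significant at
#' alpha = 0.05.
#'
#' @param pcrisk Numeric vector of cumulative risk scores.
#' @param nrpp Numeric vector of pocket counts (same length, n >= 3).
#' @return List of class `validation_report`: `pcrisk_stats`, `nrpp_stats`,
#'   `ols` ([fit_simple_ols()] report), `slope_significant`, `alpha`.
#' @export
validation_report <- function(pcrisk, nrpp) {
  ols <- fit_simple_ols(pcrisk, nrpp)
  structure(list(pcrisk_stats = descriptive_stats(pcrisk),
                 nrpp_stats = descriptive_stats(nrpp),
                 ols = ols,
                 alpha = 0.05,
                 slope_significant = ols$p_b1 < 0.05),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("== Descriptive statistics ==\n")
  cat("PCRisk: "); print(x$pcrisk_stats)
  cat("nrPP:   "); print(x$nrpp_stats)
  cat("\n== Regression of nrPP on PCRisk ==\n")
  cat(sprintf("nrPP = %.3f + %.3f x PCRisk\n", x$ols$b0, x$ols$b1))
  print(x$ols)
  cat(sprintf("\nSlope %s at alpha = %.2f (p = %.4f)\n",
              if (x$slope_significant) "significant" else "not significant",
              x$alpha, x$ols$p_b1))
  invisible(x)
}

#' Flatten a validation report to a named list of numbers
#'
#' Convenience for machine-readable export (JSON/CSV) mirroring the
#' descriptive, ANOVA and coefficient tables.
#'
#' @param report A [validation_report()].
#' @return Named list of scalars.
#' @export
report_fields <- function(report) {
  s <- report$pcrisk_stats
  p <- report$nrpp_stats
  o <- report$ols
  list(n = o$n,
       pcrisk_mean = s$mean, pcrisk_median = s$median, pcrisk_sd = s$sd,
       pcrisk_min = s$min, pcrisk_max = s$max,
       nrpp_mean = p$mean, nrpp_median = p$median, nrpp_sd = p$sd,
       nrpp_min = p$min, nrpp_max = p$max,
       b0 = o$b0, b1 = o$b1, se_b0 = o$se_b0, se_b1 = o$se_b1,
       t_b0 = o$t_b0, t_b1 = o$t_b1, p_b0 = o$p_b0, p_b1 = o$p_b1,
       ss_regression = o$ss_regression, ss_residual = o$ss_residual,
       ss_total = o$ss_total, f_stat = o$f_stat, p_f = o$p_f,
       standardized_beta = o$standardized_beta, r_squared = o$r_squared,
       slope_significant = as.integer(report$slope_significant))
}
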