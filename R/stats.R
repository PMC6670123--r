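#' Summary statistics of one sample
#'
#' Mean, SD and size — the form in which cohort tables publish continuous
#' variables, sufficient for pooled t and ANOVA reconstruction.
#'
#' @param mean sample mean.
#' @param sd sample standard deviation (`>= 0`).
#' @param n sample size (`>= 2`).
#' @return A list of class `summary_stats`.
#' @export
summary_stats <- function(mean, sd, n) {
  if (sd < 0) stop("sd must be non-negative")
  if (n < 2) stop("n must be at least 2")
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "summary_stats")
}

new_test_result <- function(statistic, df, p_value, test_name) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 test_name = test_name),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n", x$test_name,
              x$statistic, paste(signif(x$df, 6), collapse = ", "),
              x$p_value))
  invisible(x)
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson chi-square without continuity correction (the uncorrected form
#' reproduces the reference cohort's printed categorical p-values;
#' `df = (r-1)(c-1)`, upper-tail p).
#'
#' @param table an r x c matrix of non-negative counts, `r, c >= 2`.
#' @return A `test_result`.
#' @export
chi_square <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2)
    stop("contingency table needs at least 2 rows and 2 columns")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (sum(table) == 0) stop("grand total must be positive")
  rs <- rowSums(table); cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0))
    stop("a zero row or column total leaves expected counts undefined")
  expected <- outer(rs, cs) / sum(table)
  x2 <- sum((table - expected)^2 / expected)
  df <- (nrow(table) - 1) * (ncol(table) - 1)
  new_test_result(x2, df, pchisq(x2, df, lower.tail = FALSE),
                  "Pearson chi-square")
}

#' Pooled two-sample t-test from summary statistics
#'
#' Two-sided Student t with pooled variance, `df = n_a + n_b - 2`. Two
#' degenerate zero-variance cases follow the natural conventions: equal
#' means give p = 1; unequal means give p = 0 with a warning.
#'
#' @param a,b [summary_stats()] of the two samples.
#' @return A `test_result`.
#' @export
pooled_t_from_summary <- function(a, b) {
  stopifnot(inherits(a, "summary_stats"), inherits(b, "summary_stats"))
  df <- a$n + b$n - 2
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
  if (sp2 == 0) {
    if (a$mean == b$mean)
      return(new_test_result(0, df, 1, "pooled two-sample t"))
    warning("zero pooled variance with unequal means; p = 0")
    return(new_test_result(Inf, df, 0, "pooled two-sample t"))
  }
  t <- (a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
  new_test_result(t, df, 2 * pt(-abs(t), df), "pooled two-sample t")
}

#' One-way analysis of variance on raw samples
#'
#' `F = MS_between / MS_within` with `df = (k - 1, N - k)` and upper-tail
#' p. Zero within-group variance: all means equal gives p = 1; otherwise
#' p = 0 with a warning.
#'
#' @param groups a list of `>= 2` numeric vectors, each of length `>= 2`.
#' @return A `test_result`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least two groups")
  ns <- lengths(groups)
  if (any(ns < 2)) stop("each group needs at least 2 observations")
  means <- vapply(groups, mean, numeric(1))
  anova_core(means, vapply(groups, stats::sd, numeric(1)), ns)
}

#' One-way ANOVA reconstructed from summary statistics
#'
#' Rebuilds the between- and within-group sums of squares from per-group
#' mean/SD/n, so published table rows can be tested without raw data.
#' Identical contract to [one_way_anova()]; on raw samples sharing the
#' summaries the two agree exactly.
#'
#' @param groups a list of `>= 2` [summary_stats()].
#' @return A `test_result`.
#' @export
anova_from_summary <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least two groups")
  stopifnot(all(vapply(groups, inherits, logical(1), "summary_stats")))
  anova_core(vapply(groups, `[[`, numeric(1), "mean"),
             vapply(groups, `[[`, numeric(1), "sd"),
             vapply(groups, `[[`, numeric(1), "n"))
}

anova_core <- function(means, sds, ns) {
  k <- length(means); N <- sum(ns)
  grand <- sum(ns * means) / N
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((ns - 1) * sds^2)
  df1 <- k - 1; df2 <- N - k
  if (ssw == 0) {
    if (ssb == 0)
      return(new_test_result(0, c(df1, df2), 1, "one-way ANOVA"))
    warning("zero within-group variance with unequal means; p = 0")
    return(new_test_result(Inf, c(df1, df2), 0, "one-way ANOVA"))
  }
  f <- (ssb / df1) / (ssw / df2)
  new_test_result(f, c(df1, df2), pf(f, df1, df2, lower.tail = FALSE),
                  "one-way ANOVA")
}

#' Multiple linear regression of capillary density on risk factors
#'
#' Ordinary least squares with intercept on complete-case rows, with
#' two-sided t p-values per coefficient. A rank-deficient design is an
#' error naming the collinear columns rather than a silently dropped term.
#'
#' @param cohort a cohort `data.frame` (e.g. from [generate_cohort()]).
#' @param response name of the response column.
#' @param covariates character vector of covariate column names; character
#'   columns are treated as factors.
#' @return A list of class `regression_result`: `coefficients` (a
#'   data.frame with estimate, std_error, t, p per term), `r_squared`,
#'   `df_residual`, `n_used`, `n_dropped` (incomplete rows excluded).
#' @export
multiple_regression <- function(cohort, response, covariates) {
  stopifnot(is.data.frame(cohort))
  missing_cols <- setdiff(c(response, covariates), names(cohort))
  if (length(missing_cols))
    stop("columns not in cohort: ", paste(missing_cols, collapse = ", "))
  d <- cohort[, c(response, covariates), drop = FALSE]
  cc <- stats::complete.cases(d)
  d <- d[cc, , drop = FALSE]
  if (nrow(d) < length(covariates) + 2)
    stop("need at least ", length(covariates) + 2, " complete-case rows")
  fm <- stats::as.formula(paste(response, "~",
                                paste(covariates, collapse = " + ")))
  X <- stats::model.matrix(fm, d)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm(fm, data = d)
  sm <- summary(fit)
  co <- sm$coefficients
  structure(
    list(coefficients = data.frame(term = rownames(co),
                                   estimate = co[, 1], std_error = co[, 2],
                                   t = co[, 3], p = co[, 4],
                                   row.names = NULL),
         r_squared = sm$r.squared, df_residual = fit$df.residual,
         n_used = nrow(d), n_dropped = sum(!cc)),
    class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS: n = %d (%d dropped), R^2 = %.3f, residual df = %d\n",
              x$n_used, x$n_dropped, x$r_squared, x$df_residual))
  print(x$coefficients, digits = 4)
  invisible(x)
}
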