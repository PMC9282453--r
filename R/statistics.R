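#' @title Cohort statistics: gender comparison, age correlation, regression
#' @description
#' The statistical battery applied to each iodine measure: a two-sided
#' Mann-Whitney U test for the male/female comparison, Pearson correlation
#' of concentration with age, and ordinary least squares regression to
#' obtain the per-year slope used for age adjustment of reference ranges.
#' All tests are two-sided, alpha defaults to 0.05, and no multiple-testing
#' correction is applied (raw p-values per endpoint).
#' @name cohort-statistics
NULL

new_test_result <- function(test_name, statistic, p_value, n,
                            effect = NULL, alpha = 0.05) {
  p_value <- min(max(p_value, 0), 1)
  structure(list(
    test_name   = test_name,
    statistic   = statistic,
    p_value     = p_value,
    n           = n,
    effect      = effect,
    alpha       = alpha,
    significant = p_value < alpha
  ), class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic = %.4g, p = %.4g (%s at alpha = %g)\n",
              x$test_name, x$statistic, x$p_value,
              if (x$significant) "significant" else "not significant", x$alpha))
  if (!is.null(x$effect)) {
    e <- x$effect
    parts <- character(0)
    if (!is.null(e$r))         parts <- c(parts, sprintf("r = %.4f", e$r))
    if (!is.null(e$r_squared)) parts <- c(parts, sprintf("R^2 = %.4f", e$r_squared))
    if (!is.null(e$slope))     parts <- c(parts, sprintf("slope = %.4g/yr", e$slope))
    if (!is.null(e$intercept)) parts <- c(parts, sprintf("intercept = %.4g", e$intercept))
    if (length(parts)) cat("  ", paste(parts, collapse = ", "), "\n")
  }
  invisible(x)
}

# U statistic for group x against group y: number of cross pairs with
# x > y plus half the tied pairs. Computed via midranks, which is
# algebraically identical to the pair count.
mann_whitney_u_statistic <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)           # midranks
  sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
}

# Exact two-sided p by enumeration of all group-1 assignments of the pooled
# midranks (valid under ties). p = 2 * min(P(U <= u), P(U >= u)), capped at 1.
mwu_exact_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(N, n1)
  us <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
  eps <- 1e-9
  p_lo <- mean(us <= u_obs + eps)
  p_hi <- mean(us >= u_obs - eps)
  min(1, 2 * min(p_lo, p_hi))
}

# Normal approximation with midrank tie correction and continuity correction.
mwu_normal_p <- function(x, y, u) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) return(1)     # all values tied: no evidence either way
  mu <- n1 * n2 / 2
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  2 * stats::pnorm(-abs(z))
}

#' Two-sample Mann-Whitney U test
#'
#' U is the count over all cross-group pairs of (x > y) plus half the ties
#' (reported for the first group). The two-sided p-value uses exact
#' enumeration when either group has fewer than 8 observations (and the
#' enumeration is tractable), otherwise the normal approximation with
#' midrank tie correction and continuity correction.
#'
#' @param x,y numeric samples for the two groups; both non-empty and finite.
#' @param alpha significance level.
#' @param exact_limit use exact enumeration when `min(n1, n2) < 8`; the
#'   enumeration is capped at `choose(n1+n2, n1) <= 2e6` combinations.
#' @return a `test_result` with `statistic = U`.
#' @export
mann_whitney_u <- function(x, y, alpha = 0.05, exact_limit = 8) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  if (any(!is.finite(c(x, y)))) stop("all values must be finite")
  u <- mann_whitney_u_statistic(x, y)
  exact <- min(length(x), length(y)) < exact_limit &&
    choose(length(x) + length(y), length(x)) <= 2e6
  p <- if (exact) mwu_exact_p(x, y) else mwu_normal_p(x, y, u)
  new_test_result("mann_whitney_u", statistic = u, p_value = p,
                  n = c(n1 = length(x), n2 = length(y)), alpha = alpha)
}

#' Gender comparison of a concentration measure
#'
#' Mann-Whitney U test of female versus male values; the U statistic is
#' reported for the female group.
#'
#' @param values per-patient concentrations in mg/ml.
#' @param sexes matching sex labels (any coding accepted by
#'   [normalize_sex()]).
#' @param alpha significance level.
#' @return a `test_result`.
#' @export
mann_whitney_gender <- function(values, sexes, alpha = 0.05) {
  stopifnot(length(values) == length(sexes))
  sex <- if (is.factor(sexes)) sexes else normalize_sex(sexes)
  f <- values[sex == "female"]
  m <- values[sex == "male"]
  if (!length(f) || !length(m))
    stop("both sexes must be represented in the cohort")
  res <- mann_whitney_u(f, m, alpha = alpha)
  res$n <- c(female = length(f), male = length(m))
  res
}

#' Pearson correlation of concentration with age
#'
#' Two-sided p-value from the t transform with n - 2 degrees of freedom.
#'
#' @param values per-patient concentrations in mg/ml.
#' @param ages matching ages in years.
#' @param alpha significance level.
#' @return a `test_result` with `effect$r` and `effect$r_squared`.
#' @export
pearson_age <- function(values, ages, alpha = 0.05) {
  stopifnot(length(values) == length(ages))
  n <- length(values)
  if (n < 3) stop("Pearson correlation requires n >= 3")
  if (any(!is.finite(values)) || any(!is.finite(ages)))
    stop("values and ages must be finite")
  if (stats::sd(values) == 0 || stats::sd(ages) == 0)
    stop("degenerate input: zero variance in values or ages")
  r <- stats::cor(ages, values)
  r <- min(max(r, -1), 1)
  if (abs(r) == 1) {
    p <- 0
  } else {
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  }
  new_test_result("pearson", statistic = r, p_value = p, n = n,
                  effect = list(r = r, r_squared = r^2), alpha = alpha)
}

#' Simple linear regression of concentration on age
#'
#' Ordinary least squares; the slope (mg/ml per year) is the quantity used
#' to age-adjust blood-normalized reference ranges. The p-value is the
#' two-sided slope test, identical to the Pearson test on the same data.
#'
#' @param values per-patient concentrations in mg/ml.
#' @param ages matching ages in years.
#' @param alpha significance level.
#' @return a `test_result` with `effect$slope`, `effect$intercept`,
#'   `effect$r`, `effect$r_squared`.
#' @export
simple_linear_regression <- function(values, ages, alpha = 0.05) {
  stopifnot(length(values) == length(ages))
  n <- length(values)
  if (n < 3) stop("regression requires n >= 3")
  if (stats::var(ages) == 0) stop("degenerate design: all ages equal")
  slope <- stats::cov(ages, values) / stats::var(ages)
  intercept <- mean(values) - slope * mean(ages)
  if (stats::sd(values) == 0) {
    r <- 0; p <- 1
  } else {
    r <- stats::cor(ages, values)
    r <- min(max(r, -1), 1)
    p <- if (abs(r) == 1) 0 else
      2 * stats::pt(-abs(r * sqrt((n - 2) / (1 - r^2))), df = n - 2)
  }
  new_test_result("linear_regression", statistic = slope, p_value = p, n = n,
                  effect = list(slope = slope, intercept = intercept,
                                r = r, r_squared = r^2),
                  alpha = alpha)
}
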