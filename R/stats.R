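#' Pooled-variance two-sample t-test with Cohen's d
#'
#' Student's two-sided two-sample t-test with the pooled variance estimate
#' (`df = n1 + n2 - 2`), reported with Cohen's d (mean difference divided by
#' the pooled standard deviation). The pooled form (rather than Welch) is the
#' package default because the published clinical-score comparisons are
#' reproduced by it from their summary statistics. Accepts either raw samples
#' or summary statistics (means, SDs, group sizes).
#'
#' @param x,y Numeric vectors of observations (each `n >= 2`); or, when
#'   `summary = TRUE` arguments are given, leave these unset.
#' @param mean1,sd1,n1,mean2,sd2,n2 Summary-statistic interface.
#' @param m Bonferroni family size used to fill `p_adjusted = min(1, m * p)`
#'   (default 1, i.e. no correction).
#' @return A one-row tibble: `estimate` (mean1 - mean2), `statistic`, `df`,
#'   `p_value`, `p_adjusted`, `cohens_d`, `n1`, `n2`, `method`.
#' @examples
#' t_test_pooled(mean1 = 46.0, sd1 = 2.0, n1 = 10,
#'               mean2 = 42.9, sd2 = 3.8, n2 = 8)
#' @export
t_test_pooled <- function(x = NULL, y = NULL, mean1 = NULL, sd1 = NULL, n1 = NULL,
                          mean2 = NULL, sd2 = NULL, n2 = NULL, m = 1) {
  if (!is.null(x)) {
    stopifnot(is.numeric(x), is.numeric(y))
    mean1 <- mean(x); sd1 <- sd(x); n1 <- length(x)
    mean2 <- mean(y); sd2 <- sd(y); n2 <- length(y)
  }
  if (n1 < 2 || n2 < 2) {
    stop_synergait("each group needs at least 2 observations", "synergait_stats_error")
  }
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  est <- mean1 - mean2
  if (sp2 == 0) {
    if (est == 0) {
      stat <- 0; p <- 1; d <- 0
    } else {
      stop_synergait("zero pooled variance with unequal means: t is degenerate",
                     "synergait_stats_error")
    }
  } else {
    stat <- est / sqrt(sp2 * (1 / n1 + 1 / n2))
    p <- 2 * stats::pt(-abs(stat), df)
    d <- est / sqrt(sp2)
  }
  tibble::tibble(
    estimate = est, statistic = stat, df = df, p_value = p,
    p_adjusted = bonferroni(p, m), cohens_d = d, n1 = n1, n2 = n2,
    method = "pooled two-sample t-test"
  )
}

#' Bonferroni adjustment
#'
#' @param p Raw p-value(s).
#' @param m Family size.
#' @return `min(1, m * p)`, elementwise.
#' @export
bonferroni <- function(p, m) pmin(1, m * p)

#' Pearson chi-squared test for a 2x2 contingency table
#'
#' Pearson's chi-squared test without continuity correction (df = 1), the
#' form that reproduces the published sex-ratio and laxity-test comparisons
#' from their counts. The statistic equals `N (ad - bc)^2` divided by the
#' product of the marginals.
#'
#' @param table A 2x2 matrix of non-negative counts, or the four counts
#'   `a, b, c, d` given positionally (row-wise).
#' @param ... Counts `b`, `c`, `d` when `table` is the scalar `a`.
#' @param m Bonferroni family size for `p_adjusted`.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `p_adjusted`,
#'   `n`, `method`.
#' @examples
#' chi2_2x2(matrix(c(7, 3, 3, 5), 2, byrow = TRUE))
#' @export
chi2_2x2 <- function(table, ..., m = 1) {
  if (!is.matrix(table)) {
    cnt <- c(table, ...)
    stopifnot(length(cnt) == 4)
    table <- matrix(cnt, 2, 2, byrow = TRUE)
  }
  if (any(table < 0) || any(table != round(table))) {
    stop_synergait("counts must be non-negative integers", "synergait_stats_error")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop_synergait("chi-squared is undefined with a zero marginal", "synergait_stats_error")
  }
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  tibble::tibble(
    statistic = unname(res$statistic), df = 1,
    p_value = res$p.value, p_adjusted = bonferroni(res$p.value, m),
    n = sum(table), method = "Pearson chi-squared (no continuity correction)"
  )
}

#' One-way analysis of variance
#'
#' Classic one-way fixed-effects F-test (between df = g - 1, within
#' df = N - g), used here to compare muscle synergy weights across groups.
#' For two groups the F statistic equals the square of the pooled t
#' statistic.
#'
#' @param values Numeric vector of observations, or a data frame with the
#'   columns named by `value` and `group`.
#' @param group Grouping vector parallel to `values` (or column name).
#' @param value Column name when `values` is a data frame.
#' @param m Bonferroni family size for `p_adjusted`.
#' @return A one-row tibble: `statistic`, `df_between`, `df_within`,
#'   `p_value`, `p_adjusted`, `n`, `method`.
#' @export
anova_oneway <- function(values, group, value = "value", m = 1) {
  if (is.data.frame(values)) {
    group <- values[[group]]
    values <- values[[value]]
  }
  g <- factor(group)
  if (nlevels(g) < 2 || any(tabulate(g) < 2)) {
    stop_synergait("at least 2 groups with n >= 2 each are required",
                   "synergait_stats_error")
  }
  n <- length(values)
  means <- tapply(values, g, mean)
  ss_within <- sum(tapply(values, g, function(v) sum((v - mean(v))^2)))
  ss_between <- sum(tabulate(g) * (means - mean(values))^2)
  df_b <- nlevels(g) - 1
  df_w <- n - nlevels(g)
  if (ss_within == 0) {
    if (ss_between == 0) {
      stat <- 0; p <- 1
    } else {
      stop_synergait("zero within-group variance with unequal means: F is degenerate",
                     "synergait_stats_error")
    }
  } else {
    stat <- (ss_between / df_b) / (ss_within / df_w)
    p <- stats::pf(stat, df_b, df_w, lower.tail = FALSE)
  }
  tibble::tibble(
    statistic = stat, df_between = df_b, df_within = df_w,
    p_value = p, p_adjusted = bonferroni(p, m), n = n,
    method = "one-way ANOVA"
  )
}
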