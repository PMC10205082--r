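test_that("pooled t-test handles identical and degenerate samples", {
  x <- c(1, 2, 3, 4)
  r <- t_test_pooled(x, x)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$cohens_d, 0)
  r0 <- t_test_pooled(c(2, 2, 2), c(2, 2))
  expect_equal(r0$p_value, 1)
  expect_error(t_test_pooled(c(2, 2, 2), c(3, 3, 3)),
               class = "synergait_stats_error")
  expect_error(t_test_pooled(1, c(1, 2)), class = "synergait_stats_error")
})

test_that("pooled t-test reproduces the published OKS comparison from summaries", {
  r <- t_test_pooled(mean1 = 46.0, sd1 = 2.0, n1 = 10,
                     mean2 = 42.9, sd2 = 3.8, n2 = 8)
  expect_equal(round(r$p_value, 3), 0.040)
  expect_equal(r$df, 16)
  expect_gt(r$cohens_d, 1)  # large standardized group difference
})

test_that("pooled t-test matches an explicit hand computation on toy lists", {
  x <- c(1, 2, 6); y <- c(4, 8, 9)
  # hand-computed oracle via the explicit pooled formula
  sp2 <- (2 * var(x) + 2 * var(y)) / 4
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (2 / 3))
  p_hand <- 2 * pt(-abs(t_hand), 4)
  r <- t_test_pooled(x, y)
  expect_equal(r$statistic, t_hand, tolerance = 1e-12)
  expect_equal(r$p_value, p_hand, tolerance = 1e-12)
  expect_equal(r$cohens_d, (mean(x) - mean(y)) / sqrt(sp2), tolerance = 1e-12)
  # and agrees with the standard library implementation
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("chi-squared reproduces the published 2x2 comparisons", {
  expect_equal(round(chi2_2x2(matrix(c(7, 3, 3, 5), 2, byrow = TRUE))$p_value, 3),
               0.168)
  expect_equal(round(chi2_2x2(1, 9, 5, 3)$p_value, 3), 0.019)
  r <- chi2_2x2(5, 5, 5, 5)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
})

test_that("chi-squared is invariant under transposition and marginal swaps", {
  m <- matrix(c(8, 2, 4, 6), 2, byrow = TRUE)
  p0 <- chi2_2x2(m)$p_value
  expect_equal(chi2_2x2(t(m))$p_value, p0)
  expect_equal(chi2_2x2(m[2:1, ])$p_value, p0)
  expect_equal(chi2_2x2(m[, 2:1])$p_value, p0)
  expect_error(chi2_2x2(matrix(c(0, 0, 3, 5), 2, byrow = TRUE)),
               class = "synergait_stats_error")
  expect_error(chi2_2x2(1.5, 2, 3, 4), class = "synergait_stats_error")
})

test_that("one-way ANOVA matches the sum-of-squares decomposition", {
  vals <- c(3, 4, 5, 7, 8, 9, 1, 2, 2)
  grp <- rep(c("a", "b", "c"), each = 3)
  r <- anova_oneway(vals, grp)
  # brute-force oracle: explicit between/within sums of squares
  gm <- mean(vals)
  means <- tapply(vals, grp, mean)
  ssb <- sum(3 * (means - gm)^2)
  ssw <- sum((vals - means[grp])^2)
  f_hand <- (ssb / 2) / (ssw / 6)
  expect_equal(r$statistic, f_hand, tolerance = 1e-12)
  expect_equal(r$p_value, pf(f_hand, 2, 6, lower.tail = FALSE), tolerance = 1e-12)
  # independent cross-check against the standard library
  ref <- oneway.test(vals ~ factor(grp), var.equal = TRUE)
  expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("two-group ANOVA equals the squared pooled t-test", {
  set.seed(51)
  x <- rnorm(9); y <- rnorm(7, 0.8)
  a <- anova_oneway(c(x, y), rep(c("g1", "g2"), c(9, 7)))
  t <- t_test_pooled(x, y)
  expect_equal(a$statistic, t$statistic^2, tolerance = 1e-12)
  expect_equal(a$p_value, t$p_value, tolerance = 1e-12)
})

test_that("ANOVA handles identical groups and rejects degenerate input", {
  v <- rep(c(1, 2, 3), 2)
  r <- anova_oneway(v, rep(c("a", "b"), each = 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_error(anova_oneway(c(1, 1, 1, 2, 2, 2), rep(c("a", "b"), each = 3)),
               class = "synergait_stats_error")
  expect_error(anova_oneway(1:3, c("a", "a", "b")), class = "synergait_stats_error")
})

test_that("Bonferroni adjustment is monotone and capped at one", {
  p <- c(0.001, 0.01, 0.2, 0.5)
  adj <- bonferroni(p, 4)
  expect_true(all(diff(adj) >= 0))
  expect_true(all(adj <= 1))
  expect_equal(adj[1], 0.004)
  r <- t_test_pooled(c(1, 2, 3), c(5, 6, 7), m = 6)
  expect_equal(r$p_adjusted, min(1, 6 * r$p_value))
  expect_gte(r$p_adjusted, r$p_value)
})
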