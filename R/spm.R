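#' Permutation-based one-dimensional statistical parametric mapping
#'
#' Tests for group differences over whole kinematic time series (e.g.
#' 101-point gait-cycle curves) with family-wise control over the 1D domain.
#' A pointwise pooled two-sample t trajectory is computed, and the null
#' distribution of its maximum absolute value over the domain is built by
#' permuting the group labels (complete enumeration when the number of
#' distinct relabelings does not exceed `n_perm`, otherwise a seeded
#' Monte-Carlo subset). The critical threshold is the `(1 - alpha)` quantile
#' of that max-statistic null; suprathreshold clusters are the maximal runs of
#' `|t|` above it, each assigned a permutation p-value
#' `(1 + #\{null maxima >= cluster max\}) / (n_used + 1)`. This permutation
#' scheme carries the same inference contract as random-field-theory SPM
#' (family-wise error control over the domain) without its analytic
#' smoothness constants.
#'
#' Degenerate pointwise variance is handled by adding a small documented
#' ridge (`ridge` times the largest pooled variance over the domain, floored
#' at 1e-12) to the pooled variance at every node.
#'
#' @param curves1,curves2 Matrices of curves, one row per subject (columns =
#'   domain nodes; both groups must share the number of columns).
#' @param alpha Family-wise significance level (default 0.05).
#' @param n_perm Maximum number of permutations (default 1000, minimum 100).
#' @param seed Integer seed for the Monte-Carlo permutations.
#' @param ridge Relative variance ridge (default 1e-10).
#' @return An `spm_result`: list with `t` (pointwise trajectory),
#'   `threshold`, `alpha`, `clusters` (tibble: `start`, `end` node indices,
#'   `max_t`, `p_value`), `n_perm_used`, `exhaustive`, `null_max`.
#' @export
spm_ttest_1d <- function(curves1, curves2, alpha = 0.05, n_perm = 1000, seed,
                         ridge = 1e-10) {
  y1 <- as.matrix(curves1); y2 <- as.matrix(curves2)
  if (ncol(y1) != ncol(y2)) {
    stop_synergait("curve sets must share the domain length", "synergait_spm_error")
  }
  if (n_perm < 100) {
    stop_synergait("n_perm must be at least 100", "synergait_spm_error")
  }
  if (missing(seed)) stop_synergait("seed is a mandatory argument", "synergait_spm_error")
  n1 <- nrow(y1); n2 <- nrow(y2); n <- n1 + n2
  if (n1 < 2 || n2 < 2) {
    stop_synergait("each group needs at least 2 curves", "synergait_spm_error")
  }
  Y <- rbind(y1, y2)
  Y2 <- Y^2

  t_for <- function(idx1) {
    # idx1: logical membership of group 1, as a 0/1 matrix (B x n)
    m1 <- (idx1 %*% Y) / n1
    m2 <- ((1 - idx1) %*% Y) / n2
    s1 <- (idx1 %*% Y2) - n1 * m1^2
    s2 <- ((1 - idx1) %*% Y2) - n2 * m2^2
    sp2 <- (s1 + s2) / (n1 + n2 - 2)
    eps <- pmax(apply(sp2, 1, max) * ridge, 1e-12)
    (m1 - m2) / sqrt((sp2 + eps) * (1 / n1 + 1 / n2))
  }

  obs_idx <- matrix(0, 1, n); obs_idx[1, seq_len(n1)] <- 1
  t_obs <- drop(t_for(obs_idx))

  n_total <- choose(n, n1)
  exhaustive <- n_total <= n_perm
  if (exhaustive) {
    combs <- utils::combn(n, n1)
    P <- matrix(0, ncol(combs), n)
    P[cbind(rep(seq_len(ncol(combs)), each = n1), as.vector(combs))] <- 1
  } else {
    set.seed(seed)
    P <- t(replicate(n_perm, {
      v <- numeric(n); v[sample.int(n, n1)] <- 1; v
    }))
  }
  null_max <- apply(abs(t_for(P)), 1, max)
  n_used <- length(null_max)
  threshold <- quantile(null_max, 1 - alpha, names = FALSE, type = 8)

  above <- abs(t_obs) > threshold
  clusters <- find_runs(above)
  if (nrow(clusters) > 0) {
    clusters$max_t <- vapply(seq_len(nrow(clusters)), function(i) {
      max(abs(t_obs[clusters$start[i]:clusters$end[i]]))
    }, numeric(1))
    clusters$p_value <- vapply(clusters$max_t, function(mt) {
      (1 + sum(null_max >= mt)) / (n_used + 1)
    }, numeric(1))
  } else {
    clusters$max_t <- numeric(0)
    clusters$p_value <- numeric(0)
  }
  structure(
    list(t = t_obs, threshold = threshold, alpha = alpha, clusters = clusters,
         n_perm_used = n_used, exhaustive = exhaustive, null_max = null_max,
         n1 = n1, n2 = n2),
    class = "spm_result"
  )
}

find_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  tibble::tibble(start = starts[keep], end = ends[keep])
}

#' @export
print.spm_result <- function(x, ...) {
  cat(sprintf("<spm_result> %d vs %d curves, threshold |t| = %.3f (alpha %.3g, %d perms%s)\n",
              x$n1, x$n2, x$threshold, x$alpha, x$n_perm_used,
              if (x$exhaustive) ", exhaustive" else ""))
  if (nrow(x$clusters) == 0) {
    cat("no suprathreshold clusters\n")
  } else {
    print(x$clusters)
  }
  invisible(x)
}
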