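#' Non-negative matrix factorization of an EMG envelope matrix
#'
#' Factorizes a non-negative muscles x time matrix `V` (typically 8 x
#' 200*cycles of concatenated normalized cycles) into synergy modules `W`
#' (muscles x k, the time-independent coefficients) and activation
#' coefficients `H` (k x time, the time-dependent coefficients) by
#' multiplicative updates minimizing the Frobenius reconstruction error.
#' The best of `n_restarts` random initializations (smallest SSE) is kept;
#' each run stops when the relative SSE improvement over a 20-iteration
#' window falls below `tol` or after `max_iter` iterations. Columns of `W`
#' are scaled to unit maximum with compensating row scaling of `H`, and the
#' reconstruction quality is reported as `r_squared = 1 - SSE/SStot`
#' against the input matrix.
#'
#' @param V Non-negative numeric matrix (muscles x time).
#' @param k Factorization rank, `1 <= k <= nrow(V)`.
#' @param seed Integer seed for the random restarts (mandatory: all
#'   stochastic results in this package carry their seed).
#' @param n_restarts Number of random restarts (default 10).
#' @param max_iter Maximum multiplicative-update iterations per restart.
#' @param tol Relative SSE improvement threshold over `window` iterations.
#' @param window Convergence window in iterations.
#' @param keep_trace Keep the per-iteration SSE trace of the winning restart
#'   (used to verify the objective is non-increasing).
#' @return A `synergy_set` object: list with `W`, `H`, `k`, `r_squared`,
#'   `sse`, `n_cycles` (when `ncol(V)` is a multiple of 200), `patterns`
#'   (k x 200 cycle-averaged activation patterns), `seed`, `iterations`,
#'   and optionally `sse_trace`.
#' @export
nmf <- function(V, k, seed, n_restarts = 10, max_iter = 1000, tol = 1e-6,
                window = 20, keep_trace = FALSE) {
  V <- as.matrix(V)
  if (any(!is.finite(V)) || any(V < 0)) {
    stop_synergait("V must be finite and non-negative", "synergait_nmf_error")
  }
  if (k < 1 || k > nrow(V)) {
    stop_synergait(sprintf("rank k = %d outside 1..%d", k, nrow(V)),
                   "synergait_nmf_error")
  }
  if (missing(seed)) stop_synergait("seed is a mandatory argument", "synergait_nmf_error")
  set.seed(seed)
  scale0 <- sqrt(mean(V) / max(k, 1))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    W0 <- matrix(runif(nrow(V) * k, 0.1, 1), nrow(V), k) * scale0
    H0 <- matrix(runif(k * ncol(V), 0.1, 1), k, ncol(V)) * scale0
    fit <- .nmf_mu_cpp(V, W0, H0, max_iter, tol, window, keep_trace)
    if (is.null(best) || fit$sse < best$sse) best <- fit
  }
  # unit-max module columns, compensating row scaling of H
  cmax <- apply(best$W, 2, max)
  cmax[cmax == 0] <- 1
  W <- sweep(best$W, 2, cmax, "/")
  H <- sweep(best$H, 1, cmax, "*")
  rownames(W) <- rownames(V) %||% emg_channels[seq_len(nrow(V))]
  sstot <- sum((V - mean(V))^2)
  r2 <- if (sstot > 0) 1 - best$sse / sstot else 1
  n_cycles <- if (ncol(V) %% 200 == 0) ncol(V) / 200 else NA_integer_
  patterns <- if (!is.na(n_cycles)) {
    # average activation over cycles onto the 200-point normalized cycle
    p <- matrix(0, k, 200)
    for (c in seq_len(n_cycles)) p <- p + H[, (c - 1) * 200 + 1:200, drop = FALSE]
    p / n_cycles
  } else {
    NULL
  }
  structure(
    list(W = W, H = H, k = k, r_squared = r2, sse = best$sse,
         n_cycles = n_cycles, patterns = patterns, seed = seed,
         iterations = best$iterations,
         sse_trace = if (keep_trace) best$sse_trace else NULL),
    class = "synergy_set"
  )
}

#' @export
print.synergy_set <- function(x, ...) {
  cat(sprintf("<synergy_set> k = %d, r_squared = %.4f (%d muscles x %d samples, seed %d)\n",
              x$k, x$r_squared, nrow(x$W), ncol(x$H), x$seed))
  invisible(x)
}

#' Select the number of synergies for one subject-activity
#'
#' Returns the smallest rank `k` in `1..nrow(V)` whose NMF reconstruction
#' reaches `r_squared >= threshold` (default 0.90). The threshold rule is a
#' documented package contract for model-order selection; it is configurable.
#'
#' @inheritParams nmf
#' @param threshold Reconstruction-quality threshold (default 0.90).
#' @param n_restarts Restarts per candidate rank (default 5; the final
#'   reported factorization is typically refit with more restarts).
#' @param k_max Largest rank to try; the fallback when no rank reaches the
#'   threshold.
#' @return Integer rank.
#' @export
choose_rank <- function(V, seed, threshold = 0.90, n_restarts = 5,
                        k_max = nrow(as.matrix(V)), ...) {
  for (k in seq_len(k_max)) {
    fit <- nmf(V, k, seed = seed + k, n_restarts = n_restarts, ...)
    if (fit$r_squared >= threshold) return(k)
  }
  as.integer(k_max)
}

#' Impose a common synergy model order per activity
#'
#' The number of classified synergies per activity is imposed from the
#' average number of synergies extracted per group: the mean of the per-group
#' mean ranks, rounded half away from zero. With the published per-group
#' means this yields 4 for level and downhill walking and 3 for stair
#' descent.
#'
#' @param ... Numeric vectors of per-subject selected ranks, one per group
#'   (or pre-computed per-group means as length-1 values); alternatively a
#'   single list of such vectors.
#' @return Integer imposed rank.
#' @examples
#' impose_group_rank(3.7, 3.5)  # -> 4
#' impose_group_rank(c(3, 4, 3), c(3, 3, 4))
#' @export
impose_group_rank <- function(...) {
  groups <- list(...)
  if (length(groups) == 1 && is.list(groups[[1]])) groups <- groups[[1]]
  if (length(groups) == 0 || any(!vapply(groups, length, 1L))) {
    stop_synergait("at least one non-empty group is required", "synergait_rank_error")
  }
  m <- mean(vapply(groups, mean, numeric(1)))
  as.integer(sign(m) * floor(abs(m) + 0.5))
}
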