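# Shared fixtures built in code.

# Smooth random curves on a 101-point domain: fixed sinusoid basis with
# Gaussian coefficients, used as the null generating distribution for SPM
# checks (both groups drawn from the same process).
smooth_curves <- function(n, mu = rep(0, 101), sd = 1) {
  B <- sapply(1:6, function(k) sin(pi * k * seq(0, 1, length.out = 101)))
  t(sapply(seq_len(n), function(i) mu + sd * drop(B %*% rnorm(6))))
}

# Greedy one-to-one cosine matching between recovered and ground-truth
# module columns; returns the matched cosine similarities.
matched_cosines <- function(W, W_true) {
  cosm <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  k <- ncol(W_true)
  S <- outer(seq_len(ncol(W)), seq_len(k),
             Vectorize(function(i, j) cosm(W[, i], W_true[, j])))
  out <- numeric(min(ncol(W), k))
  for (s in seq_along(out)) {
    ij <- arrayInd(which.max(S), dim(S))
    out[s] <- S[ij]
    S[ij[1], ] <- -2
    S[, ij[2]] <- -2
  }
  out
}

# Normalized 200-point envelope cycles for every trial of one subject,
# concatenated into the muscles x (200 * cycles) matrix the NMF consumes.
subject_envelope_matrix <- function(trials) {
  envs <- lapply(seq_len(nrow(trials)), function(i) {
    emg_time_normalize(emg_filter_chain(trials$emg[[i]]),
                       trials$emg_events[[i]])
  })
  t(do.call(rbind, emg_normalize_amplitude(envs)))
}

# A small flat condyle fixture: `n` points per condyle all at height `z`
# above the plateau so that inverse-distance weights are equal.
flat_geometry <- function(n = 12, z = 1, spread = 6) {
  ang <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  disc <- cbind(spread * cos(ang), spread * sin(ang), rep(z, n))
  condyle_geometry(
    medial_points = sweep(disc, 2, c(22, 0, 0), "+"),
    lateral_points = sweep(disc, 2, c(-22, 0, 0), "+")
  )
}
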