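#' EMG envelope extraction: high-pass, rectify, low-pass
#'
#' Applies the standard surface-EMG conditioning chain: 4th-order Butterworth
#' high-pass at 50 Hz, full-wave rectification, then 4th-order Butterworth
#' low-pass at 20 Hz. Filters are applied zero-phase (forward-backward via
#' [signal::filtfilt()]) by default so that no group delay biases downstream
#' timing statistics such as the centre of activity; note that two passes
#' double the effective order while the cut-off frequencies stay at their
#' stated values. Negative low-pass ripple is clipped at zero so envelopes
#' are non-negative.
#'
#' @param emg A data frame with a `time` column (seconds) and one column per
#'   channel, or a numeric matrix (samples x channels).
#' @param rate Sampling rate in Hz; required for matrix input, otherwise
#'   inferred from the `time` column. Must be at least 1000 Hz.
#' @param high_cutoff,low_cutoff Cut-off frequencies in Hz.
#' @param order Butterworth order per pass (default 4).
#' @param zero_phase Apply filters forward-backward (default `TRUE`); set to
#'   `FALSE` for single-pass causal filtering.
#' @return The input with channel columns replaced by their envelopes.
#' @export
emg_filter_chain <- function(emg, rate = NULL, high_cutoff = 50, low_cutoff = 20,
                             order = 4, zero_phase = TRUE) {
  is_df <- is.data.frame(emg)
  if (is_df) {
    if (is.null(rate)) {
      if (!"time" %in% names(emg)) {
        stop_synergait("data-frame input needs a time column or an explicit rate",
                       "synergait_emg_error")
      }
      rate <- 1 / stats::median(diff(emg$time))
    }
    chans <- setdiff(names(emg), "time")
    x <- as.matrix(emg[chans])
  } else {
    if (is.null(rate)) {
      stop_synergait("matrix input requires a sampling rate", "synergait_emg_error")
    }
    x <- as.matrix(emg)
    chans <- colnames(x)
  }
  if (rate < 1000) {
    stop_synergait(
      sprintf("sampling rate %.0f Hz is below the required 1000 Hz (Nyquist margin for the %g Hz high-pass on broadband EMG)", rate, high_cutoff),
      "synergait_emg_error"
    )
  }
  hp <- signal::butter(order, high_cutoff / (rate / 2), type = "high")
  lp <- signal::butter(order, low_cutoff / (rate / 2), type = "low")
  apply_filt <- function(filt, v) {
    if (zero_phase) signal::filtfilt(filt, v) else signal::filter(filt, v)
  }
  env <- apply(x, 2, function(v) {
    pmax(0, apply_filt(lp, abs(apply_filt(hp, v))))
  })
  env <- matrix(env, nrow = nrow(x), dimnames = list(NULL, chans))
  if (is_df) {
    out <- emg
    out[chans] <- as.data.frame(env)
    tibble::as_tibble(out)
  } else {
    env
  }
}

#' Amplitude-normalize envelopes to the subject-activity maximum
#'
#' Divides each channel by its maximum value across all cycles of one
#' subject-activity, so that every channel attains 1 somewhere in that
#' subject-activity and all values lie in [0, 1].
#'
#' @param cycles A list of envelope matrices (points x channels, identical
#'   channel columns), one per cycle; a single matrix or data frame is treated
#'   as one cycle. Data frames may carry a `time` column, which is preserved.
#' @return The input structure with each channel scaled by the per-channel
#'   maximum over all cycles. An all-zero channel is returned as all zeros
#'   with a warning rather than NaN.
#' @export
emg_normalize_amplitude <- function(cycles) {
  single <- !is.list(cycles) || is.data.frame(cycles)
  if (single) cycles <- list(cycles)
  mats <- lapply(cycles, function(cy) {
    if (is.data.frame(cy)) as.matrix(cy[setdiff(names(cy), "time")]) else as.matrix(cy)
  })
  maxima <- Reduce(pmax, lapply(mats, function(m) apply(m, 2, max)))
  if (any(maxima == 0)) {
    warning("all-zero channel(s): ",
            paste(which(maxima == 0), collapse = ", "),
            "; returned as zeros")
    maxima[maxima == 0] <- 1
  }
  out <- purrr::map2(cycles, mats, function(cy, m) {
    scaled <- sweep(m, 2, maxima, "/")
    if (is.data.frame(cy)) {
      cy[colnames(m) %||% setdiff(names(cy), "time")] <- as.data.frame(scaled)
      cy
    } else {
      scaled
    }
  })
  if (single) out[[1]] else out
}

#' Time-normalize an envelope cycle to 200 points (100 stance + 100 swing)
#'
#' Resamples the stance phase (heel-strike to toe-off) to 100 points and the
#' swing phase (toe-off to next heel-strike) to 100 points, concatenating
#' them, so that activation profiles can be compared independently of the
#' absolute durations of the gait phases. Linear interpolation by default; a
#' natural cubic spline is available behind the `method` flag.
#'
#' @param envelope Numeric vector, matrix (samples x channels) or data frame
#'   of envelope samples for one cycle.
#' @param events List with `heel_strike_1`, `toe_off`, `heel_strike_2` as
#'   sample indices into `envelope`.
#' @param n_stance,n_swing Points allotted to each phase (defaults 100 + 100).
#' @param method `"linear"` (default) or `"spline"`.
#' @return A matrix (or vector) with `n_stance + n_swing` rows.
#' @export
emg_time_normalize <- function(envelope, events, n_stance = 100, n_swing = 100,
                               method = c("linear", "spline")) {
  method <- match.arg(method)
  ev <- as.list(events)
  hs1 <- ev$heel_strike_1; to <- ev$toe_off; hs2 <- ev$heel_strike_2
  vec <- is.null(dim(envelope))
  x <- if (is.data.frame(envelope)) {
    as.matrix(envelope[setdiff(names(envelope), "time")])
  } else {
    as.matrix(envelope)
  }
  if (!(hs1 < to && to < hs2) || hs2 > nrow(x)) {
    stop_synergait("events must satisfy heel_strike_1 < toe_off < heel_strike_2 within the trace",
                   "synergait_event_error")
  }
  if ((to - hs1) < 1 || (hs2 - to) < 1) {
    stop_synergait("stance and swing must each span at least 2 samples",
                   "synergait_event_error")
  }
  resample <- function(idx, n) {
    xout <- seq(idx[1], idx[length(idx)], length.out = n)
    apply(x, 2, function(v) {
      if (method == "linear") {
        approx(idx, v[idx], xout = xout)$y
      } else {
        splinefun(idx, v[idx], method = "natural")(xout)
      }
    })
  }
  stance <- resample(hs1:to, n_stance)
  swing <- resample(to:hs2, n_swing)
  out <- rbind(matrix(stance, ncol = ncol(x)), matrix(swing, ncol = ncol(x)))
  colnames(out) <- colnames(x)
  if (vec) drop(out) else out
}
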