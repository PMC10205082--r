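#' Full width at half maximum of an activation pattern
#'
#' Duration proxy for an activation burst: after subtracting the pattern
#' minimum, counts the samples strictly greater than half the resulting
#' maximum. Counting samples (rather than interpolating threshold crossings)
#' keeps widths integer-valued on the normalized 200-point grid and makes the
#' statistic invariant to positive affine transforms of the pattern.
#'
#' @param pattern Non-negative numeric vector (typically 200 points).
#' @return Integer width in samples of the cycle grid.
#' @seealso [fwhm_to_pct()] to convert to % of cycle, [coa()] for the timing
#'   counterpart.
#' @export
fwhm <- function(pattern) {
  stopifnot(is.numeric(pattern), all(is.finite(pattern)))
  x <- pattern - min(pattern)
  m <- max(x)
  if (m == 0) {
    stop_synergait("FWHM is undefined for a constant pattern", "synergait_metric_error")
  }
  sum(x > m / 2)
}

#' Convert an FWHM in cycle samples to percent of cycle
#'
#' @param points Width in samples.
#' @param n_points Cycle grid length (default 200).
#' @return Width as % of cycle.
#' @export
fwhm_to_pct <- function(points, n_points = 200) 100 * points / n_points

#' Circular centre of activity of an activation pattern
#'
#' Timing proxy for the main activation: the angle of the vector pointing to
#' the centre of mass of the pattern laid out on the circular gait cycle
#' (0-360 degrees between one touchdown and the next). Sample `t` of an
#' `n`-point pattern sits at `theta_t = 360 * (t - 1) / n` degrees, so the
#' first sample (touchdown) is at 0 deg and, for the 200-point stance+swing
#' grid, toe-off at point 101 maps to 180 deg.
#'
#' @param pattern Non-negative numeric vector with positive sum.
#' @return Angle in degrees in `[0, 360)`.
#' @export
coa <- function(pattern) {
  stopifnot(is.numeric(pattern), all(is.finite(pattern)), all(pattern >= 0))
  if (sum(pattern) == 0) {
    stop_synergait("CoA is undefined for an all-zero pattern", "synergait_metric_error")
  }
  n <- length(pattern)
  theta <- 2 * pi * (seq_len(n) - 1) / n
  a <- sum(pattern * cos(theta))
  b <- sum(pattern * sin(theta))
  (atan2(b, a) * 180 / pi) %% 360
}
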