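test_that("filter chain maps silence to silence and attenuates sub-band tones", {
  rate <- 2000
  t <- seq(0, 2, by = 1 / rate)
  zero <- matrix(0, length(t), 1)
  expect_true(all(emg_filter_chain(zero, rate = rate) == 0))
  # a 10 Hz tone sits below the 50 Hz high-pass: envelope should be tiny
  tone <- matrix(sin(2 * pi * 10 * t), ncol = 1)
  env <- emg_filter_chain(tone, rate = rate)
  mid <- seq(round(0.2 * length(t)), round(0.8 * length(t)))
  # > 40 dB attenuation relative to the rectified-tone envelope level (2/pi)
  expect_lt(max(env[mid]), (2 / pi) * 10^(-40 / 20))
})

test_that("filter chain tracks the envelope of an amplitude-modulated carrier", {
  rate <- 2000
  t <- seq(0, 3, by = 1 / rate)
  envelope <- 1 + sin(2 * pi * 2 * t)
  x <- matrix(envelope * sin(2 * pi * 150 * t), ncol = 1)
  out <- emg_filter_chain(x, rate = rate)
  mid <- seq(round(0.1 * length(t)), round(0.9 * length(t)))
  expect_gt(cor(out[mid], envelope[mid]), 0.95)
})

test_that("filter chain enforces the sampling-rate precondition", {
  expect_error(emg_filter_chain(matrix(0, 100, 1), rate = 500),
               regexp = "Nyquist", class = "synergait_emg_error")
})

test_that("amplitude normalization uses the subject-activity maximum", {
  m <- matrix(seq(0, 2.5, length.out = 20), ncol = 1)
  out <- emg_normalize_amplitude(m)
  expect_equal(max(out), 1)
  expect_equal(out, m / 2.5)
  # the maximum is taken across cycles, not per cycle
  c1 <- matrix(c(rep(0, 9), 1.0), ncol = 1)
  c2 <- matrix(c(rep(0, 9), 2.0), ncol = 1)
  out2 <- emg_normalize_amplitude(list(c1, c2))
  expect_equal(max(out2[[1]]), 0.5)
  expect_equal(max(out2[[2]]), 1.0)
  # property: per channel, the maximum over all cycles is exactly 1
  set.seed(8)
  cycles <- replicate(3, matrix(runif(40 * 8), 40, 8), simplify = FALSE)
  norm <- emg_normalize_amplitude(cycles)
  maxima <- Reduce(pmax, lapply(norm, function(m) apply(m, 2, max)))
  expect_equal(unname(maxima), rep(1, 8))
})

test_that("an all-zero channel normalizes to zeros with a warning, not NaN", {
  m <- cbind(a = rep(0, 10), b = runif(10))
  expect_warning(out <- emg_normalize_amplitude(m), "all-zero")
  expect_true(all(out[, 1] == 0))
  expect_false(anyNA(out))
})

test_that("time normalization to 100+100 points is duration independent", {
  # stance twice as long as swing, constant signal: output constant
  x <- rep(1, 300)
  out <- emg_time_normalize(x, list(heel_strike_1 = 1, toe_off = 201,
                                    heel_strike_2 = 300))
  expect_equal(out, rep(1, 200))
  # stance ramp up, swing ramp down: tent peaking at the stance/swing join
  x2 <- c(seq(0, 1, length.out = 120), seq(1, 0, length.out = 81)[-1])
  out2 <- emg_time_normalize(x2, list(heel_strike_1 = 1, toe_off = 120,
                                      heel_strike_2 = 200))
  expect_equal(which.max(out2), 100)
  expect_equal(out2[100], 1, tolerance = 1e-9)
  expect_equal(out2[101], 1, tolerance = 1e-2)
  # affine-in-time signals are resampled exactly
  x3 <- 0.5 + 2 * seq_len(150)
  out3 <- emg_time_normalize(x3, list(heel_strike_1 = 1, toe_off = 90,
                                      heel_strike_2 = 150))
  expect_equal(max(abs(diff(diff(out3[1:100])))), 0, tolerance = 1e-9)
  expect_equal(out3[1], x3[1]); expect_equal(out3[200], x3[150])
  expect_error(emg_time_normalize(x3, list(heel_strike_1 = 1, toe_off = 1,
                                           heel_strike_2 = 150)),
               class = "synergait_event_error")
})

test_that("pipeline envelopes are gain invariant and non-negative", {
  set.seed(9)
  rate <- 2000
  n <- 2200
  raw <- matrix(rnorm(n * 2), n, 2)
  ev <- list(heel_strike_1 = 1, toe_off = 1300, heel_strike_2 = n)
  run <- function(x) {
    emg_normalize_amplitude(emg_time_normalize(
      emg_filter_chain(x, rate = rate), ev))
  }
  a <- run(raw)
  b <- run(raw * 37.5)   # amplifier gain is absorbed by normalization
  expect_equal(a, b, tolerance = 1e-9)
  expect_true(all(a >= 0))
})
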