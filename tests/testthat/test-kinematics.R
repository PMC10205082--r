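test_that("equidistant condyle points reduce to the plain mean", {
  geo <- flat_geometry()
  T0 <- diag(4)
  ap <- condylar_ap(T0, geo, n_nearest = 10)
  # all points share the same plane distance, so weights are equal and the
  # result is the mean A-P coordinate of the 10 selected points
  d <- geo$medial_points[, 3]
  sel <- order(d)[1:10]
  expect_equal(ap$medial_ap, mean(geo$medial_points[sel, 2]), tolerance = 1e-12)
})

test_that("condylar A-P is equivariant under tibial A-P translation", {
  geo <- default_condyle_geometry()
  T0 <- diag(4); T0[3, 4] <- 21
  T1 <- T0; T1[2, 4] <- 5
  a0 <- condylar_ap(T0, geo)
  a1 <- condylar_ap(T1, geo)
  expect_equal(a1$medial_ap - a0$medial_ap, 5, tolerance = 1e-12)
  expect_equal(a1$lateral_ap - a0$lateral_ap, 5, tolerance = 1e-12)
})

test_that("condylar A-P matches a brute-force evaluation at arbitrary poses", {
  geo <- default_condyle_geometry()
  set.seed(21)
  for (i in 1:10) {
    R <- gs_compose(runif(1, 0, 90), runif(1, -4, 4), runif(1, -10, 10))
    T <- diag(4); T[1:3, 1:3] <- R; T[1:3, 4] <- c(runif(1, -2, 2), runif(1, -5, 5), 21)
    got <- condylar_ap(T, geo)
    # independent brute-force oracle over all points
    oracle <- function(pts) {
      moved <- t(apply(pts, 1, function(p) R %*% p + T[1:3, 4]))
      d <- moved[, 3]            # plane z = 0, normal +z
      ap <- moved[, 2]           # A-P axis +y
      sel <- order(d)[1:10]
      w <- 1 / (abs(d[sel]) + 0.1)
      sum(w * ap[sel]) / sum(w)
    }
    expect_equal(got$medial_ap, oracle(geo$medial_points), tolerance = 1e-10)
    expect_equal(got$lateral_ap, oracle(geo$lateral_points), tolerance = 1e-10)
  }
})

test_that("too-small condyle clouds fail explicitly", {
  geo <- flat_geometry()
  geo$medial_points <- geo$medial_points[1:5, ]
  expect_error(condylar_ap(diag(4), geo), class = "synergait_geometry_error")
  expect_error(condyle_geometry(matrix(0, 3, 3), matrix(0, 12, 3)),
               class = "synergait_geometry_error")
})

test_that("cycle normalization is exact for already-normalized and affine input", {
  ev <- list(heel_strike_1 = 1, toe_off = 61, heel_strike_2 = 101)
  ramp <- seq(0, 10, length.out = 101)
  tracks <- tibble::tibble(frame = 1:101, flexion = ramp)
  cyc <- time_normalize_cycle(tracks, ev)
  expect_equal(nrow(cyc), 101)
  expect_equal(cyc$flexion, ramp, tolerance = 1e-12)
  expect_equal(attr(cyc, "toe_off_pct"), 60)
  # constant input stays constant
  cyc2 <- time_normalize_cycle(tibble::tibble(frame = 1:50, flexion = rep(3, 50)),
                               list(heel_strike_1 = 1, toe_off = 30, heel_strike_2 = 50))
  expect_true(all(cyc2$flexion == 3))
  # linear ramp on an irregular frame count keeps endpoints and linearity
  tracks3 <- tibble::tibble(frame = 1:37, medial_ap = seq(2, 12, length.out = 37),
                            lateral_ap = seq(0, 5, length.out = 37))
  cyc3 <- time_normalize_cycle(tracks3, list(heel_strike_1 = 1, toe_off = 22,
                                             heel_strike_2 = 37))
  # medial-condyle referencing: medial starts at exactly zero, lateral is
  # shifted by the same reference
  expect_equal(cyc3$medial_ap[1], 0)
  expect_equal(cyc3$medial_ap[101], 10, tolerance = 1e-12)
  expect_equal(cyc3$lateral_ap[1], -2, tolerance = 1e-12)
  expect_equal(max(abs(diff(diff(cyc3$medial_ap)))), 0, tolerance = 1e-10)
})

test_that("cycle normalization rejects bad events and non-monotonic frames", {
  tracks <- tibble::tibble(frame = c(1, 2, 2, 4), flexion = 1:4)
  expect_error(time_normalize_cycle(tracks, list(heel_strike_1 = 1, toe_off = 2,
                                                 heel_strike_2 = 4)),
               class = "synergait_event_error")
  expect_error(time_normalize_cycle(tibble::tibble(frame = 1:10, flexion = 1:10),
                                    list(heel_strike_1 = 5, toe_off = 3,
                                         heel_strike_2 = 10)),
               class = "synergait_event_error")
})

test_that("RoM summary computes per-phase ranges and the intercondylar diff", {
  pct <- seq(0, 100, length.out = 101)
  cyc <- tibble::tibble(
    cycle_pct = pct,
    flexion = 10 * sin(2 * pi * pct / 100),
    medial_ap = 5.4 * sin(pi * pct / 60) * (pct <= 60),
    lateral_ap = 5.1 * sin(pi * pct / 60) * (pct <= 60)
  )
  rs <- rom_summary(cyc, toe_off_pct = 60)
  stance <- rs[rs$phase == "stance", ]
  # planted stance RoMs: sinusoid peaks inside the stance window
  expect_equal(stance$rom[stance$parameter == "medial_ap"], 5.4, tolerance = 1e-6)
  expect_equal(stance$rom[stance$parameter == "lateral_ap"], 5.1, tolerance = 1e-6)
  expect_equal(stance$rom[stance$parameter == "ap_diff"], -0.3, tolerance = 1e-6)
  # diff equals lateral minus medial RoM exactly, per phase
  for (ph in c("stance", "swing")) {
    sub <- rs[rs$phase == ph, ]
    expect_equal(sub$rom[sub$parameter == "ap_diff"],
                 sub$rom[sub$parameter == "lateral_ap"] -
                   sub$rom[sub$parameter == "medial_ap"])
  }
  # constant tracks give zero RoM
  rs0 <- rom_summary(tibble::tibble(cycle_pct = pct, medial_ap = 1, lateral_ap = 1),
                     toe_off_pct = 60)
  expect_true(all(rs0$rom == 0))
  # sinusoid completing a full period inside each phase: RoM = 2 * amplitude
  full <- tibble::tibble(cycle_pct = pct, flexion = 7 * sin(4 * pi * pct / 100))
  expect_equal(rom_summary(full, toe_off_pct = 50)$rom, c(14, 14), tolerance = 0.01)
})

test_that("heel-strike detection finds the first upward threshold crossing", {
  f <- c(rep(0, 39), rep(800, 30))
  expect_identical(detect_heelstrike(f), 40L)
  expect_identical(detect_heelstrike(rep(10, 100)), NA_integer_)
  expect_identical(detect_heelstrike(rep(0, 50)), NA_integer_)
  # a trace that starts loaded reports the first sample
  expect_identical(detect_heelstrike(c(100, 0, 100)), 1L)
})

test_that("generated force traces reproduce their stored heel-strike", {
  f0 <- generate_force(1.1, 0.6, noise_sd = 0)
  expect_identical(detect_heelstrike(f0$force), attr(f0, "heel_strike_sample"))
  # with 5 N sensor noise the event stays within one fluoroscopy frame
  frame_samples <- attr(f0, "rate") / 30
  set.seed(5)
  for (i in 1:20) {
    fn <- generate_force(1.1, 0.6, noise_sd = 5)
    expect_lt(abs(detect_heelstrike(fn$force) - attr(fn, "heel_strike_sample")),
              frame_samples)
  }
  expect_identical(detect_heelstrike(rep(0, 1000)), NA_integer_)
})
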