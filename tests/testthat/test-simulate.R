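test_that("the generator is deterministic and stable under cohort growth", {
  spec <- cohort_spec("stable", 2, 2, "level", seed = 7)
  a <- generate_kinematics(spec)
  b <- generate_kinematics(spec)
  expect_identical(a, b)
  # adding a subject never perturbs existing subjects' trials
  spec3 <- cohort_spec("stable", 3, 2, "level", seed = 7)
  c3 <- generate_kinematics(spec3)
  expect_identical(a$pose, c3$pose[c3$subject %in% c("s01", "s02")])
  expect_error(cohort_spec("stable", 0, 3, "level", seed = 1),
               class = "synergait_spec_error")
  expect_error(cohort_spec("stable", Inf, 3, "level", seed = 1),
               class = "synergait_spec_error")
})

test_that("noise-free trials decompose back to the stored ground truth", {
  spec <- cohort_spec("stable", 1, 1, "level", seed = 42)
  kin <- generate_kinematics(spec, subject_scale = 0, cycle_cv = 0)
  tr <- kin$truth[[1]]
  dec <- gs_decompose(kin$pose[[1]])
  expect_equal(dec$flexion, tr$flexion, tolerance = 1e-9)
  expect_equal(dec$adduction, tr$adduction, tolerance = 1e-9)
  expect_equal(dec$internal_rotation, tr$internal_rotation, tolerance = 1e-9)
  tf <- synergait:::pose_df_transforms(kin$pose[[1]])
  ap <- do.call(rbind, lapply(tf, function(T) as.matrix(condylar_ap(T, kin$geometry[[1]]))))
  expect_equal(unname(ap[, 1]), tr$medial_ap, tolerance = 1e-9)
  expect_equal(unname(ap[, 2]), tr$lateral_ap, tolerance = 1e-9)
})

test_that("level templates carry the published stance flexion range", {
  spec <- cohort_spec("stable", 1, 1, "level", seed = 3)
  kin <- generate_kinematics(spec, subject_scale = 0, cycle_cv = 0)
  tr <- kin$truth[[1]]; ev <- kin$events[[1]]
  stance_rom <- max(tr$flexion[1:ev$toe_off]) - min(tr$flexion[1:ev$toe_off])
  expect_equal(stance_rom, 47.2, tolerance = 1e-9)
  # with subject variability the draws stay within the published band
  set.seed(1)
  spec2 <- cohort_spec("stable", 12, 1, "level", seed = 31)
  kin2 <- generate_kinematics(spec2, subject_scale = 1, cycle_cv = 0)
  roms <- purrr::map2_dbl(kin2$truth, kin2$events, function(tr, ev) {
    max(tr$flexion[1:ev$toe_off]) - min(tr$flexion[1:ev$toe_off])
  })
  expect_lt(abs(mean(roms) - 47.2), 4.9)
})

test_that("an instability event perturbs only the affected condyle in-window", {
  spec <- cohort_spec("unstable", 1, 1, "downhill", seed = 9)
  base <- generate_kinematics(spec, subject_scale = 0, cycle_cv = 0)
  ev <- instability_event(60, 4, 4, "medial")
  pert <- generate_kinematics(spec, event = ev, subject_scale = 0, cycle_cv = 0)
  tr0 <- base$truth[[1]]; tr1 <- pert$truth[[1]]
  win <- tr0$cycle_pct > 55 & tr0$cycle_pct < 80
  dmed <- tr1$medial_ap - tr0$medial_ap
  expect_equal(max(abs(dmed[!win])), 0, tolerance = 1e-9)
  expect_gt(max(abs(dmed[win])), 2)          # brute-force pointwise difference
  expect_equal(tr1$lateral_ap, tr0$lateral_ap, tolerance = 1e-6)
  expect_error(instability_event(-5, 4, 4), class = "synergait_spec_error")
})

test_that("zero ground-truth patterns yield pure-noise EMG with a flat envelope", {
  gt <- ground_truth_synergies("level")
  gt$patterns[] <- 0
  spec <- cohort_spec("stable", 1, 1, "level", seed = 13)
  emg <- generate_emg(spec, truth = gt, noise = 0.05)
  raw <- as.matrix(emg$emg[[1]][emg_channels])
  expect_true(all(is.finite(raw)))
  env <- emg_filter_chain(emg$emg[[1]])
  # residual envelope is only the rectified noise floor
  expect_lt(max(as.matrix(env[emg_channels])), 0.2)
  gt_bad <- gt; gt_bad$modules[1, 1] <- -1
  expect_error(generate_emg(spec, truth = gt_bad), class = "synergait_spec_error")
})

test_that("the filter chain recovers a planted square envelope", {
  # single muscle, single synergy, noiseless square burst
  sq <- matrix(0, 1, 200); sq[1, 60:140] <- 1
  gt <- structure(list(modules = matrix(c(1, rep(0, 7)), 8, 1),
                       patterns = sq, k = 1, labels = "only"),
                  class = "ground_truth_synergies")
  spec <- cohort_spec("stable", 1, 1, "level", seed = 17)
  emg <- generate_emg(spec, truth = gt, noise = 0, module_sd = 0, amp_cv = 0)
  env <- emg_filter_chain(emg$emg[[1]])
  norm <- emg_time_normalize(env, emg$emg_events[[1]])
  truth200 <- emg$truth_envelope[[1]][1, ]
  expect_gt(cor(norm[, "RF"], truth200), 0.95)
  expect_true(all(norm >= 0))
})

test_that("generated EMG supports full synergy recovery", {
  gt <- ground_truth_synergies("level")
  spec <- cohort_spec("stable", 1, 4, "level", seed = 23)
  emg <- generate_emg(spec, truth = gt)
  V <- subject_envelope_matrix(emg)
  expect_equal(dim(V), c(8, 800))
  k <- choose_rank(V, seed = 1)
  expect_equal(k, 4L)
  fit <- nmf(V, 4, seed = 2)
  expect_gte(min(matched_cosines(fit$W, gt$modules)), 0.9)
})

test_that("simulate_cohort bundles coherent trials with ground truth attached", {
  spec <- cohort_spec("unstable", 2, 3, "stair", seed = 29)
  coh <- simulate_cohort(spec)
  expect_equal(nrow(coh), 6)
  expect_true(all(c("pose", "events", "geometry", "truth", "emg",
                    "emg_events", "force") %in% names(coh)))
  expect_s3_class(attr(coh, "ground_truth"), "ground_truth_synergies")
  # force heel-strike is recoverable and EMG timing matches the trial
  f <- coh$force[[1]]
  expect_identical(detect_heelstrike(f$force), attr(f, "heel_strike_sample"))
  expect_equal(max(coh$emg[[1]]$time), max(coh$pose[[1]]$time), tolerance = 1e-3)
})

test_that("ground-truth synergies satisfy their structural invariants", {
  for (act in c("level", "downhill", "stair")) {
    gt <- ground_truth_synergies(act)
    expect_true(all(gt$modules >= 0) && all(gt$patterns >= 0))
    expect_equal(unname(apply(gt$modules, 2, max)), rep(1, gt$k))
    expect_equal(gt$k, if (act == "stair") 3 else 4)
  }
  # flexor widening stretches the planted flexor FWHM as intended
  n1 <- fwhm(ground_truth_synergies("stair")$patterns[3, ])
  n2 <- fwhm(ground_truth_synergies("stair", flexor_widening = 1.75)$patterns[3, ])
  expect_gt(n2, 1.5 * n1)
})
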