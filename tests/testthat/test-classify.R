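# Build a fake per-subject synergy_set from ground-truth columns (optionally
# permuted / perturbed), mimicking what nmf() returns.
fake_set <- function(gt, cols, jitter = 0.02, seed = 1) {
  set.seed(seed)
  W <- pmax(gt$modules[, cols, drop = FALSE] +
              matrix(rnorm(8 * length(cols), 0, jitter), 8), 0)
  H <- pmax(gt$patterns[cols, , drop = FALSE] +
              matrix(rnorm(length(cols) * 200, 0, jitter), length(cols)), 0)
  structure(list(W = W, H = H, k = length(cols), patterns = H,
                 r_squared = 0.95, seed = seed, n_cycles = 1),
            class = "synergy_set")
}

test_that("planted shared synergies classify fully with correct labels", {
  gt <- ground_truth_synergies("level")
  sets <- lapply(1:5, function(s) fake_set(gt, sample(1:4), seed = s))
  cl <- classify_synergies(sets, 4, seed = 99)
  expect_equal(classifiable_ratio(cl), 1)
  expect_setequal(unique(cl$label), gt$labels)
  # each subject expresses each fundamental synergy exactly once
  tab <- table(cl$subject, cl$label)
  expect_true(all(tab == 1))
})

test_that("a duplicated synergy within a subject is flagged unclassified", {
  gt <- ground_truth_synergies("level")
  sets <- lapply(1:4, function(s) fake_set(gt, 1:4, seed = s))
  # subject 1 carries two near-identical extensor synergies instead of a flexor
  sets[[1]] <- fake_set(gt, c(1, 1, 2, 3), seed = 11)
  cl <- classify_synergies(sets, 4, seed = 100)
  expect_lt(classifiable_ratio(cl), 1)
  expect_equal(sum(cl$unclassified[cl$subject == "1"]), 1)
})

test_that("classification is invariant to subject ordering", {
  gt <- ground_truth_synergies("stair")
  sets <- lapply(1:6, function(s) fake_set(gt, sample(1:3), seed = s))
  cl1 <- classify_synergies(sets, 3, seed = 5, subjects = 1:6)
  cl2 <- classify_synergies(rev(sets), 3, seed = 5, subjects = 6:1)
  expect_equal(classifiable_ratio(cl1), classifiable_ratio(cl2))
  lab1 <- lapply(with(tidy(cl1), split(label, subject)), sort)
  lab2 <- lapply(with(tidy(cl2), split(label, subject)), sort)
  expect_equal(lab1, lab2[names(lab1)])
})

test_that("planted classifiable fractions are recovered", {
  gt <- ground_truth_synergies("level")
  # group A: 10 subjects, 2 carry a duplicate -> planted ratio 38/40 = 0.95
  setsA <- lapply(1:10, function(s) {
    cols <- if (s <= 2) c(1, 1, 2, 3) else 1:4
    fake_set(gt, cols, seed = s)
  })
  # group B: 8 subjects, 6 carry a duplicate -> planted ratio 26/32 ~ 0.81
  setsB <- lapply(1:8, function(s) {
    cols <- if (s <= 6) c(2, 2, 1, 4) else 1:4
    fake_set(gt, cols, seed = 100 + s)
  })
  rA <- classifiable_ratio(classify_synergies(setsA, 4, seed = 7))
  rB <- classifiable_ratio(classify_synergies(setsB, 4, seed = 8))
  expect_lt(abs(rA - 0.95), 0.05)
  expect_lt(abs(rB - 26 / 32), 0.05)
})

test_that("classification validates its inputs", {
  gt <- ground_truth_synergies("level")
  sets <- lapply(1:2, function(s) fake_set(gt, 1:2, seed = s))
  expect_error(classify_synergies(sets[1], 2, seed = 1),
               class = "synergait_classify_error")
  expect_error(classify_synergies(sets, 10, seed = 1),
               class = "synergait_classify_error")
})

test_that("tidy and glance summarize classifications", {
  gt <- ground_truth_synergies("stair")
  sets <- lapply(1:3, function(s) fake_set(gt, 1:3, seed = s))
  cl <- classify_synergies(sets, 3, seed = 2)
  td <- tidy(cl)
  expect_named(td, c("subject", "synergy_id", "cluster", "label",
                     "unclassified", "fwhm", "coa"))
  gl <- glance(cl)
  expect_equal(gl$n_synergies, 9)
  expect_equal(gl$classifiable_ratio, classifiable_ratio(cl))
})
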