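# synergait

Joint kinematics and muscle-synergy analysis for studies of knee stability
after total knee arthroplasty (TKA).

## What this package is for

Self-reported knee instability after TKA is common, yet implant kinematics
of stable and unstable knees during daily activities often look remarkably
similar. Detecting what *does* differ requires a fairly long analysis chain:
implant-pose–derived tibiofemoral kinematics (Grood–Suntay angles, condylar
anterior–posterior translations), gait-cycle normalization, surface-EMG
envelope processing, muscle-synergy extraction by non-negative matrix
factorization (NMF), functional classification of synergies by k-means,
activation-timing statistics (full width at half maximum, circular centre of
activity), and group statistics including permutation-based one-dimensional
statistical parametric mapping (SPM) over whole gait curves.

synergait implements that chain end to end for researchers in
musculoskeletal biomechanics and motor control, in tidyverse style: data
frames in, tibbles out, `tidy()`/`glance()` methods for fitted objects, and
`autoplot()` for each result type. Because raw fluoroscopy/EMG cohorts are
rarely redistributable, the package also ships a synthetic cohort generator
with known ground truth, so the whole pipeline is testable and its
operating characteristics (rank recovery, effect detection, type-I error)
are measurable.

## The core methods

* **Kinematics.** The femoral-to-tibial rotation R is decomposed as the
  Cardan x–y′–z″ equivalent of the Grood–Suntay joint coordinate system:
  flexion α about the femoral medio-lateral axis, ab/adduction β about the
  floating axis, internal rotation γ about the tibial longitudinal axis.
  Each condyle is tracked as the weighted mean of its 10 points nearest the
  tibial plateau plane (weights ∝ 1/(|d|+ε)); cycles are resampled to 101
  points and ranges of motion split at toe-off.
* **EMG.** 4th-order Butterworth high-pass 50 Hz → full-wave rectification →
  4th-order low-pass 20 Hz (zero-phase), amplitude normalized to the
  subject-activity maximum, time normalized to 100 stance + 100 swing
  points.
* **Synergies.** V ≈ W·H by multiplicative-update NMF (Frobenius objective,
  ≥10 restarts); per-subject rank = smallest k with R² ≥ 0.90; group rank
  imposed as the rounded mean of per-group mean ranks; k-means
  classification with per-cluster subject uniqueness; FWHM = samples above
  half maximum after minimum subtraction; CoA = circular mean angle with
  θ_t = 360°(t−1)/200.
* **Statistics.** Pooled two-sample t with Cohen's d and Bonferroni
  correction, Pearson chi-squared (no continuity correction) for 2×2
  tables, one-way ANOVA, and max-statistic permutation SPM with
  family-wise error control over the 101-point domain.

Design rationale and every numerical choice are documented in
`vignettes/synergait-methods.Rmd`.

## Worked example

Simulate a small two-group stair-descent study in which the "unstable"
cohort has a planted 1.75× widening of the flexor activation pattern, then
run the full pipeline:

```r
library(synergait)
library(dplyr)

study <- bind_rows(
  simulate_cohort(cohort_spec("stable", 4, 3, "stair", seed = 1)),
  simulate_cohort(cohort_spec("unstable", 4, 3, "stair", seed = 2),
                  truth = ground_truth_synergies("stair", flexor_widening = 1.75))
)
res <- run_pipeline(study, default_config(n_perm = 300), seed = 3)
res
#> <synergait_results> 8 subjects, imposed rank 3, 18 comparisons (seed 3)

glance(res$synergies$synergies$synergy[[1]])
#> # A tibble: 1 × 6
#>       k r_squared   sse n_cycles iterations  seed
#>   <int>     <dbl> <dbl>    <dbl>      <int> <dbl>
#> 1     3     0.976  6.27        3        380    21

sapply(res$synergies$classified, classifiable_ratio)
#>   stable unstable
#>        1        1

res$stats$report |> filter(metric == "fwhm") |>
  select(comparison, estimate, p_value, p_adjusted, cohens_d)
#>                comparison estimate  p_value p_adjusted cohens_d
#> 1 fwhm_dorsi_knee_flexors    -12.8 0.000026   0.000104   -8.132
#> 2     fwhm_knee_extensors      1.5 0.428692   1.000000    0.600
#> 3     fwhm_plantarflexors     -0.5 0.467994   1.000000   -0.548
```

Reading the output: every subject's EMG factorizes at rank 3 with R² ≈ 0.98
(three fundamental stair-descent synergies), both groups classify fully, and
the flexor-synergy FWHM is ~13 cycle points wider in the unstable group — the
planted prolonged flexor activation — surviving Bonferroni correction
(p_adj ≈ 1e-4), while extensor and plantarflexor widths do not differ. The
kinematic side of the same run yields per-phase RoM tables and SPM cluster
results:

```r
res$kinematics$rom |> filter(parameter == "flexion", phase == "stance") |>
  group_by(group) |> summarise(mean_rom = mean(rom))
#> # A tibble: 2 × 2
#>   group    mean_rom
#>   <chr>       <dbl>
#> 1 stable       87.5
#> 2 unstable     82.6
```

A thin CLI (`exec/synergait`) wraps the same functions as `simulate` and
`pipeline` subcommands for shell use.

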