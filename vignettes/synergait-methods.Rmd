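---
title: "Methods: kinematics, muscle synergies and group statistics in synergait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinematics, muscle synergies and group statistics in synergait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synergait)
```

## Scope and model

synergait implements a complete analysis chain for comparing *stable* and
*self-reported unstable* total knee arthroplasty (TKA) knees during gait
activities (level walking, downhill walking, stair descent), from two data
streams:

1. **Implant kinematics** — per-frame rigid transforms of the femoral
   component expressed in the tibial component frame (e.g. from moving
   video-fluoroscopy at 30 Hz), together with condyle point clouds and a
   tibial plateau plane;
2. **Surface EMG** — eight muscles of the implanted limb (RF, VM, VL, TA,
   HM, HL, GM, GL) sampled at force-plate rates (≥ 1 kHz).

Because raw subject data of this kind are not redistributable, the package
ships a synthetic cohort generator with known ground truth; every processing
stage is validated against that ground truth.

## Joint kinematics

**Angles.** The femoral-to-tibial rotation is decomposed in the
Grood–Suntay joint coordinate system: flexion about the femoral
medio-lateral axis, internal/external rotation about the tibial longitudinal
axis, and ab/adduction about the mutually perpendicular floating axis. This
fixed–floating–fixed construction is computed as the equivalent Cardan
x–y′–z″ sequence. Signs are fixed and documented: flexion, adduction and
internal rotation positive. `gs_decompose()` reports gimbal proximity
(|ab/adduction| → 90°) as an explicit error; over the physiological domain
(flexion −10°…130°, ab/adduction ±15°, rotation ±30°) the
decompose∘compose round trip is exact to < 1e-9°, which the test suite
verifies over 10,000 random triples.

**Condylar A-P translation.** Each femoral condyle is tracked as the
weighted mean location of its 10 points nearest the tibial plateau plane.
"Nearest" is the smallest *signed* distance along the plane normal, so
penetration counts as contact. The weighting kernel is not dictated by any
convention we know of, so the package fixes and documents one:
$w_i \propto 1/(|d_i| + \varepsilon)$ with $\varepsilon$ = 0.1 mm,
renormalized to sum to one. Closest points dominate, zero distance is
well-defined, and equal distances reduce to the plain mean. The absolute
value keeps weights positive under penetration. Both the kernel and
$\varepsilon$ are arguments of `condylar_ap()` so the choice can be swapped.

**Cycle normalization and RoM.** Cycles (heel-strike to heel-strike) are
linearly resampled to 101 points; condylar tracks are referenced to the
medial condyle position at the initial heel-strike (medial point 1 is
exactly 0 mm). Ranges of motion (max − min) are reported per phase, with
the toe-off sample included in both stance and swing — the two phases share
the toe-off instant, and excluding it from either would make per-phase
ranges depend on an arbitrary ownership convention. The intercondylar A-P
difference (lateral RoM − medial RoM) summarizes the transverse-plane pivot
pattern; it is the only "RoM" row that may be negative.

**Heel-strike** is the first upward crossing of a 25 N vertical-force
threshold; a trace that never crosses returns an explicit no-event value
(`NA`).

## EMG processing

The envelope chain is: 4th-order Butterworth high-pass at 50 Hz → full-wave
rectification → 4th-order Butterworth low-pass at 20 Hz. Filters are applied
zero-phase (forward–backward) by default: a causal chain would delay every
envelope by a channel-independent lag and bias the centre-of-activity
statistic. Two passes double the effective order; we keep the cut-offs at
their nominal printed values and record the convention rather than debating
analog equivalences. A `zero_phase = FALSE` flag restores single-pass
causal filtering. Envelopes are clipped at zero.

Amplitude is normalized per channel to the maximum over *all cycles of one
subject-activity*, so every channel attains 1 somewhere in that
subject-activity; an all-zero channel yields zeros plus a warning rather
than NaN. Time is normalized to 200 points — 100 stance, 100 swing — making
profiles comparable independently of absolute phase durations. Linear
interpolation is the default; a natural spline sits behind a flag.

## Muscle synergies

**Extraction.** Per subject-activity, the normalized cycles are concatenated
into an 8 × (200·cycles) matrix V and factorized as V ≈ W H by non-negative
matrix factorization with multiplicative updates (Frobenius objective,
implemented in C++). Defaults: 10 random restarts keeping the best SSE,
convergence when the relative SSE improvement over a 20-iteration window
drops below 1e-6, cap 1000 iterations. Module columns are scaled to unit
maximum with compensating row scaling of H. Reconstruction quality is
$R^2 = 1 - \mathrm{SSE}/\mathrm{SS_{tot}}$ against V. The objective is
provably non-increasing under multiplicative updates, and the test suite
asserts this on traced runs.

**Model order.** The per-subject rank is the smallest k whose $R^2$ reaches
0.90 (configurable). This threshold rule is a package contract, not a
reconstruction of any published criterion: with the generator's planted
four-synergy structure it recovers k = 4 essentially always, and it is
consistent with mean extracted ranks of ≈ 3.2–3.7 on 8 muscles reported for
this kind of cohort. The *imposed group rank* per activity is the mean of
the per-group mean ranks, rounded half away from zero — reproducing the
published rule of 4 synergies for level/downhill walking and 3 for stair
descent from the printed group means.

**Classification.** All synergies of a group-activity are pooled and
clustered with k-means (k = imposed rank, 50 restarts, seeded). The feature
vector — unit-norm module (8 values) concatenated with the unit-norm
activation pattern downsampled to 20 bin means — is likewise a documented
contract: it balances muscle-weighting and timing information at comparable
scale. Within a cluster, a subject may keep only its member closest to the
centroid; surplus members are flagged unclassified, and the classifiable
ratio is classified/total. Clusters are labelled by the functional muscle
group with the largest summed centroid weight (knee extensors RF+VM+VL,
plantarflexors GM+GL, dorsiflexors TA, knee flexors HM+HL), assigned
greedily so labels are unique; for three clusters (stair descent) the
dorsiflexors and knee flexors merge into one co-activated label.

**Timing statistics.** FWHM subtracts the pattern minimum and counts samples
strictly above half the resulting maximum — integer-valued on the 200-point
grid, invariant to positive affine transforms; interpolated threshold
crossings were rejected to keep widths commensurable across patterns. Widths
are reported in cycle points with `fwhm_to_pct()` as converter, since the
unit convention of published tables is ambiguous. CoA is the circular mean
angle of the pattern laid on the 0–360° cycle, with sample t at
$\theta_t = 360°,(t-1)/200$ — touchdown at 0°, so toe-off (point 101) maps
to 180°. A half-sample offset convention would shift every CoA by 0.9°,
well below between-subject variability.

## Group statistics

* **Pooled t-test** (not Welch), df = n1+n2−2, with Cohen's d on the pooled
  SD. Evidence-based choice: the published Oxford-Knee-Score comparison
  (46.0 ± 2.0, n = 10 vs 42.9 ± 3.8, n = 8 → p = 0.040) is reproduced by
  the pooled form and not by Welch (p = 0.063). Accepts summary statistics
  as well as raw samples.
* **Chi-squared** for 2×2 tables without continuity correction — required to
  reproduce the published p = 0.168 (sex ratio) and p = 0.019 (laxity
  tests) from their counts. Zero marginals are an explicit error.
* **One-way ANOVA** (classic F) on synergy module weights; for two groups F
  equals the squared pooled t, asserted to 1e-12.
* **Bonferroni**: `p_adjusted = min(1, m p)`. Family sizes are configurable
  (`default_config()`): per activity, the three translation RoM rows form
  one family and the three rotation RoM rows another; FWHM and CoA are
  corrected within metric across the classified labels. Published analyses
  state the correction but not the family sizes, so these are package
  defaults, logged with every run.
* **1D SPM by permutation.** The pointwise pooled-t trajectory over the
  101-point cycle is thresholded at the (1−α) quantile of the
  max-|t| permutation null (complete enumeration when the number of
  relabelings fits the permutation budget, otherwise a seeded Monte-Carlo
  subset; p-values carry the +1 correction). This max-statistic scheme
  delivers the same family-wise inference contract as random-field-theory
  SPM without its smoothness constants; RFT is left as an extension hook.
  Degenerate pointwise variance is handled by a documented ridge (1e-10 of
  the largest pooled variance, floored at 1e-12). Calibration: over 1000
  null simulations at α = 0.05 the empirical family-wise error is ≈ 0.05
  (the acceptance script recomputes it).

Cycles are averaged per subject before any between-group test — subjects,
not cycles, are the exchangeable units; a mixed-effects treatment of
repeated cycles is out of scope and documented as such.

## The synthetic cohort generator

The generator is first-class, tested code; its defaults *are* the study
conditions.

**Kinematics.** Angle and medial-A-P templates are piecewise smoothstep
curves (C1 monotone cubics with zero slope at control nodes) through
heel-strike, mid-stance, toe-off, mid-swing and terminal heel-strike control
points. Because extrema occur exactly at the nodes, the planted per-phase
ranges of motion are exact by construction. Per-subject control values are
drawn from normal distributions centred on the published group statistics
(e.g. stable level-walking stance flexion RoM 47.2 ± 4.9°; stance medial
A-P RoM 5.4 ± 1.4 mm); per-cycle jitter multiplies the drawn RoMs by
1 + N(0, 0.02) — the source tables publish no within-subject variance, so
2% is the package's one-time choice of a realistic cycle-to-cycle CV.
Toe-off defaults to 60% of the cycle (level/downhill) and 65% (stair);
published figures mark toe-off only graphically, so these are package
defaults. Gait cycle durations are 1.10/1.15/1.40 s for
level/downhill/stair at 30 Hz.

The condyle geometry is synthetic: two spherical caps (radius 20 mm) centred
at ±22 mm on the femoral flexion axis, so flexion spins each condyle in
place, and a tibial plane with anterior axis +y. The medial condylar A-P
target is realized *exactly* by solving the pose's A-P translation per frame
(the condylar estimator is affine in that translation with unit slope); the
lateral track then emerges from axial rotation and geometry — the
intercondylar difference is an outcome, as in vivo, not an input. For
acute-instability events (posterior-then-anterior excursion confined to the
55–80% window) on a single condyle, a per-frame axial-rotation correction is
solved by root finding so the unaffected condyle's track is preserved. The
stored ground truth is always the forward-evaluated realized curve, so
recovery tests compare exactly.

**EMG.** Planted synergies follow the fundamental gait pattern: early-stance
knee-extensor burst, stance plantarflexor burst, bimodal dorsiflexor
activation, late-swing knee-flexor burst (merged dorsi/knee-flexor synergy
for stair descent, k = 3). Pattern centres and widths were chosen once to
be temporally separated enough that the planted rank is genuinely
identifiable (the best rank-3 approximation of the noiseless k = 4
envelopes leaves ≈ 15% of the variance unexplained) while matching reported
activation timings and widths (planted flexor FWHM ≈ 21 points; the
`flexor_widening` parameter scales the width, e.g. ×1.75 → ≈ 35 points, to
plant the prolonged flexor activation reported in unstable knees). The raw
signal is the envelope multiplied by a zero-mean band-limited (50–450 Hz)
Gaussian carrier plus additive white noise at 5% of the peak envelope —
chosen precisely because the package's filter chain provably recovers the
envelope of such a signal. Per-subject module perturbations (SD 0.03) and
per-cycle log-normal amplitude jitter (CV 0.05) provide realistic
between-subject and between-cycle variability.

**Force.** A double-hump stance profile scaled by body weight (750 N
default), zero in swing, with a quiet lead-in. The stored heel-strike is
defined as the first sample at which the noise-free profile reaches 25 N,
so noise-free detection is exact and 5 N sensor noise moves the event by a
few samples at 2000 Hz — far below one fluoroscopy frame.

**Seeding.** One master seed per cohort; per-subject and per-cycle streams
derive from it by fixed offsets, so adding a subject never perturbs
existing trials, and identical (spec, seed) pairs are bit-identical.

## What the synthetic data do and do not show

The generator emulates the *structure* of the measurement chain: planted
low-rank EMG with known modules, kinematic curves with known phase RoMs,
events recoverable from force. It does not emulate waveform fidelity of real
gait curves, soft-tissue artefact, electrode crosstalk between adjacent
muscles, fatigue drift, or subject-specific implant geometry. Passing the
recovery suites therefore demonstrates that the pipeline is correct and
well-calibrated — not that it would extract these exact synergies from any
particular clinical cohort.

## Problem sizes and numerical choices

The validation suites use: 20 runs × 10 subjects × 4 cycles for synergy
recovery; 1000 null simulations × 200 permutations for SPM calibration;
10 + 8 subjects × 3 cycles for the end-to-end planted-effect and null runs.
These sizes give stable Monte-Carlo estimates (e.g. ±0.014 at 2 SE for the
type-I rate) at desk-scale runtimes. Numerical guards: NMF divisions carry a
1e-12 floor; the SPM variance ridge is described above; `uniroot` tolerances
for event realization are 1e-8; all angle work is in degrees, translations
in mm, time in % cycle.

## Known limitations

* The lateral condylar track is emergent; its RoM distribution is close to
  but not calibrated against the published lateral statistics.
* Rank selection by an $R^2$ threshold and the k-means feature space are
  documented contracts; other defensible choices exist and are swappable
  via configuration.
* Cycles are averaged per subject before testing; repeated-cycle random
  effects are not modelled.
* FWHM is reported in points of the 200-point grid; convert with
  `fwhm_to_pct()` when comparing against %-cycle conventions.
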