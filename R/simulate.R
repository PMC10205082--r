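#' Specify a synthetic cohort
#'
#' Describes one simulated group-activity cohort: group label, number of
#' subjects, cycles per subject (3-5 valid cycles per activity is typical of
#' fluoroscopy studies), activity, and the master seed. All downstream
#' generator randomness derives from the master seed through fixed
#' per-subject/per-cycle offsets, so adding a subject never perturbs the
#' trials of existing ones.
#'
#' @param group `"stable"` or `"unstable"`.
#' @param n_subjects Number of subjects (>= 1).
#' @param cycles_per_subject Cycles per subject (>= 1; 3-5 typical).
#' @param activity `"level"`, `"downhill"` or `"stair"`.
#' @param seed Integer master seed.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(group = c("stable", "unstable"), n_subjects,
                        cycles_per_subject = 4,
                        activity = c("level", "downhill", "stair"), seed) {
  group <- match.arg(group)
  activity <- match.arg(activity)
  vals <- c(n_subjects, cycles_per_subject, seed)
  if (any(!is.finite(vals)) || n_subjects < 1 || cycles_per_subject < 1) {
    stop_synergait("spec fields must be finite; n_subjects >= 1 and cycles_per_subject >= 1",
                   "synergait_spec_error")
  }
  structure(list(group = group, n_subjects = as.integer(n_subjects),
                 cycles_per_subject = as.integer(cycles_per_subject),
                 activity = activity, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Specify an acute instability event
#'
#' Parameterizes the kinematic signature of an acute instability episode: an
#' early, rapid condylar posterior translation followed by an additional
#' anterior translation in the early/mid-swing phase, superposed on the
#' normal condylar A-P track within the 55-80% cycle window.
#'
#' @param onset_pct Cycle percentage of the posterior peak (clamped to 56-78).
#' @param posterior_amplitude_mm,anterior_amplitude_mm Excursion amplitudes
#'   in mm (>= 0).
#' @param affected_condyles `"medial"`, `"lateral"` or `"both"`.
#' @return An `instability_event` object.
#' @export
instability_event <- function(onset_pct = 62, posterior_amplitude_mm = 4,
                              anterior_amplitude_mm = 4,
                              affected_condyles = c("medial", "lateral", "both")) {
  affected_condyles <- match.arg(affected_condyles)
  if (!is.finite(onset_pct) || onset_pct < 0 || onset_pct > 100 ||
      posterior_amplitude_mm < 0 || anterior_amplitude_mm < 0) {
    stop_synergait("onset_pct must lie in [0, 100] and amplitudes must be >= 0",
                   "synergait_spec_error")
  }
  structure(list(onset_pct = min(max(onset_pct, 56), 78),
                 posterior_amplitude_mm = posterior_amplitude_mm,
                 anterior_amplitude_mm = anterior_amplitude_mm,
                 affected_condyles = affected_condyles),
            class = "instability_event")
}

# Published per-group kinematic range-of-motion statistics (degrees / mm):
# stance and swing RoM means and between-subject SDs per activity for
# flexion/extension, internal/external rotation, ab/adduction, and the medial
# condylar A-P translation. These are the generator's population parameters.
activity_params <- function(activity, group) {
  p <- list(
    level = list(
      stable   = list(flex = c(47.2, 4.9, 61.8, 4.4), int = c(7.7, 1.1, 6.9, 1.8),
                      abad = c(2.1, 0.2, 2.8, 0.5), med_ap = c(5.4, 1.4, 7.0, 2.5)),
      unstable = list(flex = c(43.5, 6.8, 59.6, 8.0), int = c(7.0, 1.8, 7.8, 2.5),
                      abad = c(2.1, 0.3, 2.7, 0.7), med_ap = c(4.5, 0.9, 6.2, 1.6))
    ),
    downhill = list(
      stable   = list(flex = c(57.9, 3.8, 68.6, 4.6), int = c(5.5, 0.9, 7.0, 1.3),
                      abad = c(2.2, 0.3, 2.5, 0.4), med_ap = c(4.2, 0.9, 5.7, 1.5)),
      unstable = list(flex = c(54.9, 4.3, 67.4, 6.7), int = c(6.1, 1.2, 8.2, 1.8),
                      abad = c(2.8, 0.3, 2.8, 0.7), med_ap = c(3.4, 1.0, 5.5, 1.5))
    ),
    stair = list(
      stable   = list(flex = c(84.4, 3.4, 91.2, 4.5), int = c(8.7, 1.2, 9.4, 1.9),
                      abad = c(3.5, 0.5, 2.8, 0.6), med_ap = c(5.1, 1.6, 7.7, 1.7)),
      unstable = list(flex = c(84.5, 11.7, 92.8, 5.8), int = c(8.4, 1.0, 10.3, 2.6),
                      abad = c(3.3, 0.4, 3.1, 0.9), med_ap = c(4.6, 1.2, 6.9, 1.7))
    )
  )
  p[[activity]][[group]]
}

activity_defaults <- function(activity) {
  switch(activity,
    level = list(toe_off_pct = 60, duration = 1.10),
    downhill = list(toe_off_pct = 60, duration = 1.15),
    stair = list(toe_off_pct = 65, duration = 1.40)
  )
}

#' Default synthetic condyle geometry
#'
#' Two spherical-cap condyle point clouds (radius 20 mm, centres at
#' x = +22 mm medial and x = -22 mm lateral on the femoral flexion axis, so
#' that flexion spins each condyle in place) plus a tibial plateau plane at
#' z = 0 with anterior A-P axis +y. Only the distal band of each sphere is
#' kept so that near-plane points exist at every flexion angle.
#'
#' @param n_points Points per condyle before band selection.
#' @param radius Condyle radius (mm).
#' @param offset Medio-lateral condyle offset (mm).
#' @return A `condyle_geometry`.
#' @export
default_condyle_geometry <- function(n_points = 400, radius = 20, offset = 22) {
  pts <- fibonacci_sphere(n_points) * radius
  band <- pts[pts[, 3] <= -0.25 * radius, , drop = FALSE]
  condyle_geometry(
    medial_points = sweep(band, 2, c(offset, 0, 0), "+"),
    lateral_points = sweep(band, 2, c(-offset, 0, 0), "+")
  )
}

fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Piecewise smoothstep interpolator: a C1 monotone cubic between each pair of
# consecutive control points with zero tangents at the nodes, so curve
# extrema coincide exactly with control-point values (no spline overshoot).
smooth_through <- function(x, y) {
  force(x); force(y)
  function(p) {
    i <- pmin(pmax(findInterval(p, x), 1), length(x) - 1)
    u <- (p - x[i]) / (x[i + 1] - x[i])
    u <- pmin(pmax(u, 0), 1)
    y[i] + (y[i + 1] - y[i]) * (3 * u^2 - 2 * u^3)
  }
}

# Activity template: control points at heel-strike, mid-stance, toe-off,
# mid-swing and terminal heel-strike; phase ranges of motion equal the drawn
# control values exactly by construction.
make_templates <- function(par, toe_off_pct, f0 = 5) {
  to <- toe_off_pct
  mono <- smooth_through
  sr <- par$flex[1]; swr <- par$flex[3]
  flex <- mono(c(0, to / 2, to, (to + 100) / 2, 100),
               c(f0, f0 + 0.35 * sr, f0 + sr, f0 + swr, f0))
  ast <- par$abad[1]; asw <- par$abad[3]
  abad <- mono(c(0, to / 2, to, 100), c(0, 0.45 * ast, ast, ast - asw))
  ist <- par$int[1]; isw <- par$int[3]
  int <- mono(c(0, to / 2, to, 100), c(0, -0.45 * ist, -ist, -ist + isw))
  mst <- par$med_ap[1]; msw <- par$med_ap[3]
  med <- mono(c(0, to / 2, to, to + 0.6 * (100 - to), 100),
              c(0, 0.45 * mst, mst, mst - msw, 0))
  list(flexion = flex, adduction = abad, internal_rotation = int, medial_ap = med)
}

# Instability excursion as a function of cycle %, zero outside [55, 80].
event_excursion <- function(event, pct) {
  on <- event$onset_pct
  mid <- (on + 80) / 2
  f <- smooth_through(c(55, on, mid, 80),
                      c(0, -event$posterior_amplitude_mm,
                        event$anterior_amplitude_mm, 0))
  ifelse(pct > 55 & pct < 80, f(pct), 0)
}

#' Generate synthetic tibiofemoral kinematics for a cohort
#'
#' Builds per-trial pose series (femoral component relative to tibial
#' component), condyle geometry, gait events, and the ground-truth kinematic
#' curves they encode. Joint-angle templates are shape-preserving splines
#' through heel-strike / mid-stance / toe-off / mid-swing control points whose
#' phase ranges of motion are drawn per subject from normal distributions
#' centred on the published group statistics (see [activity_params()] values
#' embedded in the generator). The medial condylar A-P target track is
#' realized exactly by solving the pose's A-P translation per frame (the
#' condylar A-P estimator is affine in it); the lateral track then follows
#' from axial rotation and the condyle geometry, so the intercondylar
#' difference is an emergent outcome, as in vivo. When an
#' [instability_event()] is given, its posterior-then-anterior excursion is
#' superposed inside the 55-80% cycle window; for a single-condyle event a
#' small axial-rotation correction is solved per frame so the other condyle's
#' track is preserved.
#'
#' @param spec A [cohort_spec()].
#' @param event Optional [instability_event()].
#' @param subject_scale Multiplier on the published between-subject SDs
#'   (0 gives every subject the template means).
#' @param cycle_cv Coefficient of variation of cycle-to-cycle RoM jitter
#'   (0 disables within-subject variability).
#' @param rate Fluoroscopic frame rate in Hz (default 30).
#' @return A tibble with one row per trial: `subject`, `group`, `activity`,
#'   `cycle`, and list-columns `pose` (frame, time, r11..r33, tx, ty, tz),
#'   `events` (frame indices), `geometry`, and `truth` (per-frame ground-truth
#'   angle and A-P curves with `cycle_pct`).
#' @export
generate_kinematics <- function(spec, event = NULL, subject_scale = 1,
                                cycle_cv = 0.02, rate = 30) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(event)) stopifnot(inherits(event, "instability_event"))
  if (!is.finite(subject_scale) || !is.finite(cycle_cv)) {
    stop_synergait("noise controls must be finite", "synergait_spec_error")
  }
  par0 <- activity_params(spec$activity, spec$group)
  defs <- activity_defaults(spec$activity)
  geometry <- default_condyle_geometry()

  purrr::map_dfr(seq_len(spec$n_subjects), function(subj) {
    set.seed(spec$seed + 1000L * subj)
    subj_par <- lapply(par0, function(v) {
      c(max(0.5, v[1] + subject_scale * v[2] * rnorm(1)), v[2],
        max(0.5, v[3] + subject_scale * v[4] * rnorm(1)), v[4])
    })
    # swing flexion range must exceed stance range for a valid template
    subj_par$flex[3] <- max(subj_par$flex[3], subj_par$flex[1] + 1)
    subj_par$med_ap[3] <- max(subj_par$med_ap[3], subj_par$med_ap[1] + 0.1)
    f0 <- 5 + subject_scale * 1.5 * rnorm(1)

    purrr::map_dfr(seq_len(spec$cycles_per_subject), function(cy) {
      set.seed(spec$seed + 1000L * subj + cy)
      cyc_par <- lapply(subj_par, function(v) {
        c(v[1] * (1 + cycle_cv * rnorm(1)), v[2],
          v[3] * (1 + cycle_cv * rnorm(1)), v[4])
      })
      cyc_par$flex[3] <- max(cyc_par$flex[3], cyc_par$flex[1] + 1)
      cyc_par$med_ap[3] <- max(cyc_par$med_ap[3], cyc_par$med_ap[1] + 0.1)
      duration <- max(0.6, defs$duration * (1 + cycle_cv * rnorm(1)))
      n_frames <- as.integer(round(duration * rate)) + 1L
      to_frame <- 1L + as.integer(round(defs$toe_off_pct / 100 * (n_frames - 1)))
      pct <- seq(0, 100, length.out = n_frames)
      to_pct <- pct[to_frame]
      tmpl <- make_templates(cyc_par, to_pct, f0 = f0)

      trial <- realize_trial(tmpl, pct, geometry, event)
      pose <- trial$pose
      pose$frame <- seq_len(n_frames)
      pose$time <- (pose$frame - 1) / rate
      truth <- trial$truth
      truth$cycle_pct <- pct
      tibble::tibble(
        subject = sprintf("%s%02d", substr(spec$group, 1, 1), subj),
        group = spec$group, activity = spec$activity, cycle = cy,
        pose = list(pose[c("frame", "time", "r11", "r12", "r13", "r21", "r22",
                           "r23", "r31", "r32", "r33", "tx", "ty", "tz")]),
        events = list(list(heel_strike_1 = 1L, toe_off = to_frame,
                           heel_strike_2 = n_frames)),
        geometry = list(geometry),
        truth = list(tibble::as_tibble(truth))
      )
    })
  })
}

# Turn template curves into poses whose condylar A-P tracks realize the
# targets, and record the forward-evaluated ground truth.
realize_trial <- function(tmpl, pct, geometry, event, tz0 = 21) {
  n <- length(pct)
  flex <- tmpl$flexion(pct)
  abad <- tmpl$adduction(pct)
  int <- tmpl$internal_rotation(pct)
  med_t <- tmpl$medial_ap(pct)
  exc <- if (is.null(event)) rep(0, n) else event_excursion(event, pct)

  c_fun <- function(gamma_deg, i) {
    R <- gs_compose(flex[i], abad[i], gamma_deg)
    T <- make_transform(R, c(0, 0, tz0))
    c(condyle_ap_one(T, geometry$medial_points, geometry$tibial_plane, 10, 0.1),
      condyle_ap_one(T, geometry$lateral_points, geometry$tibial_plane, 10, 0.1))
  }

  out <- matrix(0, n, 12)  # r11..r33, tx, ty, tz
  med <- lat <- gamma <- numeric(n)
  for (i in seq_len(n)) {
    cc <- c_fun(int[i], i)
    ty0 <- med_t[i] - cc[1]
    med0 <- med_t[i]
    lat0 <- ty0 + cc[2]
    g <- int[i]; ty <- ty0
    if (exc[i] != 0 && !is.null(event)) {
      if (event$affected_condyles == "both") {
        ty <- ty0 + exc[i]
        med0 <- med0 + exc[i]; lat0 <- lat0 + exc[i]
      } else {
        # solve the axial rotation so only the affected condyle moves
        target_sep <- if (event$affected_condyles == "medial") {
          (med_t[i] + exc[i]) - lat0
        } else {
          med_t[i] - (lat0 + exc[i])
        }
        fr <- function(gd) { v <- c_fun(gd, i); v[1] - v[2] - target_sep }
        root <- tryCatch(
          stats::uniroot(fr, interval = int[i] + c(-35, 35), tol = 1e-8)$root,
          error = function(e) int[i]
        )
        g <- root
        v <- c_fun(g, i)
        if (event$affected_condyles == "medial") {
          ty <- lat0 - v[2]
          med0 <- med_t[i] + exc[i]
        } else {
          ty <- med_t[i] - v[1]
          lat0 <- lat0 + exc[i]
        }
      }
    }
    R <- gs_compose(flex[i], abad[i], g)
    out[i, ] <- c(t(R), 0, ty, tz0)
    # forward-evaluate the realized tracks (stored ground truth is exact)
    T <- make_transform(R, c(0, ty, tz0))
    ap <- condylar_ap(T, geometry)
    med[i] <- ap$medial_ap; lat[i] <- ap$lateral_ap
    gamma[i] <- g
  }
  pose <- as.data.frame(out)
  names(pose) <- c("r11", "r12", "r13", "r21", "r22", "r23", "r31", "r32",
                   "r33", "tx", "ty", "tz")
  list(
    pose = pose,
    truth = data.frame(flexion = flex, adduction = abad,
                       internal_rotation = gamma,
                       medial_ap = med, lateral_ap = lat)
  )
}

#' Generate a synthetic vertical ground-reaction force trace
#'
#' Produces a double-hump stance-phase force profile scaled by body weight,
#' zero during swing, preceded by a quiet lead-in, sampled at the force-plate
#' rate. The stored ground-truth heel-strike is the first sample at which the
#' noise-free profile reaches the 25 N detection threshold, so noise-free
#' detection recovers it exactly and realistic sensor noise moves it by far
#' less than one fluoroscopy frame.
#'
#' @param duration Cycle duration in seconds.
#' @param toe_off_frac Toe-off as a fraction of the cycle.
#' @param body_weight Body weight in newtons.
#' @param rate Sampling rate in Hz (default 2000).
#' @param noise_sd Additive sensor noise SD in newtons.
#' @param lead Quiet lead-in before heel-strike (s).
#' @param threshold Detection threshold used to define the stored event (N).
#' @return A tibble `time`, `force` with attributes `heel_strike_sample`
#'   (ground truth) and `rate`.
#' @export
generate_force <- function(duration = 1.1, toe_off_frac = 0.6,
                           body_weight = 750, rate = 2000, noise_sd = 0,
                           lead = 0.15, threshold = 25) {
  n_lead <- round(lead * rate)
  n_stance <- round(duration * toe_off_frac * rate)
  n_swing <- round(duration * (1 - toe_off_frac) * rate) + n_lead
  s <- seq(0, 1, length.out = n_stance)
  profile <- body_weight * pmax(0, sin(pi * s) * (1 + 0.25 * cos(2 * pi * s)))
  force <- c(rep(0, n_lead), profile, rep(0, n_swing))
  hs <- n_lead + which(profile >= threshold)[1]
  if (noise_sd > 0) force <- pmax(0, force + rnorm(length(force), 0, noise_sd))
  structure(
    tibble::tibble(time = (seq_along(force) - 1) / rate, force = force),
    heel_strike_sample = as.integer(hs), rate = rate
  )
}

#' Ground-truth muscle synergies for the generator
#'
#' Default planted synergy modules and activation patterns emulating the
#' fundamental synergies of gait: a knee-extensor burst in early stance, a
#' plantarflexor burst in (late) stance, a dorsiflexor pattern with
#' early-stance and early-swing contributions, and a knee-flexor burst around
#' touchdown (merged with the dorsiflexors into one co-activated synergy for
#' stair descent, giving k = 3). Modules are non-negative with unit-maximum
#' columns; patterns are non-negative 200-point cycle profiles (100 stance +
#' 100 swing).
#'
#' @param activity `"level"`, `"downhill"` or `"stair"` (sets k = 4, 4, 3).
#' @param flexor_widening Multiplier on the flexor-pattern width, used to
#'   plant a prolonged flexor activation (e.g. in an "unstable" cohort).
#' @return A `ground_truth_synergies` list: `modules` (8 x k, unit-max
#'   columns), `patterns` (k x 200), `k`, `labels`.
#' @export
ground_truth_synergies <- function(activity = c("level", "downhill", "stair"),
                                   flexor_widening = 1) {
  activity <- match.arg(activity)
  bump <- function(center, sigma, amp = 1, n = 200) {
    d <- abs(seq_len(n) - center)
    d <- pmin(d, n - d)
    amp * exp(-0.5 * (d / sigma)^2)
  }
  mod <- function(w) { v <- setNames(rep(0.03, 8), emg_channels); v[names(w)] <- w; v / max(v) }
  if (activity %in% c("level", "downhill")) {
    labels <- c("knee_extensors", "plantarflexors", "dorsiflexors", "knee_flexors")
    W <- cbind(
      mod(c(RF = 0.8, VM = 1, VL = 0.9)),
      mod(c(GM = 1, GL = 0.85)),
      mod(c(TA = 1)),
      mod(c(HM = 1, HL = 0.85))
    )
    # early-stance extensor burst; (late-)stance plantarflexor burst;
    # bimodal dorsiflexor (early stance + early swing); knee-flexor burst in
    # late swing with a propulsion/early-swing contribution
    H <- if (activity == "level") {
      rbind(bump(18, 12),
            bump(42, 10),
            0.5 * bump(10, 8) + bump(115, 14),
            bump(192, 9 * flexor_widening) + 0.5 * bump(103, 8))
    } else {
      rbind(bump(25, 14),
            bump(45, 12),
            0.5 * bump(10, 8) + bump(110, 20),
            bump(192, 9 * flexor_widening) + 0.6 * bump(118, 10))
    }
  } else {
    labels <- c("knee_extensors", "plantarflexors", "dorsi_knee_flexors")
    W <- cbind(
      mod(c(RF = 0.8, VM = 1, VL = 0.9)),
      mod(c(GM = 1, GL = 0.85)),
      mod(c(TA = 1, HM = 0.9, HL = 0.8))
    )
    H <- rbind(bump(50, 22),
               bump(88, 12),
               bump(110, 8.5 * flexor_widening) + 0.4 * bump(5, 8 * flexor_widening))
  }
  dimnames(W) <- list(emg_channels, labels)
  rownames(H) <- labels
  structure(list(modules = W, patterns = H, k = ncol(W), labels = labels),
            class = "ground_truth_synergies")
}

#' Generate raw synthetic surface EMG for a cohort
#'
#' Builds per-trial raw 8-channel EMG at the given sampling rate. The
#' ground-truth envelope of each trial is `modules %*% patterns` (with small
#' per-subject module perturbations and per-cycle amplitude jitter) mapped
#' onto the trial's real-time axis: stance pattern points cover the stance
#' interval and swing points the swing interval. The raw signal is the
#' envelope multiplied by a zero-mean band-limited (50-450 Hz) Gaussian
#' carrier, plus additive white noise at `noise` times the peak envelope;
#' this construction guarantees that the standard filter chain provably
#' recovers the envelope.
#'
#' @param spec A [cohort_spec()].
#' @param truth A [ground_truth_synergies()] (8 modules rows in the fixed
#'   channel order); defaults to the activity's default truth.
#' @param noise Additive noise level relative to the peak envelope
#'   (default 0.05).
#' @param rate EMG sampling rate in Hz (default 2000).
#' @param module_sd SD of per-subject module-weight perturbations.
#' @param amp_cv Per-cycle, per-synergy amplitude jitter CV.
#' @param trials Optional tibble of trial timing (columns `subject`, `cycle`,
#'   `duration`, `toe_off_frac`), e.g. derived from [generate_kinematics()]
#'   output; defaults to the activity's nominal timing.
#' @return A tibble with one row per trial: `subject`, `group`, `activity`,
#'   `cycle`, list-columns `emg` (tibble `time`, RF..GL), `emg_events`
#'   (sample indices), `truth_envelope` (8 x 200), `subject_modules` (8 x k).
#' @export
generate_emg <- function(spec, truth = ground_truth_synergies(spec$activity),
                         noise = 0.05, rate = 2000, module_sd = 0.03,
                         amp_cv = 0.05, trials = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (any(truth$modules < 0) || any(truth$patterns < 0)) {
    stop_synergait("ground-truth modules and patterns must be non-negative",
                   "synergait_spec_error")
  }
  if (nrow(truth$modules) != 8) {
    stop_synergait("truth$modules must have 8 rows in the fixed channel order",
                   "synergait_spec_error")
  }
  defs <- activity_defaults(spec$activity)
  k <- truth$k
  purrr::map_dfr(seq_len(spec$n_subjects), function(subj) {
    set.seed(spec$seed + 1000L * subj + 500000L)
    W_s <- truth$modules + matrix(rnorm(8 * k, 0, module_sd), 8, k)
    W_s <- pmax(W_s, 0)
    cmax <- apply(W_s, 2, max); cmax[cmax == 0] <- 1
    W_s <- sweep(W_s, 2, cmax, "/")
    subject <- sprintf("%s%02d", substr(spec$group, 1, 1), subj)

    purrr::map_dfr(seq_len(spec$cycles_per_subject), function(cy) {
      set.seed(spec$seed + 1000L * subj + 500000L + cy)
      if (!is.null(trials)) {
        tr <- trials[trials$subject == subject & trials$cycle == cy, ]
        duration <- tr$duration[1]; to_frac <- tr$toe_off_frac[1]
      } else {
        duration <- defs$duration; to_frac <- defs$toe_off_pct / 100
      }
      amp <- if (amp_cv > 0) exp(rnorm(k, 0, amp_cv)) else rep(1, k)
      env200 <- W_s %*% (truth$patterns * amp)
      n_samp <- round(duration * rate) + 1
      t_to <- duration * to_frac
      time <- (seq_len(n_samp) - 1) / rate
      to_samp <- round(t_to * rate) + 1
      # map the 100+100 normalized grid onto the trial's real-time axis
      t_nodes <- c(seq(0, time[to_samp], length.out = 100),
                   seq(time[to_samp], duration, length.out = 101)[-1])
      E <- t(apply(env200, 1, function(p) approx(t_nodes, p, xout = time, rule = 2)$y))
      peak <- max(E)
      raw <- E * band_carrier(n_samp, 8, rate) +
        (if (noise > 0) matrix(rnorm(8 * n_samp, 0, noise * max(peak, 1e-12)),
                               8, n_samp) else 0)
      emg_df <- tibble::as_tibble(cbind(data.frame(time = time),
                                        as.data.frame(t(raw))))
      names(emg_df) <- c("time", emg_channels)
      tibble::tibble(
        subject = subject, group = spec$group, activity = spec$activity,
        cycle = cy,
        emg = list(emg_df),
        emg_events = list(list(heel_strike_1 = 1L, toe_off = as.integer(to_samp),
                               heel_strike_2 = as.integer(n_samp))),
        truth_envelope = list(env200),
        subject_modules = list(W_s)
      )
    })
  })
}

# Zero-mean unit-variance band-limited (50-450 Hz) Gaussian carrier,
# independent per channel.
band_carrier <- function(n_samp, n_chan, rate) {
  bp <- signal::butter(4, c(50, 450) / (rate / 2), type = "pass")
  t(vapply(seq_len(n_chan), function(i) {
    x <- signal::filtfilt(bp, rnorm(n_samp + 400))[201:(n_samp + 200)]
    x / sd(x)
  }, numeric(n_samp)))
}

#' Simulate a full cohort with coherent kinematics, forces and EMG
#'
#' Convenience orchestrator: generates kinematics trials, then per-trial
#' vertical force and raw EMG sharing each trial's duration and toe-off, and
#' joins everything into one nested tibble. The ground truth (synergy
#' modules/patterns and per-trial kinematic curves) is carried alongside so
#' recovery can be scored without re-generation.
#'
#' @inheritParams generate_kinematics
#' @inheritParams generate_emg
#' @param body_weight Body weight in newtons for the force profile.
#' @param force_noise_sd Force sensor noise SD (N).
#' @return A nested tibble (one row per trial) combining the columns of
#'   [generate_kinematics()], [generate_emg()] and a `force` list-column,
#'   with attribute `ground_truth` = `truth`.
#' @export
simulate_cohort <- function(spec, truth = ground_truth_synergies(spec$activity),
                            event = NULL, subject_scale = 1, cycle_cv = 0.02,
                            noise = 0.05, module_sd = 0.03, amp_cv = 0.05,
                            body_weight = 750, force_noise_sd = 0, rate = 30,
                            emg_rate = 2000) {
  kin <- generate_kinematics(spec, event = event, subject_scale = subject_scale,
                             cycle_cv = cycle_cv, rate = rate)
  trials <- kin |>
    dplyr::mutate(
      duration = purrr::map_dbl(.data$pose, ~ max(.x$time)),
      toe_off_frac = purrr::map2_dbl(.data$events, .data$pose,
                                     ~ .y$time[.x$toe_off] / max(.y$time))
    ) |>
    dplyr::select("subject", "cycle", "duration", "toe_off_frac")
  emg <- generate_emg(spec, truth = truth, noise = noise, rate = emg_rate,
                      module_sd = module_sd, amp_cv = amp_cv, trials = trials)
  out <- dplyr::left_join(kin, dplyr::select(emg, -"group", -"activity"),
                          by = c("subject", "cycle"))
  out$force <- purrr::pmap(
    list(trials$duration, trials$toe_off_frac, seq_len(nrow(trials))),
    function(d, tf, i) {
      set.seed(spec$seed + 900000L + i)
      generate_force(d, tf, body_weight = body_weight, rate = emg_rate,
                     noise_sd = force_noise_sd)
    }
  )
  attr(out, "ground_truth") <- truth
  attr(out, "spec") <- spec
  out
}
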