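#' Time-normalize a gait cycle to 101 points
#'
#' Resamples per-frame kinematic tracks linearly in time from the first
#' heel-strike to the second heel-strike onto 101 equally spaced points
#' (0-100% cycle), records the toe-off as a percentage of the cycle, and
#' references both condylar A-P tracks to the medial condyle position at the
#' initial heel-strike (so the medial track starts at exactly 0 mm).
#'
#' @param tracks A data frame with one row per frame, containing a `frame`
#'   column plus any of `flexion`, `adduction`, `internal_rotation` (degrees)
#'   and `medial_ap`, `lateral_ap` (mm).
#' @param events A list or tibble with `heel_strike_1`, `toe_off`,
#'   `heel_strike_2` (frame indices, `heel_strike_1 < toe_off < heel_strike_2`).
#' @param n_points Number of resampled points (101 by default).
#' @return A `kinematic_cycle`: a tibble with `cycle_pct` (0..100) and the
#'   resampled tracks, with attribute `toe_off_pct`.
#' @export
time_normalize_cycle <- function(tracks, events, n_points = 101) {
  ev <- as.list(events)
  hs1 <- ev$heel_strike_1; to <- ev$toe_off; hs2 <- ev$heel_strike_2
  if (!is.finite(hs1) || !is.finite(to) || !is.finite(hs2) ||
      !(hs1 < to && to < hs2)) {
    stop_synergait("events must satisfy heel_strike_1 < toe_off < heel_strike_2",
                   "synergait_event_error")
  }
  frame <- tracks$frame %||% seq_len(nrow(tracks))
  if (any(diff(frame) <= 0)) {
    stop_synergait("frame axis must be strictly increasing", "synergait_event_error")
  }
  xout <- seq(hs1, hs2, length.out = n_points)
  value_cols <- setdiff(names(tracks), c("frame", "time"))
  out <- tibble::tibble(cycle_pct = seq(0, 100, length.out = n_points))
  for (col in value_cols) {
    out[[col]] <- approx(frame, tracks[[col]], xout = xout, rule = 2)$y
  }
  if (all(c("medial_ap", "lateral_ap") %in% value_cols)) {
    ref <- out$medial_ap[1]
    out$medial_ap <- out$medial_ap - ref
    out$lateral_ap <- out$lateral_ap - ref
  }
  toe_off_pct <- 100 * (to - hs1) / (hs2 - hs1)
  structure(out, toe_off_pct = toe_off_pct,
            class = c("kinematic_cycle", class(out)))
}

#' Range-of-motion summary of a normalized kinematic cycle
#'
#' Computes, for each kinematic parameter, the range of motion (max minus min)
#' separately over the stance and swing phases, and the intercondylar A-P
#' difference (lateral A-P RoM minus medial A-P RoM) per phase, which
#' characterizes the transverse-plane pivot pattern (negative values indicate
#' medial-pivot behaviour). The stance phase runs from the initial heel-strike
#' to toe-off and the swing phase from toe-off to the final heel-strike; the
#' toe-off sample belongs to both phases.
#'
#' @param cycle A `kinematic_cycle` from [time_normalize_cycle()], or any
#'   tibble with `cycle_pct` plus kinematic columns and a `toe_off_pct`
#'   attribute (or supplied via `toe_off_pct`).
#' @param toe_off_pct Toe-off as % cycle; defaults to the cycle's attribute.
#' @return A tibble with columns `phase`, `parameter`, `rom`. The
#'   intercondylar difference appears as parameter `"ap_diff"` (it may be
#'   negative; all other rows are true ranges and are non-negative).
#' @export
rom_summary <- function(cycle, toe_off_pct = attr(cycle, "toe_off_pct")) {
  if (is.null(toe_off_pct)) {
    stop_synergait("toe_off_pct is required (attribute or argument)",
                   "synergait_event_error")
  }
  pct <- cycle$cycle_pct
  i_to <- which.min(abs(pct - toe_off_pct))
  phases <- list(stance = seq_len(i_to), swing = seq(i_to, length(pct)))
  params <- setdiff(names(cycle), "cycle_pct")
  out <- purrr::map_dfr(names(phases), function(ph) {
    idx <- phases[[ph]]
    roms <- vapply(params, function(p) {
      v <- cycle[[p]][idx]
      max(v) - min(v)
    }, numeric(1))
    res <- tibble::tibble(phase = ph, parameter = params, rom = unname(roms))
    if (all(c("medial_ap", "lateral_ap") %in% params)) {
      res <- dplyr::bind_rows(res, tibble::tibble(
        phase = ph, parameter = "ap_diff",
        rom = roms[["lateral_ap"]] - roms[["medial_ap"]]
      ))
    }
    res
  })
  out
}

#' Detect heel-strike from a vertical ground-reaction force trace
#'
#' Returns the frame index of the first upward crossing of the force
#' threshold (25 N by default): the first sample at or above the threshold
#' that is preceded by a sample below it (or is the first sample).
#'
#' @param force Numeric vector of vertical force samples (N).
#' @param threshold Force threshold in newtons (default 25).
#' @return Integer frame index, or `NA_integer_` if the trace never crosses
#'   the threshold (explicit "no event" signal).
#' @export
detect_heelstrike <- function(force, threshold = 25) {
  stopifnot(is.numeric(force), all(is.finite(force)))
  above <- force >= threshold
  if (!any(above)) return(NA_integer_)
  idx <- which(above & !c(FALSE, above[-length(above)]))
  if (length(idx) == 0) idx <- which(above)[1]
  as.integer(idx[1])
}
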