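#' Plot a normalized kinematic cycle
#'
#' Faceted trajectories of the three joint angles and the two condylar A-P
#' tracks over the gait cycle, with the toe-off marked.
#'
#' @param object A `kinematic_cycle`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.kinematic_cycle <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object), -"cycle_pct",
                            names_to = "parameter", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cycle_pct, y = .data$value)) +
    ggplot2::geom_vline(xintercept = attr(object, "toe_off_pct"),
                        linetype = "dotted") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "Gait cycle [%]", y = "Angle [deg] / translation [mm]")
}

#' Plot a synergy factorization
#'
#' Left: module weights per muscle (bars). Right: cycle-averaged activation
#' patterns over the 200-point normalized cycle (toe-off at point 101).
#'
#' @param object A `synergy_set`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.synergy_set <- function(object, ...) {
  mods <- tidy(object, "modules")
  mods$muscle <- factor(mods$muscle, levels = emg_channels)
  pats <- tidy(object, "patterns")
  p1 <- ggplot2::ggplot(mods, ggplot2::aes(x = .data$muscle, y = .data$weight)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$synergy)) +
    ggplot2::labs(x = NULL, y = "Module weight")
  p2 <- ggplot2::ggplot(pats, ggplot2::aes(x = .data$point, y = .data$activation)) +
    ggplot2::geom_vline(xintercept = 101, linetype = "dotted") +
    ggplot2::geom_line() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$synergy), scales = "free_y") +
    ggplot2::labs(x = "Cycle point (100 stance + 100 swing)", y = "Activation")
  if (requireNamespace("patchwork", quietly = TRUE)) {
    patchwork::wrap_plots(p1, p2)
  } else {
    p2
  }
}

#' Plot an SPM t trajectory with its permutation threshold
#'
#' @param object An `spm_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.spm_result <- function(object, ...) {
  df <- tibble::tibble(node = seq_along(object$t), t = object$t)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$node, y = .data$t)) +
    ggplot2::geom_hline(yintercept = c(-1, 1) * object$threshold,
                        linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Domain node", y = "t statistic")
  if (nrow(object$clusters) > 0) {
    p <- p + ggplot2::geom_rect(
      data = object$clusters,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.15
    )
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
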