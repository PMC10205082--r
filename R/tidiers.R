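#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a synergy factorization
#'
#' @param x A `synergy_set`.
#' @param matrix `"modules"` for the muscle weights (one row per muscle and
#'   synergy) or `"patterns"` for the cycle-averaged activation patterns (one
#'   row per cycle point and synergy).
#' @param ... Unused.
#' @return A tibble in long format.
#' @exportS3Method generics::tidy
tidy.synergy_set <- function(x, matrix = c("modules", "patterns"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "modules") {
    tibble::tibble(
      muscle = rep(rownames(x$W), x$k),
      synergy = rep(seq_len(x$k), each = nrow(x$W)),
      weight = as.vector(x$W)
    )
  } else {
    if (is.null(x$patterns)) {
      stop_synergait("no cycle-averaged patterns available", "synergait_nmf_error")
    }
    tibble::tibble(
      synergy = rep(seq_len(x$k), times = ncol(x$patterns)),
      point = rep(seq_len(ncol(x$patterns)), each = x$k),
      activation = as.vector(x$patterns)
    )
  }
}

#' @rdname tidy.synergy_set
#' @exportS3Method generics::glance
glance.synergy_set <- function(x, ...) {
  tibble::tibble(k = x$k, r_squared = x$r_squared, sse = x$sse,
                 n_cycles = x$n_cycles, iterations = x$iterations,
                 seed = x$seed)
}

#' Tidy an SPM result
#'
#' @param x An `spm_result`.
#' @param ... Unused.
#' @return A tibble of suprathreshold clusters (`start`, `end`, `max_t`,
#'   `p_value`); zero rows when none.
#' @exportS3Method generics::tidy
tidy.spm_result <- function(x, ...) x$clusters

#' @rdname tidy.spm_result
#' @exportS3Method generics::glance
glance.spm_result <- function(x, ...) {
  tibble::tibble(threshold = x$threshold, alpha = x$alpha,
                 n_clusters = nrow(x$clusters), n_perm = x$n_perm_used,
                 exhaustive = x$exhaustive, n1 = x$n1, n2 = x$n2)
}

#' Tidy a functional classification
#'
#' @param x A `classified_synergies`.
#' @param ... Unused.
#' @return The per-synergy table (without the module/pattern list-columns).
#' @exportS3Method generics::tidy
tidy.classified_synergies <- function(x, ...) {
  tibble::as_tibble(x)[c("subject", "synergy_id", "cluster", "label",
                         "unclassified", "fwhm", "coa")]
}

#' @rdname tidy.classified_synergies
#' @exportS3Method generics::glance
glance.classified_synergies <- function(x, ...) {
  tibble::tibble(
    n_synergies = nrow(x),
    n_classified = sum(!x$unclassified),
    classifiable_ratio = attr(x, "classifiable_ratio"),
    n_clusters = nrow(attr(x, "centroids"))
  )
}
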