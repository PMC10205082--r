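#' Functionally classify extracted synergies across a group-activity
#'
#' Pools every synergy extracted from the subjects of one group-activity and
#' clusters them with k-means to evaluate the consistency of muscle synergies
#' across the group. The feature vector of each synergy is the concatenation
#' of its unit-norm module (8 muscle weights) and its unit-norm activation
#' pattern downsampled to 20 points; this feature construction is the
#' package's documented classification contract. Within a cluster, if one
#' subject contributed more than one synergy, only the member closest to the
#' cluster centroid is kept and the rest are flagged unclassified (each
#' subject may express each fundamental synergy at most once). Clusters are
#' labelled by the functional muscle group (knee extensors, plantarflexors,
#' dorsiflexors, knee flexors; dorsi- and knee flexors merge into one label
#' when `k_imposed < 4`, as for stair descent) with the largest summed
#' centroid weight, assigned greedily so labels are unique.
#'
#' @param synergy_sets A list of `synergy_set` objects (one per subject), or
#'   a tibble with list-column `synergy` and a `subject` column.
#' @param k_imposed Number of clusters (the imposed group model order).
#' @param seed Integer seed for the k-means restarts.
#' @param n_restarts k-means restarts (default 50).
#' @param subjects Subject identifiers parallel to `synergy_sets` (defaults
#'   to their position).
#' @return A `classified_synergies` object: a tibble with one row per
#'   extracted synergy (`subject`, `synergy_id`, `cluster`, `label`,
#'   `unclassified`, `fwhm`, `coa`) with attribute `classifiable_ratio`
#'   (classified / total) and `centroids`.
#' @export
classify_synergies <- function(synergy_sets, k_imposed, seed, n_restarts = 50,
                               subjects = NULL) {
  if (is.data.frame(synergy_sets)) {
    subjects <- subjects %||% synergy_sets$subject
    synergy_sets <- synergy_sets$synergy
  }
  subjects <- subjects %||% seq_along(synergy_sets)
  if (length(synergy_sets) < 2) {
    stop_synergait("at least 2 subjects are required for classification",
                   "synergait_classify_error")
  }
  rows <- purrr::map2_dfr(synergy_sets, subjects, function(ss, subj) {
    patterns <- ss$patterns
    if (is.null(patterns)) {
      stop_synergait("synergy_set lacks cycle-averaged patterns (input not in 200-point cycles)",
                     "synergait_classify_error")
    }
    tibble::tibble(
      subject = as.character(subj),
      within_id = seq_len(ss$k),
      module = lapply(seq_len(ss$k), function(j) ss$W[, j]),
      pattern = lapply(seq_len(ss$k), function(j) patterns[j, ])
    )
  })
  total <- nrow(rows)
  if (k_imposed > total) {
    stop_synergait("k_imposed exceeds the total number of extracted synergies",
                   "synergait_classify_error")
  }
  feats <- t(vapply(seq_len(total), function(i) {
    c(unit_norm(rows$module[[i]]), unit_norm(downsample20(rows$pattern[[i]])))
  }, numeric(28)))
  set.seed(seed)
  km <- stats::kmeans(feats, centers = k_imposed, nstart = n_restarts,
                      iter.max = 100)
  d2 <- rowSums((feats - km$centers[km$cluster, , drop = FALSE])^2)

  out <- rows |>
    dplyr::mutate(
      synergy_id = paste0(.data$subject, "_", .data$within_id),
      cluster = km$cluster,
      dist = d2
    ) |>
    dplyr::group_by(.data$cluster, .data$subject) |>
    dplyr::mutate(unclassified = dplyr::row_number(.data$dist) > 1) |>
    dplyr::ungroup()

  labels <- label_clusters(km$centers, k_imposed)
  out$label <- ifelse(out$unclassified, NA_character_, labels[out$cluster])
  out$fwhm <- vapply(out$pattern, fwhm, numeric(1))
  out$coa <- vapply(out$pattern, coa, numeric(1))
  out <- out |>
    dplyr::select("subject", "synergy_id", "cluster", "label", "unclassified",
                  "fwhm", "coa", "module", "pattern")
  structure(out,
            classifiable_ratio = sum(!out$unclassified) / total,
            centroids = km$centers,
            cluster_labels = labels,
            class = c("classified_synergies", class(out)))
}

unit_norm <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) v else v / n
}

downsample20 <- function(p) {
  # mean over 10-point bins of the 200-point pattern
  colMeans(matrix(p, nrow = length(p) / 20, ncol = 20))
}

label_clusters <- function(centers, k) {
  sets <- label_set_for(k)
  # score[cluster, label] = summed centroid weight over that muscle group
  score <- sapply(sets, function(chs) {
    idx <- match(chs, emg_channels)
    rowSums(centers[, idx, drop = FALSE])
  })
  score <- matrix(score, nrow = nrow(centers),
                  dimnames = list(NULL, names(sets)))
  labels <- rep(NA_character_, nrow(centers))
  # greedy unique assignment by decreasing score
  for (step in seq_len(min(nrow(centers), ncol(score)))) {
    best <- arrayInd(which.max(score), dim(score))
    labels[best[1]] <- colnames(score)[best[2]]
    score[best[1], ] <- -Inf
    score[, best[2]] <- -Inf
  }
  labels
}

#' Ratio of classifiable synergies in a classification
#'
#' @param x A `classified_synergies` object.
#' @return The classified / total ratio in `[0, 1]`.
#' @export
classifiable_ratio <- function(x) attr(x, "classifiable_ratio")
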