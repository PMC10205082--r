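#' Kinematics stage: poses to normalized cycles and RoM table
#'
#' For every trial, decomposes the pose series into Grood-Suntay angles,
#' computes condylar A-P translations, time-normalizes the cycle to 101
#' points, and summarizes per-phase ranges of motion.
#'
#' @param data Nested trial tibble ([simulate_cohort()] / [read_dataset()]).
#' @param config A [default_config()] list.
#' @return A list with `cycles` (trial tibble + list-column `cycle`) and
#'   `rom` (long tibble: subject, group, activity, cycle, phase, parameter,
#'   rom).
#' @export
pipeline_kinematics <- function(data, config = default_config()) {
  cycles <- data |>
    dplyr::mutate(cycle_curves = purrr::pmap(
      list(.data$pose, .data$events, .data$geometry),
      function(pose, events, geometry) {
        angles <- gs_decompose(pose)
        transforms <- pose_df_transforms(pose)
        ap <- purrr::map_dfr(transforms, condylar_ap, geometry = geometry)
        tracks <- dplyr::bind_cols(
          tibble::tibble(frame = pose$frame %||% seq_len(nrow(pose))),
          angles, ap
        )
        time_normalize_cycle(tracks, events, n_points = config$n_points_kin)
      }
    ))
  rom <- cycles |>
    dplyr::mutate(rom = purrr::map(.data$cycle_curves, rom_summary)) |>
    dplyr::select("subject", "group", "activity", "cycle", "rom") |>
    tidyr::unnest("rom")
  list(cycles = dplyr::select(cycles, "subject", "group", "activity", "cycle",
                              "cycle_curves"),
       rom = rom)
}

#' EMG stage: raw traces to amplitude- and time-normalized envelopes
#'
#' Runs the filter chain on every trial, time-normalizes each cycle to
#' 100 stance + 100 swing points, then amplitude-normalizes each channel to
#' its maximum across all cycles of the subject-activity.
#'
#' @inheritParams pipeline_kinematics
#' @return Trial tibble with list-column `envelope` (200 x 8 matrix per
#'   trial, entries in [0, 1]).
#' @export
pipeline_emg <- function(data, config = default_config()) {
  env <- data |>
    dplyr::mutate(envelope = purrr::map2(.data$emg, .data$emg_events,
      function(emg, ev) {
        filt <- emg_filter_chain(emg,
                                 high_cutoff = config$high_cutoff,
                                 low_cutoff = config$low_cutoff,
                                 order = config$filter_order,
                                 zero_phase = config$zero_phase)
        emg_time_normalize(filt, ev, n_stance = config$n_stance,
                           n_swing = config$n_swing)
      }))
  env |>
    dplyr::group_by(.data$subject, .data$activity) |>
    dplyr::mutate(envelope = emg_normalize_amplitude(.data$envelope)) |>
    dplyr::ungroup() |>
    dplyr::select("subject", "group", "activity", "cycle", "envelope")
}

#' Synergy stage: extraction, rank imposition and classification
#'
#' Per subject-activity, concatenates the normalized cycles into a
#' muscles x (200 * cycles) matrix, selects the rank with [choose_rank()],
#' and extracts synergies with [nmf()]. The group model order is then imposed
#' with [impose_group_rank()] from the per-group mean ranks and each group is
#' functionally classified with [classify_synergies()].
#'
#' @param envelopes Output of [pipeline_emg()].
#' @param config A [default_config()] list.
#' @param seed Integer seed.
#' @return A list with `synergies` (per-subject tibble: subject, group, k,
#'   r_squared, list-column `synergy`), `k_imposed`, and `classified` (named
#'   list of `classified_synergies`, one per group).
#' @export
pipeline_synergies <- function(envelopes, config = default_config(), seed) {
  per_subject <- envelopes |>
    dplyr::group_by(.data$subject, .data$group, .data$activity) |>
    dplyr::summarise(envs = list(.data$envelope), .groups = "drop") |>
    dplyr::mutate(
      V = purrr::map(.data$envs, ~ t(do.call(rbind, .x))),
      subj_seed = seed + 17L * seq_len(dplyr::n())
    ) |>
    dplyr::mutate(
      k = purrr::map2_int(.data$V, .data$subj_seed, function(v, s) {
        as.integer(choose_rank(v, seed = s, threshold = config$r2_threshold,
                               n_restarts = config$rank_restarts,
                               max_iter = config$nmf_max_iter,
                               tol = config$nmf_tol))
      }),
      synergy = purrr::pmap(list(.data$V, .data$k, .data$subj_seed),
        function(v, k, s) {
          nmf(v, k, seed = s + 1L, n_restarts = config$nmf_restarts,
              max_iter = config$nmf_max_iter, tol = config$nmf_tol)
        }),
      r_squared = purrr::map_dbl(.data$synergy, "r_squared")
    ) |>
    dplyr::select("subject", "group", "activity", "k", "r_squared", "synergy")

  ks <- split(per_subject$k, per_subject$group)
  k_imposed <- impose_group_rank(ks)
  classified <- purrr::imap(split(per_subject, per_subject$group),
    function(grp, gname) {
      classify_synergies(grp$synergy, k_imposed,
                         seed = seed + 101L + match(gname, sort(names(ks))),
                         n_restarts = config$kmeans_restarts,
                         subjects = grp$subject)
    })
  list(synergies = per_subject, k_imposed = k_imposed, classified = classified)
}

#' Statistics stage: group comparisons
#'
#' Compares the two groups: pooled t-tests on per-subject mean RoMs with
#' Bonferroni correction (translations and rotations as separate families),
#' pooled t-tests on FWHM and CoA of matching classified activation patterns
#' (corrected within metric), permutation SPM over the per-subject mean
#' kinematic curves, and one-way ANOVA on the synergy module weights of any
#' label whose FWHM or CoA differs significantly. Cycles are averaged per
#' subject before testing (documented choice).
#'
#' @param kin Output of [pipeline_kinematics()].
#' @param syn Output of [pipeline_synergies()].
#' @param config A [default_config()] list.
#' @param seed Integer seed (for the SPM permutations).
#' @return A list with `report` (tidy comparison table), `spm` (named list of
#'   `spm_result` per kinematic parameter), `anova` (module-weight ANOVAs).
#' @export
pipeline_stats <- function(kin, syn, config = default_config(), seed) {
  groups <- sort(unique(kin$rom$group))
  if (length(groups) != 2) {
    stop_synergait("statistics stage needs exactly two groups", "synergait_stats_error")
  }
  g1 <- groups[1]; g2 <- groups[2]

  # --- RoM comparisons on per-subject means -------------------------------
  rom_subj <- kin$rom |>
    dplyr::group_by(.data$subject, .data$group, .data$phase, .data$parameter) |>
    dplyr::summarise(rom = mean(.data$rom), .groups = "drop")
  fam <- config$bonferroni
  rom_report <- rom_subj |>
    dplyr::group_by(.data$phase, .data$parameter) |>
    dplyr::group_modify(function(d, key) {
      trans <- key$parameter %in% c("medial_ap", "lateral_ap", "ap_diff")
      m <- if (trans) fam$rom_translation else fam$rom_rotation
      t_test_pooled(d$rom[d$group == g1], d$rom[d$group == g2], m = m)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(comparison = paste0("rom_", .data$phase, "_", .data$parameter),
                  metric = "rom") |>
    dplyr::select("comparison", "metric", dplyr::everything(), -"phase", -"parameter")

  # --- FWHM / CoA comparisons on classified patterns ----------------------
  cls <- purrr::imap_dfr(syn$classified, function(cl, g) {
    dplyr::mutate(tibble::as_tibble(cl), group = g)
  })
  cls <- cls[!cls$unclassified & !is.na(cls$label), ]
  act_report <- purrr::map_dfr(c("fwhm", "coa"), function(metric) {
    purrr::map_dfr(sort(unique(cls$label)), function(lb) {
      v1 <- cls[[metric]][cls$label == lb & cls$group == g1]
      v2 <- cls[[metric]][cls$label == lb & cls$group == g2]
      if (length(v1) < 2 || length(v2) < 2) return(NULL)
      res <- t_test_pooled(v1, v2, m = fam[[metric]])
      dplyr::mutate(res, comparison = paste0(metric, "_", lb), metric = metric,
                    .before = 1)
    })
  })

  # --- SPM over per-subject mean curves -----------------------------------
  params <- c("flexion", "adduction", "internal_rotation", "medial_ap", "lateral_ap")
  mean_curves <- kin$cycles |>
    dplyr::group_by(.data$subject, .data$group) |>
    dplyr::summarise(curves = list(purrr::reduce(
      purrr::map(.data$cycle_curves, ~ as.matrix(.x[params])), `+`
    ) / dplyr::n()), .groups = "drop")
  spm <- setNames(lapply(seq_along(params), function(j) {
    y1 <- t(vapply(mean_curves$curves[mean_curves$group == g1],
                   function(m) m[, j], numeric(config$n_points_kin)))
    y2 <- t(vapply(mean_curves$curves[mean_curves$group == g2],
                   function(m) m[, j], numeric(config$n_points_kin)))
    spm_ttest_1d(y1, y2, alpha = config$alpha, n_perm = config$n_perm,
                 seed = seed + 31L * j)
  }), params)

  # --- ANOVA on module weights of significant FWHM/CoA labels -------------
  sig_labels <- unique(sub("^(fwhm|coa)_", "",
                           act_report$comparison[act_report$p_adjusted < config$alpha]))
  anova <- purrr::map(setNames(sig_labels, sig_labels), function(lb) {
    d <- cls[cls$label == lb, ]
    purrr::map_dfr(seq_along(emg_channels), function(i) {
      w <- vapply(d$module, `[[`, numeric(1), i)
      dplyr::mutate(anova_oneway(w, d$group), muscle = emg_channels[i],
                    label = lb, .before = 1)
    })
  })

  list(report = dplyr::bind_rows(rom_report, act_report), spm = spm, anova = anova)
}

#' Run the complete analysis pipeline
#'
#' Stages run in order: kinematics, EMG, synergy extraction/classification,
#' group statistics. The input must contain the trials of both groups (e.g.
#' two [simulate_cohort()] outputs bound together, or a [read_dataset()]
#' result).
#'
#' @param data Nested trial tibble with both groups, or a manifest path.
#' @param config A [default_config()] list.
#' @param seed Integer seed for every stochastic stage.
#' @param out_dir Optional directory to write result tables to (see
#'   [write_results()]).
#' @return A `synergait_results` list: `kinematics`, `envelopes`,
#'   `synergies`, `stats`, `config`, `seed`.
#' @export
run_pipeline <- function(data, config = default_config(), seed, out_dir = NULL) {
  if (is.character(data)) data <- read_dataset(data)
  if (nrow(data) == 0) {
    stop_synergait("no trials to process", "synergait_io_error")
  }
  kin <- pipeline_kinematics(data, config)
  env <- pipeline_emg(data, config)
  syn <- pipeline_synergies(env, config, seed = seed)
  stats <- pipeline_stats(kin, syn, config, seed = seed + 5000L)
  res <- structure(
    list(kinematics = kin, envelopes = env, synergies = syn, stats = stats,
         config = config, seed = seed),
    class = "synergait_results"
  )
  if (!is.null(out_dir)) write_results(res, out_dir)
  res
}

#' @export
print.synergait_results <- function(x, ...) {
  cat(sprintf("<synergait_results> %d subjects, imposed rank %d, %d comparisons (seed %d)\n",
              nrow(x$synergies$synergies), x$synergies$k_imposed,
              nrow(x$stats$report), x$seed))
  invisible(x)
}

#' Write pipeline results to a directory
#'
#' Writes the RoM table and statistics report as TSV, the per-subject synergy
#' factorizations as JSON, the classification table as TSV, the SPM cluster
#' tables as TSV, and a JSON snapshot of the configuration and seed.
#'
#' @param results A `synergait_results` from [run_pipeline()].
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(df, f) {
    write.table(df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wtsv(results$kinematics$rom, "rom.tsv")
  wtsv(results$stats$report, "stats_report.tsv")
  syn <- results$synergies$synergies
  jsonlite::write_json(
    purrr::pmap(list(syn$subject, syn$group, syn$synergy),
                function(s, g, ss) {
                  list(subject = s, group = g, k = ss$k, r_squared = ss$r_squared,
                       W = ss$W, H_patterns = ss$patterns)
                }),
    file.path(dir, "synergies.json"), digits = NA, auto_unbox = TRUE
  )
  cls <- purrr::imap_dfr(results$synergies$classified, function(cl, g) {
    dplyr::mutate(tibble::as_tibble(cl)[c("subject", "synergy_id", "cluster",
                                          "label", "unclassified", "fwhm", "coa")],
                  group = g)
  })
  wtsv(cls, "classification.tsv")
  spm_tab <- purrr::imap_dfr(results$stats$spm, function(s, p) {
    if (nrow(s$clusters) == 0) return(NULL)
    dplyr::mutate(s$clusters, parameter = p,
                  start_pct = (.data$start - 1) , end_pct = (.data$end - 1),
                  .before = 1)
  })
  if (!is.null(spm_tab) && nrow(spm_tab)) wtsv(spm_tab, "spm_clusters.tsv")
  jsonlite::write_json(list(config = results$config, seed = results$seed),
                       file.path(dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
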