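#' Read and write pose series as TSV
#'
#' The pose format is one row per frame with columns `frame`,
#' `r11`..`r33` (row-major rotation block of the femoral-to-tibial
#' transform) and `tx`, `ty`, `tz` (mm). Values are written with full
#' precision so a write-read round trip is lossless to well below 1e-9.
#'
#' @param pose A pose tibble.
#' @param path File path.
#' @return `read_pose_tsv()` returns a tibble; writers return `path`
#'   invisibly.
#' @export
write_pose_tsv <- function(pose, path) {
  cols <- c("frame", "r11", "r12", "r13", "r21", "r22", "r23",
            "r31", "r32", "r33", "tx", "ty", "tz")
  df <- as.data.frame(pose)[cols]
  write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pose_tsv
#' @export
read_pose_tsv <- function(path) {
  tibble::as_tibble(read.delim(path, sep = "\t"))
}

#' Read and write gait events as JSON
#'
#' Events are `heel_strike_1`, `toe_off`, `heel_strike_2` as frame (or
#' sample) indices.
#'
#' @param events Named list of the three indices.
#' @param path File path.
#' @export
write_events_json <- function(events, path) {
  jsonlite::write_json(events[c("heel_strike_1", "toe_off", "heel_strike_2")],
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_events_json
#' @export
read_events_json <- function(path) {
  ev <- jsonlite::read_json(path)
  lapply(ev, as.integer)
}

#' Read and write multi-channel EMG as CSV
#'
#' Header `time,RF,VM,VL,TA,HM,HL,GM,GL`, time in seconds.
#'
#' @param emg Tibble with `time` plus the 8 channels.
#' @param path File path.
#' @export
write_emg_csv <- function(emg, path) {
  df <- as.data.frame(emg)[c("time", emg_channels)]
  write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
              path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_emg_csv
#' @export
read_emg_csv <- function(path) {
  tibble::as_tibble(read.csv(path))
}

#' Read and write force traces as CSV (`time,force`)
#'
#' @param force Tibble with `time` (s) and `force` (N).
#' @param path File path.
#' @export
write_force_csv <- function(force, path) {
  df <- as.data.frame(force)[c("time", "force")]
  write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
              path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_force_csv
#' @export
read_force_csv <- function(path) {
  tibble::as_tibble(read.csv(path))
}

#' Read and write condyle geometry
#'
#' Point clouds are stored as CSV (`x,y,z` per row, one file per condyle) or
#' read from ASCII PLY; the tibial plateau plane is stored as JSON
#' (`point`, `normal`, `ap_axis`).
#'
#' @param geometry A `condyle_geometry`.
#' @param dir Directory receiving `medial.csv`, `lateral.csv`, `plane.json`.
#' @export
write_geometry <- function(geometry, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (side in c("medial", "lateral")) {
    m <- geometry[[paste0(side, "_points")]]
    df <- data.frame(x = m[, 1], y = m[, 2], z = m[, 3])
    write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                file.path(dir, paste0(side, ".csv")),
                sep = ",", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(geometry$tibial_plane, file.path(dir, "plane.json"),
                       digits = NA)
  invisible(dir)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(dir) {
  plane <- jsonlite::read_json(file.path(dir, "plane.json"), simplifyVector = TRUE)
  condyle_geometry(
    medial_points = read_condyle_points(file.path(dir, "medial.csv")),
    lateral_points = read_condyle_points(file.path(dir, "lateral.csv")),
    plane_point = plane$point, plane_normal = plane$normal,
    ap_axis = plane$ap_axis
  )
}

#' @rdname write_geometry
#' @param path A `.csv` (columns x,y,z) or ASCII `.ply` point-cloud file.
#' @export
read_condyle_points <- function(path) {
  if (grepl("\\.ply$", path, ignore.case = TRUE)) {
    read_ply_ascii(path)
  } else {
    as.matrix(read.csv(path)[, c("x", "y", "z")])
  }
}

# Minimal ASCII PLY vertex reader (x, y, z properties); no installed R
# package provides PLY parsing in this stack.
read_ply_ascii <- function(path) {
  lines <- readLines(path)
  if (!grepl("^ply", lines[1])) {
    stop_synergait("not a PLY file", "synergait_io_error")
  }
  if (!any(grepl("format ascii", lines))) {
    stop_synergait("only ASCII PLY is supported", "synergait_io_error")
  }
  nv <- as.integer(sub("element vertex\\s+", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  end <- which(lines == "end_header")[1]
  vals <- do.call(rbind, strsplit(trimws(lines[(end + 1):(end + nv)]), "\\s+"))
  m <- apply(vals[, 1:3, drop = FALSE], 2, as.numeric)
  colnames(m) <- c("x", "y", "z")
  m
}

#' Default pipeline configuration
#'
#' All defaults follow the published processing parameters where these are
#' printed (50 Hz / 20 Hz 4th-order Butterworth filters, 101-point kinematic
#' and 100+100-point EMG cycle grids, 25 N heel-strike threshold); remaining
#' settings (NMF restarts/tolerance, reconstruction-quality threshold,
#' k-means restarts, permutation count, Bonferroni family sizes) are
#' documented package contracts.
#'
#' @param ... Named overrides of the defaults (unknown keys are an error).
#' @return A named list of settings.
#' @export
default_config <- function(...) {
  cfg <- list(
    high_cutoff = 50, low_cutoff = 20, filter_order = 4, zero_phase = TRUE,
    n_points_kin = 101, n_stance = 100, n_swing = 100,
    force_threshold = 25,
    nmf_restarts = 10, rank_restarts = 5, nmf_tol = 1e-6, nmf_max_iter = 1000,
    r2_threshold = 0.90,
    kmeans_restarts = 50,
    alpha = 0.05, n_perm = 1000,
    bonferroni = list(rom_translation = 3, rom_rotation = 3,
                      fwhm = 4, coa = 4)
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad)) {
      stop_synergait(paste0("unknown config key(s): ", paste(bad, collapse = ", ")),
                     "synergait_config_error")
    }
    cfg <- modifyList(cfg, overrides)
  }
  cfg
}

#' Write a simulated cohort to disk in the package's standard formats
#'
#' Lays out one directory per trial (pose TSV, events JSON, EMG CSV, force
#' CSV), a geometry directory per subject, the dataset ground truth as
#' `ground_truth.json`, and a `manifest.json` tying every file to its
#' subject, group, activity, cycle and the master seed. A failed write
#' removes the partially written dataset directory.
#'
#' @param cohort A nested trial tibble from [simulate_cohort()].
#' @param dir Output directory (created; must not be an existing non-empty
#'   dataset unless `overwrite = TRUE`).
#' @param overwrite Remove an existing directory first.
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(cohort, dir, overwrite = FALSE) {
  if (dir.exists(dir)) {
    if (!overwrite && length(list.files(dir))) {
      stop_synergait(sprintf("directory %s exists and is not empty", dir),
                     "synergait_io_error")
    }
    unlink(dir, recursive = TRUE)
  }
  dir.create(dir, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(dir, recursive = TRUE), add = TRUE)

  spec <- attr(cohort, "spec")
  truth <- attr(cohort, "ground_truth")
  trials <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    row <- cohort[i, ]
    tdir <- file.path(dir, sprintf("%s_%s_c%02d", row$subject, row$activity, row$cycle))
    dir.create(tdir)
    write_pose_tsv(row$pose[[1]], file.path(tdir, "pose.tsv"))
    write_events_json(row$events[[1]], file.path(tdir, "events.json"))
    if (!is.null(cohort$emg)) {
      write_emg_csv(row$emg[[1]], file.path(tdir, "emg.csv"))
      write_events_json(row$emg_events[[1]], file.path(tdir, "emg_events.json"))
    }
    if (!is.null(cohort$force)) {
      write_force_csv(row$force[[1]], file.path(tdir, "force.csv"))
    }
    gdir <- file.path(dir, "geometry", row$subject)
    if (!dir.exists(gdir)) write_geometry(row$geometry[[1]], gdir)
    trials[[i]] <- list(
      subject = row$subject, group = row$group, activity = row$activity,
      cycle = row$cycle, dir = basename(tdir),
      geometry = file.path("geometry", row$subject)
    )
  }
  if (!is.null(truth)) {
    jsonlite::write_json(
      list(modules = truth$modules, patterns = truth$patterns, k = truth$k,
           labels = truth$labels),
      file.path(dir, "ground_truth.json"), digits = NA, auto_unbox = TRUE
    )
  }
  manifest <- list(
    generator = paste0("synergait ", as.character(utils::packageVersion("synergait"))),
    seed = if (!is.null(spec)) spec$seed else NA,
    activity = if (!is.null(spec)) spec$activity else cohort$activity[1],
    trials = trials
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  ok <- TRUE
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param manifest Path to a `manifest.json` (or its directory).
#' @return A nested trial tibble with the same columns as
#'   [simulate_cohort()] output (minus stored truth curves), with attribute
#'   `ground_truth` when `ground_truth.json` is present.
#' @export
read_dataset <- function(manifest) {
  if (dir.exists(manifest)) manifest <- file.path(manifest, "manifest.json")
  if (!file.exists(manifest)) {
    stop_synergait(sprintf("manifest not found: %s", manifest), "synergait_io_error")
  }
  man <- jsonlite::read_json(manifest, simplifyVector = FALSE)
  if (length(man$trials) == 0) {
    stop_synergait("manifest lists no trials", "synergait_io_error")
  }
  root <- dirname(manifest)
  geoms <- list()
  rows <- purrr::map_dfr(man$trials, function(tr) {
    tdir <- file.path(root, tr$dir)
    if (is.null(geoms[[tr$subject]])) {
      geoms[[tr$subject]] <<- read_geometry(file.path(root, tr$geometry))
    }
    emg_path <- file.path(tdir, "emg.csv")
    force_path <- file.path(tdir, "force.csv")
    tibble::tibble(
      subject = tr$subject, group = tr$group, activity = tr$activity,
      cycle = tr$cycle,
      pose = list(read_pose_tsv(file.path(tdir, "pose.tsv"))),
      events = list(read_events_json(file.path(tdir, "events.json"))),
      geometry = list(geoms[[tr$subject]]),
      emg = if (file.exists(emg_path)) list(read_emg_csv(emg_path)) else list(NULL),
      emg_events = if (file.exists(file.path(tdir, "emg_events.json"))) {
        list(read_events_json(file.path(tdir, "emg_events.json")))
      } else {
        list(NULL)
      },
      force = if (file.exists(force_path)) list(read_force_csv(force_path)) else list(NULL)
    )
  })
  gt_path <- file.path(root, "ground_truth.json")
  if (file.exists(gt_path)) {
    gt <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    attr(rows, "ground_truth") <- structure(
      list(modules = matrix(unlist(gt$modules), 8,
                            dimnames = list(emg_channels, gt$labels)),
           patterns = matrix(unlist(gt$patterns), gt$k, byrow = FALSE),
           k = gt$k, labels = gt$labels),
      class = "ground_truth_synergies"
    )
  }
  attr(rows, "seed") <- man$seed
  rows
}
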