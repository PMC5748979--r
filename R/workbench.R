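# default run configuration; every stage parameter has its module default
.default_config <- function() {
  list(
    seed = 1L,
    output_dir = "centrotrack-out",
    simulate = list(
      n_pairs = 10L,
      fraction_clustering = 0.5,
      render_stacks = FALSE,
      n_tripolar = 0L,
      tripolar_angle_mean = 80,
      tripolar_angle_sd = 15,
      n_afm_cells = 0L,
      n_afm_positions = 4L,
      n_afm_curves_per_position = 10L,
      motion = list(),  # overrides for motion_params()
      optics = list(),  # overrides for optics_params()
      afm = list()      # overrides for afm_sim_params()
    ),
    track = list(
      stack_dir = NULL,
      seeds_csv = NULL,
      anchor_spacing = 6L,
      mean_speed = 0.02,
      max_gap = 2L
    ),
    analyze = list(
      trajectory_dir = NULL,
      truth_dir = NULL,
      angles_csv = NULL,
      afm_dir = NULL,
      d_clustered = 2,
      stability_window = 5L,
      stability_sd = 0.3,
      bin_width = 1,
      n_boot = 1000L,
      angle_bin_width = 10,
      max_depth = 800,
      tip_half_angle = 35,
      poisson_ratio = 0.5
    )
  )
}

.merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  extra <- setdiff(names(user), names(defaults))
  if (length(extra))
    stop(sprintf("unknown config key%s: %s",
                 if (length(extra) > 1) "s" else "",
                 paste0(path, extra, collapse = ", ")))
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- .merge_config(defaults[[nm]], user[[nm]],
                                      paste0(path, nm, "."))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a single YAML mapping, validates it strictly against the known
#' schema (unknown keys are rejected), and fills unspecified values with
#' the module defaults. `motion`, `optics` and `afm` submaps override
#' [motion_params()], [optics_params()] and [afm_sim_params()] fields.
#'
#' @param path YAML config path, or `NULL` for all defaults.
#' @param overrides optional named list merged on top (e.g. a command-line
#'   `--seed`).
#' @return A validated config list of class `run_config`.
#' @export
run_config <- function(path = NULL, overrides = NULL) {
  user <- if (!is.null(path)) yaml::read_yaml(path) else list()
  cfg <- .merge_config(.default_config(), user)
  if (!is.null(overrides)) cfg <- .merge_config(cfg, overrides)
  # the motion/optics/afm submaps are validated by their constructors
  do.call(motion_params, c(cfg$simulate$motion, list(seed = 1L))[
    unique(c(names(cfg$simulate$motion), "seed"))])
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "run_config"
  cfg
}

.config_checksum <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}

.write_manifest <- function(files, dir, cfg, stage) {
  files <- files[file.exists(files)]
  manifest <- list(stage = stage,
                   config_checksum = .config_checksum(cfg),
                   files = lapply(files, function(f)
                     list(path = basename(f), md5 = unname(tools::md5sum(f)))))
  path <- file.path(dir, paste0(stage, "-manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  path
}

#' Write truth trajectories of one simulated pair
#' @noRd
.write_truth <- function(truth, stem) {
  n <- dim(truth$positions)[1]
  df <- do.call(rbind, lapply(1:2, function(s)
    data.frame(frame = seq_len(n), centrosome_id = s,
               x_um = truth$positions[, "x", s],
               y_um = truth$positions[, "y", s],
               z_um = truth$positions[, "z", s])))
  utils::write.csv(df, paste0(stem, "-truth.csv"), row.names = FALSE)
  side <- list(params = unclass(truth$params),
               motorized_onset_frame = truth$motorized_onset_frame,
               completion_frame = truth$completion_frame,
               anaphase_onset_frame = truth$anaphase_onset_frame,
               onset_separation_emitted = truth$onset_separation_emitted)
  jsonlite::write_json(side, paste0(stem, "-truth.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  c(paste0(stem, "-truth.csv"), paste0(stem, "-truth.json"))
}

#' Generate every synthetic input the pipeline consumes
#'
#' Writes, under `output_dir`: per-pair truth trajectories (CSV + JSON
#' sidecar with parameters and truth events), optionally rendered image
#' stacks (multi-page TIFF + calibration sidecar), a tripolar pole table,
#' and AFM force curves (TSV + JSON metadata), plus a manifest JSON listing
#' every artifact with its checksum. All randomness derives from the
#' config's global seed.
#'
#' @param config a [run_config()].
#' @return The manifest path, invisibly; the manifest records all files.
#' @export
run_simulate <- function(config = run_config()) {
  cfg <- if (inherits(config, "run_config")) config else run_config(overrides = config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- cfg$simulate
  files <- character(0)
  n_pairs <- as.integer(sim$n_pairs)
  n_cluster <- round(n_pairs * sim$fraction_clustering)
  for (i in seq_len(n_pairs)) {
    clustering <- i <= n_cluster
    mp <- do.call(motion_params, c(
      list(cluster = clustering, seed = cfg$seed * 1000L + i),
      sim$motion))
    truth <- simulate_pair(mp, midpoint = c(9, 9, 8.75))
    stem <- file.path(cfg$output_dir, sprintf("pair%03d", i))
    files <- c(files, .write_truth(truth, stem))
    if (isTRUE(sim$render_stacks)) {
      op <- do.call(optics_params, c(list(seed = cfg$seed * 1000L + i),
                                     sim$optics))
      stack <- render_stack(truth, op, volume_xy_um = c(18, 18))
      tif <- paste0(stem, ".tif")
      write_stack(stack, tif)
      files <- c(files, tif, paste0(tif, ".json"))
    }
  }
  if (sim$n_tripolar > 0) {
    spindles <- simulate_tripolar(sim$n_tripolar, sim$tripolar_angle_mean,
                                  sim$tripolar_angle_sd,
                                  seed = cfg$seed * 1000L + 501L)
    df <- do.call(rbind, lapply(spindles, function(s)
      data.frame(cell_id = s$cell_id, pole_index = 1:3,
                 x_um = s$poles[, "x"], y_um = s$poles[, "y"],
                 condition = "synthetic", truth_angle = s$truth_angle)))
    p <- file.path(cfg$output_dir, "tripolar-poles.csv")
    utils::write.csv(df, p, row.names = FALSE)
    files <- c(files, p)
  }
  if (sim$n_afm_cells > 0) {
    for (ci in seq_len(sim$n_afm_cells)) {
      for (pi in seq_len(sim$n_afm_positions)) {
        for (ri in seq_len(sim$n_afm_curves_per_position)) {
          ap <- do.call(afm_sim_params, c(
            list(seed = cfg$seed * 100000L + ci * 1000L + pi * 100L + ri),
            sim$afm))
          curve <- simulate_force_curve(ap, position_id = sprintf("c%dp%d", ci, pi),
                                        cell_id = sprintf("c%d", ci))
          p <- file.path(cfg$output_dir,
                         sprintf("afm-c%02d-p%d-r%02d.tsv", ci, pi, ri))
          write_force_curve(curve, p)
          files <- c(files, p, paste0(p, ".json"))
        }
      }
    }
  }
  invisible(.write_manifest(files, cfg$output_dir, cfg, "simulate"))
}

#' Track all simulated or recorded stacks in a directory
#'
#' Runs the full detection chain (anchor seeding, plan propagation within
#' spherical masks, Gaussian refinement, gated linking) on every
#' `*.tif` stack under `track$stack_dir` (default: the output directory).
#' Writes per-stack spot and trajectory CSVs, the propagation plan JSON,
#' and a run log recording the computed gate radius and thresholds.
#'
#' @param config a [run_config()].
#' @return Invisibly, the manifest path.
#' @export
run_track <- function(config = run_config()) {
  cfg <- if (inherits(config, "run_config")) config else run_config(overrides = config)
  tr <- cfg$track
  stack_dir <- tr$stack_dir %||% cfg$output_dir
  stacks <- list.files(stack_dir, pattern = "\\.tif$", full.names = TRUE)
  if (!length(stacks)) stop("no .tif stacks found in ", stack_dir)
  seeds <- if (!is.null(tr$seeds_csv)) utils::read.csv(tr$seeds_csv) else NULL
  files <- character(0)
  for (tif in stacks) {
    stack <- read_stack(tif)
    n <- dim(stack$data)[1]
    anchors <- seq(1L, n, by = as.integer(tr$anchor_spacing))
    trajs <- track_stack(stack, anchor_frames = anchors, seeds = seeds,
                         mean_speed = tr$mean_speed, max_gap = tr$max_gap)
    stem <- sub("\\.tif$", "", tif)
    spots <- attr(trajs, "spots")
    if (!is.null(spots) && nrow(spots)) {
      spots$spot_id <- seq_len(nrow(spots))
      utils::write.csv(spots, paste0(stem, "-spots.csv"), row.names = FALSE)
    } else {
      utils::write.csv(data.frame(), paste0(stem, "-spots.csv"), row.names = FALSE)
    }
    tdf <- if (length(trajs)) do.call(rbind, trajs) else
      data.frame(centrosome_id = integer(0), frame = integer(0),
                 time_s = numeric(0), x_um = numeric(0), y_um = numeric(0),
                 z_um = numeric(0), interpolated = logical(0))
    utils::write.csv(tdf, paste0(stem, "-trajectories.csv"), row.names = FALSE)
    plan <- attr(trajs, "plan")
    jsonlite::write_json(
      list(anchor_frames = plan$anchor_frames,
           source_of = as.list(plan$source_of),
           gate_radius_um = attr(trajs, "gate_radius_um"),
           mean_speed_um_per_s = tr$mean_speed,
           frame_interval_s = stack$frame_interval),
      paste0(stem, "-plan.json"), auto_unbox = TRUE, digits = NA)
    files <- c(files, paste0(stem, "-spots.csv"),
               paste0(stem, "-trajectories.csv"), paste0(stem, "-plan.json"))
  }
  log <- list(gate_radius_um = mask_radius(stack$frame_interval, tr$mean_speed),
              mean_speed_um_per_s = tr$mean_speed,
              anchor_spacing = tr$anchor_spacing, max_gap = tr$max_gap,
              n_stacks = length(stacks))
  jsonlite::write_json(log, file.path(stack_dir, "track-log.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c(files, file.path(stack_dir, "track-log.json"))
  invisible(.write_manifest(files, stack_dir, cfg, "track"))
}

#' Run all available sub-analyses and write their tables
#'
#' Consumes trajectory CSVs (from [run_track()] or truth CSVs from
#' [run_simulate()]), a pole table and AFM curves, whichever exist, and
#' writes: per-pair classification and segmentation tables, the MSD curve,
#' aligned population statistics, the search-phase separation histogram,
#' the angle table, and per-position/per-cell elasticity tables. Absent
#' inputs skip their sub-analysis with a message. A JSON audit file logs
#' every parameter.
#'
#' @param config a [run_config()].
#' @return Invisibly, the manifest path.
#' @export
run_analyze <- function(config = run_config()) {
  cfg <- if (inherits(config, "run_config")) config else run_config(overrides = config)
  an <- cfg$analyze
  dir <- an$trajectory_dir %||% an$truth_dir %||% cfg$output_dir
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  # --- pair kinematics ---
  traj_files <- list.files(dir, pattern = "-(trajectories|truth)\\.csv$",
                           full.names = TRUE)
  # prefer tracked trajectories over truth tables for the same stem
  stems <- sub("(-trajectories|-truth)\\.csv$", "", traj_files)
  is_traj <- grepl("-trajectories\\.csv$", traj_files)
  traj_files <- unlist(lapply(unique(stems), function(s) {
    sel <- traj_files[stems == s]
    if (any(is_traj[stems == s])) sel[is_traj[stems == s]][1] else sel[1]
  }))
  series <- list()
  for (f in traj_files) {
    df <- utils::read.csv(f)
    if (!nrow(df)) next
    idc <- if ("centrosome_id" %in% names(df)) "centrosome_id" else NULL
    if (is.null(idc) || length(unique(df[[idc]])) < 2) next
    ids <- sort(unique(df[[idc]]))[1:2]
    side <- sub("(-trajectories|-truth)\\.csv$", "-truth.json", f)
    ana <- if (file.exists(side))
      jsonlite::read_json(side)$anaphase_onset_frame %||% NA_integer_ else NA_integer_
    pair_id <- sub("(-trajectories|-truth)\\.csv$", "", basename(f))
    a <- df[df[[idc]] == ids[1], ]
    b <- df[df[[idc]] == ids[2], ]
    if (!"time_s" %in% names(df)) {
      a$time_s <- (a$frame - 1) * 40; b$time_s <- (b$frame - 1) * 40
    }
    s <- tryCatch(separation_series(a, b, pair_id = pair_id,
                                    anaphase_onset_frame = ana),
                  error = function(e) NULL)
    if (!is.null(s)) series[[length(series) + 1L]] <- s
  }
  if (length(series)) {
    cls <- classify_pairs(series, an$d_clustered, an$stability_window,
                          an$stability_sd)
    segs <- lapply(seq_along(series), function(i) {
      comp <- cls$table$completion_frame[i]
      if (is.na(comp)) return(NULL)
      seg <- segment_phases(series[[i]], comp)
      if (isTRUE(seg$segmentable)) seg else NULL
    })
    utils::write.csv(cls$table, file.path(out, "classification.csv"),
                     row.names = FALSE)
    seg_df <- do.call(rbind, lapply(seq_along(series), function(i) {
      seg <- segs[[i]]
      data.frame(pair_id = series[[i]]$pair_id,
                 clustered = cls$table$clustered[i],
                 completion_frame = cls$table$completion_frame[i],
                 motorized_onset_frame = if (!is.null(seg)) seg$motorized_onset_frame else NA,
                 onset_separation_um = if (!is.null(seg)) seg$onset_separation else NA,
                 motorized_speed_um_s = if (!is.null(seg)) seg$motorized_speed else NA,
                 motorized_duration_s = if (!is.null(seg))
                   (seg$completion_frame - seg$motorized_onset_frame) *
                     series[[i]]$frame_interval else NA)
    }))
    utils::write.csv(seg_df, file.path(out, "segmentation.csv"), row.names = FALSE)
    msd_df <- msd(series, phase = "search", segmentations = segs)
    utils::write.csv(as.data.frame(msd_df), file.path(out, "msd.csv"),
                     row.names = FALSE)
    aligned <- tryCatch(
      align_population(series, "anaphase_onset"),
      error = function(e) NULL)
    if (!is.null(aligned))
      utils::write.csv(aligned, file.path(out, "aligned-stats.csv"),
                       row.names = FALSE)
    hist <- phase_histogram(series, segs, bin_width = an$bin_width,
                            n_boot = an$n_boot, boot_seed = cfg$seed)
    utils::write.csv(
      data.frame(bin_lo = hist$breaks[-length(hist$breaks)],
                 bin_hi = hist$breaks[-1], count = hist$counts),
      file.path(out, "separation-histogram.csv"), row.names = FALSE)
    files <- c(files, file.path(out, c("classification.csv", "segmentation.csv",
                                       "msd.csv", "aligned-stats.csv",
                                       "separation-histogram.csv")))
  } else message("no trajectory inputs: skipping kinematics")

  # --- tripolar angles ---
  angles_csv <- an$angles_csv %||% {
    p <- file.path(dir, "tripolar-poles.csv"); if (file.exists(p)) p else NULL
  }
  if (!is.null(angles_csv) && file.exists(angles_csv)) {
    spindles <- read_pole_table(angles_csv)
    ang <- vapply(spindles, smallest_pole_angle, numeric(1))
    adf <- data.frame(cell_id = vapply(spindles, `[[`, numeric(1), "cell_id"),
                      smallest_angle_deg = ang)
    utils::write.csv(adf, file.path(out, "angles.csv"), row.names = FALSE)
    rh <- rose_histogram(ang, an$angle_bin_width)
    jsonlite::write_json(list(mean_angle = rh$mean_angle, n = rh$n,
                              breaks = rh$breaks, counts = rh$counts),
                         file.path(out, "angles-summary.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, file.path(out, c("angles.csv", "angles-summary.json")))
  } else message("no pole table: skipping angle analysis")

  # --- AFM elasticity ---
  afm_dir <- an$afm_dir %||% dir
  afm_files <- list.files(afm_dir, pattern = "^afm-.*\\.tsv$", full.names = TRUE)
  if (length(afm_files)) {
    curves <- lapply(afm_files, read_force_curve)
    by_pos <- split(curves, vapply(curves, `[[`, character(1), "position_id"))
    ests <- lapply(by_pos, function(cs) {
      di <- lapply(cs, function(c) indentation_force(c, find_contact_point(c)))
      avg <- average_position_curves(di)
      est <- fit_sneddon(avg, an$max_depth, an$tip_half_angle,
                         an$poisson_ratio, position_id = cs[[1]]$position_id)
      est$cell_id <- cs[[1]]$cell_id
      est
    })
    pos_df <- do.call(rbind, lapply(ests, function(e)
      data.frame(position_id = e$position_id, cell_id = e$cell_id,
                 apparent_modulus_Pa = e$apparent_modulus,
                 fit_rms_pN = e$fit_rms, depth_used_nm = e$depth_used,
                 n_curves = e$n_curves_averaged)))
    utils::write.csv(pos_df, file.path(out, "elasticity-positions.csv"),
                     row.names = FALSE)
    utils::write.csv(cell_elasticity(ests),
                     file.path(out, "elasticity-cells.csv"), row.names = FALSE)
    files <- c(files, file.path(out, c("elasticity-positions.csv",
                                       "elasticity-cells.csv")))
  } else message("no AFM curves: skipping elasticity analysis")

  audit <- list(parameters = an, seed = cfg$seed,
                config_checksum = .config_checksum(cfg))
  jsonlite::write_json(audit, file.path(out, "analyze-audit.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  files <- c(files, file.path(out, "analyze-audit.json"))
  invisible(.write_manifest(files, out, cfg, "analyze"))
}
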