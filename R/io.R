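# File formats and the pipeline driver: multi-page TIFF movies with a YAML
# metadata/ground-truth sidecar, CSV event and calibration tables, YAML
# pipeline configuration with strict key validation, and run_pipeline().

#' Write a movie bundle to TIFF files with a metadata sidecar
#'
#' Each channel goes to a 16-bit multi-page TIFF with pages ordered T-major
#' then Z (page `(t-1) * n_z + z`); acquisition metadata and, if present,
#' the ground-truth event table and cell tracks go to a YAML sidecar.
#' Intensities are rounded to integer counts on write.
#'
#' @param bundle a [movie_bundle].
#' @param red_path,green_path,metadata_path output file paths.
#' @param overwrite overwrite existing files? Default FALSE (refuses).
#' @return Invisibly, the three paths.
#' @export
write_movie <- function(bundle, red_path, green_path, metadata_path,
                        overwrite = FALSE) {
  .chk(inherits(bundle, "movie_bundle"), "bundle must be a movie_bundle")
  .chk(length(bundle$red) > 0, "empty stack")
  if (!overwrite) {
    for (p in c(red_path, green_path, metadata_path))
      .chk(!file.exists(p), sprintf("refusing to overwrite existing file '%s'", p))
  }
  p <- bundle$params
  mx <- .intensity_max(p)
  pages <- function(stack) {
    out <- vector("list", p$n_frames * p$n_z)
    k <- 0L
    for (t in seq_len(p$n_frames)) for (z in seq_len(p$n_z)) {
      k <- k + 1L
      out[[k]] <- matrix(round(stack[t, z, , ]) / mx, p$fov_px[1], p$fov_px[2])
    }
    out
  }
  tiff::writeTIFF(pages(bundle$red), red_path, bits.per.sample = 16L,
                  compression = "none")
  tiff::writeTIFF(pages(bundle$green), green_path, bits.per.sample = 16L,
                  compression = "none")

  meta <- list(pixel_size_um = p$pixel_size_um, z_step_um = p$z_step_um,
               n_z = p$n_z, frame_interval_s = p$frame_interval_s,
               n_frames = p$n_frames, fov_px = as.integer(p$fov_px),
               photon_scale = if (is.finite(p$photon_scale)) p$photon_scale else ".inf",
               read_noise_sd = p$read_noise_sd,
               background_counts = p$background_counts,
               bit_depth = p$bit_depth,
               seed = p$seed)
  gt <- bundle$ground_truth
  if (!is.null(gt)) {
    events <- if (!is.null(gt$event_table) && nrow(gt$event_table))
      lapply(seq_len(nrow(gt$event_table)), function(i)
        as.list(gt$event_table[i, ]))
    else list()
    meta$ground_truth <- list(
      events = events,
      paths = lapply(gt$paths, function(pp) list(
        x_um = round(unname(pp[, 1]), 3), y_um = round(unname(pp[, 2]), 3))))
  }
  yaml::write_yaml(meta, metadata_path)
  invisible(c(red = red_path, green = green_path, metadata = metadata_path))
}

#' Read a movie bundle written by [write_movie()]
#'
#' Validates that each channel's page count equals `n_frames * n_z` from the
#' metadata and that both channels share the declared shape.
#'
#' @param red_path,green_path,metadata_path input file paths.
#' @return A [movie_bundle]; any ground-truth event table from the sidecar
#'   is attached under `$ground_truth$event_table`.
#' @export
read_movie <- function(red_path, green_path, metadata_path) {
  for (p in c(red_path, green_path, metadata_path))
    .chk(file.exists(p), sprintf("file not found: '%s'", p))
  meta <- yaml::read_yaml(metadata_path)
  ps <- if (identical(meta$photon_scale, ".inf")) Inf else meta$photon_scale
  params <- acquisition_params(fov_px = unlist(meta$fov_px),
                               n_frames = meta$n_frames,
                               pixel_size_um = meta$pixel_size_um,
                               z_step_um = meta$z_step_um, n_z = meta$n_z,
                               frame_interval_s = meta$frame_interval_s,
                               photon_scale = ps,
                               read_noise_sd = meta$read_noise_sd,
                               background_counts = meta$background_counts %||% 0,
                               bit_depth = meta$bit_depth, seed = meta$seed)
  mx <- .intensity_max(params)
  load_stack <- function(path, channel) {
    pg <- tiff::readTIFF(path, all = TRUE)
    .chk(length(pg) == params$n_frames * params$n_z,
         sprintf("%s channel has %d pages, metadata declares %d (T=%d x Z=%d)",
                 channel, length(pg), params$n_frames * params$n_z,
                 params$n_frames, params$n_z))
    .chk(all(dim(pg[[1]]) == params$fov_px),
         sprintf("%s channel page shape mismatch with metadata", channel))
    stk <- array(0, dim = c(params$n_frames, params$n_z, params$fov_px))
    k <- 0L
    for (t in seq_len(params$n_frames)) for (z in seq_len(params$n_z)) {
      k <- k + 1L
      stk[t, z, , ] <- round(pg[[k]] * mx)
    }
    stk
  }
  red <- load_stack(red_path, "red")
  green <- load_stack(green_path, "green")
  gt <- NULL
  if (!is.null(meta$ground_truth)) {
    et <- if (length(meta$ground_truth$events))
      do.call(rbind, lapply(meta$ground_truth$events, as.data.frame))
    else data.frame()
    gt <- list(event_table = et,
               paths = lapply(meta$ground_truth$paths, function(pp)
                 cbind(x_um = unlist(pp$x_um), y_um = unlist(pp$y_um))))
  }
  movie_bundle(red, green, params, ground_truth = gt)
}

#' Write / read detected events as CSV
#'
#' One row per event: id, kind, frame span, duration, area (um^2), peak
#' amplitude (SD units), centroid (um).
#'
#' @param events a `ca_events` object (or its table).
#' @param path CSV path.
#' @return `write_events_csv` the path invisibly; `read_events_csv` a data
#'   frame.
#' @export
write_events_csv <- function(events, path) {
  tab <- if (inherits(events, "ca_events")) events$table else events
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write per-frame event footprints as a label-image TIFF
#'
#' One 16-bit page per frame; pixel values carry the event id (0 =
#' background).
#'
#' @param events a `ca_events` object.
#' @param path TIFF path.
#' @param n_frames total frames in the movie.
#' @export
write_label_tiff <- function(events, path, n_frames) {
  H <- events$frame_dim[1]; W <- events$frame_dim[2]
  pages <- lapply(seq_len(n_frames), function(t) matrix(0, H, W))
  for (i in seq_along(events$footprints)) {
    for (tn in names(events$footprints[[i]])) {
      t <- as.integer(tn)
      fp <- events$footprints[[i]][[tn]]
      pages[[t]][fp] <- i
    }
  }
  tiff::writeTIFF(lapply(pages, function(m) m / 65535), path,
                  bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read / write calibration points as CSV
#'
#' Columns: `ca_nM`, `ratio`, optional `replicate_id`.
#'
#' @param points data frame of calibration points.
#' @param path CSV path.
#' @export
write_calibration_csv <- function(points, path) {
  utils::write.csv(points, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calibration_csv
#' @export
read_calibration_csv <- function(path) {
  pts <- utils::read.csv(path, stringsAsFactors = FALSE)
  .chk(all(c("ca_nM", "ratio") %in% names(pts)),
       "calibration CSV must have columns ca_nM and ratio")
  pts
}

#' Write a fitted Hill curve as structured text
#'
#' @param fit a `hill_fit`.
#' @param path YAML path.
#' @export
write_hill_fit <- function(fit, path) {
  .chk(inherits(fit, "hill_fit"), "fit must be a hill_fit")
  yaml::write_yaml(list(
    parameters = as.list(coef(fit)),
    standard_errors = as.list(fit$se),
    rss = fit$rss, converged = fit$converged, n_points = fit$n_points), path)
  invisible(path)
}

# ---- pipeline configuration -------------------------------------------------

.config_keys <- list(
  top = c("seed", "output_dir", "input", "acquisition", "scene", "preprocess",
          "detection", "calibration", "polarity"),
  input = c("red", "green", "metadata"),
  acquisition = c("fov_px", "n_frames", "pixel_size_um", "z_step_um", "n_z",
                  "frame_interval_s", "photon_scale", "read_noise_sd",
                  "background_counts", "bit_depth"),
  scene = c("n_cells", "n_sparkles", "n_cellwide", "n_autofluor", "cell",
            "sparkle_peak_ca_nM", "sparkle_amp_range",
            "sparkle_duration_frames", "cellwide_peak_ca_nM",
            "cellwide_duration_frames", "autofluor"),
  cell = c("radius_um", "nucleus_radius_frac", "nuclear_label_frac",
           "red_brightness", "baseline_ca_nM", "speed_um_min",
           "persistence_s"),
  autofluor = c("radius_um", "red_brightness", "green_brightness",
                "drift_um_min"),
  preprocess = c("median_radius_px", "median_shape", "bernsen_radius_px",
                 "bernsen_contrast_8bit", "mask_dilation_px", "red_scale",
                 "manual_exclusions", "mask_autofluor",
                 "mean_after_red_subtraction"),
  detection = c("local_thresh_sd", "cellwide_thresh_sd", "local_min_area_um2",
                "cellwide_min_area_um2", "connectivity", "gap_frames",
                "coincidence_rule"),
  calibration = c("points_csv", "init", "output"),
  polarity = c("frame", "window", "cell_id", "red_floor")
)

#' @noRd
.validate_section <- function(cfg, section) {
  known <- .config_keys[[section]]
  bad <- setdiff(names(cfg), known)
  .chk(length(bad) == 0,
       sprintf("unknown config key '%s' in section '%s'",
               bad[1], section))
}

#' Read and validate a pipeline configuration file
#'
#' YAML with sections `acquisition`, `scene`, `preprocess`, `detection`,
#' `calibration`, `polarity`, `input`, plus top-level `seed` and
#' `output_dir`. Unknown keys are rejected by name.
#'
#' @param path YAML config path, or an already-parsed named list.
#' @return Validated config list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  .validate_section(cfg, "top")
  for (s in intersect(names(cfg), c("input", "acquisition", "scene",
                                    "preprocess", "detection", "calibration",
                                    "polarity")))
    .validate_section(cfg[[s]], s)
  if (!is.null(cfg$scene$cell)) .validate_section(cfg$scene$cell, "cell")
  if (!is.null(cfg$scene$autofluor)) .validate_section(cfg$scene$autofluor, "autofluor")
  cfg
}

#' @noRd
.params_from_config <- function(cfg) {
  a <- cfg$acquisition
  .chk(!is.null(a), "config lacks an 'acquisition' section")
  ps <- a$photon_scale %||% Inf
  if (identical(ps, ".inf")) ps <- Inf
  acquisition_params(fov_px = unlist(a$fov_px), n_frames = a$n_frames,
                     pixel_size_um = a$pixel_size_um %||% 0.684,
                     z_step_um = a$z_step_um %||% 4,
                     n_z = a$n_z %||% 6,
                     frame_interval_s = a$frame_interval_s %||% 5,
                     photon_scale = ps,
                     read_noise_sd = a$read_noise_sd %||% 0,
                     background_counts = a$background_counts %||% 0,
                     bit_depth = a$bit_depth %||% 16,
                     seed = cfg$seed %||% 1L)
}

#' @noRd
.preprocess_config_from <- function(cfg) {
  do.call(preprocess_config, cfg$preprocess %||% list())
}

#' @noRd
.detection_config_from <- function(cfg) {
  do.call(detection_config, cfg$detection %||% list())
}

#' Run a pipeline stage (or the whole pipeline)
#'
#' Subcommands: `"simulate"` renders the configured scene and writes
#' `red.tif` / `green.tif` / `metadata.yaml`; `"preprocess"` runs the
#' conditioning chain on an input movie and writes the processed green
#' stack, mask and provenance; `"detect"` additionally detects events and
#' writes `events.csv`, `labels.tif` and `summary.yaml`; `"calibrate"` fits
#' the four-parameter Hill equation to a calibration CSV; `"polarity"` runs
#' the front/back comparison on a simulated movie's first ground-truth
#' cell; `"all"` chains simulate, preprocess, detect and summarise in
#' memory. Every stage logs its derived quantities (stack SD, pixel-area
#' thresholds, event counts) via `message()`.
#'
#' @param subcommand one of `"simulate"`, `"preprocess"`, `"detect"`,
#'   `"calibrate"`, `"polarity"`, `"all"`.
#' @param config path to a YAML config or a named list (see
#'   [read_pipeline_config()]).
#' @return Invisibly, a list of produced artifacts (varies by subcommand).
#' @export
run_pipeline <- function(subcommand = c("all", "simulate", "preprocess",
                                        "detect", "calibrate", "polarity"),
                         config) {
  subcommand <- match.arg(subcommand)
  cfg <- read_pipeline_config(config)
  out_dir <- cfg$output_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- cfg$seed %||% 1L
  message(sprintf("[casparkle] %s: seed = %d, output = %s", subcommand, seed, out_dir))

  simulate_stage <- function() {
    params <- .params_from_config(cfg)
    scene <- build_scene(cfg$scene %||% list(), params, seed)
    message(sprintf("[casparkle] scene: %d cell(s), %d event(s), %d autofluorescent object(s)",
                    length(scene$cells), length(scene$events), length(scene$autofluor)))
    bundle <- render_movie(scene$cells, scene$events, scene$autofluor, params,
                           seed = seed)
    write_movie(bundle, file.path(out_dir, "red.tif"),
                file.path(out_dir, "green.tif"),
                file.path(out_dir, "metadata.yaml"), overwrite = TRUE)
    bundle
  }

  load_input <- function() {
    inp <- cfg$input
    if (is.null(inp)) {
      inp <- list(red = file.path(out_dir, "red.tif"),
                  green = file.path(out_dir, "green.tif"),
                  metadata = file.path(out_dir, "metadata.yaml"))
    }
    read_movie(inp$red, inp$green, inp$metadata)
  }

  preprocess_stage <- function(bundle) {
    pc <- .preprocess_config_from(cfg)
    pp <- preprocess(bundle, pc)
    message(sprintf("[casparkle] preprocess: %.1f%% of field analyzable",
                    100 * mean(pp$analysis_mask)))
    pp
  }

  detect_stage <- function(pp) {
    dc <- .detection_config_from(cfg)
    psz <- pp$params$pixel_size_um
    message(sprintf("[casparkle] detect: stack SD = %.4g; area thresholds %d px (local) / %d px (cell-wide) at %.3f um/px",
                    stack_sd(pp), ceiling(dc$local_min_area_um2 / psz^2),
                    ceiling(dc$cellwide_min_area_um2 / psz^2), psz))
    ev <- detect_events(pp, dc)
    message(sprintf("[casparkle] detect: %d local, %d cell-wide, %d excluded",
                    sum(ev$table$kind == "local"),
                    sum(ev$table$kind == "cell_wide"),
                    sum(ev$table$kind == "local_excluded")))
    write_events_csv(ev, file.path(out_dir, "events.csv"))
    write_label_tiff(ev, file.path(out_dir, "labels.tif"), pp$params$n_frames)
    s <- summarize_events(ev)
    yaml::write_yaml(list(counts = as.list(s$counts),
                          relative_frequency = as.list(s$relative_frequency),
                          median_local_area_um2 = s$median_local_area_um2,
                          mean_peak_amplitude_sd = s$mean_peak_amplitude_sd),
                     file.path(out_dir, "summary.yaml"))
    ev
  }

  switch(subcommand,
    simulate = invisible(list(bundle = simulate_stage())),
    preprocess = {
      pp <- preprocess_stage(load_input())
      mx <- 65535
      pages <- lapply(seq_len(pp$params$n_frames), function(t) {
        m <- matrix(pp$processed_green[t, , ], pp$params$fov_px[1])
        m[is.na(m)] <- 0
        m
      })
      rng <- max(abs(unlist(lapply(pages, range))), 1)
      tiff::writeTIFF(lapply(pages, function(m) (m / rng + 1) / 2),
                      file.path(out_dir, "processed_green.tif"),
                      bits.per.sample = 32L, sample.format = "float")
      tiff::writeTIFF(list(pp$analysis_mask * 1),
                      file.path(out_dir, "analysis_mask.tif"))
      writeLines(pp$provenance, file.path(out_dir, "provenance.txt"))
      invisible(list(processed = pp))
    },
    detect = {
      pp <- preprocess_stage(load_input())
      invisible(list(events = detect_stage(pp)))
    },
    calibrate = {
      cc <- cfg$calibration
      .chk(!is.null(cc$points_csv), "calibration section needs points_csv")
      pts <- read_calibration_csv(cc$points_csv)
      fit <- fit_hill(pts, init = cc$init)
      message(sprintf("[casparkle] calibrate: Kd = %.4g nM, n = %.3g (%s)",
                      coef(fit)["kd_nM"], coef(fit)["hill_n"],
                      if (fit$converged) "converged" else "NOT converged"))
      write_hill_fit(fit, file.path(out_dir, cc$output %||% "hill_fit.yaml"))
      invisible(list(fit = fit))
    },
    polarity = {
      bundle <- load_input()
      .chk(!is.null(bundle$ground_truth$paths),
           "polarity subcommand needs a simulated movie with ground-truth tracks")
      pc <- cfg$polarity %||% list()
      frame <- pc$frame %||% max(1, bundle$params$n_frames - (pc$window %||% 5))
      window <- pc$window %||% 5
      cell_id <- pc$cell_id %||% 1
      floor_ <- pc$red_floor %||% 1
      red_p <- max_project_z(array(bundle$red[frame, , , ],
                                   dim = dim(bundle$red)[2:4]))
      green_p <- max_project_z(array(bundle$green[frame, , , ],
                                     dim = dim(bundle$green)[2:4]))
      ratio <- gr_ratio(green_p, red_p, floor_)
      mask <- red_p > floor_
      path <- bundle$ground_truth$paths[[as.character(cell_id)]]
      pr <- polarity_report(ratio, mask, path, frame, window,
                            bundle$params$pixel_size_um)
      message(sprintf("[casparkle] polarity: front median %.4g vs back %.4g, p = %.3g",
                      pr$median_front, pr$median_back, pr$p))
      utils::write.csv(data.frame(
        side = c(rep("front", pr$n_front), rep("back", pr$n_back)),
        gr_ratio = c(pr$front, pr$back)),
        file.path(out_dir, "polarity_pixels.csv"), row.names = FALSE)
      invisible(list(polarity = pr))
    },
    all = {
      bundle <- simulate_stage()
      pp <- preprocess_stage(bundle)
      ev <- detect_stage(pp)
      invisible(list(bundle = bundle, processed = pp, events = ev,
                     summary = summarize_events(ev)))
    })
}
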