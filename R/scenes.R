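# Ready-made synthetic scenes: noise/response calibration, the sparkle
# recovery benchmark, white-noise control movies, and scene construction
# from pipeline configuration.

#' Calibrate the processed noise scale and sparkle amplitude gain
#'
#' Renders two short pilot movies at the given acquisition settings -- one
#' with a single resting cell and no events, one identical but carrying
#' probe sparkles of known noiseless green increment -- runs both through
#' the standard preprocessing chain, and measures (i) the processed-stack
#' noise SD and (ii) the gain relating a sparkle's noiseless green increment
#' to its realised per-pixel signal level after processing (the median
#' filter and projection slightly attenuate a small footprint). Scene
#' builders use these two constants to place sparkle amplitudes at
#' prescribed multiples of the noise SD, the way indicator responses are
#' calibrated on an instrument before an experiment.
#'
#' @param params an [acquisition_params] whose noise model and geometry
#'   (pixel size, z sampling, bit depth) should be matched.
#' @param cell reference [cell_spec] supplying brightness and baseline.
#' @param seed integer seed for the pilot renders.
#' @return List with `sigma` (processed noise SD, counts) and `gain`
#'   (measured SD-units amplitude per `sigma` of noiseless increment).
#' @export
calibrate_sparkle_response <- function(params, cell = cell_spec(1), seed = 1) {
  pcal <- acquisition_params(fov_px = c(64, 64), n_frames = 40,
                             pixel_size_um = params$pixel_size_um,
                             z_step_um = params$z_step_um, n_z = params$n_z,
                             frame_interval_s = params$frame_interval_s,
                             photon_scale = params$photon_scale,
                             read_noise_sd = params$read_noise_sd,
                             background_counts = params$background_counts,
                             bit_depth = params$bit_depth, seed = seed)
  mid <- c(32, 32) * pcal$pixel_size_um
  probe_cell <- cell_spec(1, radius_um = cell$radius_um,
                          nucleus_radius_frac = cell$nucleus_radius_frac,
                          nuclear_label_frac = cell$nuclear_label_frac,
                          red_brightness = cell$red_brightness,
                          baseline_ca_nM = cell$baseline_ca_nM,
                          speed_um_min = cell$speed_um_min,
                          persistence_s = cell$persistence_s,
                          center_um = mid)
  base <- render_movie(list(probe_cell), list(), list(), pcal, seed = seed)
  pp <- preprocess(base, preprocess_config())
  sigma <- stack_sd(pp)
  if (sigma <= 0) return(list(sigma = 0, gain = 1))

  # probe sparkles with a known noiseless green increment of 7 sigma
  dg <- 7 * sigma
  peak <- .peak_ca_for_increment(dg, probe_cell)
  frames <- seq(5, 33, by = 4)
  probes <- lapply(seq_along(frames), function(i)
    ca_event_spec("local", 1, frames[i], 1, peak, offset_um = c(2.4, 0)))
  mv <- render_movie(list(probe_cell), probes, list(), pcal, seed = seed)
  pp2 <- preprocess(mv, preprocess_config())
  s2 <- stack_sd(pp2)
  amps <- vapply(seq_along(probes), function(i) {
    fp <- mv$ground_truth$events[[i]]$footprints[[as.character(frames[i])]]
    mean(pp2$processed_green[cbind(frames[i], fp[, 1], fp[, 2])], na.rm = TRUE)
  }, numeric(1)) / s2
  list(sigma = sigma, gain = mean(amps) / 7)
}

# Peak Ca (nM) producing a noiseless green increment `dg` (counts) on a
# resting cell, via the Hill response: dG = (B/5) (f(P)/f(b0) - 1).
#' @noRd
.peak_ca_for_increment <- function(dg, cell, indicator = salsa6f_hill("steady")) {
  f0 <- .green_fraction(cell$baseline_ca_nM, indicator)
  f <- f0 * (1 + 5 * dg / cell$red_brightness)
  .chk(f < 0.999,
       "requested sparkle increment exceeds the indicator's dynamic range; raise red_brightness or lower the target")
  indicator$kd_nM * (f / (1 - f))^(1 / indicator$hill_n)
}

#' Sparkle-recovery benchmark scene
#'
#' A seeded movie of motile T cells carrying ground-truth 2 x 2-pixel
#' sparkles of 1-2 frame duration whose measured amplitudes span a
#' prescribed SD band (default 6-8 SD, bracketing the ~6.5 SD mean sparkle
#' amplitude seen in tissue), under Gaussian read noise at 0.684 um/px.
#'
#' @param seed integer seed.
#' @param n_frames movie length in frames (default 300, a 25-min session at
#'   5 s/stack).
#' @param fov_px field of view (default 128 x 128 px).
#' @param n_cells number of cells.
#' @param n_sparkles number of ground-truth sparkles (spread round-robin
#'   over cells, separated in time within each cell).
#' @param amp_range target per-pixel amplitude band in SD units.
#' @param read_noise_sd Gaussian read noise (counts).
#' @param background_counts uniform background level (counts).
#' @param pixel_size_um lateral resolution (default 0.684).
#' @return List with `params`, `cells`, `events`, `calibration` (the
#'   [calibrate_sparkle_response()] result) and `target_amplitude_sd`.
#' @export
sparkle_benchmark_scene <- function(seed = 1, n_frames = 300,
                                    fov_px = c(128, 128), n_cells = 5,
                                    n_sparkles = 60, amp_range = c(6, 8),
                                    read_noise_sd = 20,
                                    background_counts = 100,
                                    pixel_size_um = 0.684) {
  params <- acquisition_params(fov_px = fov_px, n_frames = n_frames,
                               pixel_size_um = pixel_size_um,
                               read_noise_sd = read_noise_sd,
                               background_counts = background_counts,
                               seed = seed)
  ref <- cell_spec(1)
  cal <- calibrate_sparkle_response(params, ref, seed = .sub_seed(seed, 77))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(.sub_seed(seed, 78))

  Lx <- fov_px[2] * pixel_size_um; Ly <- fov_px[1] * pixel_size_um
  grid_n <- ceiling(sqrt(n_cells))
  gx <- (seq_len(grid_n) - 0.5) / grid_n * Lx
  gy <- (seq_len(grid_n) - 0.5) / grid_n * Ly
  centres <- expand.grid(x = gx, y = gy)[seq_len(n_cells), ]
  cells <- lapply(seq_len(n_cells), function(i)
    cell_spec(i, center_um = c(centres$x[i], centres$y[i]) +
                stats::runif(2, -2, 2)))

  amps <- stats::runif(n_sparkles, amp_range[1], amp_range[2])
  durs <- rep(c(1L, 2L), length.out = n_sparkles)
  host <- rep(seq_len(n_cells), length.out = n_sparkles)
  events <- vector("list", n_sparkles)
  for (i in seq_len(n_sparkles)) {
    per_cell <- sum(host == host[i])
    k <- sum(host[seq_len(i)] == host[i])          # index within this cell
    slot <- floor((n_frames - 6) / per_cell)
    start <- 3 + (k - 1) * slot + sample.int(max(slot - 3, 1), 1)
    ang <- stats::runif(1, 0, 2 * pi)
    dg <- amps[i] * cal$sigma / cal$gain
    events[[i]] <- ca_event_spec("local", host[i], start, durs[i],
                                 .peak_ca_for_increment(dg, cells[[host[i]]]),
                                 offset_um = 2.4 * c(cos(ang), sin(ang)))
  }
  list(params = params, cells = cells, events = events,
       calibration = cal, target_amplitude_sd = amps)
}

#' Pure-noise control movie
#'
#' A movie with no cells and no events, only detector noise: the white-noise
#' control on which the sparkle detector should essentially never fire at
#' the 5.4 SD / 3-pixel setting.
#'
#' @param seed integer seed.
#' @param n_frames,fov_px,n_z geometry (defaults give 4e6 pixel-frames).
#' @param read_noise_sd Gaussian read noise (counts).
#' @param background_counts uniform background level (counts).
#' @param pixel_size_um lateral resolution.
#' @return A [movie_bundle].
#' @export
white_noise_movie <- function(seed = 1, n_frames = 100, fov_px = c(200, 200),
                              n_z = 1, read_noise_sd = 20,
                              background_counts = 100,
                              pixel_size_um = 0.684) {
  params <- acquisition_params(fov_px = fov_px, n_frames = n_frames,
                               n_z = n_z, pixel_size_um = pixel_size_um,
                               read_noise_sd = read_noise_sd,
                               background_counts = background_counts,
                               seed = seed)
  render_movie(list(), list(), list(), params, seed = seed)
}

#' Build a scene from pipeline configuration
#'
#' Constructs cells, Ca2+ events and autofluorescent objects from the
#' `scene:` section of a pipeline config (see [run_pipeline()]). Sparkle
#' amplitudes are either given directly as `sparkle_peak_ca_nM` or placed in
#' a measured SD band via `sparkle_amp_range` (requires nonzero noise).
#'
#' @param scene named list, the `scene:` config section.
#' @param params an [acquisition_params].
#' @param seed integer seed.
#' @return List with `cells`, `events`, `autofluor`.
#' @export
build_scene <- function(scene, params, seed = params$seed) {
  n_cells <- scene$n_cells %||% 2L
  n_sparkles <- scene$n_sparkles %||% 0L
  n_cellwide <- scene$n_cellwide %||% 0L
  n_autofluor <- scene$n_autofluor %||% 0L
  cargs <- scene$cell %||% list()
  cw_dur <- scene$cellwide_duration_frames %||% 2
  # cell-wide events live in a reserved tail segment so sparkles never
  # coincide with them by construction
  cw_span <- if (n_cellwide > 0) n_cellwide * (cw_dur + 2) + 1 else 0
  sparkle_end <- params$n_frames - cw_span
  .chk(sparkle_end >= 4 || n_sparkles == 0,
       "movie too short for the requested events")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(.sub_seed(seed, 55))

  Lx <- params$fov_px[2] * params$pixel_size_um
  Ly <- params$fov_px[1] * params$pixel_size_um
  grid_n <- max(ceiling(sqrt(n_cells + n_autofluor)), 1)
  gx <- (seq_len(grid_n) - 0.5) / grid_n * Lx
  gy <- (seq_len(grid_n) - 0.5) / grid_n * Ly
  centres <- expand.grid(x = gx, y = gy)

  cells <- lapply(seq_len(n_cells), function(i)
    do.call(cell_spec, c(list(id = i,
                              center_um = c(centres$x[i], centres$y[i])),
                         cargs)))

  events <- list()
  if (n_sparkles > 0) {
    .chk(n_cells > 0, "sparkles need at least one cell")
    peak <- scene$sparkle_peak_ca_nM
    cal <- NULL
    if (is.null(peak)) {
      rng <- scene$sparkle_amp_range %||% c(6, 8)
      cal <- calibrate_sparkle_response(params, cells[[1]], .sub_seed(seed, 77))
      .chk(cal$sigma > 0, "sparkle_amp_range requires a noisy acquisition; give sparkle_peak_ca_nM instead")
    }
    dur <- scene$sparkle_duration_frames %||% c(1, 2)
    host <- rep(seq_len(n_cells), length.out = n_sparkles)
    for (i in seq_len(n_sparkles)) {
      per_cell <- sum(host == host[i])
      k <- sum(host[seq_len(i)] == host[i])
      slot <- max(floor((sparkle_end - 4) / per_cell), 1)
      start <- min(2 + (k - 1) * slot + sample.int(max(slot - 2, 1), 1),
                   sparkle_end - max(dur) + 1)
      ang <- stats::runif(1, 0, 2 * pi)
      pk <- if (!is.null(peak)) peak else
        .peak_ca_for_increment(stats::runif(1, rng[1], rng[2]) * cal$sigma / cal$gain,
                               cells[[host[i]]])
      events[[length(events) + 1L]] <-
        ca_event_spec("local", host[i], start,
                      sample(rep(dur, 2), 1), pk,
                      offset_um = 2.4 * c(cos(ang), sin(ang)))
    }
  }
  if (n_cellwide > 0) {
    pk <- scene$cellwide_peak_ca_nM %||% 1000
    host <- rep(rev(seq_len(n_cells)), length.out = n_cellwide)
    for (i in seq_len(n_cellwide)) {
      start <- min(sparkle_end + 1 + (i - 1) * (cw_dur + 2),
                   params$n_frames - cw_dur + 1)
      events[[length(events) + 1L]] <-
        ca_event_spec("cell_wide", host[i], start, cw_dur, pk)
    }
  }

  aargs <- scene$autofluor %||% list()
  autofluor <- lapply(seq_len(n_autofluor), function(j)
    do.call(autofluor_spec,
            c(list(center_um = c(centres$x[n_cells + j], centres$y[n_cells + j])),
              aargs)))
  list(cells = cells, events = events, autofluor = autofluor)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
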