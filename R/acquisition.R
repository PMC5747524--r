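#' Acquisition parameters for a two-channel time-lapse movie
#'
#' Describes the imaging geometry and noise model of a (real or simulated)
#' two-photon recording: lateral pixel size, z-spacing and number of optical
#' sections, frame interval, field of view, and the photon/read-noise model
#' used when synthesising movies. Defaults follow common two-photon lymph-node
#' protocols: 0.684 um/pixel (0.488 is the usual alternative), six optical
#' sections 4 um apart, one stack every 5 s.
#'
#' @param fov_px integer length-2, field of view in pixels `c(height, width)`.
#' @param n_frames number of time points (stacks) in the movie.
#' @param pixel_size_um lateral pixel size in micrometres.
#' @param z_step_um spacing between optical sections in micrometres.
#' @param n_z number of optical sections per stack.
#' @param frame_interval_s time between consecutive stacks in seconds.
#' @param photon_scale expected photons per intensity count; shot noise is
#'   simulated as `Poisson(photon_scale * I) / photon_scale`. `Inf` (or 0)
#'   disables shot noise.
#' @param read_noise_sd standard deviation of additive Gaussian read noise,
#'   in intensity counts.
#' @param background_counts uniform background level (counts) added to both
#'   channels before noise, emulating detector offset plus diffuse tissue
#'   fluorescence; keeps the noise floor symmetric (no clipping at zero).
#' @param bit_depth detector bit depth; intensities live in
#'   `[0, 2^bit_depth - 1]`.
#' @param seed integer seed controlling all randomness derived from these
#'   parameters.
#'
#' @return An object of class `acquisition_params`.
#' @examples
#' acquisition_params(fov_px = c(64, 64), n_frames = 10)
#' @export
acquisition_params <- function(fov_px, n_frames,
                               pixel_size_um = 0.684,
                               z_step_um = 4,
                               n_z = 6,
                               frame_interval_s = 5,
                               photon_scale = Inf,
                               read_noise_sd = 0,
                               background_counts = 0,
                               bit_depth = 16,
                               seed = 1L) {
  fov_px <- as.integer(fov_px)
  .chk(length(fov_px) == 2 && all(fov_px >= 16), "fov_px must be two integers >= 16")
  .chk(is.numeric(n_frames) && n_frames >= 1, "n_frames must be >= 1")
  .chk(pixel_size_um > 0, "pixel_size_um must be positive")
  .chk(z_step_um > 0, "z_step_um must be positive")
  .chk(n_z >= 1, "n_z must be >= 1")
  .chk(frame_interval_s > 0, "frame_interval_s must be positive")
  .chk(photon_scale >= 0, "photon_scale must be non-negative")
  .chk(read_noise_sd >= 0, "read_noise_sd must be non-negative")
  .chk(background_counts >= 0, "background_counts must be non-negative")
  .chk(bit_depth >= 1, "bit_depth must be >= 1")
  structure(list(
    fov_px = fov_px,
    n_frames = as.integer(n_frames),
    pixel_size_um = pixel_size_um,
    z_step_um = z_step_um,
    n_z = as.integer(n_z),
    frame_interval_s = frame_interval_s,
    photon_scale = photon_scale,
    read_noise_sd = read_noise_sd,
    background_counts = background_counts,
    bit_depth = as.integer(bit_depth),
    seed = as.integer(seed)
  ), class = "acquisition_params")
}

#' @export
print.acquisition_params <- function(x, ...) {
  cat("Acquisition parameters\n")
  cat(sprintf("  field of view : %d x %d px (%.1f x %.1f um at %.3f um/px)\n",
              x$fov_px[1], x$fov_px[2],
              x$fov_px[1] * x$pixel_size_um, x$fov_px[2] * x$pixel_size_um,
              x$pixel_size_um))
  cat(sprintf("  z             : %d sections, %.1f um apart\n", x$n_z, x$z_step_um))
  cat(sprintf("  time          : %d frames, one stack every %.1f s\n",
              x$n_frames, x$frame_interval_s))
  cat(sprintf("  noise         : photon_scale = %s, read_noise_sd = %.3g, %d-bit\n",
              format(x$photon_scale), x$read_noise_sd, x$bit_depth))
  invisible(x)
}

# z positions (um) of the optical sections, first section at z = 0.
#' @noRd
.z_positions <- function(params) (seq_len(params$n_z) - 1) * params$z_step_um

#' @noRd
.intensity_max <- function(params) 2^params$bit_depth - 1
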