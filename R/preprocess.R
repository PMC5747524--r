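# Image conditioning chain: median filtering, z max-projection, temporal
# averaging, Bernsen autofluorescence masking with dilation and manual
# exclusions, scaled red-channel subtraction, temporal-mean subtraction.

#' Preprocessing configuration
#'
#' Defaults reproduce the standard ratiometric conditioning chain: 1-pixel
#' radius median filter, Bernsen local thresholding with a 5-pixel radius on
#' the temporal averages, 4-pixel mask dilation, and subtraction of a 0.2x
#' scaled red image (the measured resting red:green ratio of 5:1), followed
#' by temporal-mean subtraction.
#'
#' @param median_radius_px radius of the median filter (>= 1).
#' @param median_shape `"disc"` (default; at radius 1 the 5-pixel cross,
#'   which preserves 2 x 2-pixel features) or `"square"`.
#' @param bernsen_radius_px radius of the Bernsen neighbourhood.
#' @param bernsen_contrast_8bit Bernsen contrast threshold expressed on an
#'   8-bit scale (the classical default 15); rescaled internally to the
#'   image bit depth.
#' @param mask_dilation_px dilation of the autofluorescence mask in pixels.
#' @param red_scale scale applied to the red image before subtraction from
#'   the green image; 0.2 encodes the 5:1 resting ratio.
#' @param manual_exclusions list of regions excluded from analysis: each
#'   element either a numeric vector `c(row_min, row_max, col_min, col_max)`
#'   (axis-aligned box) or an `n x 2` matrix of polygon vertices in
#'   `(row, col)` pixel coordinates.
#' @param mask_autofluor logical; apply the Bernsen autofluorescence mask.
#' @param mean_after_red_subtraction logical; if TRUE (default) the temporal
#'   mean removed at the final step is the mean of the red-subtracted green
#'   stack, otherwise the mean of the raw green projection.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(median_radius_px = 1,
                              median_shape = c("disc", "square"),
                              bernsen_radius_px = 5,
                              bernsen_contrast_8bit = 15,
                              mask_dilation_px = 4,
                              red_scale = 0.2,
                              manual_exclusions = list(),
                              mask_autofluor = TRUE,
                              mean_after_red_subtraction = TRUE) {
  median_shape <- match.arg(median_shape)
  .chk(median_radius_px >= 1, "median_radius_px must be >= 1")
  .chk(bernsen_radius_px >= 1, "bernsen_radius_px must be >= 1")
  .chk(bernsen_contrast_8bit > 0, "bernsen_contrast_8bit must be positive")
  .chk(mask_dilation_px >= 0, "mask_dilation_px must be >= 0")
  .chk(red_scale >= 0, "red_scale must be non-negative")
  structure(list(median_radius_px = as.integer(median_radius_px),
                 median_shape = median_shape,
                 bernsen_radius_px = as.integer(bernsen_radius_px),
                 bernsen_contrast_8bit = bernsen_contrast_8bit,
                 mask_dilation_px = as.integer(mask_dilation_px),
                 red_scale = red_scale,
                 manual_exclusions = manual_exclusions,
                 mask_autofluor = isTRUE(mask_autofluor),
                 mean_after_red_subtraction = isTRUE(mean_after_red_subtraction)),
            class = "preprocess_config")
}

#' Median filter a 2-D image
#'
#' Each pixel is replaced by the median of its neighbourhood (disc of radius
#' `radius_px`, or `(2r+1)^2` square), with mirror-padded borders. At radius
#' 1 the disc is the 5-pixel cross; the 9-pixel square is available but
#' erases isolated 2 x 2-pixel features (at most 4 of its 9 samples can lie
#' on such a feature), so the disc is the default.
#'
#' @param image numeric matrix.
#' @param radius_px filter radius (>= 1).
#' @param shape `"disc"` or `"square"`.
#' @return Filtered matrix of the same shape.
#' @export
median_filter <- function(image, radius_px = 1, shape = c("disc", "square")) {
  shape <- match.arg(shape)
  .chk(is.matrix(image), "image must be a 2-D matrix")
  .chk(radius_px >= 1, "radius_px must be >= 1")
  off <- if (shape == "disc") .disc_offsets(radius_px) else .square_offsets(radius_px)
  .elementwise_median(.shifted_copies(image, off, radius_px))
}

#' Maximum-intensity projection over z
#'
#' @param stack 4-D `T x Z x Y x X` array (or 3-D `Z x Y x X` for a single
#'   frame).
#' @return `T x Y x X` array (or `Y x X` matrix) of per-pixel maxima over z.
#' @export
max_project_z <- function(stack) {
  d <- dim(stack)
  .chk(!is.null(d) && length(d) %in% c(3, 4), "stack must be Z x Y x X or T x Z x Y x X")
  if (length(d) == 3) {
    .chk(d[1] >= 1, "empty z dimension")
    out <- stack[1, , ]
    if (d[1] > 1) for (z in 2:d[1]) out <- pmax(out, stack[z, , ])
    return(matrix(out, d[2], d[3]))
  }
  .chk(d[2] >= 1, "empty z dimension")
  out <- array(stack[, 1, , ], dim = d[c(1, 3, 4)])
  if (d[2] > 1) for (z in 2:d[2]) out <- pmax(out, array(stack[, z, , ], dim = d[c(1, 3, 4)]))
  out
}

#' Temporal average of a projected stack
#'
#' @param stack `T x Y x X` array.
#' @return `Y x X` matrix of per-pixel means over frames.
#' @export
temporal_average <- function(stack) {
  d <- dim(stack)
  .chk(length(d) == 3 && d[1] >= 1, "stack must be a T x Y x X array with T >= 1")
  matrix(colMeans(matrix(stack, d[1], d[2] * d[3])), d[2], d[3])
}

#' Bernsen local thresholding
#'
#' Classifies bright objects: with local neighbourhood minimum `m` and
#' maximum `M` over a disc of `radius_px`, a pixel is foreground iff the
#' local contrast `M - m` reaches `contrast` and the pixel value exceeds the
#' midgrey `(m + M) / 2`; low-contrast neighbourhoods are background.
#'
#' @param image numeric matrix (typically a temporal average).
#' @param radius_px neighbourhood radius, default 5.
#' @param contrast positive contrast threshold on the image's intensity
#'   scale.
#' @return Logical matrix, TRUE on bright objects.
#' @export
bernsen_mask <- function(image, radius_px = 5, contrast) {
  .chk(is.matrix(image), "image must be a 2-D matrix")
  .chk(contrast > 0, "contrast must be positive")
  off <- .disc_offsets(radius_px)
  shifts <- .shifted_copies(image, off, radius_px)
  m <- .elementwise_min(shifts)
  M <- .elementwise_max(shifts)
  (M - m >= contrast) & (image > (m + M) / 2)
}

#' Morphological dilation of a binary mask
#'
#' Dilation with a disc structuring element of radius `n_px`; the output
#' always contains the input. `n_px = 0` is the identity.
#'
#' @param mask logical matrix.
#' @param n_px dilation radius in pixels (>= 0).
#' @return Logical matrix.
#' @export
dilate_mask <- function(mask, n_px = 4) {
  .chk(is.matrix(mask) && is.logical(mask), "mask must be a logical matrix")
  .chk(n_px >= 0, "n_px must be >= 0")
  if (n_px == 0) return(mask)
  H <- nrow(mask); W <- ncol(mask)
  off <- .disc_offsets(n_px)
  out <- matrix(FALSE, H, W)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(out)
  for (i in seq_len(nrow(off))) {
    r <- idx[, 1] + off$dy[i]
    c <- idx[, 2] + off$dx[i]
    keep <- r >= 1 & r <= H & c >= 1 & c <= W
    out[cbind(r[keep], c[keep])] <- TRUE
  }
  out
}

#' @noRd
.manual_region_mask <- function(regions, H, W) {
  out <- matrix(FALSE, H, W)
  for (rg in regions) {
    if (is.matrix(rg)) {
      .chk(ncol(rg) == 2 && nrow(rg) >= 3, "polygon region must be an n x 2 matrix")
      .chk(all(rg[, 1] >= 1 & rg[, 1] <= H & rg[, 2] >= 1 & rg[, 2] <= W),
           "manual region outside field")
      ys <- rg[, 1]; xs <- rg[, 2]
      rows <- matrix(seq_len(H), H, W)
      cols <- matrix(seq_len(W), H, W, byrow = TRUE)
      inside <- matrix(FALSE, H, W)
      j <- nrow(rg)
      for (i in seq_len(nrow(rg))) {        # even-odd crossing rule
        cross <- ((ys[i] > rows) != (ys[j] > rows)) &
          (cols < (xs[j] - xs[i]) * (rows - ys[i]) / (ys[j] - ys[i]) + xs[i])
        inside <- xor(inside, cross)
        j <- i
      }
      out <- out | inside
    } else {
      .chk(length(rg) == 4, "box region must be c(row_min,row_max,col_min,col_max)")
      .chk(rg[1] >= 1 && rg[2] <= H && rg[3] >= 1 && rg[4] <= W && rg[1] <= rg[2] && rg[3] <= rg[4],
           "manual region outside field")
      out[rg[1]:rg[2], rg[3]:rg[4]] <- TRUE
    }
  }
  out
}

#' Build the analysis mask from temporal averages
#'
#' Autofluorescent objects (bright in the averaged red or green image) are
#' found by Bernsen thresholding, dilated, united with any manual exclusion
#' regions, and complemented: the analysis mask is TRUE where pixels are
#' analyzable.
#'
#' @param red_avg,green_avg temporally averaged projected images (same
#'   shape).
#' @param config a [preprocess_config].
#' @param bit_depth detector bit depth used to rescale the 8-bit Bernsen
#'   contrast default to native intensity units.
#' @return Logical `Y x X` matrix, TRUE = analyzable.
#' @export
build_analysis_mask <- function(red_avg, green_avg, config = preprocess_config(),
                                bit_depth = 16) {
  .chk(identical(dim(red_avg), dim(green_avg)), "averaged images must share shape")
  H <- nrow(red_avg); W <- ncol(red_avg)
  excl <- matrix(FALSE, H, W)
  if (config$mask_autofluor) {
    contrast <- config$bernsen_contrast_8bit / 255 * (2^bit_depth - 1)
    b <- bernsen_mask(red_avg, config$bernsen_radius_px, contrast) |
      bernsen_mask(green_avg, config$bernsen_radius_px, contrast)
    excl <- dilate_mask(b, config$mask_dilation_px)
  }
  excl <- excl | .manual_region_mask(config$manual_exclusions, H, W)
  !excl
}

#' Subtract a scaled red image from a green image
#'
#' `green - red_scale * red`, unclipped (values may be negative: the signed
#' zero-mean background is exactly what the SD thresholds assume). At the
#' default scale 0.2 a resting cell, whose red fluorescence is fivefold its
#' green, is nulled.
#'
#' @param green_frame,red_frame numeric matrices/arrays of identical shape.
#' @param red_scale non-negative scale, default 0.2.
#' @return Signed array of the same shape.
#' @export
subtract_scaled_red <- function(green_frame, red_frame, red_scale = 0.2) {
  .chk(identical(dim(green_frame), dim(red_frame)), "shape mismatch")
  .chk(red_scale >= 0, "red_scale must be non-negative")
  green_frame - red_scale * red_frame
}

#' Subtract the per-pixel temporal mean from a stack
#'
#' @param stack `T x Y x X` array with `T >= 2`.
#' @return Signed array whose per-pixel temporal mean is zero.
#' @export
subtract_temporal_mean <- function(stack) {
  d <- dim(stack)
  .chk(length(d) == 3 && d[1] >= 2, "stack must be T x Y x X with T >= 2")
  m <- temporal_average(stack)
  stack - rep(m, each = d[1])
}

#' Run the full preprocessing chain on a movie
#'
#' Applies, in order: per-plane median filtering of both channels, maximum
#' intensity z-projection, analysis-mask construction from the temporal
#' averages, scaled red subtraction, and temporal-mean subtraction. Pixels
#' outside the analysis mask are set to `NA` in the processed green stack
#' and excluded from all downstream statistics.
#'
#' @param bundle a [movie_bundle].
#' @param config a [preprocess_config].
#' @return An object of class `processed_movie` with components
#'   `processed_green` (`T x Y x X`, signed, `NA` outside the mask),
#'   `projected_red` (`T x Y x X`), `analysis_mask` (`Y x X` logical),
#'   `provenance` (ordered character vector of applied steps), `params`, and
#'   `config`.
#' @export
preprocess <- function(bundle, config = preprocess_config()) {
  .chk(inherits(bundle, "movie_bundle"), "bundle must be a movie_bundle")
  p <- bundle$params
  n <- p$n_frames; nz <- p$n_z
  H <- p$fov_px[1]; W <- p$fov_px[2]
  prov <- character(0)

  red_proj <- array(0, dim = c(n, H, W))
  green_proj <- array(0, dim = c(n, H, W))
  for (t in seq_len(n)) {
    rplanes <- lapply(seq_len(nz), function(z)
      median_filter(matrix(bundle$red[t, z, , ], H, W),
                    config$median_radius_px, config$median_shape))
    gplanes <- lapply(seq_len(nz), function(z)
      median_filter(matrix(bundle$green[t, z, , ], H, W),
                    config$median_radius_px, config$median_shape))
    red_proj[t, , ] <- .elementwise_max(rplanes)
    green_proj[t, , ] <- .elementwise_max(gplanes)
  }
  prov <- c(prov,
            sprintf("median_filter(radius=%d, shape=%s) per z-plane, both channels",
                    config$median_radius_px, config$median_shape),
            "max_project_z both channels")

  red_avg <- temporal_average(red_proj)
  green_avg <- temporal_average(green_proj)
  mask <- build_analysis_mask(red_avg, green_avg, config, p$bit_depth)
  prov <- c(prov,
            sprintf("build_analysis_mask(bernsen_radius=%d, contrast_8bit=%g, dilation=%d, manual=%d region(s))",
                    config$bernsen_radius_px, config$bernsen_contrast_8bit,
                    config$mask_dilation_px, length(config$manual_exclusions)))

  g <- subtract_scaled_red(green_proj, red_proj, config$red_scale)
  prov <- c(prov, sprintf("subtract_scaled_red(red_scale=%g)", config$red_scale))

  if (config$mean_after_red_subtraction) {
    g <- subtract_temporal_mean(g)
    prov <- c(prov, "subtract_temporal_mean(of red-subtracted green)")
  } else {
    g <- g - rep(green_avg, each = n)
    prov <- c(prov, "subtract_temporal_mean(of raw green projection)")
  }

  g[rep(!mask, each = n)] <- NA_real_

  structure(list(processed_green = g, projected_red = red_proj,
                 analysis_mask = mask, provenance = prov,
                 params = p, config = config),
            class = "processed_movie")
}

#' @export
print.processed_movie <- function(x, ...) {
  d <- dim(x$processed_green)
  cat(sprintf("Processed movie: %d frames x %d x %d px, %.1f%% analyzable\n",
              d[1], d[2], d[3], 100 * mean(x$analysis_mask)))
  cat("Provenance:\n")
  for (s in x$provenance) cat("  -", s, "\n")
  invisible(x)
}

#' Estimate the red-subtraction scale from resting frames
#'
#' Robust (least absolute deviation via iterated reweighting) regression of
#' projected green on projected red over analyzable pixels, for sessions
#' where the 5:1 resting ratio needs re-estimating. The pipeline default
#' remains the fixed 0.2.
#'
#' @param red_proj,green_proj projected `T x Y x X` stacks.
#' @param mask optional logical `Y x X` analysis mask.
#' @return Estimated scale (scalar).
#' @export
estimate_red_scale <- function(red_proj, green_proj, mask = NULL) {
  .chk(identical(dim(red_proj), dim(green_proj)), "shape mismatch")
  keep <- if (is.null(mask)) rep(TRUE, length(red_proj))
          else rep(as.vector(mask), each = dim(red_proj)[1])
  x <- as.numeric(red_proj[keep]); y <- as.numeric(green_proj[keep])
  sel <- x > stats::quantile(x, 0.5)   # regress on pixels carrying signal
  x <- x[sel]; y <- y[sel]
  b <- stats::median(y / x)
  for (i in 1:5) {
    w <- 1 / pmax(abs(y - b * x), 1e-6)
    b <- sum(w * x * y) / sum(w * x^2)
  }
  b
}
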