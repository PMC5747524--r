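# Front/back polarity analysis: split a motile cell's footprint along its
# motion vector and compare ratiometric pixel values between the halves with
# a Mann-Whitney test.

#' Motion direction of a cell over a frame window
#'
#' Unit vector of the centroid displacement from `frame` to
#' `frame + window_frames`. Polarity is undefined for a stationary cell.
#'
#' @param path `n x 2` matrix of centroid positions (um), as returned by
#'   [simulate_motility()].
#' @param frame starting frame (1-based).
#' @param window_frames displacement window; `frame + window_frames` must
#'   not exceed the path length.
#' @return Length-2 unit vector `(x, y)`.
#' @export
motion_vector <- function(path, frame, window_frames) {
  .chk(frame >= 1 && frame + window_frames <= nrow(path),
       "window outside path bounds")
  d <- path[frame + window_frames, ] - path[frame, ]
  nd <- sqrt(sum(d^2))
  .chk(nd > 0, "zero displacement: polarity undefined")
  unname(d / nd)
}

#' Split a cell mask into front and back halves
#'
#' Pixels are assigned by the sign of the dot product between the pixel
#' offset from the centroid and the motion unit vector: positive offsets are
#' front, negative back; pixels exactly on the dividing line go to the front
#' (fixed tie rule). Front and back partition the mask.
#'
#' @param cell_mask logical `Y x X` matrix.
#' @param centroid `c(x, y)` centroid in pixel units (may be fractional;
#'   pixel `(r, c)` sits at `(c, r)`).
#' @param unit_vector `c(x, y)` motion direction.
#' @return List with logical matrices `front` and `back`.
#' @export
split_front_back <- function(cell_mask, centroid, unit_vector) {
  .chk(is.matrix(cell_mask) && any(cell_mask), "cell mask must be non-empty")
  nv <- sqrt(sum(unit_vector^2))
  .chk(is.finite(nv) && nv > 0, "invalid unit vector")
  u <- unit_vector / nv
  H <- nrow(cell_mask); W <- ncol(cell_mask)
  px <- matrix(seq_len(W), H, W, byrow = TRUE)   # x = column
  py <- matrix(seq_len(H), H, W)                 # y = row
  dot <- (px - centroid[1]) * u[1] + (py - centroid[2]) * u[2]
  front <- cell_mask & dot >= 0
  back <- cell_mask & dot < 0
  list(front = front, back = back)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test with midranks for ties. The null distribution is
#' enumerated exactly (all labelings of the combined sample) when
#' `n_a + n_b <= exact_limit`, otherwise the normal approximation with tie
#' correction is used. The two-sided p doubles the smaller tail, capped at
#' 1.
#'
#' @param a,b numeric samples (each non-empty).
#' @param exact_limit switch from exact enumeration to the normal
#'   approximation when the combined size exceeds this (default 16).
#' @return List with `U` (statistic for sample `a`), `p`, `method`,
#'   `n_a`, `n_b`.
#' @export
mann_whitney <- function(a, b, exact_limit = 16) {
  .chk(length(a) >= 1 && length(b) >= 1, "both samples must be non-empty")
  na <- length(a); nb <- length(b); N <- na + nb
  v <- c(a, b)
  r <- rank(v)                                   # midranks
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (N <= exact_limit) {
    sets <- utils::combn(N, na)
    us <- colSums(matrix(r[sets], nrow = na)) - na * (na + 1) / 2
    eps <- 1e-9
    p_lo <- mean(us <= U + eps)
    p_hi <- mean(us >= U - eps)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact enumeration"
  } else {
    ties <- table(v)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- na * nb / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1   # every observation tied: no evidence either way
    } else {
      z <- (U - na * nb / 2) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal approximation, tie-corrected"
  }
  list(U = U, p = p, method = method, n_a = na, n_b = nb)
}

#' Front/back polarity comparison of a ratiometric image
#'
#' Composes [motion_vector()], [split_front_back()] and [mann_whitney()]:
#' extracts per-pixel G/R ratio values from the front and back halves of a
#' cell footprint (split perpendicular to the motion direction through the
#' centroid) and compares them with a two-sided Mann-Whitney test.
#'
#' @param ratio_image `Y x X` matrix of G/R ratios (NA allowed; NA pixels
#'   are dropped).
#' @param cell_mask logical `Y x X` cell footprint at `frame`.
#' @param path cell centroid path in um (`n x 2`).
#' @param frame frame at which the mask was taken.
#' @param window displacement window in frames for the motion vector.
#' @param pixel_size_um pixel size converting the path to pixel units.
#' @return An object of class `polarity_result`: front/back pixel values,
#'   medians, `U`, `p`, and the pixel counts.
#' @export
polarity_report <- function(ratio_image, cell_mask, path, frame, window,
                            pixel_size_um) {
  u <- motion_vector(path, frame, window)
  centroid_px <- path[frame, ] / pixel_size_um + 0.5
  halves <- split_front_back(cell_mask, centroid_px, u)
  fv <- ratio_image[halves$front]; fv <- fv[!is.na(fv)]
  bv <- ratio_image[halves$back]; bv <- bv[!is.na(bv)]
  .chk(length(fv) >= 1 && length(bv) >= 1,
       "front or back half has no usable pixels")
  mw <- mann_whitney(fv, bv)
  structure(list(front = fv, back = bv,
                 median_front = stats::median(fv),
                 median_back = stats::median(bv),
                 U = mw$U, p = mw$p, method = mw$method,
                 n_front = length(fv), n_back = length(bv),
                 unit_vector = u),
            class = "polarity_result")
}

#' @export
print.polarity_result <- function(x, ...) {
  cat("Front/back polarity comparison\n")
  cat(sprintf("  front: n = %d, median = %.4g\n", x$n_front, x$median_front))
  cat(sprintf("  back : n = %d, median = %.4g\n", x$n_back, x$median_back))
  cat(sprintf("  Mann-Whitney U = %g, p = %.3g (%s)\n", x$U, x$p, x$method))
  invisible(x)
}
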