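# Internal helpers shared across modules: neighbourhood offsets, mirror
# padding, and vectorised rank filtering via shifted copies of the image.

#' @noRd
.chk <- function(cond, msg, call. = FALSE) {
  if (!isTRUE(cond)) stop(msg, call. = call.)
}

# Integer offsets (dy, dx) of a disc of radius r (dy^2 + dx^2 <= r^2).
# r = 1 gives the 5-pixel cross.
#' @noRd
.disc_offsets <- function(r) {
  s <- -r:r
  g <- expand.grid(dy = s, dx = s)
  g[g$dy^2 + g$dx^2 <= r^2, , drop = FALSE]
}

#' @noRd
.square_offsets <- function(r) {
  s <- -r:r
  expand.grid(dy = s, dx = s)
}

# Symmetric (edge-inclusive) reflection of out-of-range indices.
#' @noRd
.reflect_idx <- function(p, n) {
  for (i in 1:4) {
    p <- ifelse(p < 1L, 1L - p + 1L - 1L, p)   # p < 1 -> 1 - p (symmetric)
    p <- ifelse(p > n, 2L * n + 1L - p, p)
  }
  p
}

# Pad a matrix by r pixels on every side, mirror (symmetric) boundary.
#' @noRd
.pad_mirror <- function(img, r) {
  n <- nrow(img); m <- ncol(img)
  img[.reflect_idx(seq.int(1L - r, n + r), n),
      .reflect_idx(seq.int(1L - r, m + r), m), drop = FALSE]
}

# List of shifted copies of img (one per offset row), mirror-padded so each
# copy has the original dimensions.
#' @noRd
.shifted_copies <- function(img, offsets, r) {
  n <- nrow(img); m <- ncol(img)
  P <- .pad_mirror(img, r)
  lapply(seq_len(nrow(offsets)), function(i) {
    dy <- offsets$dy[i]; dx <- offsets$dx[i]
    P[(1 + r + dy):(n + r + dy), (1 + r + dx):(m + r + dx), drop = FALSE]
  })
}

# Exact elementwise median over a list of equal-shaped matrices, computed by
# a full pmin/pmax exchange sort (vectorised, no per-pixel loop).
#' @noRd
.elementwise_median <- function(mats) {
  k <- length(mats)
  for (i in seq_len(k - 1L)) {
    for (j in seq_len(k - i)) {
      lo <- pmin(mats[[j]], mats[[j + 1L]])
      hi <- pmax(mats[[j]], mats[[j + 1L]])
      mats[[j]] <- lo
      mats[[j + 1L]] <- hi
    }
  }
  if (k %% 2L == 1L) mats[[(k + 1L) / 2L]] else (mats[[k / 2L]] + mats[[k / 2L + 1L]]) / 2
}

#' @noRd
.elementwise_min <- function(mats) Reduce(pmin, mats)

#' @noRd
.elementwise_max <- function(mats) Reduce(pmax, mats)

# Derive a stream-specific RNG seed from a user seed, kept below 2^31.
#' @noRd
.sub_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + k * 7919) %% 2147483647
}
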