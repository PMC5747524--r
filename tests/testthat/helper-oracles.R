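# Brute-force oracles, written independently of the package internals:
# plain double loops and recursive flood fill on small images.

reflect1 <- function(p, n) {
  while (p < 1 || p > n) {
    if (p < 1) p <- 1 - p
    if (p > n) p <- 2 * n + 1 - p
  }
  p
}

neighborhood_vals <- function(img, r0, c0, offsets) {
  vapply(seq_len(nrow(offsets)), function(k) {
    img[reflect1(r0 + offsets[k, 1], nrow(img)),
        reflect1(c0 + offsets[k, 2], ncol(img))]
  }, numeric(1))
}

oracle_offsets <- function(radius, shape) {
  g <- as.matrix(expand.grid(-radius:radius, -radius:radius))
  if (shape == "disc") g <- g[g[, 1]^2 + g[, 2]^2 <= radius^2, , drop = FALSE]
  g
}

median_oracle <- function(img, radius, shape) {
  off <- oracle_offsets(radius, shape)
  out <- img
  for (r in seq_len(nrow(img))) for (c in seq_len(ncol(img)))
    out[r, c] <- stats::median(neighborhood_vals(img, r, c, off))
  out
}

bernsen_oracle <- function(img, radius, contrast) {
  off <- oracle_offsets(radius, "disc")
  out <- matrix(FALSE, nrow(img), ncol(img))
  for (r in seq_len(nrow(img))) for (c in seq_len(ncol(img))) {
    v <- neighborhood_vals(img, r, c, off)
    if (max(v) - min(v) >= contrast) out[r, c] <- img[r, c] > (min(v) + max(v)) / 2
  }
  out
}

dilate_oracle <- function(mask, n_px) {
  off <- oracle_offsets(n_px, "disc")
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  idx <- which(mask, arr.ind = TRUE)
  for (i in seq_len(nrow(idx))) for (k in seq_len(nrow(off))) {
    r <- idx[i, 1] + off[k, 1]; c <- idx[i, 2] + off[k, 2]
    if (r >= 1 && r <= nrow(mask) && c >= 1 && c <= ncol(mask)) out[r, c] <- TRUE
  }
  out
}

# Recursive flood fill labelling of a binary matrix.
flood_labels <- function(bin, connectivity) {
  lab <- matrix(0L, nrow(bin), ncol(bin))
  off <- if (connectivity == 8)
    rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  else rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  nl <- 0L
  fill <- function(r, c, l) {
    stack <- list(c(r, c))
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      if (p[1] < 1 || p[1] > nrow(bin) || p[2] < 1 || p[2] > ncol(bin)) next
      if (!bin[p[1], p[2]] || lab[p[1], p[2]] != 0L) next
      lab[p[1], p[2]] <<- l
      for (k in seq_len(nrow(off)))
        stack[[length(stack) + 1L]] <- p + off[k, ]
    }
  }
  for (r in seq_len(nrow(bin))) for (c in seq_len(ncol(bin))) {
    if (bin[r, c] && lab[r, c] == 0L) { nl <- nl + 1L; fill(r, c, nl) }
  }
  lab
}

# Pixel sets of flood-fill components of size >= min_area.
flood_components <- function(bin, connectivity, min_area = 1) {
  lab <- flood_labels(bin, connectivity)
  out <- list()
  for (l in setdiff(sort(unique(as.vector(lab))), 0L)) {
    px <- which(lab == l, arr.ind = TRUE)
    if (nrow(px) >= min_area) out[[length(out) + 1L]] <- px
  }
  out
}

# Canonical signature of a component list for set comparison.
comp_signature <- function(pixel_sets, H) {
  sets <- lapply(pixel_sets, function(px) sort((px[, 2] - 1) * H + px[, 1]))
  sets[order(vapply(sets, min, numeric(1)))]
}

# Exact two-sided Mann-Whitney p by full permutation enumeration.
mw_enum_oracle <- function(a, b) {
  na <- length(a); nb <- length(b); N <- na + nb
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  idx <- utils::combn(N, na)
  us <- apply(idx, 2, function(s) sum(r[s]) - na * (na + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
}
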