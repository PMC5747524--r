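# Detection and classification of Ca2+ events from a processed movie:
# SD/area thresholding, connected components, frame linking, sparkle vs
# cell-wide classification with coincidence exclusion, background-event
# statistics, and event summaries.

#' Detection configuration
#'
#' The printed defaults: local ("sparkle") events at 5.4 SD and >= 1.4 um^2,
#' cell-wide events at 2.1 SD and >= 25 um^2. Area thresholds convert to
#' pixel counts as `ceiling(min_area_um2 / pixel_size^2)`; at 0.684 um/px,
#' 1.4 um^2 is exactly a 3-pixel rule and 25 um^2 a 54-pixel rule.
#'
#' @param local_thresh_sd SD threshold for local events.
#' @param cellwide_thresh_sd SD threshold for cell-wide events; must be
#'   below `local_thresh_sd`.
#' @param local_min_area_um2,cellwide_min_area_um2 minimum areas (um^2).
#' @param connectivity pixel connectivity, 4 or 8 (default 8).
#' @param gap_frames frames an event may skip and still be linked (default
#'   0: a one-frame gap splits events).
#' @param coincidence_rule how "a local event coincides with a cell-wide
#'   event" is judged: `"spatiotemporal"` (>= 1 shared pixel in >= 1 shared
#'   frame, default) or `"frames_only"` (any shared frame).
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(local_thresh_sd = 5.4, cellwide_thresh_sd = 2.1,
                             local_min_area_um2 = 1.4,
                             cellwide_min_area_um2 = 25,
                             connectivity = 8, gap_frames = 0,
                             coincidence_rule = c("spatiotemporal", "frames_only")) {
  coincidence_rule <- match.arg(coincidence_rule)
  .chk(local_thresh_sd > cellwide_thresh_sd && cellwide_thresh_sd > 0,
       "need local_thresh_sd > cellwide_thresh_sd > 0")
  .chk(local_min_area_um2 > 0 && cellwide_min_area_um2 > 0, "areas must be positive")
  .chk(connectivity %in% c(4, 8), "connectivity must be 4 or 8")
  .chk(gap_frames >= 0, "gap_frames must be >= 0")
  structure(list(local_thresh_sd = local_thresh_sd,
                 cellwide_thresh_sd = cellwide_thresh_sd,
                 local_min_area_um2 = local_min_area_um2,
                 cellwide_min_area_um2 = cellwide_min_area_um2,
                 connectivity = as.integer(connectivity),
                 gap_frames = as.integer(gap_frames),
                 coincidence_rule = coincidence_rule),
            class = "detection_config")
}

#' Standard deviation of a masked processed stack
#'
#' Population SD over all analyzable pixels across all frames of one imaging
#' session; this single noise scale anchors both SD thresholds.
#'
#' @param processed_green `T x Y x X` array (NA = masked) or a
#'   `processed_movie`.
#' @param analysis_mask optional logical `Y x X` mask (TRUE = analyzable).
#' @return Scalar SD in intensity units.
#' @export
stack_sd <- function(processed_green, analysis_mask = NULL) {
  if (inherits(processed_green, "processed_movie")) {
    if (is.null(analysis_mask)) analysis_mask <- processed_green$analysis_mask
    processed_green <- processed_green$processed_green
  }
  x <- processed_green
  if (!is.null(analysis_mask)) {
    .chk(identical(dim(analysis_mask), dim(x)[2:3]), "mask shape mismatch")
    x[rep(!analysis_mask, each = dim(x)[1])] <- NA_real_
  }
  x <- x[!is.na(x)]
  .chk(length(x) >= 2, "need >= 2 analyzable pixel-frames")
  sqrt(mean((x - mean(x))^2))
}

#' Suprathreshold connected components of one frame
#'
#' Connected components (4- or 8-connectivity) of pixels at or above
#' `thresh_sd * sd`, discarding components smaller than `min_area_px`
#' pixels. `NA` pixels (outside the analysis mask) never contribute.
#'
#' @param frame numeric matrix (signed processed intensities, NA = masked).
#' @param sd positive noise scale from [stack_sd()].
#' @param thresh_sd threshold in SD units.
#' @param min_area_px minimum component size in pixels.
#' @param connectivity 4 or 8.
#' @return List of components; each has `pixels` (n x 2 matrix of row, col),
#'   `area_px`, `peak` (maximum intensity), `values`.
#' @export
frame_components <- function(frame, sd, thresh_sd, min_area_px = 1,
                             connectivity = 8) {
  .chk(is.matrix(frame), "frame must be a matrix")
  .chk(is.finite(sd) && sd > 0, "sd must be positive")
  .chk(connectivity %in% c(4, 8), "connectivity must be 4 or 8")
  H <- nrow(frame); W <- ncol(frame)
  bin <- !is.na(frame) & frame >= thresh_sd * sd
  if (!any(bin)) return(list())
  off <- if (connectivity == 8)
    cbind(dy = c(-1, -1, -1, 0, 0, 1, 1, 1), dx = c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(dy = c(-1, 0, 0, 1), dx = c(0, -1, 1, 0))

  lin <- function(r, c) (c - 1L) * H + r
  visited <- matrix(FALSE, H, W)
  comps <- list()
  seeds <- which(bin)
  for (s in seeds) {
    if (visited[s]) next
    members <- s
    visited[s] <- TRUE
    frontier <- s
    while (length(frontier)) {
      r0 <- (frontier - 1L) %% H + 1L
      c0 <- (frontier - 1L) %/% H + 1L
      nr <- rep(r0, times = nrow(off)) + rep(off[, "dy"], each = length(frontier))
      nc <- rep(c0, times = nrow(off)) + rep(off[, "dx"], each = length(frontier))
      ok <- nr >= 1 & nr <= H & nc >= 1 & nc <= W
      cand <- unique(lin(nr[ok], nc[ok]))
      cand <- cand[bin[cand] & !visited[cand]]
      visited[cand] <- TRUE
      members <- c(members, cand)
      frontier <- cand
    }
    if (length(members) >= min_area_px) {
      px <- cbind(row = (members - 1L) %% H + 1L, col = (members - 1L) %/% H + 1L)
      comps[[length(comps) + 1L]] <- list(pixels = px,
                                          area_px = nrow(px),
                                          peak = max(frame[members]),
                                          values = frame[members])
    }
  }
  comps
}

#' Link per-frame components into multi-frame events
#'
#' Components in consecutive frames whose footprints share at least one
#' pixel are merged into one event (transitively); with `gap_frames = 0` a
#' one-frame gap splits events. Duration is the number of frames an event
#' spans; the reported area is the footprint area at the peak-amplitude
#' frame.
#'
#' @param components_by_frame list over frames, each a list of components
#'   from [frame_components()].
#' @param gap_frames maximum frame gap to bridge (default 0).
#' @param pixel_size_um pixel size for area/centroid conversion.
#' @param sd noise scale; amplitudes are reported in SD units.
#' @param frame_dim `c(H, W)` of a frame (for pixel bookkeeping).
#' @return List of unclassified events; each has `frames`, `footprints`
#'   (per-frame pixel matrices), `duration_frames`, `start_frame`,
#'   `end_frame`, `peak_frame`, `area_um2`, `peak_amplitude_sd`,
#'   `centroid_um`.
#' @export
link_events <- function(components_by_frame, gap_frames = 0,
                        pixel_size_um = 0.684, sd = 1,
                        frame_dim = NULL) {
  n <- length(components_by_frame)
  flat <- list(); fr <- integer(0)
  for (t in seq_len(n)) for (cmp in components_by_frame[[t]]) {
    flat[[length(flat) + 1L]] <- cmp
    fr <- c(fr, t)
  }
  k <- length(flat)
  if (k == 0) return(list())
  if (is.null(frame_dim)) {
    mxr <- max(vapply(flat, function(cc) max(cc$pixels[, 1]), numeric(1)))
    frame_dim <- c(mxr, 0)
  }
  H <- frame_dim[1]
  linsets <- lapply(flat, function(cc) (cc$pixels[, 2] - 1L) * H + cc$pixels[, 1])

  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    dfr <- abs(fr[j] - fr[i])
    if (dfr < 1 || dfr > gap_frames + 1) next
    if (length(intersect(linsets[[i]], linsets[[j]]))) union(i, j)
  }
  roots <- vapply(seq_len(k), find, integer(1))

  lapply(unique(roots), function(r) {
    idx <- which(roots == r)
    frames <- sort(unique(fr[idx]))
    fp <- lapply(frames, function(t) {
      do.call(rbind, lapply(idx[fr[idx] == t], function(i) flat[[i]]$pixels))
    })
    names(fp) <- as.character(frames)
    pk <- vapply(frames, function(t)
      max(vapply(idx[fr[idx] == t], function(i) flat[[i]]$peak, numeric(1))),
      numeric(1))
    peak_frame <- frames[which.max(pk)]
    pfp <- fp[[as.character(peak_frame)]]
    centroid <- c(x_um = (mean(pfp[, 2]) - 0.5) * pixel_size_um,
                  y_um = (mean(pfp[, 1]) - 0.5) * pixel_size_um)
    list(frames = frames, footprints = fp,
         start_frame = frames[1], end_frame = frames[length(frames)],
         duration_frames = length(frames),
         peak_frame = peak_frame,
         area_um2 = nrow(pfp) * pixel_size_um^2,
         peak_amplitude_sd = max(pk) / sd,
         centroid_um = centroid)
  })
}

# Do two events share >= 1 pixel in >= 1 common frame?
#' @noRd
.events_coincide <- function(a, b, rule = "spatiotemporal", H = 1e6) {
  shared <- intersect(a$frames, b$frames)
  if (!length(shared)) return(FALSE)
  if (rule == "frames_only") return(TRUE)
  for (t in shared) {
    pa <- a$footprints[[as.character(t)]]
    pb <- b$footprints[[as.character(t)]]
    la <- (pa[, 2] - 1) * H + pa[, 1]
    lb <- (pb[, 2] - 1) * H + pb[, 1]
    if (length(intersect(la, lb))) return(TRUE)
  }
  FALSE
}

#' Classify linked events as local, cell-wide, or excluded
#'
#' An event is cell-wide iff its peak reaches `cellwide_thresh_sd` and its
#' peak-frame area reaches `cellwide_min_area_um2`; local iff its peak
#' reaches `local_thresh_sd` with area in `[local_min_area_um2,
#' cellwide_min_area_um2)`. An event meeting both criteria is cell-wide
#' (size dominates). A local event that coincides with a cell-wide event is
#' re-labelled `local_excluded` and leaves the sparkle set.
#'
#' @param events list of events from [link_events()].
#' @param config a [detection_config].
#' @return The events, each with a `kind` field (`"local"`, `"cell_wide"`,
#'   `"local_excluded"`, or `NA` if neither criterion is met).
#' @export
classify_events <- function(events, config = detection_config()) {
  for (i in seq_along(events)) {
    ev <- events[[i]]
    kind <- NA_character_
    if (ev$peak_amplitude_sd >= config$cellwide_thresh_sd &&
        ev$area_um2 >= config$cellwide_min_area_um2) {
      kind <- "cell_wide"
    } else if (ev$peak_amplitude_sd >= config$local_thresh_sd &&
               ev$area_um2 >= config$local_min_area_um2 &&
               ev$area_um2 < config$cellwide_min_area_um2) {
      kind <- "local"
    }
    events[[i]]$kind <- kind
  }
  cw <- events[vapply(events, function(e) identical(e$kind, "cell_wide"), logical(1))]
  for (i in seq_along(events)) {
    if (!identical(events[[i]]$kind, "local")) next
    for (b in cw) {
      if (.events_coincide(events[[i]], b, config$coincidence_rule)) {
        events[[i]]$kind <- "local_excluded"
        break
      }
    }
  }
  events
}

#' Detect and classify Ca2+ events in a processed movie
#'
#' Runs two detection passes over the processed green stack -- a local pass
#' at `local_thresh_sd` / `local_min_area_um2` and a cell-wide pass at
#' `cellwide_thresh_sd` / `cellwide_min_area_um2` -- links components across
#' frames, classifies, and applies coincidence exclusion. Local-pass events
#' whose area reaches the cell-wide minimum are dropped as duplicates of
#' their cell-wide detection (size dominates).
#'
#' @param processed a `processed_movie` from [preprocess()].
#' @param config a [detection_config].
#' @return An object of class `ca_events`: a table (`$table`, one row per
#'   event: id, kind, frames, duration, area, amplitude, centroid) plus
#'   per-event per-frame footprints (`$footprints`), the session noise SD
#'   (`$sd`), and the pixel size.
#' @export
detect_events <- function(processed, config = detection_config()) {
  .chk(inherits(processed, "processed_movie"), "processed must be a processed_movie")
  p <- processed$params
  psz <- p$pixel_size_um
  sd <- stack_sd(processed)
  g <- processed$processed_green
  n <- dim(g)[1]; H <- dim(g)[2]; W <- dim(g)[3]
  la_px <- ceiling(config$local_min_area_um2 / psz^2)
  cw_px <- ceiling(config$cellwide_min_area_um2 / psz^2)

  comp_l <- vector("list", n); comp_c <- vector("list", n)
  for (t in seq_len(n)) {
    fm <- matrix(g[t, , ], H, W)
    comp_l[[t]] <- frame_components(fm, sd, config$local_thresh_sd, la_px,
                                    config$connectivity)
    comp_c[[t]] <- frame_components(fm, sd, config$cellwide_thresh_sd, cw_px,
                                    config$connectivity)
  }
  ev_l <- link_events(comp_l, config$gap_frames, psz, sd, frame_dim = c(H, W))
  ev_c <- link_events(comp_c, config$gap_frames, psz, sd, frame_dim = c(H, W))

  # drop local-pass events at cell-wide scale (duplicates of the cw pass)
  ev_l <- ev_l[vapply(ev_l, function(e)
    e$area_um2 < config$cellwide_min_area_um2, logical(1))]
  for (i in seq_along(ev_l)) ev_l[[i]]$kind <- "local"
  for (i in seq_along(ev_c)) ev_c[[i]]$kind <- "cell_wide"
  for (i in seq_along(ev_l)) {
    for (b in ev_c) {
      if (.events_coincide(ev_l[[i]], b, config$coincidence_rule, H)) {
        ev_l[[i]]$kind <- "local_excluded"
        break
      }
    }
  }
  events <- c(ev_c, ev_l)
  # deterministic order: by start frame, then centroid
  if (length(events)) {
    o <- order(vapply(events, function(e) e$start_frame, numeric(1)),
               vapply(events, function(e) e$centroid_um[1], numeric(1)),
               vapply(events, function(e) e$centroid_um[2], numeric(1)))
    events <- events[o]
  }
  tab <- if (length(events)) {
    do.call(rbind, lapply(seq_along(events), function(i) {
      e <- events[[i]]
      data.frame(id = i, kind = e$kind, start_frame = e$start_frame,
                 end_frame = e$end_frame, duration_frames = e$duration_frames,
                 area_um2 = e$area_um2, peak_amplitude_sd = e$peak_amplitude_sd,
                 centroid_x_um = unname(e$centroid_um["x_um"]),
                 centroid_y_um = unname(e$centroid_um["y_um"]))
    }))
  } else {
    data.frame(id = integer(0), kind = character(0), start_frame = integer(0),
               end_frame = integer(0), duration_frames = integer(0),
               area_um2 = numeric(0), peak_amplitude_sd = numeric(0),
               centroid_x_um = numeric(0), centroid_y_um = numeric(0))
  }
  structure(list(table = tab,
                 footprints = lapply(events, function(e) e$footprints),
                 sd = sd, pixel_size_um = psz, config = config,
                 frame_dim = c(H, W)),
            class = "ca_events")
}

#' @export
print.ca_events <- function(x, ...) {
  cat(sprintf("Detected Ca2+ events (stack SD = %.4g):\n", x$sd))
  print(table(factor(x$table$kind, c("local", "cell_wide", "local_excluded"))))
  invisible(x)
}

#' @export
as.data.frame.ca_events <- function(x, ...) x$table

#' Background suprathreshold-pixel rate under a normal noise model
#'
#' Expected number of pixels per suprathreshold pixel, `1 / Q(z)` with `Q`
#' the standard normal upper-tail probability. At the mean sparkle amplitude
#' of 6.5 SD this is ~2.49e10, i.e. one pixel in ~2 x 10^10.
#'
#' @param z threshold in SD units.
#' @return Scalar rate (pixels per expected false pixel).
#' @examples
#' background_rate(6.5)
#' background_rate(0)  # 2: half of all pixels exceed the mean
#' @export
background_rate <- function(z) {
  1 / stats::pnorm(z, lower.tail = FALSE)
}

#' Expected false suprathreshold pixels in a session
#'
#' Reports the expected number of suprathreshold pixel-frames from pure
#' noise, `N * Q(z)` with `N = analyzable pixels per frame x frames`, and
#' (alongside) the area-filtered expectation `N * Q(z)^k` for `k`-pixel
#' components under independence, so the "fewer than one event expected"
#' bound can be reproduced under either reading.
#'
#' @param n_pixels_per_frame analyzable pixels per frame, or an
#'   [acquisition_params] (the full field is used).
#' @param n_frames number of frames (>= 0).
#' @param z threshold in SD units.
#' @param min_area_px component-size rule for the area-filtered bound.
#' @return List with `pixelwise` and `area_filtered` expectations.
#' @export
expected_false_pixels <- function(n_pixels_per_frame, n_frames, z,
                                  min_area_px = 1) {
  if (inherits(n_pixels_per_frame, "acquisition_params"))
    n_pixels_per_frame <- prod(n_pixels_per_frame$fov_px)
  .chk(n_pixels_per_frame > 0, "need positive pixel count")
  .chk(n_frames >= 0, "n_frames must be >= 0")
  q <- stats::pnorm(z, lower.tail = FALSE)
  N <- n_pixels_per_frame * n_frames
  list(pixelwise = N * q, area_filtered = N * q^min_area_px)
}

#' Summarise detected events
#'
#' Counts by kind, relative frequencies of local vs cell-wide events, median
#' local-event area, mean peak amplitude (SD units), and a duration
#' histogram. An empty event set yields zero counts, not an error.
#'
#' @param events a `ca_events` object from [detect_events()].
#' @return An object of class `event_summary`.
#' @export
summarize_events <- function(events) {
  tab <- if (inherits(events, "ca_events")) events$table else events
  kinds <- c("local", "cell_wide", "local_excluded")
  counts <- vapply(kinds, function(k) sum(tab$kind == k, na.rm = TRUE), numeric(1))
  counted <- counts[c("local", "cell_wide")]
  rel <- if (sum(counted) > 0) counted / sum(counted) else counted * NA
  loc <- tab[tab$kind == "local" & !is.na(tab$kind), , drop = FALSE]
  kept <- tab[tab$kind %in% c("local", "cell_wide"), , drop = FALSE]
  structure(list(
    counts = counts,
    relative_frequency = rel,
    median_local_area_um2 = if (nrow(loc)) stats::median(loc$area_um2) else NA_real_,
    mean_peak_amplitude_sd = if (nrow(kept)) mean(kept$peak_amplitude_sd) else NA_real_,
    duration_table = if (nrow(kept)) table(kept$duration_frames) else table(integer(0))
  ), class = "event_summary")
}

#' @export
print.event_summary <- function(x, ...) {
  cat("Event summary\n")
  cat(sprintf("  counts         : local %d, cell-wide %d, excluded %d\n",
              x$counts["local"], x$counts["cell_wide"], x$counts["local_excluded"]))
  if (!all(is.na(x$relative_frequency)))
    cat(sprintf("  rel. frequency : local %.2f / cell-wide %.2f\n",
                x$relative_frequency["local"], x$relative_frequency["cell_wide"]))
  cat(sprintf("  median local area : %.3g um^2\n", x$median_local_area_um2))
  cat(sprintf("  mean amplitude    : %.3g SD\n", x$mean_peak_amplitude_sd))
  invisible(x)
}

#' Fluorescence intensity trace at a location
#'
#' Mean processed intensity over a disc around a fixed pixel location, per
#' frame, in SD units. Sparkles appear as 1-2 frame spikes; a drifting
#' autofluorescent process instead produces a sustained plateau, which is
#' how the two are discriminated.
#'
#' @param processed a `processed_movie` or `T x Y x X` array.
#' @param location `c(row, col)` pixel location; must lie in the field.
#' @param radius_px disc radius in pixels.
#' @param sd noise scale (defaults to [stack_sd()] of the input).
#' @return Numeric vector of length `n_frames`.
#' @export
intensity_trace <- function(processed, location, radius_px = 2, sd = NULL) {
  g <- if (inherits(processed, "processed_movie")) processed$processed_green else processed
  d <- dim(g)
  .chk(length(d) == 3, "processed stack must be T x Y x X")
  .chk(location[1] >= 1 && location[1] <= d[2] &&
         location[2] >= 1 && location[2] <= d[3], "location outside field")
  if (is.null(sd)) sd <- stack_sd(g)
  off <- .disc_offsets(radius_px)
  r <- location[1] + off$dy; c <- location[2] + off$dx
  ok <- r >= 1 & r <= d[2] & c >= 1 & c <= d[3]
  r <- r[ok]; c <- c[ok]
  vapply(seq_len(d[1]), function(t) {
    v <- g[cbind(t, r, c)]
    mean(v, na.rm = TRUE)
  }, numeric(1)) / sd
}

#' Precision and recall of detected sparkles against ground truth
#'
#' Matches detected events of a given kind to ground-truth events of the
#' same kind by spatiotemporal footprint overlap (>= 1 shared pixel in a
#' shared frame). Recall is the fraction of ground-truth events matched by
#' any detection; precision the fraction of detections matching any
#' ground-truth event.
#'
#' @param events a `ca_events` object from [detect_events()].
#' @param ground_truth the `$ground_truth` of a synthetic [movie_bundle].
#' @param kind event kind to evaluate (default `"local"`).
#' @return List with `precision`, `recall`, `n_detected`, `n_truth`.
#' @export
event_match_stats <- function(events, ground_truth, kind = "local") {
  H <- events$frame_dim[1]
  det_idx <- which(events$table$kind == kind)
  det_fp <- events$footprints[det_idx]
  truth <- Filter(function(ge) ge$spec$kind == ifelse(kind == "local", "local", "cell_wide"),
                  ground_truth$events)
  overlap <- function(fpa, fpb) {
    shared <- intersect(names(fpa), names(fpb))
    for (t in shared) {
      la <- (fpa[[t]][, 2] - 1) * H + fpa[[t]][, 1]
      lb <- (fpb[[t]][, 2] - 1) * H + fpb[[t]][, 1]
      if (length(intersect(la, lb))) return(TRUE)
    }
    FALSE
  }
  truth_fp <- lapply(truth, function(ge) ge$footprints)
  matched_truth <- vapply(truth_fp, function(tf)
    any(vapply(det_fp, function(df) overlap(df, tf), logical(1))), logical(1))
  matched_det <- vapply(det_fp, function(df)
    any(vapply(truth_fp, function(tf) overlap(df, tf), logical(1))), logical(1))
  list(precision = if (length(matched_det)) mean(matched_det) else NA_real_,
       recall = if (length(matched_truth)) mean(matched_truth) else NA_real_,
       n_detected = length(det_fp), n_truth = length(truth_fp))
}
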