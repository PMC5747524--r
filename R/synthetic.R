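# Synthetic two-channel time-lapse generator: spherical T cells with nuclear
# indicator exclusion, persistent-random-walk motility, Hill-type green
# fluorescence over a Ca2+ timeline, autofluorescent objects, and
# Poisson + Gaussian noise, with full ground truth.

#' Specification of a simulated T cell
#'
#' Cells are rendered as spheres intersected with the optical sections. The
#' red (Ca2+-insensitive) label fills the cytosol at unit density and the
#' nucleus at `nuclear_label_frac` (nuclear exclusion of the indicator); the
#' green channel follows the Hill-type Ca2+ response so that the resting
#' red:green ratio is exactly 5:1.
#'
#' @param id unique integer cell id.
#' @param radius_um cell radius (T-cell scale, ~3.5-5 um).
#' @param nucleus_radius_frac nucleus radius as a fraction of the cell radius,
#'   in (0, 1).
#' @param nuclear_label_frac residual label density inside the nucleus, in
#'   `[0, 1)`.
#' @param red_brightness noiseless red intensity (counts) of cytosolic label.
#' @param baseline_ca_nM resting cytosolic Ca2+ (nM), ~100.
#' @param speed_um_min RMS speed of the motility process (um/min).
#' @param persistence_s directional persistence time (s).
#' @param center_um optional initial `(x, y)` position in um; random if NULL.
#' @param z_um optional z position of the cell centre in um; defaults to the
#'   middle of the imaged volume.
#' @return An object of class `cell_spec`.
#' @export
cell_spec <- function(id, radius_um = 4.5, nucleus_radius_frac = 0.5,
                      nuclear_label_frac = 0.2, red_brightness = 600,
                      baseline_ca_nM = 100, speed_um_min = 10,
                      persistence_s = 60, center_um = NULL, z_um = NULL) {
  .chk(radius_um > 0, "radius_um must be positive")
  .chk(nucleus_radius_frac > 0 && nucleus_radius_frac < 1,
       "nucleus_radius_frac must be in (0, 1)")
  .chk(nuclear_label_frac >= 0 && nuclear_label_frac < 1,
       "nuclear_label_frac must be in [0, 1)")
  .chk(red_brightness >= 0, "red_brightness must be non-negative")
  .chk(baseline_ca_nM > 0, "baseline_ca_nM must be positive")
  .chk(speed_um_min >= 0, "speed_um_min must be non-negative")
  structure(list(id = as.integer(id), radius_um = radius_um,
                 nucleus_radius_frac = nucleus_radius_frac,
                 nuclear_label_frac = nuclear_label_frac,
                 red_brightness = red_brightness,
                 baseline_ca_nM = baseline_ca_nM,
                 speed_um_min = speed_um_min, persistence_s = persistence_s,
                 center_um = center_um, z_um = z_um),
            class = "cell_spec")
}

#' Specification of a simulated Ca2+ event
#'
#' Local events ("sparkles") occupy a small pixel block that travels with the
#' host cell; cell-wide events raise Ca2+ over the whole cytosol. Where
#' events overlap, the per-pixel maximum Ca2+ applies.
#'
#' @param kind `"local"` or `"cell_wide"`.
#' @param cell_id id of the host cell.
#' @param start_frame first frame of the event (1-based).
#' @param duration_frames event duration in frames (>= 1); sparkles typically
#'   last one or two frames.
#' @param peak_ca_nM Ca2+ during the event; must exceed the host baseline.
#' @param offset_um for local events, `(x, y)` offset of the footprint centre
#'   from the cell centroid, in um.
#' @param width_px for local events, footprint size in pixels `c(w, h)`; the
#'   default 2 x 2 block is ~2 um^2 at 0.684 um/px.
#' @return An object of class `ca_event_spec`.
#' @export
ca_event_spec <- function(kind = c("local", "cell_wide"), cell_id, start_frame,
                          duration_frames, peak_ca_nM, offset_um = c(0, 0),
                          width_px = c(2, 2)) {
  kind <- match.arg(kind)
  .chk(duration_frames >= 1, "duration_frames must be >= 1")
  .chk(start_frame >= 1, "start_frame must be >= 1")
  .chk(peak_ca_nM > 0, "peak_ca_nM must be positive")
  .chk(length(width_px) == 2 && all(width_px >= 1), "width_px must be two ints >= 1")
  structure(list(kind = kind, cell_id = as.integer(cell_id),
                 start_frame = as.integer(start_frame),
                 duration_frames = as.integer(duration_frames),
                 peak_ca_nM = peak_ca_nM, offset_um = offset_um,
                 width_px = as.integer(width_px)),
            class = "ca_event_spec")
}

#' Specification of an autofluorescent object
#'
#' Endogenously fluorescent cells are bright in both channels (green:red ~ 1)
#' and either static or slowly drifting; the preprocessing chain masks them
#' out via temporal averaging and Bernsen thresholding.
#'
#' @param center_um initial `(x, y)` position (um).
#' @param radius_um object radius (um).
#' @param red_brightness,green_brightness intensities in counts (both >= 0).
#' @param drift_um_min `(x, y)` drift velocity (um/min), default static.
#' @param z_um z position of the centre; defaults to mid-volume.
#' @return An object of class `autofluor_spec`.
#' @export
autofluor_spec <- function(center_um, radius_um = 4,
                           red_brightness = 8000, green_brightness = 8000,
                           drift_um_min = c(0, 0), z_um = NULL) {
  .chk(red_brightness >= 0 && green_brightness >= 0,
       "brightness must be non-negative in both channels")
  .chk(radius_um > 0, "radius_um must be positive")
  structure(list(center_um = center_um, radius_um = radius_um,
                 red_brightness = red_brightness,
                 green_brightness = green_brightness,
                 drift_um_min = drift_um_min, z_um = z_um),
            class = "autofluor_spec")
}

#' Simulate a persistent-random-walk motility path
#'
#' The cell velocity follows a two-dimensional Ornstein-Uhlenbeck process
#' with correlation time `persistence_s` and stationary RMS speed
#' `speed_um_min`; positions are the exactly integrated velocity (no
#' time-discretisation bias), so the mean squared displacement follows the
#' classical persistent-random-walk form
#' `MSD(t) = 2 v^2 P (t - P (1 - exp(-t/P)))`. Paths reflect at the field
#' boundary.
#'
#' @param spec a [cell_spec].
#' @param params an [acquisition_params].
#' @param seed integer seed; identical seeds give identical paths.
#' @return `n_frames x 2` matrix of `(x, y)` centroid positions in um.
#' @export
simulate_motility <- function(spec, params, seed = params$seed) {
  .chk(inherits(spec, "cell_spec"), "spec must be a cell_spec")
  .chk(inherits(params, "acquisition_params"), "params must be acquisition_params")
  .chk(spec$persistence_s > 0, "persistence_s must be positive")
  n <- params$n_frames
  Ly <- params$fov_px[1] * params$pixel_size_um
  Lx <- params$fov_px[2] * params$pixel_size_um

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  start <- spec$center_um
  if (is.null(start)) {
    m <- min(spec$radius_um, Lx / 4, Ly / 4)
    start <- c(stats::runif(1, m, Lx - m), stats::runif(1, m, Ly - m))
  }
  pos <- matrix(0, n, 2, dimnames = list(NULL, c("x_um", "y_um")))
  pos[1, ] <- start
  if (n == 1) return(pos)

  v_rms <- spec$speed_um_min / 60          # um/s
  sv <- v_rms / sqrt(2)                    # per-component stationary SD
  tau <- spec$persistence_s
  dt <- params$frame_interval_s
  a <- exp(-dt / tau)
  svv <- sv^2 * (1 - a^2)
  sxx <- sv^2 * tau^2 * (2 * dt / tau - 3 + 4 * a - a^2)
  sxv <- sv^2 * tau * (1 - a)^2

  v <- stats::rnorm(2, 0, sv)
  L <- c(Lx, Ly)
  for (k in 2:n) {
    if (sv > 0) {
      xi1 <- stats::rnorm(2); xi2 <- stats::rnorm(2)
      eta_v <- sqrt(svv) * xi1
      eta_x <- (sxv / sqrt(svv)) * xi1 + sqrt(max(sxx - sxv^2 / svv, 0)) * xi2
    } else {
      eta_v <- eta_x <- c(0, 0)
    }
    p <- pos[k - 1, ] + tau * (1 - a) * v + eta_x
    v <- a * v + eta_v
    # reflect at field edges (flip the matching velocity component)
    for (d in 1:2) {
      for (it in 1:4) {
        if (p[d] < 0) { p[d] <- -p[d]; v[d] <- -v[d] }
        if (p[d] > L[d]) { p[d] <- 2 * L[d] - p[d]; v[d] <- -v[d] }
      }
    }
    pos[k, ] <- p
  }
  pos
}

#' @noRd
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}

#' @noRd
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Per-frame Ca2+ field of a cell
#'
#' Builds a generator for the Ca2+ concentration (nM) inside one cell's
#' cytosol as a function of frame and position relative to the cell centroid.
#' Frames without events return the baseline everywhere; during an event the
#' footprint sits at the event's peak Ca2+; where events overlap the
#' per-pixel maximum applies.
#'
#' @param cell a [cell_spec].
#' @param events list of [ca_event_spec] objects, all referencing this cell.
#' @param params an [acquisition_params] (bounds-checks event frames).
#' @param pixel_size_um pixel size used to convert local footprint widths.
#' @return A function `f(frame, rel_xy_um)` mapping an `n x 2` matrix of
#'   positions (um, relative to the centroid) to Ca2+ concentrations (nM).
#' @export
calcium_timeline <- function(cell, events, params,
                             pixel_size_um = params$pixel_size_um) {
  .chk(inherits(cell, "cell_spec"), "cell must be a cell_spec")
  for (ev in events) {
    .chk(inherits(ev, "ca_event_spec"), "events must be ca_event_spec objects")
    .chk(ev$cell_id == cell$id, "event references a different cell")
    .chk(ev$start_frame >= 1 &&
           ev$start_frame + ev$duration_frames - 1 <= params$n_frames,
         "event frames outside movie range")
    .chk(ev$peak_ca_nM > cell$baseline_ca_nM,
         "peak_ca_nM must exceed the host cell baseline")
  }
  force(pixel_size_um)
  function(frame, rel_xy_um) {
    rel_xy_um <- rbind(rel_xy_um)
    ca <- rep(cell$baseline_ca_nM, nrow(rel_xy_um))
    for (ev in events) {
      if (frame < ev$start_frame || frame > ev$start_frame + ev$duration_frames - 1)
        next
      if (ev$kind == "cell_wide") {
        ca <- pmax(ca, ev$peak_ca_nM)
      } else {
        w <- ev$width_px * pixel_size_um
        lo_x <- ev$offset_um[1] - w[1] / 2
        lo_y <- ev$offset_um[2] - w[2] / 2
        # half-open box: exactly width_px pixel centres per axis
        inside <- rel_xy_um[, 1] >= lo_x & rel_xy_um[, 1] < lo_x + w[1] &
                  rel_xy_um[, 2] >= lo_y & rel_xy_um[, 2] < lo_y + w[2]
        ca[inside] <- pmax(ca[inside], ev$peak_ca_nM)
      }
    }
    ca
  }
}

# Fractional Hill occupancy used for the green channel.
#' @noRd
.green_fraction <- function(ca_nM, hp) {
  ca_nM^hp$hill_n / (hp$kd_nM^hp$hill_n + ca_nM^hp$hill_n)
}

#' Add Poisson shot noise and Gaussian read noise to a stack
#'
#' Shot noise: `Poisson(photon_scale * I) / photon_scale` (disabled when
#' `photon_scale` is 0 or infinite); read noise: additive
#' `N(0, read_noise_sd)`. Output is clipped to the detector range.
#'
#' @param stack non-negative numeric array.
#' @param params an [acquisition_params] supplying `photon_scale`,
#'   `read_noise_sd`, `bit_depth`.
#' @param seed integer seed; identical seeds give identical noise.
#' @return Array of the same shape.
#' @export
add_noise <- function(stack, params, seed = params$seed) {
  .chk(all(stack >= 0), "stack values must be non-negative")
  .chk(params$photon_scale >= 0 && params$read_noise_sd >= 0,
       "noise parameters must be non-negative")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  out <- stack
  ps <- params$photon_scale
  if (is.finite(ps) && ps > 0) {
    out[] <- stats::rpois(length(stack), ps * as.numeric(stack)) / ps
  }
  if (params$read_noise_sd > 0) {
    out[] <- out + stats::rnorm(length(stack), 0, params$read_noise_sd)
  }
  out[out < 0] <- 0
  mx <- .intensity_max(params)
  out[out > mx] <- mx
  out
}

#' Two-channel movie bundle
#'
#' Container for paired red/green `T x Z x Y x X` intensity stacks, the
#' acquisition parameters, and (for synthetic movies) ground truth.
#'
#' @param red,green numeric 4-D arrays of identical shape, in
#'   `[0, 2^bit_depth - 1]`.
#' @param params an [acquisition_params].
#' @param ground_truth optional ground-truth list (see [render_movie()]).
#' @return An object of class `movie_bundle`.
#' @export
movie_bundle <- function(red, green, params, ground_truth = NULL) {
  .chk(identical(dim(red), dim(green)), "red and green stacks must share shape")
  .chk(length(dim(red)) == 4, "stacks must be T x Z x Y x X arrays")
  .chk(min(red) >= 0 && min(green) >= 0, "intensities must be non-negative")
  mx <- .intensity_max(params)
  .chk(max(red) <= mx && max(green) <= mx, "intensities exceed bit-depth maximum")
  structure(list(red = red, green = green, params = params,
                 ground_truth = ground_truth),
            class = "movie_bundle")
}

#' @export
print.movie_bundle <- function(x, ...) {
  d <- dim(x$red)
  cat(sprintf("Two-channel movie: %d frames x %d z x %d x %d px\n",
              d[1], d[2], d[3], d[4]))
  if (!is.null(x$ground_truth))
    cat(sprintf("  ground truth: %d cells, %d events\n",
                length(x$ground_truth$paths), length(x$ground_truth$events)))
  print(x$params)
  invisible(x)
}

#' Render a synthetic two-channel movie
#'
#' Composes cell geometry, motility, Ca2+ timelines, autofluorescent objects
#' and the noise model into a [movie_bundle] with ground truth. Noiseless red
#' intensity is `red_brightness * label density` (cytosol 1, nucleus
#' `nuclear_label_frac`); noiseless green is `red / 5 * f(ca) / f(baseline)`
#' with `f` the Hill fractional occupancy (Salsa6f steady-state parameters),
#' so the resting red:green ratio is exactly 5:1 and the red channel never
#' depends on the Ca2+ timeline.
#'
#' @param cells list of [cell_spec] objects (unique ids).
#' @param events list of [ca_event_spec] objects.
#' @param autofluor list of [autofluor_spec] objects.
#' @param params an [acquisition_params].
#' @param seed integer seed controlling motility and noise.
#' @param indicator a [hill_params] for the green response (Salsa6f
#'   steady-state by default).
#' @return A [movie_bundle]; `$ground_truth` holds `cell_masks` (per-frame
#'   integer label matrices of projected cell footprints), `events` (per
#'   event: spec, active frames, per-frame footprint pixel matrices),
#'   `event_table` (one row per event) and `paths` (per-cell centroid
#'   tracks in um).
#' @export
render_movie <- function(cells, events = list(), autofluor = list(), params,
                         seed = params$seed, indicator = salsa6f_hill("steady")) {
  .chk(inherits(params, "acquisition_params"), "params must be acquisition_params")
  ids <- vapply(cells, function(cl) cl$id, integer(1))
  .chk(!anyDuplicated(ids), "overlapping (duplicate) cell ids")
  .chk(params$photon_scale >= 0, "photon_scale must be non-negative")

  n <- params$n_frames
  nz <- params$n_z
  H <- params$fov_px[1]; W <- params$fov_px[2]
  psz <- params$pixel_size_um
  zs <- .z_positions(params)
  z_mid <- mean(range(zs))

  paths <- lapply(seq_along(cells), function(i)
    simulate_motility(cells[[i]], params, seed = .sub_seed(seed, 100 + i)))
  names(paths) <- as.character(ids)

  ev_by_cell <- split(events, vapply(events, function(e) e$cell_id, integer(1)))
  timelines <- lapply(seq_along(cells), function(i) {
    evs <- ev_by_cell[[as.character(ids[i])]]
    calcium_timeline(cells[[i]], if (is.null(evs)) list() else evs, params, psz)
  })

  af_paths <- lapply(autofluor, function(a) {
    t(vapply(seq_len(n), function(k)
      a$center_um + a$drift_um_min / 60 * (k - 1) * params$frame_interval_s,
      numeric(2)))
  })

  xc <- (seq_len(W) - 0.5) * psz   # pixel-centre physical coordinates
  yc <- (seq_len(H) - 0.5) * psz

  red <- array(0, dim = c(n, nz, H, W))
  green <- array(0, dim = c(n, nz, H, W))
  cell_masks <- vector("list", n)

  # per-event footprint bookkeeping
  gt_events <- lapply(events, function(ev)
    list(spec = ev, frames = seq(ev$start_frame,
                                 ev$start_frame + ev$duration_frames - 1),
         footprints = list()))

  for (t in seq_len(n)) {
    lab <- matrix(0L, H, W)
    planes_r <- lapply(seq_len(nz), function(z) matrix(0, H, W))
    planes_g <- lapply(seq_len(nz), function(z) matrix(0, H, W))

    for (i in seq_along(cells)) {
      cl <- cells[[i]]
      if (cl$red_brightness == 0) next
      cen <- paths[[i]][t, ]
      zc <- if (is.null(cl$z_um)) z_mid else cl$z_um
      r <- cl$radius_um
      rn <- r * cl$nucleus_radius_frac

      # projected (2D) footprint for ground truth
      rho2_by_z <- pmax(r^2 - (zs - zc)^2, 0)
      rho_proj2 <- max(rho2_by_z)
      if (rho_proj2 <= 0) next
      rows <- which(abs(yc - cen[2]) <= sqrt(rho_proj2))
      cols <- which(abs(xc - cen[1]) <= sqrt(rho_proj2))
      if (length(rows) && length(cols)) {
        d2 <- outer((yc[rows] - cen[2])^2, (xc[cols] - cen[1])^2, "+")
        sub <- lab[rows, cols, drop = FALSE]
        sub[d2 <= rho_proj2 & sub == 0L] <- cl$id
        lab[rows, cols] <- sub
      }

      f0 <- .green_fraction(cl$baseline_ca_nM, indicator)
      for (z in seq_len(nz)) {
        rho2 <- rho2_by_z[z]
        if (rho2 <= 0) next
        rho <- sqrt(rho2)
        rws <- which(abs(yc - cen[2]) <= rho)
        cls_ <- which(abs(xc - cen[1]) <= rho)
        if (!length(rws) || !length(cls_)) next
        dy2 <- (yc[rws] - cen[2])^2
        dx2 <- (xc[cls_] - cen[1])^2
        d2 <- outer(dy2, dx2, "+")
        inside <- d2 <= rho2
        if (!any(inside)) next
        rho_n2 <- rn^2 - (zs[z] - zc)^2
        dens <- matrix(1, length(rws), length(cls_))
        if (rho_n2 > 0) dens[d2 <= rho_n2] <- cl$nuclear_label_frac
        red_add <- cl$red_brightness * dens * inside

        idx <- which(inside, arr.ind = TRUE)
        rel <- cbind(xc[cls_][idx[, 2]] - cen[1], yc[rws][idx[, 1]] - cen[2])
        ca <- timelines[[i]](t, rel)
        fr <- .green_fraction(ca, indicator) / f0
        fr_m <- matrix(0, length(rws), length(cls_))
        fr_m[idx] <- fr
        green_add <- red_add / 5 * fr_m

        planes_r[[z]][rws, cls_] <- planes_r[[z]][rws, cls_] + red_add
        planes_g[[z]][rws, cls_] <- planes_g[[z]][rws, cls_] + green_add
      }
    }

    for (j in seq_along(autofluor)) {
      a <- autofluor[[j]]
      cen <- af_paths[[j]][t, ]
      zc <- if (is.null(a$z_um)) z_mid else a$z_um
      for (z in seq_len(nz)) {
        rho2 <- a$radius_um^2 - (zs[z] - zc)^2
        if (rho2 <= 0) next
        rho <- sqrt(rho2)
        rws <- which(abs(yc - cen[2]) <= rho)
        cls_ <- which(abs(xc - cen[1]) <= rho)
        if (!length(rws) || !length(cls_)) next
        d2 <- outer((yc[rws] - cen[2])^2, (xc[cls_] - cen[1])^2, "+")
        inside <- d2 <= rho2
        planes_r[[z]][rws, cls_] <- planes_r[[z]][rws, cls_] + a$red_brightness * inside
        planes_g[[z]][rws, cls_] <- planes_g[[z]][rws, cls_] + a$green_brightness * inside
      }
    }

    for (z in seq_len(nz)) {
      red[t, z, , ] <- planes_r[[z]]
      green[t, z, , ] <- planes_g[[z]]
    }
    cell_masks[[t]] <- lab

    # ground-truth footprints for events active at t
    for (e in seq_along(gt_events)) {
      ge <- gt_events[[e]]
      if (!(t %in% ge$frames)) next
      ev <- ge$spec
      i <- match(ev$cell_id, ids)
      cen <- paths[[i]][t, ]
      # host mask from the cell's own projected disc (robust to cell overlap)
      cl <- cells[[i]]
      zc <- if (is.null(cl$z_um)) z_mid else cl$z_um
      rho_proj2 <- max(pmax(cl$radius_um^2 - (zs - zc)^2, 0))
      rows <- which(abs(yc - cen[2]) <= sqrt(rho_proj2))
      cols <- which(abs(xc - cen[1]) <= sqrt(rho_proj2))
      d2 <- outer((yc[rows] - cen[2])^2, (xc[cols] - cen[1])^2, "+")
      hidx <- which(d2 <= rho_proj2, arr.ind = TRUE)
      host <- cbind(row = rows[hidx[, 1]], col = cols[hidx[, 2]])
      if (ev$kind == "cell_wide") {
        fp <- host
      } else {
        w <- ev$width_px * psz
        lo_x <- cen[1] + ev$offset_um[1] - w[1] / 2
        lo_y <- cen[2] + ev$offset_um[2] - w[2] / 2
        px <- xc[host[, 2]]; py <- yc[host[, 1]]
        keep <- px >= lo_x & px < lo_x + w[1] & py >= lo_y & py < lo_y + w[2]
        fp <- host[keep, , drop = FALSE]
      }
      gt_events[[e]]$footprints[[as.character(t)]] <- fp
    }
  }

  mx <- .intensity_max(params)
  if (params$background_counts > 0) {
    red <- red + params$background_counts
    green <- green + params$background_counts
  }
  red[red > mx] <- mx
  green[green > mx] <- mx
  red <- add_noise(red, params, seed = .sub_seed(seed, 1))
  green <- add_noise(green, params, seed = .sub_seed(seed, 2))

  event_table <- if (length(events)) {
    do.call(rbind, lapply(seq_along(events), function(e) {
      ev <- events[[e]]
      fps <- gt_events[[e]]$footprints
      area_px <- if (length(fps)) max(vapply(fps, nrow, integer(1))) else 0L
      data.frame(id = e, kind = ev$kind, cell_id = ev$cell_id,
                 start_frame = ev$start_frame,
                 duration_frames = ev$duration_frames,
                 peak_ca_nM = ev$peak_ca_nM,
                 area_um2 = area_px * psz^2)
    }))
  } else data.frame()

  movie_bundle(red, green, params,
               ground_truth = list(cell_masks = cell_masks,
                                   events = gt_events,
                                   event_table = event_table,
                                   paths = paths))
}
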