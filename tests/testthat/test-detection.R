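# SD/area-threshold event detection, classification and statistics.

test_that("stack SD is the population SD over analyzable pixel-frames", {
  expect_equal(stack_sd(array(3, dim = c(2, 3, 3))), 0)
  half <- array(c(-1, 1), dim = c(2, 4, 4))
  expect_equal(stack_sd(half), 1)
  set.seed(1)
  x <- array(rnorm(5 * 8 * 8), dim = c(5, 8, 8))
  mask <- matrix(TRUE, 8, 8); mask[1:2, 1:2] <- FALSE
  poisoned <- x
  poisoned[, 1:2, 1:2] <- 1e6
  # mask-exclusion oracle: masked values are irrelevant, and the result is
  # the population SD over exactly the kept pixel-frames
  expect_equal(stack_sd(poisoned, mask), stack_sd(x, mask))
  kept <- as.vector(x)[rep(as.vector(mask), each = 5)]
  expect_equal(stack_sd(poisoned, mask), sqrt(mean((kept - mean(kept))^2)))
  expect_error(stack_sd(array(NA_real_, dim = c(2, 2, 2))), "analyzable")
})

test_that("frame components threshold, label and area-filter correctly", {
  empty <- matrix(0, 16, 16)
  expect_length(frame_components(empty, 1, 5.4, 1), 0)
  blk <- matrix(0, 16, 16); blk[5:6, 5:6] <- 6
  cm <- frame_components(blk, 1, 5.4, 3)
  expect_length(cm, 1)
  expect_equal(cm[[1]]$area_px, 4)
  expect_equal(cm[[1]]$peak, 6)
  iso <- matrix(0, 16, 16); iso[8, 8] <- 10
  expect_length(frame_components(iso, 1, 5.4, 3), 0)
  expect_length(frame_components(iso, 1, 5.4, 1), 1)
  expect_error(frame_components(blk, 0, 5.4, 1), "positive")
  # NA (masked) pixels never form components
  blk[5, 5] <- NA
  expect_length(frame_components(blk, 1, 5.4, 4), 0)
})

test_that("connectivity 4 vs 8 splits or joins diagonal components", {
  diagm <- matrix(0, 8, 8); diagm[3, 3] <- diagm[4, 4] <- 9
  expect_length(frame_components(diagm, 1, 5, 1, connectivity = 8), 1)
  expect_length(frame_components(diagm, 1, 5, 1, connectivity = 4), 2)
})

test_that("linking merges consecutive overlapping components only", {
  mk <- function(px) list(list(pixels = px, area_px = nrow(px),
                               peak = 10, values = rep(10, nrow(px))))
  fp <- cbind(row = c(4, 4, 5, 5), col = c(4, 5, 4, 5))
  # same footprint in t, t+1: one event of duration 2
  ev <- link_events(list(mk(fp), mk(fp), list()), 0, 0.684, 1, c(16, 16))
  expect_length(ev, 1)
  expect_equal(ev[[1]]$duration_frames, 2)
  expect_equal(ev[[1]]$area_um2, 4 * 0.684^2)
  # a one-frame gap splits
  ev2 <- link_events(list(mk(fp), list(), mk(fp)), 0, 0.684, 1, c(16, 16))
  expect_length(ev2, 2)
  expect_true(all(vapply(ev2, function(e) e$duration_frames, numeric(1)) == 1))
  # gap_frames = 1 bridges it
  ev3 <- link_events(list(mk(fp), list(), mk(fp)), 1, 0.684, 1, c(16, 16))
  expect_length(ev3, 1)
  # disjoint footprints never merge
  fp2 <- fp + 6
  ev4 <- link_events(list(mk(fp), mk(fp2)), 0, 0.684, 1, c(16, 16))
  expect_length(ev4, 2)
})

test_that("classification applies thresholds, size dominance and coincidence", {
  cfg <- detection_config()
  mk_ev <- function(frames, px, amp, area_um2) {
    fp <- lapply(frames, function(t) px)
    names(fp) <- as.character(frames)
    list(frames = frames, footprints = fp, start_frame = frames[1],
         end_frame = frames[length(frames)], duration_frames = length(frames),
         peak_frame = frames[1], area_um2 = area_um2,
         peak_amplitude_sd = amp, centroid_um = c(x_um = 1, y_um = 1))
  }
  px <- cbind(row = 5:6, col = 5:6)
  big <- cbind(row = rep(1:10, each = 10), col = rep(1:10, 10))
  # 54 px at 2.5 SD at 0.684 um/px: 25.27 um^2 -> cell-wide
  ev <- classify_events(list(mk_ev(3, big[1:54, ], 2.5, 54 * 0.684^2)), cfg)
  expect_equal(ev[[1]]$kind, "cell_wide")
  # local inside a concurrent cell-wide -> excluded
  both <- classify_events(list(
    mk_ev(3, big, 3, nrow(big) * 0.684^2),
    mk_ev(3, px, 7, 4 * 0.684^2)), cfg)
  expect_equal(both[[1]]$kind, "cell_wide")
  expect_equal(both[[2]]$kind, "local_excluded")
  # disjoint frames: both kept
  apart <- classify_events(list(
    mk_ev(3, big, 3, nrow(big) * 0.684^2),
    mk_ev(8, px, 7, 4 * 0.684^2)), cfg)
  expect_equal(apart[[2]]$kind, "local")
  # frames-only rule excludes even spatially disjoint locals
  cfg2 <- detection_config(coincidence_rule = "frames_only")
  far <- classify_events(list(
    mk_ev(3, big, 3, nrow(big) * 0.684^2),
    mk_ev(3, px + 100, 7, 4 * 0.684^2)), cfg2)
  expect_equal(far[[2]]$kind, "local_excluded")
  # an event meeting both criteria is cell-wide (size dominates)
  tie <- classify_events(list(mk_ev(3, big[1:60, ], 8, 60 * 0.684^2)), cfg)
  expect_equal(tie[[1]]$kind, "cell_wide")
  # below every threshold: no kind
  expect_true(is.na(classify_events(list(mk_ev(3, px, 3, 4 * 0.684^2)), cfg)[[1]]$kind))
})

test_that("detect_events resolves sparkles, cell-wide events and exclusion", {
  # noisy movie so the noise SD, not the events, sets the thresholds; the
  # cell-wide amplitude is placed between 2.1 and 5.4 SD so a concurrent
  # sparkle forms its own 5.4 SD component and gets coincidence-excluded
  p <- tiny_params(n_frames = 20, read_noise_sd = 15, background_counts = 80)
  cl1 <- cell_spec(1, center_um = c(12, 12), speed_um_min = 4)
  cl2 <- cell_spec(2, center_um = c(24, 24), speed_um_min = 4)
  sigma <- stack_sd(preprocess(render_movie(list(cl1, cl2), list(), list(),
                                            p, seed = 6)))
  hp <- salsa6f_hill("steady")
  peak_for <- function(dg) invert_hill(hill_ratio(100, hp) * (1 + 5 * dg / 600), hp)
  cw_peak <- peak_for(3.5 * sigma)    # between the two SD thresholds
  sp_peak <- peak_for(12 * sigma)     # clearly above the local threshold
  evs <- list(ca_event_spec("local", 1, 4, 2, sp_peak, offset_um = c(2.4, 0)),
              ca_event_spec("local", 2, 16, 1, sp_peak, offset_um = c(0, 2.4)),
              # sparkle during (and inside) a cell-wide on cell 1: excluded
              ca_event_spec("local", 1, 10, 1, sp_peak, offset_um = c(-2.4, 0)),
              ca_event_spec("cell_wide", 1, 10, 2, cw_peak))
  mv <- render_movie(list(cl1, cl2), evs, list(), p, seed = 6)
  pp <- preprocess(mv)
  det <- detect_events(pp)
  expect_equal(sum(det$table$kind == "local"), 2)
  expect_equal(sum(det$table$kind == "cell_wide"), 1)
  expect_equal(sum(det$table$kind == "local_excluded"), 1)
  # every detected footprint pixel is analyzable
  for (fp in det$footprints) for (m in fp)
    expect_true(all(pp$analysis_mask[m]))
  stats <- event_match_stats(det, mv$ground_truth, "local")
  expect_gte(stats$precision, 0.99)
})

test_that("raising thresholds never increases the sparkle count", {
  sc <- sparkle_benchmark_scene(seed = 4, n_frames = 60, fov_px = c(96, 96),
                                n_cells = 3, n_sparkles = 12)
  pp <- preprocess(render_movie(sc$cells, sc$events, list(), sc$params, seed = 4))
  n_at <- function(th, area) {
    det <- detect_events(pp, detection_config(local_thresh_sd = th,
                                              local_min_area_um2 = area))
    sum(det$table$kind == "local")
  }
  base <- n_at(5.4, 1.4)
  expect_lte(n_at(6.5, 1.4), base)
  expect_lte(n_at(8.0, 1.4), n_at(6.5, 1.4))
  expect_lte(n_at(5.4, 2.5), base)
})

test_that("background rate follows the standard normal upper tail", {
  expect_equal(background_rate(0), 2)
  expect_equal(background_rate(1.959964), 40, tolerance = 1e-4)
  expect_equal(background_rate(6.5), 2.49e10, tolerance = 0.01)
})

test_that("expected false pixels scale with field size and the area rule", {
  expect_equal(expected_false_pixels(1000, 0, 6.5)$pixelwise, 0)
  e <- expected_false_pixels(1e6, 1, 6.5)
  expect_equal(e$pixelwise, 4.02e-5, tolerance = 0.01)
  e2 <- expected_false_pixels(4e5, 100, 5.4, min_area_px = 3)
  expect_lt(e2$area_filtered, 1e-10)  # << 1 under the joint-tail bound
  expect_gt(e2$pixelwise, e2$area_filtered)
  p <- tiny_params(n_frames = 2)
  expect_equal(expected_false_pixels(p, 10, 6.5)$pixelwise,
               48 * 48 * 10 * pnorm(6.5, lower.tail = FALSE))
})

test_that("summaries count kinds, areas and durations", {
  s0 <- summarize_events(data.frame(id = integer(0), kind = character(0),
                                    duration_frames = integer(0),
                                    area_um2 = numeric(0),
                                    peak_amplitude_sd = numeric(0)))
  expect_true(all(s0$counts == 0))
  tab <- data.frame(id = 1:4, kind = c("local", "local", "local", "cell_wide"),
                    duration_frames = c(1, 1, 2, 3),
                    area_um2 = c(4, 4, 4, 60) * 0.684^2,
                    peak_amplitude_sd = c(6, 7, 6.5, 3))
  s <- summarize_events(tab)
  expect_equal(unname(s$relative_frequency), c(0.75, 0.25))
  expect_equal(s$median_local_area_um2, 1.872, tolerance = 1e-3)
  expect_equal(s$mean_peak_amplitude_sd, mean(c(6, 7, 6.5, 3)))
})

test_that("intensity traces separate transients from drifting objects", {
  sm <- sparkle_movie(start = 7, duration = 2)
  pp <- preprocess(sm$bundle)
  sdv <- stack_sd(pp)
  fp <- sm$bundle$ground_truth$events[[1]]$footprints[["7"]]
  tr <- intensity_trace(pp, c(fp[1, 1], fp[1, 2]), radius_px = 1, sd = sdv)
  expect_gt(max(tr[7:8]), 2)
  # off-event frames carry only the (negative) temporal-mean leakage
  expect_lt(max(tr[-(7:8)]), 1)
  # event-free noiseless movie: a trace of exact zeros
  quiet <- preprocess(resting_cell_movie()$bundle)
  tr0 <- intensity_trace(quiet, c(24, 24), radius_px = 2, sd = 1)
  expect_lt(max(abs(tr0)), 1e-6)
  expect_error(intensity_trace(pp, c(500, 2)), "outside field")
  # drifting autofluorescent object, masking disabled: sustained plateau
  p <- tiny_params(n_frames = 16)
  af <- autofluor_spec(center_um = c(8, 16), radius_um = 3,
                       red_brightness = 2000, green_brightness = 2000,
                       drift_um_min = c(8, 0))
  cl <- cell_spec(1, center_um = c(30, 30), speed_um_min = 2)
  ev <- ca_event_spec("local", 1, 6, 1, 800, offset_um = c(2.4, 0))
  mv <- render_movie(list(cl), list(ev), list(af), p, seed = 2)
  ppu <- preprocess(mv, preprocess_config(mask_autofluor = FALSE))
  sdu <- stack_sd(ppu)
  tru <- intensity_trace(ppu, c(24, 16), radius_px = 2, sd = sdu)
  expect_gt(sum(tru > 1), 5)   # plateau, not a 1-2 frame spike
})

test_that("autofluorescent objects are masked and spawn no events", {
  p <- tiny_params(n_frames = 16)
  af <- autofluor_spec(center_um = c(10, 10), radius_um = 3)
  cl <- cell_spec(1, center_um = c(26, 26), speed_um_min = 4)
  ev <- ca_event_spec("local", 1, 6, 1, 800, offset_um = c(2.4, 0))
  mv <- render_movie(list(cl), list(ev), list(af), p, seed = 2)
  pp <- preprocess(mv)
  # the object is outside the analysis mask
  expect_false(pp$analysis_mask[15, 15])
  det <- detect_events(pp)
  expect_equal(sum(det$table$kind == "local"), 1)
  # no detected footprint pixel is masked out
  for (fps in det$footprints) for (m in fps)
    expect_true(all(pp$analysis_mask[m]))
})
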