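# Synthetic movie generator: motility, Ca2+ timelines, rendering, noise.

test_that("zero-speed motility is the identity and paths are seeded", {
  p <- tiny_params(n_frames = 10)
  still <- cell_spec(1, speed_um_min = 0, center_um = c(10, 12))
  path <- simulate_motility(still, p, seed = 4)
  expect_equal(path, matrix(c(10, 12), 10, 2, byrow = TRUE,
                            dimnames = list(NULL, c("x_um", "y_um"))))
  mover <- cell_spec(2, speed_um_min = 12, center_um = c(10, 12))
  expect_identical(simulate_motility(mover, p, seed = 9),
                   simulate_motility(mover, p, seed = 9))
  expect_false(identical(simulate_motility(mover, p, seed = 9),
                         simulate_motility(mover, p, seed = 10)))
  expect_error(simulate_motility(cell_spec(3, persistence_s = 0), p), "persistence")
})

test_that("motility MSD matches the persistent-random-walk closed form", {
  # large field so reflections never engage; exact-integrator paths should
  # track MSD(t) = 2 v^2 P (t - P(1 - exp(-t/P)))
  p <- acquisition_params(c(3000, 3000), n_frames = 41, pixel_size_um = 1)
  cl <- cell_spec(1, speed_um_min = 10, persistence_s = 60,
                  center_um = c(1500, 1500))
  msd <- matrix(0, 300, 40)
  for (s in 1:300) {
    pa <- simulate_motility(cl, p, seed = s)
    d <- sweep(pa[-1, , drop = FALSE], 2, pa[1, ])
    msd[s, ] <- rowSums(d^2)
  }
  tt <- (1:40) * p$frame_interval_s
  v <- 10 / 60; P <- 60
  theory <- 2 * v^2 * P * (tt - P * (1 - exp(-tt / P)))
  probe <- c(4, 10, 20, 40)
  expect_lt(max(abs(colMeans(msd)[probe] / theory[probe] - 1)), 0.1)
})

test_that("paths stay inside the field (reflecting boundary)", {
  p <- tiny_params(n_frames = 200)
  fast <- cell_spec(1, speed_um_min = 25, center_um = c(2, 2))
  pa <- simulate_motility(fast, p, seed = 3)
  L <- p$fov_px * p$pixel_size_um
  expect_true(all(pa[, 1] >= 0 & pa[, 1] <= L[2]))
  expect_true(all(pa[, 2] >= 0 & pa[, 2] <= L[1]))
})

test_that("calcium timeline composes events by per-pixel maximum", {
  p <- tiny_params(n_frames = 10)
  cl <- cell_spec(1, center_um = c(16, 16))
  pts <- as.matrix(expand.grid(x = seq(-3, 3, by = 0.684),
                               y = seq(-3, 3, by = 0.684)))
  # no events: baseline everywhere, every frame
  tl0 <- calcium_timeline(cl, list(), p)
  for (t in c(1, 5, 10)) expect_true(all(tl0(t, pts) == 100))
  # one local event: peak exactly on its footprint during its 2 frames
  ev <- ca_event_spec("local", 1, 4, 2, 1000, offset_um = c(1, 1))
  tl1 <- calcium_timeline(cl, list(ev), p)
  for (t in c(3, 6)) expect_true(all(tl1(t, pts) == 100))
  for (t in 4:5) {
    ca <- tl1(t, pts)
    w <- 2 * 0.684
    inside <- pts[, 1] >= 1 - w / 2 & pts[, 1] < 1 + w / 2 &
              pts[, 2] >= 1 - w / 2 & pts[, 2] < 1 + w / 2
    expect_true(all(ca[inside] == 1000))
    expect_true(all(ca[!inside] == 100))
  }
  # overlapping local (1000) + cell-wide (600): max wins on shared pixels
  cw <- ca_event_spec("cell_wide", 1, 4, 2, 600)
  tl2 <- calcium_timeline(cl, list(ev, cw), p)
  ca <- tl2(4, pts)
  brute <- pmax(ifelse(pts[, 1] >= 1 - 0.684 & pts[, 1] < 1 + 0.684 &
                         pts[, 2] >= 1 - 0.684 & pts[, 2] < 1 + 0.684, 1000, 100),
                600)
  expect_equal(ca, brute)
  expect_error(calcium_timeline(cl, list(ca_event_spec("local", 1, 9, 5, 500)), p),
               "outside movie range")
  expect_error(calcium_timeline(cl, list(ca_event_spec("local", 2, 1, 1, 500)), p),
               "different cell")
  expect_error(calcium_timeline(cl, list(ca_event_spec("local", 1, 1, 1, 50)), p),
               "baseline")
})

test_that("a null scene renders all-zero stacks", {
  p <- tiny_params(n_frames = 3, n_z = 2)
  dark <- cell_spec(1, red_brightness = 0, center_um = c(10, 10))
  mv <- render_movie(list(dark), list(), list(), p, seed = 1)
  expect_true(all(mv$red == 0) && all(mv$green == 0))
})

test_that("resting red:green ratio is exactly 5:1 in noiseless renders", {
  mv <- resting_cell_movie()$bundle
  cyt <- mv$red > 0
  expect_equal(mean(mv$red[cyt]) / mean(mv$green[cyt]), 5, tolerance = 1e-3)
  # per-pixel too, not just in the mean
  expect_lt(max(abs(mv$red[cyt] / mv$green[cyt] - 5)), 1e-9)
})

test_that("the red channel is bit-identical across Ca2+ scenarios", {
  p <- tiny_params(n_frames = 10, read_noise_sd = 15, background_counts = 50)
  cl <- cell_spec(1, center_um = c(16, 16), speed_um_min = 6)
  quiet <- render_movie(list(cl), list(), list(), p, seed = 8)
  active <- render_movie(list(cl),
                         list(ca_event_spec("cell_wide", 1, 3, 4, 1000)),
                         list(), p, seed = 8)
  expect_identical(quiet$red, active$red)
  expect_false(identical(quiet$green, active$green))
})

test_that("nuclear exclusion dims the cell centre", {
  # single plane through the cell centre so the nucleus is not bridged by
  # out-of-plane cytosol
  p <- acquisition_params(c(48, 48), n_frames = 1, n_z = 1)
  cl <- cell_spec(1, center_um = c(16, 16), z_um = 0, speed_um_min = 0,
                  nuclear_label_frac = 0.2)
  mv <- render_movie(list(cl), list(), list(), p, seed = 1)
  img <- matrix(mv$red[1, 1, , ], 48, 48)
  xc <- (seq_len(48) - 0.5) * p$pixel_size_um
  d2 <- outer((xc - 16)^2, (xc - 16)^2, "+")
  rn <- cl$radius_um * cl$nucleus_radius_frac
  nuc <- d2 <= (0.8 * rn)^2
  ring <- d2 > rn^2 & d2 <= cl$radius_um^2 * 0.9
  expect_lt(mean(img[nuc]), mean(img[ring]))
  expect_equal(mean(img[nuc]) / mean(img[ring]), 0.2, tolerance = 0.05)
})

test_that("ground-truth footprints stay inside the host cell mask", {
  sm <- sparkle_movie()
  gt <- sm$bundle$ground_truth
  for (ge in gt$events) {
    for (tn in names(ge$footprints)) {
      fp <- ge$footprints[[tn]]
      expect_gt(nrow(fp), 0)
      lab <- gt$cell_masks[[as.integer(tn)]]
      expect_true(all(lab[fp] == ge$spec$cell_id))
    }
  }
})

test_that("rendering is deterministic end-to-end for a fixed seed", {
  p <- tiny_params(n_frames = 6, read_noise_sd = 10, photon_scale = 2,
                   background_counts = 80)
  cl <- cell_spec(1, center_um = c(16, 16), speed_um_min = 8)
  ev <- list(ca_event_spec("local", 1, 2, 1, 700, offset_um = c(2.4, 0)))
  a <- render_movie(list(cl), ev, list(), p, seed = 21)
  b <- render_movie(list(cl), ev, list(), p, seed = 21)
  expect_identical(a$red, b$red)
  expect_identical(a$green, b$green)
  expect_false(identical(a$green,
                         render_movie(list(cl), ev, list(), p, seed = 22)$green))
})

test_that("duplicate cell ids are rejected", {
  p <- tiny_params(n_frames = 2)
  expect_error(render_movie(list(cell_spec(1, center_um = c(5, 5)),
                                 cell_spec(1, center_um = c(20, 20))),
                            list(), list(), p, seed = 1), "duplicate")
})

test_that("add_noise reduces to the identity without noise sources", {
  p <- tiny_params(n_frames = 2, photon_scale = Inf, read_noise_sd = 0)
  x <- array(runif(2 * 6 * 48 * 48, 0, 500), dim = c(2, 6, 48, 48))
  expect_identical(add_noise(x, p, seed = 1), x)
  expect_error(add_noise(x - 1000, p, seed = 1), "non-negative")
})

test_that("Poisson component has variance equal to its mean", {
  p <- acquisition_params(c(1000, 1000), n_frames = 1, n_z = 1,
                          photon_scale = 1, read_noise_sd = 0)
  x <- array(100, dim = c(1, 1, 1000, 1000))
  y <- add_noise(x, p, seed = 42)
  expect_lt(abs(var(as.vector(y)) / 100 - 1), 0.02)
  expect_lt(abs(mean(y) / 100 - 1), 0.01)
  expect_identical(y, add_noise(x, p, seed = 42))
})
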