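# Image conditioning chain: filters, projections, masking, subtractions.

test_that("median filter removes impulses and preserves constants", {
  const <- matrix(7, 9, 9)
  expect_equal(median_filter(const, 1, "disc"), const)
  expect_equal(median_filter(const, 1, "square"), const)
  imp <- matrix(0, 9, 9); imp[5, 5] <- 100
  expect_equal(median_filter(imp, 1, "disc"), matrix(0, 9, 9))
  expect_equal(median_filter(imp, 1, "square"), matrix(0, 9, 9))
  expect_error(median_filter(const, 0), ">= 1")
  # a 2x2 block survives the disc (cross) but not the square
  blk <- matrix(0, 9, 9); blk[4:5, 4:5] <- 10
  expect_equal(median_filter(blk, 1, "disc"), blk)
  expect_equal(median_filter(blk, 1, "square"), matrix(0, 9, 9))
})

test_that("median filter equals the double-loop oracle on random images", {
  set.seed(31)
  for (i in 1:8) {
    img <- matrix(rnorm(81), 9, 9)
    expect_equal(median_filter(img, 1, "disc"), median_oracle(img, 1, "disc"))
    expect_equal(median_filter(img, 1, "square"), median_oracle(img, 1, "square"))
    expect_equal(median_filter(img, 2, "disc"), median_oracle(img, 2, "disc"))
  }
})

test_that("z max-projection is the per-pixel maximum", {
  one <- array(rnorm(1 * 5 * 5), dim = c(1, 5, 5))
  expect_equal(max_project_z(one), matrix(one[1, , ], 5, 5))
  two <- array(0, dim = c(2, 4, 4)); two[2, , ] <- 7
  expect_equal(max_project_z(two), matrix(7, 4, 4))
  set.seed(2)
  stk <- array(rnorm(3 * 6 * 7), dim = c(3, 6, 7))
  loop <- matrix(0, 6, 7)
  for (r in 1:6) for (c in 1:7) loop[r, c] <- max(stk[, r, c])
  expect_equal(max_project_z(stk), loop)
  # 4-D input, frame by frame
  stk4 <- array(rnorm(2 * 3 * 4 * 5), dim = c(2, 3, 4, 5))
  pr <- max_project_z(stk4)
  for (t in 1:2) for (r in 1:4) for (c in 1:5)
    expect_equal(pr[t, r, c], max(stk4[t, , r, c]))
})

test_that("temporal average is the per-pixel mean over frames", {
  one <- array(rnorm(12), dim = c(1, 3, 4))
  expect_equal(temporal_average(one), matrix(one[1, , ], 3, 4))
  two <- array(0, dim = c(2, 3, 3)); two[2, , ] <- 10
  expect_equal(temporal_average(two), matrix(5, 3, 3))
  set.seed(3)
  stk <- array(rnorm(5 * 4 * 4), dim = c(5, 4, 4))
  loop <- matrix(0, 4, 4)
  for (r in 1:4) for (c in 1:4) loop[r, c] <- mean(stk[, r, c])
  expect_equal(temporal_average(stk), loop, tolerance = 1e-12)
})

test_that("Bernsen thresholding finds bright objects, not flat fields", {
  expect_false(any(bernsen_mask(matrix(50, 20, 20), 5, 15)))
  img <- matrix(10, 32, 32); img[13:20, 13:20] <- 200
  m <- bernsen_mask(img, 5, 15)
  expect_true(all(m[14:19, 14:19]))             # block interior is foreground
  expect_false(any(m[1:6, ]))                   # far background is not
  expect_error(bernsen_mask(img, 5, 0), "positive")
})

test_that("Bernsen mask equals the double-loop oracle on random images", {
  set.seed(7)
  for (i in 1:6) {
    img <- matrix(runif(20 * 20, 0, 100), 20, 20)
    expect_equal(bernsen_mask(img, 3, 20), bernsen_oracle(img, 3, 20))
  }
})

test_that("dilation grows masks by a disc and never shrinks them", {
  m <- matrix(FALSE, 11, 11); m[6, 6] <- TRUE
  expect_identical(dilate_mask(m, 0), m)
  d1 <- dilate_mask(m, 1)
  expect_equal(sum(d1), 5)                      # r=1 disc = 5-pixel cross
  expect_true(all(dilate_mask(matrix(TRUE, 5, 5), 3)))
  set.seed(11)
  for (i in 1:6) {
    mm <- matrix(runif(15 * 15) < 0.1, 15, 15)
    dd <- dilate_mask(mm, 2)
    expect_true(all(dd[mm]))                    # output contains input
    expect_equal(dd, dilate_oracle(mm, 2))
  }
})

test_that("analysis mask excludes dilated bright objects and manual regions", {
  flat <- matrix(100, 40, 40)
  expect_true(all(build_analysis_mask(flat, flat, preprocess_config())))
  bright <- flat; bright[15:20, 15:20] <- 30000
  m <- build_analysis_mask(bright, bright, preprocess_config())
  expect_false(any(m[15:20, 15:20]))
  expect_false(m[11, 17])                        # 4-px dilation reaches out
  expect_true(m[5, 5])
  cfgbox <- preprocess_config(manual_exclusions = list(c(2, 6, 3, 9)))
  mb <- build_analysis_mask(flat, flat, cfgbox)
  expect_false(any(mb[2:6, 3:9]))
  expect_true(all(mb[-(2:6), ]))
  expect_error(build_analysis_mask(flat, flat,
    preprocess_config(manual_exclusions = list(c(0, 6, 3, 9)))), "outside field")
  # polygon exclusion: right triangle
  tri <- rbind(c(5, 5), c(5, 25), c(25, 5))
  mt <- build_analysis_mask(flat, flat, preprocess_config(manual_exclusions = list(tri)))
  expect_false(mt[10, 10])
  expect_true(mt[24, 24])
  # monotonicity: adding exclusions never enlarges the analyzable area
  expect_lte(sum(build_analysis_mask(bright, bright, cfgbox)),
             sum(build_analysis_mask(bright, bright, preprocess_config())))
})

test_that("scaled red subtraction nulls a resting cell and keeps signs", {
  g <- matrix(100, 5, 5); r <- matrix(500, 5, 5)
  expect_equal(subtract_scaled_red(g, r, 0.2), matrix(0, 5, 5))
  expect_equal(subtract_scaled_red(g, r, 0), g)
  expect_equal(subtract_scaled_red(c(10, 20), c(20, 40), 0.2), c(6, 12))
  expect_true(any(subtract_scaled_red(matrix(0, 2, 2), matrix(5, 2, 2)) < 0))
  expect_error(subtract_scaled_red(matrix(1, 2, 2), matrix(1, 3, 3)), "shape")
})

test_that("temporal-mean subtraction yields an exactly zero-mean stack", {
  const <- array(4, dim = c(3, 4, 4))
  expect_equal(subtract_temporal_mean(const), array(0, dim = c(3, 4, 4)))
  two <- array(0, dim = c(2, 2, 2)); two[2, , ] <- 10
  out <- subtract_temporal_mean(two)
  expect_equal(as.vector(out[1, , ]), rep(-5, 4))
  expect_equal(as.vector(out[2, , ]), rep(5, 4))
  set.seed(5)
  stk <- array(rnorm(10 * 6 * 6), dim = c(10, 6, 6))
  expect_lt(max(abs(temporal_average(subtract_temporal_mean(stk)))), 1e-10)
  expect_error(subtract_temporal_mean(array(1, dim = c(1, 3, 3))), "T >= 2")
})

test_that("noiseless event-free movies preprocess to exactly zero", {
  mv <- resting_cell_movie()$bundle
  pp <- preprocess(mv)
  expect_lt(max(abs(pp$processed_green), na.rm = TRUE), 1e-6)
  expect_true(length(pp$provenance) >= 4)
})

test_that("a sparkle is the only positive structure in processed green", {
  sm <- sparkle_movie(start = 5, duration = 2)
  pp <- preprocess(sm$bundle)
  g <- pp$processed_green
  gt <- sm$bundle$ground_truth$events[[1]]
  # strong positives exactly at the footprint space-time
  hot <- which(g > 50, arr.ind = TRUE)
  expect_true(all(hot[, 1] %in% 5:6))
  for (t in 5:6) {
    fp <- gt$footprints[[as.character(t)]]
    hot_t <- hot[hot[, 1] == t, 2:3, drop = FALSE]
    expect_setequal(paste(hot_t[, 1], hot_t[, 2]), paste(fp[, 1], fp[, 2]))
  }
  # everywhere off the footprint columns, the chain still cancels exactly
  cols <- unique(do.call(rbind, gt$footprints))
  off_mask <- matrix(TRUE, 48, 48); off_mask[cols] <- FALSE
  for (t in seq_len(dim(g)[1]))
    expect_lt(max(abs(matrix(g[t, , ], 48, 48)[off_mask]), na.rm = TRUE), 1e-6)
})

test_that("the processing order is pinned and alternatives change output", {
  sm <- sparkle_movie()
  pp <- preprocess(sm$bundle)
  expect_match(pp$provenance[1], "median_filter")
  expect_match(pp$provenance[2], "max_project")
  expect_match(pp$provenance[4], "subtract_scaled_red")
  expect_match(pp$provenance[5], "subtract_temporal_mean")
  # component-reduction degeneracy: red_scale 0 and no masking equals the
  # mean-subtracted green projection
  cfg0 <- preprocess_config(red_scale = 0, mask_autofluor = FALSE)
  pp0 <- preprocess(sm$bundle, cfg0)
  gproj <- array(0, dim = dim(sm$bundle$green)[c(1, 3, 4)])
  for (t in seq_len(dim(sm$bundle$green)[1])) {
    planes <- lapply(seq_len(dim(sm$bundle$green)[2]), function(z)
      median_filter(matrix(sm$bundle$green[t, z, , ], 48, 48), 1, "disc"))
    gproj[t, , ] <- Reduce(pmax, planes)
  }
  expect_equal(pp0$processed_green, subtract_temporal_mean(gproj))
  # alternative temporal-mean convention changes the result
  ppalt <- preprocess(sm$bundle, preprocess_config(mean_after_red_subtraction = FALSE))
  expect_false(isTRUE(all.equal(pp$processed_green, ppalt$processed_green)))
  # square median element changes the result (the sparkle is erased)
  ppsq <- preprocess(sm$bundle, preprocess_config(median_shape = "square"))
  expect_lt(max(ppsq$processed_green, na.rm = TRUE),
            0.5 * max(pp$processed_green, na.rm = TRUE))
})

test_that("estimate_red_scale recovers the built-in 5:1 ratio", {
  mv <- resting_cell_movie(n_frames = 8)$bundle
  red_p <- max_project_z(mv$red)
  green_p <- max_project_z(mv$green)
  expect_equal(estimate_red_scale(red_p, green_p), 0.2, tolerance = 0.02)
})
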