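# equivalent-ellipse fitting, the prolate-spheroid formula, and volume
# trace assembly with short-gap repair

test_that("moment fitting recovers disk and ellipse axes", {
  d <- disk_mask(96, 96, 48, 48, 20)
  g <- fit_spheroid(d, 0.1)
  expect_equal(g$long_radius, 2, tolerance = 0.02)
  expect_equal(g$short_radius, 2, tolerance = 0.02)
  e <- ellipse_mask(128, 128, 64, 64, 30, 15)
  ge <- fit_spheroid(e, 1)
  expect_equal(ge$long_radius, 30, tolerance = 0.02 * 30)
  expect_equal(ge$short_radius, 15, tolerance = 0.02 * 15)
})

test_that("moment fitting is invariant under rotation", {
  e0 <- fit_spheroid(ellipse_mask(128, 128, 64, 64, 30, 15), 1)
  e37 <- fit_spheroid(ellipse_mask(128, 128, 64, 64, 30, 15,
                                   theta = 37 * pi / 180), 1)
  expect_equal(e37$long_radius, e0$long_radius,
               tolerance = 0.01 * e0$long_radius)
  expect_equal(e37$short_radius, e0$short_radius,
               tolerance = 0.01 * e0$short_radius)
  expect_equal(abs(e37$orientation) * 180 / pi, 37, tolerance = 0.05)
})

test_that("an empty mask signals the no-geometry condition", {
  expect_error(fit_spheroid(matrix(FALSE, 8, 8), 0.1),
               class = "cystovol_empty_mask")
})

test_that("the prolate-spheroid volume formula evaluates exactly", {
  expect_equal(volume_from_axes(1, 1), 4.18879, tolerance = 5e-7)
  expect_equal(volume_from_axes(3, 2), 16 * pi)
  expect_equal(volume_from_axes(5, 0), 0)
  expect_error(volume_from_axes(-1, 0), "nonnegative")
  expect_error(volume_from_axes(1, 2), "long_radius")
})

test_that("short invalid runs are linearly interpolated, long runs kept invalid", {
  nf <- 9
  masks <- array(FALSE, dim = c(96, 96, nf))
  r1 <- 14; r2 <- 13.4
  for (i in seq_len(nf)) masks[, , i] <- disk_mask(96, 96, 48, 48, r1)
  masks[, , 4] <- disk_mask(96, 96, 48, 48, r2)
  masks[, , 5:9] <- masks[, , 5:9] & FALSE   # placeholder, reset below
  for (i in 5:9) masks[, , i] <- disk_mask(96, 96, 48, 48, r2)
  ms <- mask_sequence(masks)
  ms$masks[, , 2:3] <- FALSE; ms$valid[2:3] <- FALSE   # 2-frame gap
  tt <- (seq_len(nf) - 1) / 30
  v <- build_volume_trace(ms, tt, 0.15, max_gap = 2)
  expect_true(all(v$valid))
  v1 <- v$volume[1]; v4 <- v$volume[4]
  expect_equal(v$volume[2], v1 + (v4 - v1) / 3)
  expect_equal(v$volume[3], v1 + 2 * (v4 - v1) / 3)
  # interpolated samples stay within the flanking values
  expect_true(all(v$volume[2:3] <= max(v1, v4) & v$volume[2:3] >= min(v1, v4)))
  # a 5-frame gap exceeds max_gap and stays invalid
  ms2 <- mask_sequence(masks)
  ms2$masks[, , 3:7] <- FALSE; ms2$valid[3:7] <- FALSE
  v2 <- build_volume_trace(ms2, tt, 0.15, max_gap = 2)
  expect_false(any(v2$valid[3:7]))
  expect_true(all(v2$valid[c(1, 2, 8, 9)]))
  # an all-invalid sequence is diagnosed
  ms3 <- mask_sequence(array(FALSE, dim = c(8, 8, 3)),
                       valid = rep(FALSE, 3))
  expect_error(build_volume_trace(ms3, 0:2 / 30, 0.15), "invalid")
})

test_that("volumes scale with the cube of the pixel size", {
  m <- ellipse_mask(96, 96, 48, 48, 25, 16)
  g1 <- fit_spheroid(m, 0.1)
  g2 <- fit_spheroid(m, 0.2)
  expect_equal(g2$long_radius, 2 * g1$long_radius)
  expect_equal(g2$short_radius, 2 * g1$short_radius)
  expect_equal(volume_from_axes(g2$long_radius, g2$short_radius),
               8 * volume_from_axes(g1$long_radius, g1$short_radius))
})

test_that("noise-free end-to-end volumetry recovers the true volume", {
  cfg <- quick_config(seed = 3, noise_sd = 0, background = FALSE,
                      pixel_size = 0.1, image_shape = c(144L, 144L),
                      duration = 8)
  tr <- simulate_recording(cfg)
  masks <- segment_sequence(tr$frames, seg_params(cfg$pixel_size),
                            smooth_window = 1, quiet = TRUE)
  v <- build_volume_trace(masks, tr$frames$timestamps, cfg$pixel_size)
  vt <- tr$volume_trace$volume
  sel <- vt >= 5
  err <- abs(v$volume[sel] - vt[sel]) / pmax(vt[sel], 5)
  expect_true(all(v$valid[sel]))
  expect_lt(max(err), 0.05)
})
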