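# rolling average, reference per-frame segmentation, sequence segmentation

test_that("rolling average reproduces constants and degenerates to identity", {
  f <- array(rep(c(0.2, 0.2, 0.2), each = 64), dim = c(8, 8, 3))
  fs <- frame_sequence(f, 0:2 / 30, 0.1)
  expect_equal(rolling_average(fs, 3)$frames, fs$frames)
  g <- array(runif(8 * 8 * 5), dim = c(8, 8, 5))
  gs <- frame_sequence(g, 0:4 / 30, 0.1)
  expect_identical(rolling_average(gs, 1)$frames, gs$frames)
  expect_error(rolling_average(gs, 4), "odd")
})

test_that("rolling average of an impulse spreads to the window mean", {
  n <- 31
  f <- array(0, dim = c(5, 5, n))
  f[3, 3, 16] <- 15
  fs <- frame_sequence(f, (0:(n - 1)) / 30, 0.1)
  out <- rolling_average(fs, 15)$frames
  # frames fully inside the impulse window see 15/15 = 1 at that pixel
  expect_equal(out[3, 3, 16], 1)
  expect_equal(out[3, 3, 12], 1)
  expect_equal(out[3, 3, 20], 1)
  expect_equal(out[3, 3, 1], 0)   # shrunken edge window never reaches it
  expect_equal(out[2, 2, 16], 0)
})

test_that("a clean rendered frame is segmented at high overlap", {
  cfg <- quick_config(seed = 2, noise_sd = 0, background = FALSE,
                      duration = 2)
  tr <- simulate_recording(cfg)
  k <- which.max(tr$volume_trace$volume)
  res <- segment_frame(tr$frames$frames[, , k], seg_params(cfg$pixel_size))
  expect_true(res$valid)
  expect_gte(dice(res$mask, tr$masks$masks[, , k]), 0.98)
})

test_that("degenerate frames yield invalid, never an error", {
  p <- seg_params(0.15)
  res <- segment_frame(matrix(0.5, 64, 64), p)
  expect_false(res$valid)
  expect_false(any(res$mask))
  expect_error(segment_frame(matrix(c(NA, 0.5), 8, 8), p), "finite")
})

test_that("of two dark blobs only the largest is retained", {
  frame <- matrix(0.8, 96, 96)
  big <- disk_mask(96, 96, 30, 30, 13)     # ~530 px
  small <- disk_mask(96, 96, 70, 70, 5)    # ~80 px
  frame[big] <- 0.1
  frame[small] <- 0.1
  res <- segment_frame(frame, seg_params(0.15, min_area = 20))
  expect_true(res$valid)
  expect_gt(sum(res$mask & big), 0.9 * sum(big))
  expect_identical(sum(res$mask & small), 0L)
})

test_that("largest-component selection is idempotent and 8-connected", {
  m <- matrix(FALSE, 20, 20)
  m[2:5, 2:5] <- TRUE
  m[6, 6] <- TRUE          # diagonal touch joins the big component
  m[15:16, 15] <- TRUE
  one <- largest_component(m)
  expect_identical(largest_component(one), one)
  expect_true(one[6, 6])
  expect_false(any(one[15:16, 15]))
})

test_that("sequence segmentation flags exactly the degenerate frames", {
  cfg <- quick_config(seed = 4, duration = 2)
  tr <- simulate_recording(cfg)
  fr <- tr$frames
  fr$frames[, , c(20, 45)] <- 0.5   # blank two frames mid-sequence
  masks <- segment_sequence(fr, seg_params(cfg$pixel_size),
                            smooth_window = 1, quiet = TRUE)
  expect_false(any(masks$valid[c(20, 45)]))
  expect_true(all(masks$valid[-c(20, 45)]))
  # every valid mask is a single connected component (count oracle)
  for (i in which(masks$valid)) {
    lab <- EBImage::bwlabel(EBImage::Image(masks$masks[, , i] * 1))
    expect_equal(max(lab), 1)
  }
})

test_that("a fully voided interval is invalid where the bladder vanishes", {
  cfg <- quick_config(seed = 6, noise_sd = 0, background = FALSE,
                      fill_rate = 300, capacity_threshold = 50,
                      residual_fraction = 0, duration = 14)
  tr <- simulate_recording(cfg)
  masks <- segment_sequence(tr$frames, seg_params(cfg$pixel_size),
                            smooth_window = 1, quiet = TRUE)
  p <- seg_params(cfg$pixel_size)
  gt_area <- apply(tr$masks$masks, 3, sum)
  expect_true(all(masks$valid[gt_area >= 1.5 * p$min_area]))
  expect_true(all(!masks$valid[gt_area <= 0.5 * p$min_area]))
})

test_that("segmentation quality degrades monotonically with sensor noise", {
  med <- vapply(c(0.01, 0.06, 0.15), function(ns) {
    cfg <- quick_config(seed = 9, noise_sd = ns, duration = 4)
    tr <- simulate_recording(cfg)
    masks <- segment_sequence(tr$frames, seg_params(cfg$pixel_size),
                              quiet = TRUE)
    holdout_evaluate(masks, tr$masks, 1, seed = 1, quiet = TRUE)$median
  }, numeric(1))
  expect_true(all(diff(med) <= 1e-9))
})
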