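# synthetic lower-urinary-tract generator: volume balance, void events,
# nonvoiding contractions, rendering geometry

test_that("constant filling integrates the configured rate exactly", {
  cfg <- sim_config(fill_rate = 20, capacity_threshold = 1e5, duration = 60,
                    nvc_rate = 0, seed = 1)
  tr <- simulate_dynamics(cfg)
  v <- tr$volume_trace$volume
  expect_equal(v[length(v)] - v[1], 20, tolerance = 1e-3)
  expect_true(all(diff(v) >= 0))
})

test_that("quiescent configuration leaves volume and pressure flat", {
  cfg <- sim_config(fill_rate = 0, nvc_rate = 0, capacity_threshold = 100,
                    duration = 30, seed = 1)
  tr <- simulate_dynamics(cfg)
  expect_equal(diff(range(tr$volume_trace$volume)), 0)
  expect_equal(unique(tr$pressure_trace$pressure), cfg$baseline_pressure)
  expect_identical(nrow(tr$void_events), 0L)
})

test_that("a triggered void reaches the residual target and conserves volume", {
  # recording starts at the residual volume (50 ul), so capacity is first
  # reached after 150 s of filling at 20 ul/min; stop before the second cycle
  cfg <- sim_config(fill_rate = 20, capacity_threshold = 100,
                    residual_fraction = 0.5, duration = 200, nvc_rate = 0,
                    seed = 3)
  tr <- simulate_dynamics(cfg)
  expect_identical(nrow(tr$void_events), 1L)
  ev <- tr$void_events
  expect_equal(ev$voided, 50, tolerance = 0.01)
  # conservation: volume drop across the void equals the integral of
  # (outflow - inflow) over it, by quadrature of the generated outflow
  t <- tr$volume_trace$time
  sel <- t >= ev$onset & t <= ev$end
  q_net <- trapezoid(t[sel], tr$outflow[sel]) -
    cfg$fill_rate / 60 * (ev$end - ev$onset)
  expect_equal(q_net, ev$voided, tolerance = 0.01)
})

test_that("nonphysical configurations are rejected with a diagnostic", {
  expect_error(sim_config(fill_rate = -1), "fill_rate")
  expect_error(sim_config(residual_fraction = 1.2), "residual_fraction")
  expect_error(sim_config(capacity_threshold = 0), "capacity_threshold")
  expect_error(sim_config(aspect_ratio = 0.8), "aspect_ratio")
  expect_error(sim_config(frame_rate = 0), "frame_rate")
  # filling faster than the urethra can void is diagnosed at run time
  cfg <- sim_config(fill_rate = 3000, capacity_threshold = 50, duration = 10)
  expect_error(simulate_dynamics(cfg), "outflow")
})

test_that("identical configuration reproduces traces and frames bit for bit", {
  cfg <- quick_config(seed = 11, duration = 3)
  a <- simulate_recording(cfg)
  b <- simulate_recording(cfg)
  expect_identical(a$volume_trace, b$volume_trace)
  expect_identical(a$pressure_trace, b$pressure_trace)
  expect_identical(a$void_events, b$void_events)
  expect_identical(a$frames$frames, b$frames$frames)
  expect_identical(a$masks$masks, b$masks$masks)
})

test_that("nonvoiding contractions raise pressure without moving volume", {
  cfg <- sim_config(fill_rate = 10, capacity_threshold = 1e5, duration = 120,
                    nvc_rate = 4, nvc_amplitude = 8, seed = 7)
  tr <- simulate_dynamics(cfg)
  expect_gt(length(tr$nvc_times), 2)
  vf <- approxfun(tr$volume_trace$time, tr$volume_trace$volume)
  fill <- cfg$fill_rate / 60
  for (t0 in tr$nvc_times) {
    dv <- vf(t0 + cfg$nvc_duration) - vf(t0) - fill * cfg$nvc_duration
    expect_lt(abs(dv), 0.5)
  }
  expect_gt(max(tr$pressure_trace$pressure),
            cfg$baseline_pressure + 0.9 * cfg$nvc_amplitude)
})

test_that("rendered spheroid geometry matches the volume formula", {
  # sphere: V = 33.51 ul with aspect 1 must render a 2 mm radius circle
  cfg <- sim_config(fill_rate = 0, capacity_threshold = 100, duration = 0.2,
                    aspect_ratio = 1, noise_sd = 0, background = FALSE,
                    nvc_rate = 0, pixel_size = 0.1,
                    image_shape = c(96L, 96L), seed = 2)
  tr <- simulate_dynamics(cfg)
  tr$volume_trace$volume[] <- 33.51
  rend <- render_frames(tr, cfg)
  g <- fit_spheroid(rend$masks$masks[, , 1], cfg$pixel_size)
  expect_equal(g$long_radius, 2, tolerance = 0.02)
  expect_equal(g$short_radius, 2, tolerance = 0.02)
  # mask area agrees with pi * a * b in pixel units
  ab_px <- rend$axes_per_frame[1, ] / cfg$pixel_size
  expect_equal(sum(rend$masks$masks[, , 1]), pi * prod(ab_px),
               tolerance = 0.02 * pi * prod(ab_px))
})

test_that("zero volume renders an empty ground-truth mask", {
  cfg <- quick_config(noise_sd = 0, background = FALSE)
  tr <- simulate_dynamics(cfg)
  tr$volume_trace$volume[] <- 0
  rend <- render_frames(tr, cfg)
  expect_false(any(rend$masks$masks))
})

test_that("a bladder too large for the field names the offending frame", {
  cfg <- sim_config(fill_rate = 0, capacity_threshold = 1e5, duration = 0.1,
                    image_shape = c(48L, 48L), pixel_size = 0.1,
                    nvc_rate = 0, seed = 1)
  tr <- simulate_dynamics(cfg)
  tr$volume_trace$volume[] <- 400   # ~6 mm semi-axis >> 2.4 mm half-field
  expect_error(render_frames(tr, cfg), "frame 1")
})

test_that("ground-truth masks round-trip through spheroid fitting", {
  cfg <- quick_config(seed = 5, noise_sd = 0, background = FALSE,
                      duration = 8)
  tr <- simulate_recording(cfg)
  v <- tr$volume_trace$volume
  for (i in which(v >= 5)) {
    g <- fit_spheroid(tr$masks$masks[, , i], cfg$pixel_size)
    expect_equal(g$long_radius, unname(tr$axes_per_frame[i, "long"]),
                 tolerance = 0.02)
    expect_equal(g$short_radius, unname(tr$axes_per_frame[i, "short"]),
                 tolerance = 0.02)
  }
})
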