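# void detection, per-void urodynamic parameters, NVC counting

test_that("quiescent traces yield no void events", {
  tt <- (0:600) / 30
  v <- volume_trace(tt, rep(40, length(tt)))
  fl <- compute_ufr(v)
  expect_identical(nrow(detect_voids(v, fl)), 0L)
})

test_that("a single simulated void is found close to its true onset", {
  cfg <- sim_config(fill_rate = 60, capacity_threshold = 100,
                    residual_fraction = 0, duration = 130, nvc_rate = 0,
                    seed = 9)
  tr <- simulate_dynamics(cfg)
  a <- analyze_truth(tr)
  ev <- detect_voids(a$vsm, a$flow)
  expect_identical(nrow(ev), 1L)
  expect_lt(abs(ev$onset[1] - tr$void_events$onset[1]), 0.5)
})

test_that("two voids give the right count and intercontractile interval", {
  cfg <- sim_config(fill_rate = 20, capacity_threshold = 100,
                    residual_fraction = 0, duration = 650, nvc_rate = 0,
                    seed = 4)
  tr <- simulate_dynamics(cfg)
  a <- analyze_truth(tr)
  ev <- detect_voids(a$vsm, a$flow)
  expect_identical(nrow(ev), 2L)
  vp <- void_parameters(ev, a$vsm, a$flow)
  gt_ici <- diff(tr$void_events$onset)
  expect_lt(abs(vp$ici[2] - gt_ici), 1)
})

test_that("per-void parameters follow their definitions on a linear void", {
  tt <- seq(0, 10, by = 1 / 30)
  V <- ifelse(tt < 4, 100, ifelse(tt < 6, 100 - 50 * (tt - 4), 0))
  v <- volume_trace(tt, V)
  fl <- compute_ufr(v)
  ev <- detect_voids(v, fl)
  expect_identical(nrow(ev), 1L)
  vp <- void_parameters(ev, v, fl)
  expect_equal(vp$BC, 100, tolerance = 0.02 * 100)
  expect_lt(vp$RV, 2)
  expect_equal(vp$efficiency, 100, tolerance = 2)
  # 20% -> 80% of a linear decline spans 60% of its 2 s duration
  expect_equal(vp$t20_80, 1.2, tolerance = 1 / 30)
  expect_lte(vp$t20_80, vp$end - vp$onset)
})

test_that("efficiency follows 100 * (BC - RV) / BC for partial voids", {
  tt <- seq(0, 10, by = 1 / 30)
  V <- ifelse(tt < 4, 100, ifelse(tt < 6, 100 - 25 * (tt - 4), 50))
  v <- volume_trace(tt, V)
  fl <- compute_ufr(v)
  vp <- void_parameters(detect_voids(v, fl), v, fl)
  expect_equal(vp$BC, 100, tolerance = 1)
  expect_equal(vp$RV, 50, tolerance = 1)
  expect_equal(vp$efficiency, 50, tolerance = 1.5)
})

test_that("a zero-capacity event has undefined efficiency", {
  tt <- (0:90) / 30
  v <- volume_trace(tt, rep(0, length(tt)))
  fl <- compute_ufr(v)
  vp <- void_parameters(data.frame(onset = 1, end = 2), v, fl)
  expect_true(is.na(vp$efficiency))
})

test_that("batch parameter recovery stays within urodynamic tolerances", {
  caps <- c(50, 120, 250, 400)
  rfs <- c(0, 0.25, 0.5, 0.25)
  n_ok <- 0
  for (i in seq_along(caps)) {
    cfg <- sim_config(fill_rate = 100, capacity_threshold = caps[i],
                      residual_fraction = rfs[i],
                      duration = ceiling(caps[i] * 0.6) + 30,
                      nvc_rate = 1, seed = 40 + i)
    tr <- simulate_dynamics(cfg)
    a <- analyze_truth(tr, with_pressure = TRUE)
    ev <- detect_voids(a$vsm, a$flow)
    expect_identical(nrow(ev), nrow(tr$void_events))
    vp <- void_parameters(ev, a$vsm, a$flow, a$p)
    vtrue <- approxfun(tr$volume_trace$time, tr$volume_trace$volume)
    for (k in seq_len(nrow(ev))) {
      bc <- vtrue(tr$void_events$onset[k])
      rv <- vtrue(tr$void_events$end[k])
      expect_lt(abs(vp$BC[k] - bc), max(0.05 * bc, 3))
      expect_lt(abs(vp$RV[k] - rv), max(0.05 * rv, 3))
      expect_lt(abs(vp$efficiency[k] - 100 * (bc - rv) / bc), 3)
      expect_lte(vp$t20_80[k], vp$end[k] - vp$onset[k])
      n_ok <- n_ok + 1
    }
  }
  expect_gte(n_ok, 4)
})

test_that("NVC counting matches the generator and its exclusion rules", {
  # flat pressure: nothing to count
  tt <- (0:3000) / 30
  v <- volume_trace(tt, rep(50, length(tt)))
  expect_identical(count_nvcs(rep(10, length(tt)), v, 90), 0L)
  # three constructed 8 cmH2O pulses in the window
  p <- rep(10, length(tt))
  for (t0 in c(30, 50, 70))
    p <- p + 8 * sin(pi * pmin(pmax((tt - t0) / 3, 0), 1))^2
  expect_identical(count_nvcs(p, v, 90), 3L)
  # a pulse with a 20 ul volume drop is a leak/void, not an NVC
  V2 <- 50 - 20 * pmin(pmax((tt - 50) / 3, 0), 1)
  v2 <- volume_trace(tt, V2)
  p2 <- rep(10, length(tt)) +
    8 * sin(pi * pmin(pmax((tt - 50) / 3, 0), 1))^2
  expect_identical(count_nvcs(p2, v2, 90), 0L)
})

test_that("NVC counts agree with ground truth on simulated recordings", {
  cfg <- sim_config(fill_rate = 120, capacity_threshold = 200,
                    duration = 120, nvc_rate = 3, seed = 5)
  tr <- simulate_dynamics(cfg)
  a <- analyze_truth(tr, with_pressure = TRUE)
  on1 <- tr$void_events$onset[1]
  mid <- tr$nvc_times + cfg$nvc_duration / 2
  gt_n <- sum(mid >= on1 - 80 & mid < on1)
  expect_identical(count_nvcs(a$p, a$vsm, on1), as.integer(gt_n))
})
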