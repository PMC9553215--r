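# shared fixtures: all synthetic, generated at test time

# small, fast recording: one filling/voiding cycle on a 96x96 field
quick_config <- function(seed = 1L, ...) {
  args <- list(fill_rate = 300, capacity_threshold = 60,
               residual_fraction = 0.25, duration = 10,
               image_shape = c(96L, 96L), pixel_size = 0.15, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

# smoothed trace + flow (+ aligned pressure/UFC when requested)
analyze_truth <- function(truth, with_pressure = FALSE, sg_window = 31L) {
  vsm <- smooth_volume(truth$volume_trace, window = sg_window)
  flow <- compute_ufr(vsm)
  p <- NULL
  if (with_pressure) {
    p <- align_pressure(truth$pressure_trace, vsm$time)
    flow <- compute_ufc(flow, p)
  }
  list(vsm = vsm, flow = flow, p = p)
}

# rasterized filled ellipse mask (axis-aligned unless rotated)
ellipse_mask <- function(nr, nc, cr, cc, a, b, theta = 0) {
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  u <- ((cols - cc) * cos(theta) + (rows - cr) * sin(theta)) / a
  w <- (-(cols - cc) * sin(theta) + (rows - cr) * cos(theta)) / b
  u * u + w * w <= 1
}

disk_mask <- function(nr, nc, cr, cc, r) ellipse_mask(nr, nc, cr, cc, r, r)

# brute-force Dice by explicit pixel loop (independent oracle)
dice_pixel_loop <- function(x, y) {
  inter <- 0L; sx <- 0L; sy <- 0L
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
    if (x[i, j]) sx <- sx + 1L
    if (y[i, j]) sy <- sy + 1L
    if (x[i, j] && y[i, j]) inter <- inter + 1L
  }
  if (sx + sy == 0L) return(NA_real_)
  2 * inter / (sx + sy)
}

trapezoid <- function(t, y) sum((y[-1] + y[-length(y)]) * diff(t)) / 2
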