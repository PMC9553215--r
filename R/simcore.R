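# Synthetic lower-urinary-tract simulator: volume/pressure dynamics with
# voiding and nonvoiding contractions, rendered as fluoroscopy-like frames
# with ground-truth masks. Provides the ground truth against which every
# downstream stage of the package is validated.

#' Simulation configuration
#'
#' Parameters of the synthetic cystometry experiment. Defaults emulate a
#' catheterized-mouse recording: pump infusion at 20 ul/min, bladder
#' capacity near 90 ul, imaging at 30 frames/s and pressure sampling at
#' 50 Hz. For the noninvasive (renal-filling) regime lower the fill rate to
#' ~7 ul/min and ignore the pressure trace.
#'
#' @param fill_rate bladder filling rate, ul/min.
#' @param capacity_threshold volume that triggers a voiding contraction, ul.
#' @param residual_fraction fraction of capacity left in the bladder when a
#'   void ends, in `[0, 1]`.
#' @param void_conductance peak urethral flow conductance during a void,
#'   ul s^-1 cmH2O^-1.
#' @param contraction_pressure peak voiding-contraction amplitude above
#'   baseline, cmH2O.
#' @param baseline_pressure resting intravesical pressure, cmH2O.
#' @param nvc_rate rate of nonvoiding contractions, events/min.
#' @param nvc_amplitude peak amplitude of a nonvoiding contraction, cmH2O.
#' @param nvc_duration duration of a nonvoiding-contraction pulse, s.
#' @param duration simulated recording length, s.
#' @param image_shape rendered frame size, pixels (rows, cols).
#' @param pixel_size mm per pixel.
#' @param frame_rate imaging rate, frames/s.
#' @param pressure_rate pressure sampling rate, samples/s.
#' @param aspect_ratio long/short semi-axis ratio of the rendered prolate
#'   spheroid (>= 1).
#' @param background render the moving high-contrast background structures
#'   (`FALSE` gives a uniform background, e.g. for rendering round-trip
#'   checks).
#' @param background_motion_amplitude RMS excursion of the moving background
#'   structures, pixels.
#' @param bladder_motion_step per-frame standard deviation of the bladder
#'   center random walk, pixels.
#' @param attenuation contrast attenuation coefficient of the filled
#'   bladder, mm^-1 (Beer-Lambert along the projection chord).
#' @param noise_sd additive sensor noise standard deviation, intensity units
#'   (frames are on a `[0, 1]` scale).
#' @param seed integer seed controlling all randomness of the simulation.
#' @return An object of class `sim_config`.
#' @seealso [simulate_dynamics()], [render_frames()], [simulate_recording()]
#' @export
sim_config <- function(fill_rate = 20,
                       capacity_threshold = 90,
                       residual_fraction = 0.25,
                       void_conductance = 2,
                       contraction_pressure = 25,
                       baseline_pressure = 10,
                       nvc_rate = 2,
                       nvc_amplitude = 8,
                       nvc_duration = 3,
                       duration = 300,
                       image_shape = c(128L, 128L),
                       pixel_size = 0.2,
                       frame_rate = 30,
                       pressure_rate = 50,
                       aspect_ratio = 1.5,
                       background = TRUE,
                       background_motion_amplitude = 4,
                       bladder_motion_step = 0.25,
                       attenuation = 0.5,
                       noise_sd = 0.03,
                       seed = 1L) {
  cfg <- list(fill_rate = fill_rate, capacity_threshold = capacity_threshold,
              residual_fraction = residual_fraction,
              void_conductance = void_conductance,
              contraction_pressure = contraction_pressure,
              baseline_pressure = baseline_pressure,
              nvc_rate = nvc_rate, nvc_amplitude = nvc_amplitude,
              nvc_duration = nvc_duration, duration = duration,
              image_shape = as.integer(image_shape), pixel_size = pixel_size,
              frame_rate = frame_rate, pressure_rate = pressure_rate,
              aspect_ratio = aspect_ratio, background = isTRUE(background),
              background_motion_amplitude = background_motion_amplitude,
              bladder_motion_step = bladder_motion_step,
              attenuation = attenuation, noise_sd = noise_sd,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  check <- function(ok, msg) if (!isTRUE(ok)) stop("invalid sim_config: ", msg,
                                                   call. = FALSE)
  check(cfg$fill_rate >= 0, "fill_rate must be >= 0 (ul/min)")
  check(cfg$capacity_threshold > 0, "capacity_threshold must be > 0 (ul)")
  check(cfg$residual_fraction >= 0 && cfg$residual_fraction <= 1,
        "residual_fraction must lie in [0, 1]")
  check(cfg$void_conductance >= 0, "void_conductance must be >= 0")
  check(cfg$contraction_pressure >= 0, "contraction_pressure must be >= 0")
  check(cfg$nvc_rate >= 0, "nvc_rate must be >= 0 (events/min)")
  check(cfg$nvc_duration > 0, "nvc_duration must be > 0 (s)")
  check(cfg$duration > 0, "duration must be > 0 (s)")
  check(cfg$frame_rate > 0, "frame_rate must be > 0")
  check(cfg$pressure_rate > 0, "pressure_rate must be > 0")
  check(cfg$aspect_ratio >= 1, "aspect_ratio must be >= 1")
  check(cfg$pixel_size > 0, "pixel_size must be > 0 (mm/pixel)")
  check(all(cfg$image_shape >= 16L), "image_shape must be at least 16x16 px")
  check(cfg$noise_sd >= 0, "noise_sd must be >= 0")
  check(cfg$attenuation > 0, "attenuation must be > 0 (1/mm)")
  invisible(cfg)
}

# run expr with a private RNG stream; global .Random.seed is untouched
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# raised-cosine (Hann) pulse shape on [0, 1]
hann_pulse <- function(u) ifelse(u > 0 & u < 1, sin(pi * u)^2, 0)

#' Simulate lower-urinary-tract dynamics (no images)
#'
#' Integrates the volume balance `dV/dt = fill - outflow` on a fine time
#' grid. Filling is constant at `fill_rate`. A voiding contraction is
#' triggered whenever the volume reaches `capacity_threshold`: intravesical
#' pressure rises by a raised-cosine pulse of amplitude
#' `contraction_pressure` while the urethral conductance opens along a
#' raised-cosine profile peaking mid-void (peak `void_conductance`), so the
#' outflow is `conductance(t) * p_ves(t)`. The void ends when the volume
#' falls to `residual_fraction` times the capacity at onset (or when the
#' contraction profile ends, whichever comes first). Nonvoiding contractions
#' are raised-cosine pressure pulses at Poisson times (`nvc_rate`) with no
#' associated volume change; pulses that would overlap a void are dropped.
#'
#' @param config a [sim_config()].
#' @return An object of class `sim_truth`: a list with `volume_trace`
#'   (sampled at `frame_rate`), `pressure_trace` (sampled at
#'   `pressure_rate`), `outflow` (ul/s, on the volume timebase),
#'   `void_events` (data frame `onset`, `end`, `voided` in s/s/ul),
#'   `nvc_times` (s), and the `config`.
#' @export
simulate_dynamics <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, simulate_dynamics_impl(config))
}

simulate_dynamics_impl <- function(cfg) {
  dt <- 1 / max(500, 4 * cfg$pressure_rate, 4 * cfg$frame_rate)
  n <- ceiling(cfg$duration / dt) + 1L
  tt <- (seq_len(n) - 1L) * dt
  fill <- cfg$fill_rate / 60          # ul/s
  A <- cfg$contraction_pressure
  g_peak <- cfg$void_conductance
  p0 <- cfg$baseline_pressure

  # candidate NVC onset times: Poisson process with a refractory gap
  # (successive contractions do not overlap), thinned later around voids
  nvc_cand <- numeric(0)
  if (cfg$nvc_rate > 0) {
    t_acc <- 0
    last <- -Inf
    repeat {
      t_acc <- t_acc + rexp(1, rate = cfg$nvc_rate / 60)
      if (t_acc > cfg$duration - cfg$nvc_duration) break
      if (t_acc - last >= cfg$nvc_duration + 2) {
        nvc_cand <- c(nvc_cand, t_acc)
        last <- t_acc
      }
    }
  }

  # nominal void length: raised-cosine conductance against the pulse
  # pressure removes g_peak*(p0/2 + 3A/8) ul/s on average; allow headroom so
  # the residual target is reached before the profile closes
  mean_outflow <- g_peak * (p0 / 2 + 3 * A / 8)
  if (cfg$fill_rate > 0 && mean_outflow > 0 && fill >= 0.8 * mean_outflow)
    stop(sprintf(paste0("fill rate (%.1f ul/s) approaches or exceeds the ",
                        "mean urethral outflow during a void (%.1f ul/s); ",
                        "voids could not empty the bladder -- lower ",
                        "fill_rate or raise void_conductance/pressures"),
                 fill, mean_outflow))

  V <- numeric(n); p_void <- numeric(n); outflow <- numeric(n)
  V[1] <- cfg$residual_fraction * cfg$capacity_threshold
  in_void <- FALSE; closing <- FALSE
  v_on <- NA_real_; t_on <- NA_real_; t_close <- NA_real_
  T_void <- NA_real_; resid_target <- NA_real_
  ramp_T <- 0.15   # urethral closing time, s: keeps outflow continuous
  events <- list()

  for (i in seq_len(n - 1L)) {
    if (!in_void && V[i] >= cfg$capacity_threshold && mean_outflow > 0) {
      in_void <- TRUE; closing <- FALSE
      t_on <- tt[i]; v_on <- V[i]
      resid_target <- cfg$residual_fraction * v_on
      T_void <- 1.6 * (v_on - resid_target) / (mean_outflow - fill)
    }
    q <- 0
    if (in_void) {
      u <- (tt[i] - t_on) / T_void
      p_void[i] <- A * hann_pulse(u)
      q <- g_peak * hann_pulse(u) * (p0 + p_void[i])
      # start closing when the volume still to be voided matches what the
      # closing ramp itself will pass, so the residual target is met
      if (!closing && u > 0.05 && V[i] - resid_target <= q * ramp_T / 2) {
        closing <- TRUE
        t_close <- tt[i]
      }
      if (closing) {
        w <- if (tt[i] < t_close + ramp_T)
          0.5 * (1 + cos(pi * (tt[i] - t_close) / ramp_T)) else 0
        q <- q * w
        p_void[i] <- p_void[i] * w
      }
      if ((closing && tt[i] >= t_close + ramp_T) || u >= 1) {
        in_void <- FALSE; closing <- FALSE
        events[[length(events) + 1L]] <-
          c(onset = t_on, end = tt[i], voided = v_on - V[i])
        p_void[i] <- 0
        q <- 0
      }
    }
    outflow[i] <- q
    V[i + 1L] <- max(0, V[i] + dt * (fill - q))
  }
  if (in_void)   # void still in progress when the recording ends
    events[[length(events) + 1L]] <-
      c(onset = t_on, end = tt[n], voided = v_on - V[n])
  ev <- if (length(events))
    as.data.frame(do.call(rbind, events))
  else data.frame(onset = numeric(0), end = numeric(0), voided = numeric(0))
  # logged onset = start of measurable urine expulsion (outflow crossing
  # 1% of the void's peak), not the contraction trigger: flow under the
  # raised-cosine opening profile is negligible for a while after the
  # trigger, and void timing is defined on the flow/volume signal
  if (nrow(ev)) for (k in seq_len(nrow(ev))) {
    sel <- which(tt >= ev$onset[k] & tt <= ev$end[k])
    qk <- outflow[sel]
    j <- sel[which(qk > 0.01 * max(qk))[1]]
    if (length(j) && !is.na(j)) {
      ev$onset[k] <- tt[j]
      ev$voided[k] <- V[j] - approx(tt, V, xout = ev$end[k], rule = 2)$y
    }
  }

  # NVCs: keep pulses clear of voids (1 s guard), superimpose on pressure
  nvc <- nvc_cand
  if (length(nvc) && nrow(ev)) {
    clear <- vapply(nvc, function(t0) {
      all(t0 + cfg$nvc_duration < ev$onset - 1 | t0 > ev$end + 1)
    }, logical(1))
    nvc <- nvc[clear]
  }
  p_fine <- p0 + p_void
  for (t0 in nvc) {
    u <- (tt - t0) / cfg$nvc_duration
    p_fine <- p_fine + cfg$nvc_amplitude * hann_pulse(u)
  }

  t_img <- seq(0, cfg$duration, by = 1 / cfg$frame_rate)
  t_prs <- seq(0, cfg$duration, by = 1 / cfg$pressure_rate)
  v_img <- approx(tt, V, xout = t_img, rule = 2)$y
  q_img <- approx(tt, outflow, xout = t_img, rule = 2)$y
  p_smp <- approx(tt, p_fine, xout = t_prs, rule = 2)$y

  structure(list(
    volume_trace = volume_trace(t_img, v_img),
    pressure_trace = pressure_trace(t_prs, p_smp),
    outflow = q_img,
    void_events = ev,
    nvc_times = nvc,
    config = cfg,
    masks = NULL,
    axes_per_frame = NULL
  ), class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %.0f s, %d voids, %d NVCs, V in [%.1f, %.1f] ul%s\n",
              x$config$duration, nrow(x$void_events), length(x$nvc_times),
              min(x$volume_trace$volume), max(x$volume_trace$volume),
              if (is.null(x$masks)) "" else ", rendered"))
  invisible(x)
}

# semi-axes (mm) of a prolate spheroid of volume V at aspect ratio k:
# V = (4/3) pi a b^2 with a = k b
axes_from_volume <- function(volume, aspect_ratio) {
  b <- (3 * volume / (4 * pi * aspect_ratio))^(1 / 3)
  cbind(long = aspect_ratio * b, short = b)
}

#' Render simulated dynamics as a fluoroscopy-like image sequence
#'
#' Each frame composites (i) a bright background with two or three rigid
#' high-contrast bars ("bones") translating and rotating along their own
#' seeded random walk, (ii) the projection of a prolate-spheroid bladder
#' whose semi-axes satisfy `V = (4/3) pi a b^2` at the configured aspect
#' ratio, attenuating the scene by `exp(-attenuation * chord)` where `chord`
#' is the X-ray path length through the spheroid, and (iii) additive
#' Gaussian sensor noise. The bladder center drifts and its orientation
#' rotates along a seeded random walk. The ground-truth mask of a frame is
#' the support of the rendered ellipse.
#'
#' @param truth a `sim_truth` from [simulate_dynamics()].
#' @param config the same [sim_config()] used for the dynamics.
#' @return A list with `frames` (a [frame_sequence()]), `masks` (a
#'   [mask_sequence()]; ground truth), and `axes_per_frame` (matrix of long
#'   and short semi-axes in mm).
#' @export
render_frames <- function(truth, config) {
  stopifnot(inherits(truth, "sim_truth"))
  validate_sim_config(config)
  if (any(truth$volume_trace$volume < 0))
    stop("volume trace must be nonnegative")
  with_seed(config$seed + 1L, render_frames_impl(truth, config))
}

render_frames_impl <- function(truth, cfg) {
  v <- truth$volume_trace$volume
  nf <- length(v)
  nr <- cfg$image_shape[1]; nc <- cfg$image_shape[2]
  ax <- axes_from_volume(v, cfg$aspect_ratio)   # mm
  a_px <- ax[, "long"] / cfg$pixel_size
  b_px <- ax[, "short"] / cfg$pixel_size

  max_r <- min(nr, nc) / 2 - 2
  too_big <- which(a_px > max_r)
  if (length(too_big))
    stop(sprintf(paste0("bladder too large for image_shape at frame %d ",
                        "(semi-axis %.1f px, limit %.1f px); enlarge ",
                        "image_shape or pixel_size"),
                 too_big[1], a_px[too_big[1]], max_r))

  # bladder pose random walk (center px, orientation rad)
  cr <- (nr + 1) / 2 + cumsum(rnorm(nf, 0, cfg$bladder_motion_step))
  cc <- (nc + 1) / 2 + cumsum(rnorm(nf, 0, cfg$bladder_motion_step))
  th <- cumsum(rnorm(nf, 0, 0.02))
  # keep the ellipse inside the field of view
  cr <- pmin(pmax(cr, a_px + 2), nr - a_px - 1)
  cc <- pmin(pmax(cc, a_px + 2), nc - a_px - 1)

  # background bars: rigid lines through a drifting point at a slowly
  # rotating angle
  nbar <- if (cfg$background) sample(2:3, 1) else 0L
  if (nbar > 0L) {
  bar_w <- runif(nbar, 2, 3.5)               # half-width, px
  bar_lvl <- runif(nbar, 0.40, 0.50)         # bar intensity
  # distinct skeletal structures: orientations evenly spaced with jitter,
  # never near-parallel
  bar_phi0 <- (seq_len(nbar) - 1) * pi / nbar + runif(1, 0, pi) +
    runif(nbar, -pi / (6 * nbar), pi / (6 * nbar))
  bar_dphi <- rnorm(nbar, 0, 0.004)
  amp <- cfg$background_motion_amplitude
  bar_r0 <- matrix(runif(nbar, 1, nr), nbar, 1)
  bar_c0 <- matrix(runif(nbar, 1, nc), nbar, 1)
  bar_dr <- matrix(rnorm(nbar * nf, 0, amp / sqrt(nf)), nbar, nf)
  bar_dc <- matrix(rnorm(nbar * nf, 0, amp / sqrt(nf)), nbar, nf)
  bar_r <- sweep(t(apply(bar_dr, 1, cumsum)), 1, bar_r0, `+`)
  bar_c <- sweep(t(apply(bar_dc, 1, cumsum)), 1, bar_c0, `+`)
  }

  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  bg_level <- 0.75

  noise <- if (cfg$noise_sd > 0)
    array(rnorm(nr * nc * nf, 0, cfg$noise_sd), dim = c(nr, nc, nf))
  else NULL

  frames <- array(0, dim = c(nr, nc, nf))
  masks <- array(FALSE, dim = c(nr, nc, nf))
  for (i in seq_len(nf)) {
    scene <- matrix(bg_level, nr, nc)
    if (nbar > 0L) for (k in seq_len(nbar)) {
      phi <- bar_phi0[k] + bar_dphi[k] * i
      d <- abs((rows - bar_r[k, i]) * cos(phi) - (cols - bar_c[k, i]) * sin(phi))
      scene[d < bar_w[k]] <- bar_lvl[k]
    }
    if (v[i] > 0 && b_px[i] > 0) {
      dr <- rows - cr[i]; dc <- cols - cc[i]
      u <- (dc * cos(th[i]) + dr * sin(th[i])) / a_px[i]
      w <- (-dc * sin(th[i]) + dr * cos(th[i])) / b_px[i]
      q <- u * u + w * w
      inside <- q <= 1
      chord <- 2 * ax[i, "short"] * sqrt(pmax(0, 1 - q))   # mm
      scene <- scene * exp(-cfg$attenuation * chord)
      masks[, , i] <- inside
    }
    if (!is.null(noise)) scene <- scene + noise[, , i]
    frames[, , i] <- pmin(pmax(scene, 0), 1)
  }
  list(frames = frame_sequence(frames, truth$volume_trace$time,
                               cfg$pixel_size),
       masks = mask_sequence(masks),
       axes_per_frame = ax)
}

#' Simulate a complete recording (dynamics plus rendered frames)
#'
#' Convenience wrapper running [simulate_dynamics()] then [render_frames()]
#' and attaching the rendered masks and per-frame axes to the returned
#' ground truth.
#'
#' @param config a [sim_config()].
#' @return A `sim_truth` whose `masks`, `axes_per_frame` and `frames` fields
#'   are filled.
#' @export
simulate_recording <- function(config) {
  truth <- simulate_dynamics(config)
  rend <- render_frames(truth, config)
  truth$frames <- rend$frames
  truth$masks <- rend$masks
  truth$axes_per_frame <- rend$axes_per_frame
  truth
}
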