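# End-to-end analysis pipeline: frames -> masks -> volume trace -> flow and
# conductance -> per-void parameter table, with reproducible file outputs
# and a provenance log of every effective parameter.

#' Analysis run configuration
#'
#' Collects every tunable parameter of [run_pipeline()]. All windows must
#' be odd so that temporal filters stay centered.
#'
#' @param pixel_size mm/pixel of the input frames.
#' @param frame_rate frames/s (used when frame timestamps are synthesized).
#' @param rolling_window rolling-average window, frames.
#' @param sg_window Savitzky-Golay window, samples.
#' @param sg_polyorder Savitzky-Golay polynomial order.
#' @param max_gap longest invalid-frame run repaired by interpolation.
#' @param pressure_floor cmH2O floor below which UFC is undefined.
#' @param nvc_window pre-void NVC analysis window, s.
#' @param seg a [seg_params()]; defaults to `seg_params(pixel_size)`.
#' @param voids a [void_params()].
#' @param nvc an [nvc_params()].
#' @param seed integer seed (holdout draws and any stochastic extras).
#' @return An object of class `run_config`.
#' @export
run_config <- function(pixel_size = 0.2, frame_rate = 30,
                       rolling_window = 15L, sg_window = 31L,
                       sg_polyorder = 3L, max_gap = 2L, pressure_floor = 3,
                       nvc_window = 80, seg = NULL, voids = NULL, nvc = NULL,
                       seed = 1L) {
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (frame_rate <= 0) stop("frame_rate must be > 0")
  for (w in c(rolling_window, sg_window))
    if (w < 1 || w %% 2 == 0) stop("windows must be odd and positive")
  if (is.null(seg)) seg <- seg_params(pixel_size)
  if (is.list(seg) && !inherits(seg, "seg_params"))
    seg <- do.call(seg_params, c(list(pixel_size = pixel_size), seg))
  if (is.null(voids)) voids <- void_params()
  if (is.list(voids) && !inherits(voids, "void_params"))
    voids <- do.call(void_params, voids)
  if (is.null(nvc)) nvc <- nvc_params()
  if (is.list(nvc) && !inherits(nvc, "nvc_params"))
    nvc <- do.call(nvc_params, nvc)
  structure(list(pixel_size = pixel_size, frame_rate = frame_rate,
                 rolling_window = as.integer(rolling_window),
                 sg_window = as.integer(sg_window),
                 sg_polyorder = as.integer(sg_polyorder),
                 max_gap = as.integer(max_gap),
                 pressure_floor = pressure_floor, nvc_window = nvc_window,
                 seg = seg, voids = voids, nvc = nvc,
                 seed = as.integer(seed)),
            class = "run_config")
}

config_log_lines <- function(cfg) {
  flat <- c(pixel_size = cfg$pixel_size, frame_rate = cfg$frame_rate,
            rolling_window = cfg$rolling_window, sg_window = cfg$sg_window,
            sg_polyorder = cfg$sg_polyorder, max_gap = cfg$max_gap,
            pressure_floor = cfg$pressure_floor, nvc_window = cfg$nvc_window,
            seed = cfg$seed,
            seg.method = cfg$seg$method,
            seg.threshold = if (is.null(cfg$seg$threshold)) "auto"
                            else cfg$seg$threshold,
            seg.offset = cfg$seg$offset,
            seg.min_area = sprintf("%.2f", cfg$seg$min_area),
            seg.opening_radius = cfg$seg$opening_radius,
            seg.closing_radius = cfg$seg$closing_radius,
            voids.ufr_on = cfg$voids$ufr_on,
            voids.min_voided = cfg$voids$min_voided,
            voids.merge_gap = cfg$voids$merge_gap,
            voids.edge_fraction = cfg$voids$edge_fraction,
            nvc.amplitude = cfg$nvc$amplitude,
            nvc.min_duration = cfg$nvc$min_duration,
            nvc.max_volume_drop = cfg$nvc$max_volume_drop,
            nvc.baseline_window = cfg$nvc$baseline_window)
  paste0("param ", names(flat), " = ", unname(flat))
}

#' Run the full fluoroscopic volumetry pipeline
#'
#' Composes the analysis chain: segmentation of every frame (rolling
#' average + reference operator), volume trace with short-gap repair,
#' Savitzky-Golay smoothing, urethral flow rate, optional pressure
#' alignment and urethral flow conductance, void detection, per-void
#' parameters and pre-void NVC counts. When `out_dir` is given, writes
#' `trace.csv` (per-frame signals), `voids.csv` (per-void table) and
#' `run.log` (every effective parameter, for provenance); outputs are
#' deterministic given identical inputs and configuration, and partial
#' outputs are removed if a stage fails.
#'
#' @param frames a [frame_sequence()] or a path accepted by
#'   [read_frames()].
#' @param pressure optional [pressure_trace()] or CSV path (see
#'   [read_pressure()]); when absent the run is noninvasive and
#'   pressure-dependent outputs (UFC, p_max, NVC counts) are omitted.
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @param quiet suppress progress log lines.
#' @return List with `masks`, `volume` (raw trace), `smoothed`, `flow`,
#'   `pressure` (aligned, or `NULL`), `voids` (per-void data frame in the
#'   CSV column layout), and `files` (written paths, or `NULL`), invisibly.
#' @export
run_pipeline <- function(frames, pressure = NULL, config = run_config(),
                         out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  written <- character(0)
  on_fail <- function(stage) function(e) {
    for (f in written) unlink(f)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }
  say <- function(...) if (!quiet) message(sprintf(...))

  if (is.character(frames))
    frames <- tryCatch(read_frames(frames, frame_rate = config$frame_rate,
                                   pixel_size = config$pixel_size),
                       error = on_fail("read_frames"))
  stopifnot(inherits(frames, "frame_sequence"))
  if (is.character(pressure))
    pressure <- tryCatch(read_pressure(pressure),
                         error = on_fail("read_pressure"))

  say("run_pipeline: %d frames, pressure %s", length(frames),
      if (is.null(pressure)) "absent (noninvasive mode)" else "present")

  masks <- tryCatch(
    segment_sequence(frames, config$seg, config$rolling_window,
                     quiet = quiet),
    error = on_fail("segment_sequence"))
  vraw <- tryCatch(
    build_volume_trace(masks, frames$timestamps, config$pixel_size,
                       config$max_gap),
    error = on_fail("build_volume_trace"))
  vsm <- tryCatch(
    smooth_volume(vraw, config$sg_window, config$sg_polyorder),
    error = on_fail("smooth_volume"))
  flow <- tryCatch(compute_ufr(vsm), error = on_fail("compute_ufr"))

  p_aligned <- NULL
  if (!is.null(pressure)) {
    p_aligned <- tryCatch(align_pressure(pressure, vsm$time),
                          error = on_fail("align_pressure"))
    flow <- tryCatch(compute_ufc(flow, p_aligned, config$pressure_floor),
                     error = on_fail("compute_ufc"))
  }

  events <- tryCatch(detect_voids(vsm, flow, config$voids),
                     error = on_fail("detect_voids"))
  voids <- tryCatch(void_parameters(events, vsm, flow, p_aligned),
                    error = on_fail("void_parameters"))
  if (!is.null(p_aligned)) {
    voids$nvc_count <- vapply(seq_len(nrow(voids)), function(k)
      count_nvcs(p_aligned, vsm, voids$onset[k], config$nvc_window,
                 config$nvc), integer(1))
  }
  say("run_pipeline: %d void(s) detected", nrow(voids))

  out <- format_void_table(voids, has_pressure = !is.null(p_aligned))
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(trace = file.path(out_dir, "trace.csv"),
               voids = file.path(out_dir, "voids.csv"),
               log = file.path(out_dir, "run.log"))
    written <- files
    tryCatch({
      tr <- data.frame(time_s = vsm$time, volume_ul = vsm$volume,
                       valid = vraw$valid, ufr_ul_s = flow$ufr)
      if (!is.null(p_aligned)) {
        tr$pressure_cmH2O <- p_aligned
        tr$ufc <- flow$ufc
      }
      write.csv(tr, files["trace"], row.names = FALSE, quote = FALSE)
      write.csv(out, files["voids"], row.names = FALSE, quote = FALSE)
      writeLines(c("cystovol run_pipeline", config_log_lines(config),
                   sprintf("frames n = %d", length(frames)),
                   sprintf("voids n = %d", nrow(out))),
                 files["log"])
    }, error = on_fail("write_outputs"))
  }
  invisible(list(masks = masks, volume = vraw, smoothed = vsm, flow = flow,
                 pressure = p_aligned, voids = out, files = files))
}

# per-void table in the documented CSV column layout; pressure-dependent
# columns are absent in noninvasive mode
format_void_table <- function(voids, has_pressure) {
  n <- nrow(voids)
  out <- data.frame(void_id = seq_len(n),
                    onset_s = voids$onset, end_s = voids$end,
                    BC_ul = voids$BC, RV_ul = voids$RV,
                    voided_ul = voids$voided,
                    efficiency_pct = voids$efficiency,
                    t20_80_s = voids$t20_80,
                    ufr_max_ul_s = voids$ufr_max)
  if (has_pressure) {
    out$ufc_max <- voids$ufc_max
    out$p_max_cmH2O <- voids$p_max
  }
  out$ici_s <- voids$ici
  if (has_pressure && !is.null(voids$nvc_count))
    out$nvc_count <- voids$nvc_count
  out
}
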