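# File input/output: multi-page TIFF and PNG-directory frame stacks,
# mask stacks, CSV traces and event tables, and YAML run configuration.

#' Read a fluoroscopy frame sequence
#'
#' Accepts either a multi-page TIFF file or a directory of PNG frames in
#' lexicographic order. Intensities are returned on the common `[0, 1]`
#' scale regardless of source bit depth (8/16-bit integer or 32-bit float).
#' When no timestamps are supplied they are synthesized from `frame_rate`
#' as `0, 1/rate, 2/rate, ...`.
#'
#' @param path TIFF file or directory of `.png` frames.
#' @param frame_rate frames/s used to synthesize timestamps.
#' @param pixel_size mm/pixel recorded on the sequence.
#' @param timestamps optional explicit timestamps (s), one per frame.
#' @return A [frame_sequence()].
#' @export
read_frames <- function(path, frame_rate = 30, pixel_size = 0.2,
                        timestamps = NULL) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (!length(files))
      stop("no .png frames found in directory ", path)
    frames <- lapply(files, function(f) {
      img <- tryCatch(png::readPNG(f),
                      error = function(e) stop("unreadable frame file ", f,
                                               ": ", conditionMessage(e)))
      collapse_channels(img)
    })
  } else if (file.exists(path)) {
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                      error = function(e) stop("unreadable TIFF ", path, ": ",
                                               conditionMessage(e)))
    if (!is.list(pages)) pages <- list(pages)
    frames <- lapply(pages, collapse_channels)
  } else stop("no such file or directory: ", path)
  shapes <- unique(lapply(frames, dim))
  if (length(shapes) != 1L)
    stop("mixed frame shapes in ", path)
  if (is.null(timestamps))
    timestamps <- (seq_along(frames) - 1) / frame_rate
  frame_sequence(frames, timestamps, pixel_size)
}

collapse_channels <- function(img) {
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img
}

#' Write a frame sequence as a multi-page TIFF
#'
#' Intensities are clipped to `[0, 1]` and written at the requested bit
#' depth (16-bit integer by default, the conventional fluoroscopy export;
#' 32 selects float samples).
#'
#' @param seq a [frame_sequence()].
#' @param path output TIFF path.
#' @param bits bits per sample: 8, 16 or 32.
#' @return `path`, invisibly.
#' @export
write_frames <- function(seq, path, bits = 16L) {
  stopifnot(inherits(seq, "frame_sequence"))
  n <- dim(seq$frames)[3L]
  pages <- lapply(seq_len(n),
                  function(i) pmin(pmax(seq$frames[, , i], 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits),
                  compression = "none")
  invisible(path)
}

#' Write a mask sequence as an 8-bit 0/255 multi-page TIFF
#'
#' @param masks a [mask_sequence()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_masks <- function(masks, path) {
  stopifnot(inherits(masks, "mask_sequence"))
  n <- length(masks)
  pages <- lapply(seq_len(n), function(i) masks$masks[, , i] * 1)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}

#' Read a mask sequence from a 0/255 multi-page TIFF
#'
#' @param path mask TIFF written by [write_masks()] (any nonzero pixel is
#'   foreground).
#' @return A [mask_sequence()].
#' @export
read_masks <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  mask_sequence(lapply(pages, function(p) collapse_channels(p) > 0.5))
}

#' Read an intravesical pressure trace from CSV
#'
#' Expects a comma-separated file with the header
#' `time_s,pressure_cmH2O`. Time must be strictly increasing; the first
#' offending row is named otherwise.
#'
#' @param path CSV path.
#' @return A [pressure_trace()].
#' @export
read_pressure <- function(path) {
  df <- read.csv(path)
  need <- c("time_s", "pressure_cmH2O")
  if (!all(need %in% names(df)))
    stop("pressure CSV must have header `time_s,pressure_cmH2O` (got: ",
         paste(names(df), collapse = ","), ")")
  bad <- which(diff(df$time_s) <= 0)
  if (length(bad))
    stop(sprintf("non-monotonic time in %s at row %d (t = %g follows t = %g)",
                 path, bad[1] + 1L, df$time_s[bad[1] + 1L], df$time_s[bad[1]]))
  pressure_trace(df$time_s, df$pressure_cmH2O)
}

#' Write a pressure trace to CSV (`time_s,pressure_cmH2O`)
#' @param p a [pressure_trace()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_pressure <- function(p, path) {
  stopifnot(inherits(p, "pressure_trace"))
  write.csv(data.frame(time_s = p$time, pressure_cmH2O = p$pressure),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a complete simulated recording to a directory
#'
#' Produces the standard file layout of the `simulate` CLI subcommand:
#' `frames.tif` (16-bit image stack), `masks.tif` (8-bit 0/255 ground-truth
#' masks), `volume.csv` (`time_s,volume_ul`), `pressure.csv`
#' (`time_s,pressure_cmH2O`) and `events.csv` (`onset_s,end_s,voided_ul`).
#'
#' @param truth a rendered `sim_truth` from [simulate_recording()].
#' @param dir output directory (created if missing).
#' @return Named character vector of written paths, invisibly.
#' @export
write_simulation <- function(truth, dir) {
  stopifnot(inherits(truth, "sim_truth"))
  if (is.null(truth$frames))
    stop("truth has no rendered frames; use simulate_recording()")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(frames = file.path(dir, "frames.tif"),
             masks = file.path(dir, "masks.tif"),
             volume = file.path(dir, "volume.csv"),
             pressure = file.path(dir, "pressure.csv"),
             events = file.path(dir, "events.csv"))
  write_frames(truth$frames, paths["frames"])
  write_masks(truth$masks, paths["masks"])
  write.csv(data.frame(time_s = truth$volume_trace$time,
                       volume_ul = truth$volume_trace$volume),
            paths["volume"], row.names = FALSE, quote = FALSE)
  write_pressure(truth$pressure_trace, paths["pressure"])
  write.csv(data.frame(onset_s = truth$void_events$onset,
                       end_s = truth$void_events$end,
                       voided_ul = truth$void_events$voided),
            paths["events"], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Read a run configuration from a YAML file
#'
#' Flat key-value YAML; recognized keys mirror the arguments of
#' [run_config()]. Unknown keys are rejected so that typos cannot silently
#' fall back to defaults.
#'
#' @param path YAML file.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}
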