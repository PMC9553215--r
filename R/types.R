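# S3 containers shared across the pipeline. All are plain lists with a class
# attribute and a validating constructor; masks/frames are stored as 3-D
# arrays (row x col x frame) so per-frame slices are ordinary matrices.

#' Ordered grayscale frame stack with timestamps and pixel calibration
#'
#' @param frames 3-D numeric array (row x col x frame) or list of equally
#'   sized matrices; intensities on an arbitrary common scale.
#' @param timestamps numeric vector of acquisition times in seconds, strictly
#'   increasing, one per frame.
#' @param pixel_size isotropic pixel size in mm/pixel.
#' @return An object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, timestamps, pixel_size) {
  if (is.list(frames)) {
    shapes <- unique(lapply(frames, dim))
    if (length(shapes) != 1L)
      stop("all frames must have the same shape")
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(shapes[[1L]], length(frames)))
  }
  if (length(dim(frames)) != 3L)
    stop("`frames` must be a row x col x frame array")
  n <- dim(frames)[3L]
  timestamps <- as.numeric(timestamps)
  if (length(timestamps) != n)
    stop("need one timestamp per frame (", n, " frames, ",
         length(timestamps), " timestamps)")
  if (n > 1L && any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number (mm/pixel)")
  structure(list(frames = frames, timestamps = timestamps,
                 pixel_size = pixel_size),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_sequence> %d frames of %dx%d px, %.4g mm/px, %.3f-%.3f s\n",
              d[3], d[1], d[2], x$pixel_size,
              x$timestamps[1], x$timestamps[length(x$timestamps)]))
  invisible(x)
}

#' @export
length.frame_sequence <- function(x) dim(x$frames)[3L]

#' Per-frame binary bladder masks with validity flags
#'
#' A mask is valid when segmentation (or ground-truth rendering) found a
#' bladder object in that frame; invalid frames carry an all-`FALSE` mask.
#'
#' @param masks 3-D logical array (row x col x frame) or list of logical
#'   matrices.
#' @param valid logical vector, one flag per frame. Defaults to "mask
#'   nonempty".
#' @return An object of class `mask_sequence`.
#' @export
mask_sequence <- function(masks, valid = NULL) {
  if (is.list(masks)) {
    shapes <- unique(lapply(masks, dim))
    if (length(shapes) != 1L)
      stop("all masks must have the same shape")
    masks <- array(unlist(masks, use.names = FALSE),
                   dim = c(shapes[[1L]], length(masks)))
  }
  if (length(dim(masks)) != 3L)
    stop("`masks` must be a row x col x frame array")
  storage.mode(masks) <- "logical"
  n <- dim(masks)[3L]
  if (is.null(valid))
    valid <- apply(masks, 3L, any)
  if (length(valid) != n)
    stop("need one validity flag per mask")
  structure(list(masks = masks, valid = as.logical(valid)),
            class = "mask_sequence")
}

#' @export
print.mask_sequence <- function(x, ...) {
  d <- dim(x$masks)
  cat(sprintf("<mask_sequence> %d masks of %dx%d px, %d valid\n",
              d[3], d[1], d[2], sum(x$valid)))
  invisible(x)
}

#' @export
length.mask_sequence <- function(x) dim(x$masks)[3L]

#' Time-stamped bladder volume trace
#'
#' @param time seconds, strictly increasing.
#' @param volume intravesical volume in microlitres; must be nonnegative
#'   wherever `valid` is `TRUE`.
#' @param valid logical per-sample validity flag.
#' @return An object of class `volume_trace`.
#' @export
volume_trace <- function(time, volume, valid = rep(TRUE, length(time))) {
  time <- as.numeric(time); volume <- as.numeric(volume)
  if (length(time) != length(volume) || length(time) != length(valid))
    stop("`time`, `volume` and `valid` must have equal length")
  if (length(time) > 1L && any(diff(time) <= 0))
    stop("`time` must be strictly increasing")
  if (any(valid & (is.na(volume) | volume < 0)))
    stop("valid samples must have nonnegative, non-missing volume")
  structure(list(time = time, volume = volume, valid = as.logical(valid)),
            class = "volume_trace")
}

#' @export
print.volume_trace <- function(x, ...) {
  cat(sprintf("<volume_trace> %d samples over %.1f s, %d valid, V in [%.1f, %.1f] ul\n",
              length(x$time), diff(range(x$time)), sum(x$valid),
              min(x$volume[x$valid]), max(x$volume[x$valid])))
  invisible(x)
}

#' Time-stamped intravesical pressure trace
#'
#' @param time seconds, strictly increasing.
#' @param pressure intravesical pressure in cmH2O.
#' @return An object of class `pressure_trace`.
#' @export
pressure_trace <- function(time, pressure) {
  time <- as.numeric(time); pressure <- as.numeric(pressure)
  if (length(time) != length(pressure))
    stop("`time` and `pressure` must have equal length")
  if (length(time) > 1L && any(diff(time) <= 0))
    stop("`time` must be strictly increasing")
  structure(list(time = time, pressure = pressure), class = "pressure_trace")
}

#' @export
print.pressure_trace <- function(x, ...) {
  cat(sprintf("<pressure_trace> %d samples over %.1f s, p in [%.1f, %.1f] cmH2O\n",
              length(x$time), diff(range(x$time)),
              min(x$pressure), max(x$pressure)))
  invisible(x)
}

#' Urethral flow trace on the image timebase
#'
#' Holds the urethral flow rate (UFR, positive = outflow through the
#' urethra) and, once pressure is available, the urethral flow conductance
#' (UFC = UFR / p_ves; `NA` where pressure is below the floor).
#'
#' @param time seconds (the volume-trace timebase).
#' @param ufr urethral flow rate in ul/s.
#' @param ufc urethral flow conductance in ul s^-1 cmH2O^-1, or `NULL`.
#' @return An object of class `flow_trace`.
#' @export
flow_trace <- function(time, ufr, ufc = NULL) {
  time <- as.numeric(time); ufr <- as.numeric(ufr)
  if (length(time) != length(ufr))
    stop("`time` and `ufr` must have equal length")
  if (!is.null(ufc) && length(ufc) != length(time))
    stop("`ufc` must match the timebase")
  structure(list(time = time, ufr = ufr, ufc = ufc), class = "flow_trace")
}

#' @export
print.flow_trace <- function(x, ...) {
  cat(sprintf("<flow_trace> %d samples, peak UFR %.2f ul/s%s\n",
              length(x$time), max(x$ufr),
              if (is.null(x$ufc)) "" else ", UFC filled"))
  invisible(x)
}

# linear interpolation of a (possibly invalid-gapped) volume trace at
# arbitrary times, using valid samples only
volume_at <- function(v, t) {
  ok <- v$valid & !is.na(v$volume)
  if (sum(ok) < 2L) stop("need at least two valid volume samples")
  approx(v$time[ok], v$volume[ok], xout = t, rule = 2)$y
}
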