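# Mask-to-volume conversion: equivalent-ellipse axes from second-order
# central moments, the prolate-spheroid volume formula, and assembly of a
# per-frame volume trace with short-gap repair.

#' Fit the equivalent ellipse of a binary mask
#'
#' Semi-axes are derived from the normalized second-order central moments
#' of the mask: the returned ellipse has the same centroid and second
#' moments as the pixel support (for a solid ellipse the variance along a
#' principal axis is `a^2/4`, so `a = 2 sqrt(lambda)`). This estimator is
#' deterministic and invariant under rotation of the mask.
#'
#' @param mask logical matrix; must contain at least one `TRUE` pixel.
#' @param pixel_size mm/pixel.
#' @return An object of class `bladder_geometry`: list with `long_radius`
#'   and `short_radius` (mm, semi-axes, `long >= short`), `center` (0-based
#'   `(row, col)` pixel coordinates of the centroid), and `orientation`
#'   (radians of the major axis relative to the column axis, in
#'   `(-pi/2, pi/2]`).
#' @export
fit_spheroid <- function(mask, pixel_size) {
  if (!is.logical(mask)) storage.mode(mask) <- "logical"
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0L)
    stop(errorCondition("empty mask: no geometry to fit",
                        class = c("cystovol_empty_mask", "error",
                                  "condition")))
  mu <- colMeans(idx)
  dr <- idx[, 1L] - mu[1L]
  dc <- idx[, 2L] - mu[2L]
  S <- matrix(c(mean(dr * dr), mean(dr * dc),
                mean(dr * dc), mean(dc * dc)), 2L, 2L)
  e <- eigen(S, symmetric = TRUE)
  ax_px <- 2 * sqrt(pmax(e$values, 0))
  vec <- e$vectors[, 1L]                 # (row, col) direction, major axis
  ang <- atan2(vec[1L], vec[2L])
  if (ang <= -pi / 2) ang <- ang + pi
  if (ang > pi / 2) ang <- ang - pi
  structure(list(long_radius = ax_px[1L] * pixel_size,
                 short_radius = ax_px[2L] * pixel_size,
                 center = unname(mu) - 1,        # 0-based (row, col)
                 orientation = ang),
            class = "bladder_geometry")
}

#' @export
print.bladder_geometry <- function(x, ...) {
  cat(sprintf("<bladder_geometry> a = %.2f mm, b = %.2f mm, center (%.1f, %.1f), %.1f deg\n",
              x$long_radius, x$short_radius, x$center[1], x$center[2],
              x$orientation * 180 / pi))
  invisible(x)
}

#' Prolate-spheroid volume from in-plane semi-axes
#'
#' The bladder is modelled as a prolate spheroid whose out-of-plane
#' semi-axis equals the short in-plane semi-axis, so
#' `V = (4/3) * pi * a * b^2` with `a` the long and `b` the short semi-axis
#' in mm. The result is in mm^3, reported as microlitres (1 mm^3 = 1 ul).
#'
#' @param long_radius major semi-axis `a`, mm.
#' @param short_radius minor semi-axis `b`, mm; must satisfy
#'   `long_radius >= short_radius >= 0`.
#' @return Volume in ul. Vectorized over its arguments.
#' @export
volume_from_axes <- function(long_radius, short_radius) {
  if (any(short_radius < 0) || any(long_radius < 0))
    stop("semi-axes must be nonnegative")
  if (any(long_radius < short_radius - 1e-9))
    stop("`long_radius` must be >= `short_radius`")
  (4 / 3) * pi * long_radius * short_radius^2
}

#' Build a bladder volume trace from a mask sequence
#'
#' Each valid mask is converted to a volume via [fit_spheroid()] and
#' [volume_from_axes()]. Brief segmentation failures are repaired: runs of
#' at most `max_gap` consecutive invalid frames flanked by valid frames are
#' filled by linear interpolation of the flanking volumes and marked valid;
#' longer runs (and invalid runs touching the sequence ends) remain
#' invalid.
#'
#' @param masks a [mask_sequence()].
#' @param timestamps seconds, one per mask.
#' @param pixel_size mm/pixel.
#' @param max_gap longest invalid run (frames) repaired by interpolation.
#' @return A [volume_trace()] with one sample per frame.
#' @export
build_volume_trace <- function(masks, timestamps, pixel_size, max_gap = 2L) {
  stopifnot(inherits(masks, "mask_sequence"))
  n <- length(masks)
  if (length(timestamps) != n)
    stop("`timestamps` must be aligned with `masks`")
  vol <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!masks$valid[i] || !any(masks$masks[, , i])) next
    g <- fit_spheroid(masks$masks[, , i], pixel_size)
    vol[i] <- volume_from_axes(g$long_radius, g$short_radius)
  }
  valid <- !is.na(vol)
  if (!any(valid))
    stop("all frames invalid: cannot build a volume trace")
  # repair interior invalid runs of length <= max_gap
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$lengths)) {
    if (r$values[k] || r$lengths[k] > max_gap) next
    if (starts[k] == 1L || ends[k] == n) next    # no flanking valid sample
    i0 <- starts[k] - 1L; i1 <- ends[k] + 1L
    fill <- starts[k]:ends[k]
    vol[fill] <- approx(timestamps[c(i0, i1)], vol[c(i0, i1)],
                        xout = timestamps[fill])$y
    valid[fill] <- TRUE
  }
  vol[!valid] <- NA_real_
  volume_trace(timestamps, ifelse(valid, vol, NA_real_), valid)
}
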