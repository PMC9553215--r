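# Volume-trace signal processing: Savitzky-Golay smoothing before
# differentiation, urethral flow rate as the negative volume derivative,
# alignment of the independently sampled pressure trace onto the image
# timebase, and urethral flow conductance.

#' Savitzky-Golay smoothing of a volume trace
#'
#' Least-squares local-polynomial smoothing applied to the volume trace
#' before differentiation. Sequence edges are handled by the filter's
#' boundary projection (polynomial fits anchored at the ends), so any input
#' that is exactly a polynomial of degree `<= polyorder` passes through
#' unchanged. Invalid samples are bridged by linear interpolation for the
#' purpose of filtering; their validity flags are preserved.
#'
#' @param v a [volume_trace()] with (near-)uniform sampling.
#' @param window odd filter window length in samples; the default 31
#'   (about 1 s at 30 frames/s) suppresses frame-to-frame volumetry noise
#'   while preserving multi-second voids.
#' @param polyorder polynomial order, `< window`.
#' @return A smoothed [volume_trace()] on the same timebase.
#' @export
smooth_volume <- function(v, window = 31L, polyorder = 3L) {
  stopifnot(inherits(v, "volume_trace"))
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  n <- length(v$time)
  if (window %% 2L == 0L || window < 3L)
    stop("`window` must be an odd integer >= 3")
  if (polyorder >= window)
    stop("`polyorder` must be smaller than `window`")
  if (window > n)
    stop(sprintf("`window` (%d) exceeds the trace length (%d)", window, n))
  x <- v$volume
  if (any(!v$valid)) {
    ok <- v$valid
    if (sum(ok) < 2L) stop("need at least two valid samples to smooth")
    x[!ok] <- approx(v$time[ok], x[ok], xout = v$time[!ok], rule = 2)$y
  }
  sm <- signal::sgolayfilt(x, p = polyorder, n = window)
  sm <- pmax(sm, 0)                      # volumes cannot be negative
  volume_trace(v$time, ifelse(v$valid, sm, NA_real_) , v$valid)
}

#' Urethral flow rate from a volume trace
#'
#' UFR is the negative time derivative of the bladder volume,
#' `ufr(t) = -dV/dt`, computed by central differences on the interior and
#' one-sided differences at the edges. Positive values mean outflow through
#' the urethra (voiding); filling gives small negative values. The trace
#' should be smoothed (see [smooth_volume()]) before differentiation.
#'
#' @param v a [volume_trace()] with at least 3 valid samples.
#' @return A [flow_trace()] on the same timebase (UFC unset).
#' @export
compute_ufr <- function(v) {
  stopifnot(inherits(v, "volume_trace"))
  ok <- v$valid & !is.na(v$volume)
  if (sum(ok) < 3L)
    stop("need at least 3 valid samples to differentiate")
  t <- v$time
  x <- v$volume
  if (any(!ok))  # bridge residual gaps so the derivative is defined
    x[!ok] <- approx(t[ok], x[ok], xout = t[!ok], rule = 2)$y
  n <- length(t)
  ufr <- numeric(n)
  ufr[1] <- -(x[2] - x[1]) / (t[2] - t[1])
  ufr[n] <- -(x[n] - x[n - 1]) / (t[n] - t[n - 1])
  if (n > 2L) {
    i <- 2:(n - 1L)
    ufr[i] <- -(x[i + 1L] - x[i - 1L]) / (t[i + 1L] - t[i - 1L])
  }
  flow_trace(t, ufr)
}

#' Align a pressure trace onto the image timebase
#'
#' Pressure is sampled independently (50 Hz nominal) of the imaging
#' (30 frames/s nominal); alignment is by linear interpolation onto the
#' requested timebase, with endpoints clamped to the nearest pressure
#' sample. Queries at an existing pressure timestamp return that sample
#' exactly.
#'
#' @param p a [pressure_trace()].
#' @param timebase seconds at which pressure is required; must overlap the
#'   pressure recording.
#' @return Numeric vector of pressures (cmH2O) on `timebase`.
#' @export
align_pressure <- function(p, timebase) {
  stopifnot(inherits(p, "pressure_trace"))
  pr <- range(p$time); tr <- range(timebase)
  if (tr[1] > pr[2] || tr[2] < pr[1])
    stop(sprintf(paste0("pressure recording [%.3f, %.3f] s does not overlap ",
                        "the requested timebase [%.3f, %.3f] s"),
                 pr[1], pr[2], tr[1], tr[2]))
  approx(p$time, p$pressure, xout = timebase, rule = 2)$y
}

#' Urethral flow conductance
#'
#' UFC relates the urethral flow to the driving intravesical pressure:
#' `ufc = max(ufr, 0) / p_ves` wherever the pressure is at least
#' `pressure_floor`; below the floor the conductance is undefined (`NA`),
#' preventing division blow-ups between contractions. Negative flow
#' (filling) maps to zero conductance.
#'
#' @param flow a [flow_trace()] (UFR filled).
#' @param p_aligned pressure (cmH2O) on the same timebase, e.g. from
#'   [align_pressure()].
#' @param pressure_floor cmH2O below which UFC is undefined.
#' @return The input [flow_trace()] with `ufc` filled
#'   (ul s^-1 cmH2O^-1).
#' @export
compute_ufc <- function(flow, p_aligned, pressure_floor = 3) {
  stopifnot(inherits(flow, "flow_trace"))
  if (length(p_aligned) != length(flow$time))
    stop("`p_aligned` must be on the flow timebase")
  ufc <- ifelse(p_aligned >= pressure_floor,
                pmax(flow$ufr, 0) / p_aligned, NA_real_)
  flow$ufc <- ufc
  flow
}

# trapezoidal quadrature on an irregular grid
trapz <- function(t, y) {
  n <- length(t)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(t)) / 2
}
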