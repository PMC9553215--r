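# Void-event detection and per-void urodynamic parameters: bladder
# capacity (BC), residual volume (RV), voiding efficiency, t20-80 void
# duration, peak UFR/UFC/pressure, intercontractile interval (ICI), and
# nonvoiding-contraction (NVC) counts in the pre-void window.

#' Void-detection parameters
#'
#' @param ufr_on flow threshold (ul/s) above which samples are candidate
#'   voiding samples.
#' @param min_voided smallest volume drop (ul) accepted as a void.
#' @param merge_gap candidate intervals closer than this (s) are merged
#'   into one void.
#' @param edge_fraction onset/end are refined to where the flow crosses
#'   this fraction of the void's peak UFR.
#' @return An object of class `void_params`.
#' @export
void_params <- function(ufr_on = 2, min_voided = 10, merge_gap = 2,
                        edge_fraction = 0.05) {
  stopifnot(ufr_on > 0, min_voided >= 0, merge_gap >= 0,
            edge_fraction > 0, edge_fraction < 1)
  structure(list(ufr_on = ufr_on, min_voided = min_voided,
                 merge_gap = merge_gap, edge_fraction = edge_fraction),
            class = "void_params")
}

# linear-interpolated crossing time of y (values at t) through level,
# searching downward from index i toward 1 (dir = -1) or n (dir = +1):
# returns the time where y first drops below `level` in that direction
edge_crossing <- function(t, y, i, level, dir) {
  n <- length(t)
  j <- i
  while (j + dir >= 1L && j + dir <= n && y[j + dir] > level) j <- j + dir
  k <- j + dir
  if (k < 1L || k > n) return(t[j])
  # y[j] > level >= y[k]: interpolate
  if (abs(y[j] - y[k]) < 1e-12) return(t[k])
  t[j] + (t[k] - t[j]) * (y[j] - level) / (y[j] - y[k])
}

#' Detect voiding episodes in a volume/flow trace
#'
#' A candidate void is a maximal run of samples whose urethral flow rate
#' exceeds `ufr_on`; candidates separated by less than `merge_gap` seconds
#' are merged. Each candidate's onset and end are refined to the times
#' where the flow crosses `edge_fraction` of that void's peak UFR (linear
#' interpolation between samples), and the candidate is accepted if the
#' volume drop across it is at least `min_voided`.
#'
#' @param v a smoothed [volume_trace()].
#' @param flow the matching [flow_trace()] from [compute_ufr()].
#' @param params a [void_params()].
#' @return Data frame with one row per void: `onset`, `end` (s). Empty on
#'   quiescent traces.
#' @export
detect_voids <- function(v, flow, params = void_params()) {
  stopifnot(inherits(v, "volume_trace"), inherits(flow, "flow_trace"))
  t <- flow$time; ufr <- flow$ufr
  above <- ufr > params$ufr_on
  if (!any(above))
    return(data.frame(onset = numeric(0), end = numeric(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  iv <- cbind(starts[r$values], ends[r$values])
  # merge candidates separated by < merge_gap seconds
  merged <- list(iv[1, ])
  if (nrow(iv) > 1L) for (k in 2:nrow(iv)) {
    last <- merged[[length(merged)]]
    if (t[iv[k, 1]] - t[last[2]] < params$merge_gap)
      merged[[length(merged)]] <- c(last[1], iv[k, 2])
    else merged[[length(merged) + 1L]] <- iv[k, ]
  }
  out <- lapply(merged, function(b) {
    seg <- b[1]:b[2]
    ipk <- seg[which.max(ufr[seg])]
    thr <- params$edge_fraction * ufr[ipk]
    onset <- edge_crossing(t, ufr, ipk, thr, -1L)
    end <- edge_crossing(t, ufr, ipk, thr, +1L)
    c(onset = onset, end = end)
  })
  ev <- as.data.frame(do.call(rbind, out))
  # refinement can make neighbours overlap: merge those too
  if (nrow(ev) > 1L) {
    keep <- list(ev[1, ])
    for (k in 2:nrow(ev)) {
      last <- keep[[length(keep)]]
      if (ev$onset[k] < last$end + params$merge_gap) {
        last$end <- max(last$end, ev$end[k])
        keep[[length(keep)]] <- last
      } else keep[[length(keep) + 1L]] <- ev[k, ]
    }
    ev <- do.call(rbind, keep)
  }
  voided <- volume_at(v, ev$onset) - volume_at(v, ev$end)
  ev <- ev[voided >= params$min_voided, , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

# first time within [t0, t1] at which the volume drops to `level`,
# by linear interpolation between samples (NA if never reached)
level_crossing_time <- function(v, t0, t1, level) {
  ok <- v$valid & !is.na(v$volume)
  t <- v$time[ok]; x <- v$volume[ok]
  v0 <- approx(t, x, xout = t0, rule = 2)$y
  if (v0 <= level) return(t0)
  sel <- which(t > t0 & t <= t1)
  tp <- t0; xp <- v0
  for (i in sel) {
    if (x[i] <= level)
      return(tp + (t[i] - tp) * (xp - level) / (xp - x[i]))
    tp <- t[i]; xp <- x[i]
  }
  NA_real_
}

#' Per-void urodynamic parameters
#'
#' For each detected void: bladder capacity `BC = V(onset)`, residual
#' volume `RV = V(end)`, voided volume `BC - RV`, voiding efficiency
#' `100 * (BC - RV) / BC` (percent; `NA` when `BC = 0`), and the void
#' duration measure `t20_80` -- the interval between the times at which
#' the volume has fallen by 20% and by 80% of the voided volume (crossing
#' times by linear interpolation between samples). When pressure is
#' supplied, the peak UFR, UFC and pressure over `[onset, end]` and the
#' onset-to-onset intercontractile interval (ICI) are included.
#'
#' @param events data frame from [detect_voids()] (columns `onset`, `end`),
#'   or any events with those columns (e.g. ground truth).
#' @param v the (smoothed) [volume_trace()].
#' @param flow the matching [flow_trace()].
#' @param p_aligned optional pressure (cmH2O) on the flow timebase; when
#'   `NULL` (noninvasive recordings) the pressure-dependent columns
#'   `ufc_max` and `p_max` are omitted.
#' @return Data frame with one row per void: `onset`, `end`, `BC`, `RV`,
#'   `voided`, `efficiency`, `t20_80`, `ufr_max`, (`ufc_max`, `p_max`,)
#'   `ici` (`NA` for the first void).
#' @export
void_parameters <- function(events, v, flow, p_aligned = NULL) {
  stopifnot(inherits(v, "volume_trace"), inherits(flow, "flow_trace"))
  ne <- nrow(events)
  has_p <- !is.null(p_aligned)
  cols <- c("onset", "end", "BC", "RV", "voided", "efficiency", "t20_80",
            "ufr_max", if (has_p) c("ufc_max", "p_max"), "ici")
  if (ne == 0L) {
    out <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    return(out)
  }
  span <- range(v$time)
  rows <- lapply(seq_len(ne), function(k) {
    onset <- events$onset[k]; end <- events$end[k]
    if (end <= onset) stop("void end must be after onset")
    if (onset < span[1] - 1e-9 || end > span[2] + 1e-9)
      stop(sprintf("void [%0.2f, %0.2f] s lies outside the trace span",
                   onset, end))
    BC <- volume_at(v, onset); RV <- volume_at(v, end)
    voided <- BC - RV
    eff <- if (BC > 0) 100 * voided / BC else NA_real_
    t20 <- level_crossing_time(v, onset, end, BC - 0.2 * voided)
    t80 <- level_crossing_time(v, onset, end, BC - 0.8 * voided)
    t2080 <- if (is.na(t20) || is.na(t80)) NA_real_ else t80 - t20
    sel <- flow$time >= onset & flow$time <= end
    ufr_max <- max(flow$ufr[sel])
    row <- c(onset = onset, end = end, BC = BC, RV = RV, voided = voided,
             efficiency = eff, t20_80 = t2080, ufr_max = ufr_max)
    if (has_p) {
      ufc_max <- if (!is.null(flow$ufc) && any(!is.na(flow$ufc[sel])))
        max(flow$ufc[sel], na.rm = TRUE) else NA_real_
      row <- c(row, ufc_max = ufc_max, p_max = max(p_aligned[sel]))
    }
    row
  })
  out <- as.data.frame(do.call(rbind, rows))
  out$ici <- c(NA_real_, diff(out$onset))
  out[, cols]
}

#' Nonvoiding-contraction counting parameters
#'
#' Conventional cystometry definition of an NVC: a pressure excursion of at
#' least `amplitude` cmH2O above a rolling-median baseline, lasting at
#' least `min_duration` seconds, with no concomitant urine loss (volume
#' drop during the excursion at most `max_volume_drop` ul).
#'
#' @param amplitude cmH2O above baseline.
#' @param min_duration seconds.
#' @param max_volume_drop ul; larger drops mark the excursion as a
#'   voiding/leak event, not an NVC.
#' @param baseline_window rolling-median window for the pressure baseline,
#'   seconds.
#' @return An object of class `nvc_params`.
#' @export
nvc_params <- function(amplitude = 5, min_duration = 1, max_volume_drop = 2,
                       baseline_window = 15) {
  stopifnot(amplitude > 0, min_duration >= 0, max_volume_drop >= 0,
            baseline_window > 0)
  structure(list(amplitude = amplitude, min_duration = min_duration,
                 max_volume_drop = max_volume_drop,
                 baseline_window = baseline_window),
            class = "nvc_params")
}

#' Count nonvoiding contractions in the pre-void window
#'
#' Counts pressure excursions (see [nvc_params()]) whose midpoint lies in
#' `[void_onset - window, void_onset)`. Overlapping excursions form a
#' single above-threshold run and are counted once.
#'
#' @param p_aligned pressure (cmH2O) on the volume-trace timebase.
#' @param v the [volume_trace()] providing the timebase and the volume used
#'   for the no-urine-loss check.
#' @param void_onset onset of the void (s).
#' @param window length of the analysis window preceding the void, s
#'   (80 s standard); clipped to the start of the trace.
#' @param params an [nvc_params()].
#' @return Integer NVC count.
#' @export
count_nvcs <- function(p_aligned, v, void_onset, window = 80,
                       params = nvc_params()) {
  stopifnot(inherits(v, "volume_trace"))
  t <- v$time
  if (length(p_aligned) != length(t))
    stop("`p_aligned` must be on the volume-trace timebase")
  dt <- median(diff(t))
  k <- max(3L, as.integer(params$baseline_window / dt))
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, length(t) - (1 - length(t) %% 2L))
  base <- runmed(p_aligned, k, endrule = "median")
  above <- (p_aligned - base) > params$amplitude
  if (!any(above)) return(0L)
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  x <- v$volume
  ok <- v$valid & !is.na(x)
  if (any(!ok)) x[!ok] <- approx(t[ok], x[ok], xout = t[!ok], rule = 2)$y
  n_nvc <- 0L
  for (j in seq_len(nrow(runs))) {
    i0 <- runs[j, 1]; i1 <- runs[j, 2]
    mid <- (t[i0] + t[i1]) / 2
    if (mid < void_onset - window || mid >= void_onset) next
    if (t[i1] - t[i0] < params$min_duration) next
    drop <- x[i0] - min(x[i0:i1])
    if (drop > params$max_volume_drop) next
    n_nvc <- n_nvc + 1L
  }
  n_nvc
}
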