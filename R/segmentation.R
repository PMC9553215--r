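# Per-frame bladder segmentation: temporal rolling average, contrast
# normalization, dark-object thresholding, morphological cleanup, and the
# largest-closed-object rule. A classical reference operator stands behind
# the mask-per-frame contract; any external predictor honouring the same
# contract can be plugged in via `predictor`.

#' Temporal rolling average of a frame sequence
#'
#' Centered moving mean over `window` frames, the standard pre-smoothing
#' step that stabilizes fluoroscopy contrast before bladder delineation.
#' At the sequence edges the window shrinks symmetrically (frame `i`
#' averages `i - k` .. `i + k` with the largest `k` that fits), so
#' timestamps are unchanged and no frames are dropped.
#'
#' @param seq a [frame_sequence()].
#' @param window odd positive window length in frames; 15 frames (0.5 s at
#'   30 frames/s) is the standard choice for rodent fluoroscopy.
#' @return A [frame_sequence()] of the same length.
#' @export
rolling_average <- function(seq, window = 15L) {
  stopifnot(inherits(seq, "frame_sequence"))
  window <- as.integer(window)
  if (is.na(window) || window < 1L)
    stop("`window` must be a positive integer")
  if (window %% 2L == 0L)
    stop("`window` must be odd so the average is centered")
  if (window == 1L) return(seq)
  d <- dim(seq$frames)
  n <- d[3L]
  m <- matrix(seq$frames, ncol = n)
  cs <- matrix(0, nrow(m), n + 1L)
  for (j in seq_len(n)) cs[, j + 1L] <- cs[, j] + m[, j]
  half <- (window - 1L) %/% 2L
  out <- matrix(0, nrow(m), n)
  for (i in seq_len(n)) {
    k <- min(half, i - 1L, n - i)
    out[, i] <- (cs[, i + k + 1L] - cs[, i - k]) / (2L * k + 1L)
  }
  seq$frames <- array(out, dim = d)
  seq
}

#' Segmentation parameters
#'
#' @param pixel_size mm/pixel of the frames to be segmented; used to derive
#'   the default minimum object area.
#' @param method automatic threshold rule for the inverted
#'   contrast-normalized frame: `"background"` (default; background level
#'   plus `offset` -- localizes the object boundary close to its true
#'   support under a smooth attenuation edge), `"otsu"`, or `"manual"`
#'   (requires `threshold`).
#' @param threshold manual threshold on the inverted normalized intensity
#'   in `[0, 1]`; only used when `method = "manual"`.
#' @param offset offset above the background level for
#'   `method = "background"`, in normalized intensity units.
#' @param seed_level hysteresis dark-core level in normalized inverted
#'   intensity: only components containing at least one pixel above this
#'   level are bladder candidates. The contrast-filled bladder is by far
#'   the most attenuating structure in the field, so its core always
#'   reaches the top of the normalized range while bones/background
#'   structures do not; this keeps the precise low-threshold boundary yet
#'   prevents a large background structure from being selected. `NULL`
#'   disables seeding (pure largest-object rule).
#' @param min_volume smallest bladder volume considered detectable, ul; the
#'   default minimum object area is the projected area of a sphere of this
#'   volume (4 ul, the practical detection floor during efficient voids).
#' @param min_area minimum object area in pixels; overrides `min_volume`.
#' @param opening_radius radius (px) of the disc structuring element of the
#'   grayscale morphological opening applied to the inverted frame before
#'   thresholding; it erases thin high-contrast structures (bones) and
#'   noise speckle while leaving the wide bladder blob intact.
#' @param closing_radius radius (px) of the disc for the closing that
#'   smooths the object boundary before hole filling.
#' @param ellipse_refine_scale the retained component is pruned to the
#'   support of its own equivalent ellipse scaled by this factor
#'   (iterated to convergence), cutting protrusions left where background
#'   structures meet the bladder edge while keeping the true boundary;
#'   the bladder is elliptical by assumption (the volume model is a
#'   spheroid). `NULL` disables refinement.
#' @return An object of class `seg_params`.
#' @export
seg_params <- function(pixel_size,
                       method = c("background", "otsu", "manual"),
                       threshold = NULL,
                       offset = 0.12,
                       seed_level = 0.6,
                       min_volume = 4,
                       min_area = NULL,
                       opening_radius = 4L,
                       closing_radius = 3L,
                       ellipse_refine_scale = 1.05) {
  method <- match.arg(method)
  if (method == "manual" && (is.null(threshold) || threshold <= 0 ||
                             threshold >= 1))
    stop("manual method needs a `threshold` in (0, 1)")
  if (is.null(min_area)) {
    r_mm <- (3 * min_volume / (4 * pi))^(1 / 3)
    min_area <- pi * r_mm^2 / pixel_size^2
  }
  structure(list(pixel_size = pixel_size, method = method,
                 threshold = threshold, offset = offset,
                 seed_level = seed_level, min_area = min_area,
                 opening_radius = as.integer(opening_radius),
                 closing_radius = as.integer(closing_radius),
                 ellipse_refine_scale = ellipse_refine_scale),
            class = "seg_params")
}

disc_brush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels that
# touch diagonally are merged afterwards with a union-find over the label
# adjacency (vectorized over the four diagonal shifts).
label_components <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]    # down-right diagonal pairs
  c_ <- lab[-nr, -1]; d <- lab[-1, -nc]   # down-left diagonal pairs
  pairs <- rbind(cbind(as.vector(a), as.vector(b)),
                 cbind(as.vector(c_), as.vector(d)))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs)) {
    parent <- seq_len(nlab)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_len(nlab), find, integer(1))
    relab <- match(root, sort(unique(root)))
    lab[lab > 0] <- relab[lab[lab > 0]]
  }
  lab
}

#' Keep only the largest connected component of a binary mask
#'
#' Components are 8-connected. Idempotent: applying it to its own output
#' returns the same mask.
#'
#' @param mask logical matrix.
#' @return Logical matrix containing only the largest component (all
#'   `FALSE` if the input is empty).
#' @export
largest_component <- function(mask) {
  if (!any(mask)) return(mask & FALSE)
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

# 1 - Dice between a mask and the support of its own equivalent ellipse:
# ~0 for clean elliptical blobs, large when appendages or elongated
# structures distort the fit
ellipse_residual <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 8L) return(Inf)
  mu <- colMeans(idx)
  dr <- idx[, 1L] - mu[1L]; dc <- idx[, 2L] - mu[2L]
  S <- matrix(c(mean(dr * dr), mean(dr * dc),
                mean(dr * dc), mean(dc * dc)), 2L, 2L)
  e <- eigen(S, symmetric = TRUE)
  ax <- pmax(2 * sqrt(pmax(e$values, 0)), 0.5)
  half <- ceiling(ax[1]) + 1L
  rr <- max(1L, floor(mu[1] - half)):min(nrow(mask), ceiling(mu[1] + half))
  cc <- max(1L, floor(mu[2] - half)):min(ncol(mask), ceiling(mu[2] + half))
  gr <- matrix(rr, length(rr), length(cc)) - mu[1]
  gc <- matrix(cc, length(rr), length(cc), byrow = TRUE) - mu[2]
  u <- (gr * e$vectors[1, 1] + gc * e$vectors[2, 1]) / ax[1]
  w <- (gr * e$vectors[1, 2] + gc * e$vectors[2, 2]) / ax[2]
  inside <- u * u + w * w <= 1
  inter <- sum(inside & mask[rr, cc])
  1 - 2 * inter / (sum(inside) + nrow(idx))
}

# the connected piece of `mask` holding the darkest core of `inv`
dark_core_piece <- function(mask, inv) {
  lab <- label_components(mask)
  vals <- ifelse(mask, inv, -Inf)
  lab == lab[which.max(vals)]
}

# prune mask pixels outside the equivalent ellipse of the mask itself,
# scaled by `scale`; iterate to convergence (typically 2-3 passes)
refine_to_ellipse <- function(mask, scale, max_iter = 5L) {
  for (it in seq_len(max_iter)) {
    idx <- which(mask, arr.ind = TRUE)
    if (nrow(idx) < 8L) return(mask)
    mu <- colMeans(idx)
    dr <- idx[, 1L] - mu[1L]; dc <- idx[, 2L] - mu[2L]
    S <- matrix(c(mean(dr * dr), mean(dr * dc),
                  mean(dr * dc), mean(dc * dc)), 2L, 2L)
    e <- eigen(S, symmetric = TRUE)
    ax <- pmax(2 * sqrt(pmax(e$values, 0)), 1) * scale
    u <- (dr * e$vectors[1, 1] + dc * e$vectors[2, 1]) / ax[1]
    w <- (dr * e$vectors[1, 2] + dc * e$vectors[2, 2]) / ax[2]
    keep <- u * u + w * w <= 1
    if (all(keep)) return(mask)
    mask[idx[!keep, , drop = FALSE]] <- FALSE
  }
  mask
}

#' Segment the bladder in a single fluoroscopy frame
#'
#' Reference segmentation operator: contrast normalization to `[0, 1]`,
#' inversion (the contrast-filled bladder is the dark object), grayscale
#' opening (suppressing thin high-contrast structures), automatic or
#' manual global thresholding, morphological closing, hole filling,
#' 8-connected component labeling, and retention of the single largest
#' component among those seeded by the dark core (see `seed_level` in
#' [seg_params()]). A frame in which no seeded component reaches the
#' minimum area yields an empty mask and `valid = FALSE`; degenerate
#' frames never raise an error.
#'
#' @param frame numeric intensity matrix (finite values).
#' @param params a [seg_params()].
#' @return A list with `mask` (logical matrix, one 8-connected hole-filled
#'   component or empty) and `valid` (logical flag).
#' @export
segment_frame <- function(frame, params) {
  stopifnot(inherits(params, "seg_params"))
  if (!all(is.finite(frame)))
    stop("frame must be finite-valued")
  empty <- list(mask = matrix(FALSE, nrow(frame), ncol(frame)), valid = FALSE)
  rng <- range(frame)
  if (diff(rng) < 1e-12) return(empty)           # flat frame: no object
  inv <- (rng[2] - frame) / (rng[2] - rng[1])    # bladder -> bright
  if (params$opening_radius > 0)
    inv <- EBImage::imageData(
      EBImage::opening(EBImage::Image(inv),
                       disc_brush(params$opening_radius)))
  thr <- switch(params$method,
    background = median(inv) + params$offset,
    otsu = EBImage::otsu(EBImage::Image(inv), range = c(0, 1)),
    manual = params$threshold)
  if (thr >= 1) return(empty)
  bw <- EBImage::Image((inv > thr) * 1)
  if (params$closing_radius > 0)
    bw <- EBImage::closing(bw, disc_brush(params$closing_radius))
  mask <- EBImage::imageData(bw) > 0.5
  if (!any(mask)) return(empty)
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0])
  cand <- seq_along(sizes)
  if (!is.null(params$seed_level)) {
    seeded <- unique(lab[lab > 0 & inv > params$seed_level])
    cand <- intersect(cand, seeded)
  }
  if (!length(cand)) return(empty)
  best <- cand[which.max(sizes[cand])]
  if (sizes[best] < params$min_area) return(empty)
  mask <- lab == best
  # background structures crossing or tangent to the bladder merge with it
  # into one component; openings at increasing radius split them off, and
  # at each radius the piece holding the darkest core (the bladder
  # attenuates far more than any bone) is a candidate. The candidate most
  # consistent with the elliptical bladder model is retained.
  if (params$opening_radius > 0) {
    cands <- list(dark_core_piece(mask, inv))
    for (r in unique(c(params$opening_radius, 6L, 8L))) {
      tm <- EBImage::imageData(
        EBImage::opening(EBImage::Image(mask * 1), disc_brush(r))) > 0.5
      if (!any(tm)) next
      piece <- dark_core_piece(tm, inv)
      if (sum(piece) >= params$min_area)
        cands[[length(cands) + 1L]] <- piece
    }
    scores <- vapply(cands, ellipse_residual, numeric(1))
    mask <- cands[[which.min(scores)]]
  }
  if (!is.null(params$ellipse_refine_scale))
    mask <- refine_to_ellipse(mask, params$ellipse_refine_scale)
  if (sum(mask) < params$min_area) return(empty)
  # "closed object": fill interior holes of the selected component
  mask <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask * 1))) > 0.5
  list(mask = mask, valid = TRUE)
}

#' Segment every frame of a fluoroscopy sequence
#'
#' Applies [rolling_average()] followed by [segment_frame()] (or a
#' user-supplied predictor with the same contract) to each frame, and
#' records a per-frame validity flag. Every invalid frame is reported with
#' a log line.
#'
#' @param seq a [frame_sequence()].
#' @param params a [seg_params()]; defaults to `seg_params(seq$pixel_size)`.
#' @param smooth_window rolling-average window in frames (odd; 1 disables).
#' @param predictor optional function `function(frame)` returning a list
#'   with `mask` and `valid`, replacing the reference operator (e.g. an
#'   external neural-network predictor).
#' @param quiet suppress per-frame failure log lines.
#' @return A [mask_sequence()].
#' @export
segment_sequence <- function(seq, params = seg_params(seq$pixel_size),
                             smooth_window = 15L, predictor = NULL,
                             quiet = FALSE) {
  stopifnot(inherits(seq, "frame_sequence"))
  sm <- rolling_average(seq, smooth_window)
  n <- dim(sm$frames)[3L]
  op <- if (is.null(predictor)) function(f) segment_frame(f, params)
        else predictor
  masks <- array(FALSE, dim = dim(sm$frames))
  valid <- logical(n)
  for (i in seq_len(n)) {
    res <- op(sm$frames[, , i])
    masks[, , i] <- res$mask
    valid[i] <- isTRUE(res$valid)
    if (!valid[i] && !quiet)
      message(sprintf("segment_sequence: no bladder object in frame %d (t = %.3f s)",
                      i, sm$timestamps[i]))
  }
  mask_sequence(masks, valid)
}
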