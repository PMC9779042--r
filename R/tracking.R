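#' Otsu threshold of a numeric sample
#'
#' Classic between-class variance maximization on a 256-bin histogram of the
#' input range. Used both for fly segmentation on background-difference
#' images and for ROI construction on fluorescence projections.
#'
#' @param values numeric vector (or matrix) of intensities.
#' @param n_bins histogram bins.
#' @return threshold on the scale of `values`; pixels `>=` threshold are
#'   foreground.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) stop("cannot threshold a constant image")
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(findInterval(v, br, rightmost.closed = TRUE), n_bins)
  mids <- (br[-1] + br[-length(br)]) / 2
  w1 <- cumsum(counts)
  w2 <- sum(counts) - w1
  m1 <- cumsum(counts * mids) / pmax(w1, 1)
  m2 <- (sum(counts * mids) - cumsum(counts * mids)) / pmax(w2, 1)
  between <- w1 * w2 * (m1 - m2)^2
  between[w1 == 0 | w2 == 0] <- -Inf
  k <- which.max(between)
  # threshold at the upper edge of the chosen bin: foreground is > bin k
  br[k + 1L]
}

#' Label 8-connected components of a binary mask
#'
#' Iterative flood fill; adequate for the sparse masks this pipeline sees
#' (one fly blob, or one terminal blob, per image).
#'
#' @param mask logical matrix.
#' @return integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  fg <- which(mask)
  for (p in fg) {
    if (lab[p] != 0L) next
    nxt <- nxt + 1L
    stack <- p
    lab[p] <- nxt
    while (length(stack)) {
      q <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((q - 1L) %% h) + 1L
      cc <- ((q - 1L) %/% h) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; c2 <- cc + dc
        if (rr >= 1L && rr <= h && c2 >= 1L && c2 <= w) {
          qq <- (c2 - 1L) * h + rr
          if (mask[qq] && lab[qq] == 0L) {
            lab[qq] <- nxt
            stack <- c(stack, qq)
          }
        }
      }
    }
  }
  lab
}

#' Temporal-median background model
#'
#' Per-pixel median over a subsample of frames; a fly that keeps moving
#' occupies any one pixel a minority of the time, so the median recovers the
#' empty arena.
#'
#' @param frames a `frame_sequence` (from [render_frames()]) or an
#'   `h x w x n` array.
#' @param method only `"median"` is implemented.
#' @param max_frames at most this many frames (evenly spaced) enter the
#'   median, to bound memory and time.
#' @return background image matrix.
#' @export
estimate_background <- function(frames, method = "median", max_frames = 101L) {
  arr <- if (inherits(frames, "frame_sequence")) frames$frames else frames
  stopifnot(length(dim(arr)) == 3L)
  n <- dim(arr)[3]
  if (n < 3L) stop("need at least 3 frames to estimate a background")
  method <- match.arg(method, "median")
  idx <- unique(round(seq(1, n, length.out = min(n, max_frames))))
  apply(arr[, , idx, drop = FALSE], c(1, 2), stats::median)
}

#' Detect the fly in one frame
#'
#' Absolute background difference inside the chamber ROI, binarized (Otsu by
#' default), largest 8-connected component of at least `min_area_px` pixels,
#' intensity-weighted centroid. A frame with no adequate blob yields a
#' missing detection, which is a value, not an error.
#'
#' @param frame grayscale matrix.
#' @param background matrix of identical dimensions.
#' @param geometry a [chamber_geometry()]; its `roi_px` and chamber size (in
#'   px) bound the search region.
#' @param min_area_px minimum blob area.
#' @param threshold fixed threshold on the difference image; `NULL` (default)
#'   uses Otsu within the ROI.
#' @return list `(found, cx_px, cy_px, area_px, major_axis_px)`; coordinates
#'   in full-frame continuous pixel units.
#' @export
detect_fly <- function(frame, background, geometry, min_area_px = 4L,
                       threshold = NULL) {
  if (!all(dim(frame) == dim(background)))
    stop("frame and background dimensions differ")
  x0 <- geometry$roi_px[1]; y0 <- geometry$roi_px[2]
  cols <- max(1L, floor(x0) + 1L):
    min(ncol(frame), ceiling(x0 + geometry$length_mm * geometry$px_per_mm))
  rows <- max(1L, floor(y0) + 1L):
    min(nrow(frame), ceiling(y0 + geometry$width_mm * geometry$px_per_mm))
  diffim <- abs(frame[rows, cols, drop = FALSE] -
                background[rows, cols, drop = FALSE])
  miss <- list(found = FALSE, cx_px = NA_real_, cy_px = NA_real_,
               area_px = 0L, major_axis_px = NA_real_)
  if (diff(range(diffim)) == 0) return(miss)
  thr <- if (is.null(threshold)) otsu_threshold(diffim) else threshold
  mask <- diffim >= thr
  if (!any(mask)) return(miss)
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  if (max(sizes) < min_area_px) return(miss)
  best <- which.max(sizes)
  sel <- lab == best
  wts <- diffim[sel]
  pix <- which(sel, arr.ind = TRUE)
  # pixel centers at (col - 0.5, row - 0.5) within the ROI crop
  cx <- sum((pix[, "col"] - 0.5) * wts) / sum(wts) + cols[1] - 1L
  cy <- sum((pix[, "row"] - 0.5) * wts) / sum(wts) + rows[1] - 1L
  # blob major axis from second moments (4 sd of the larger principal axis)
  mx <- sum(pix[, "col"] * wts) / sum(wts)
  my <- sum(pix[, "row"] * wts) / sum(wts)
  cxx <- sum(wts * (pix[, "col"] - mx)^2) / sum(wts) + 1 / 12
  cyy <- sum(wts * (pix[, "row"] - my)^2) / sum(wts) + 1 / 12
  cxy <- sum(wts * (pix[, "col"] - mx) * (pix[, "row"] - my)) / sum(wts)
  ev <- (cxx + cyy) / 2 + sqrt(((cxx - cyy) / 2)^2 + cxy^2)
  list(found = TRUE, cx_px = cx, cy_px = cy, area_px = sum(sel),
       major_axis_px = 4 * sqrt(ev))
}

#' Track a fly through a frame sequence
#'
#' Per-frame detection, decimation to exactly 1 Hz (nearest frame to each
#' integer second), pixel-to-mm conversion, and the gap policy: detection
#' gaps of at most `max_gap_s` seconds are bridged by linear interpolation;
#' longer gaps stay undetected (they are excluded from activity sums and
#' break sleep bouts downstream, so tracking dropouts never manufacture
#' sleep). Body length is estimated as the median blob major axis unless
#' overridden.
#'
#' @param frames a `frame_sequence`.
#' @param geometry a [chamber_geometry()] carrying the px calibration
#'   (an error is raised if `px_per_mm` is missing).
#' @param min_area_px,threshold passed to [detect_fly()].
#' @param max_gap_s longest gap bridged by interpolation (default 5 s).
#' @param body_length_mm override for the estimated body length.
#' @param fly_id,chamber_id identifiers.
#' @return a [trajectory()].
#' @export
track_frames <- function(frames, geometry, min_area_px = 4L, threshold = NULL,
                         max_gap_s = 5L, body_length_mm = NULL,
                         fly_id = "fly1", chamber_id = 1L) {
  stopifnot(inherits(frames, "frame_sequence"))
  if (is.null(geometry$px_per_mm) || !is.finite(geometry$px_per_mm))
    stop("geometry lacks px_per_mm calibration")
  bg <- estimate_background(frames)
  t_s <- seq(ceiling(min(frames$t_s)), floor(max(frames$t_s)))
  pick <- vapply(t_s, function(s) which.min(abs(frames$t_s - s)), 1L)
  det <- lapply(pick, function(i)
    detect_fly(frames$frames[, , i], bg, geometry, min_area_px, threshold))
  found <- vapply(det, `[[`, logical(1), "found")
  cx <- vapply(det, `[[`, numeric(1), "cx_px")
  cy <- vapply(det, `[[`, numeric(1), "cy_px")
  x_mm <- (cx - geometry$roi_px[1]) / geometry$px_per_mm
  y_mm <- (cy - geometry$roi_px[2]) / geometry$px_per_mm

  filled <- fill_gaps(found, x_mm, y_mm, max_gap_s)
  if (is.null(body_length_mm)) {
    maj <- vapply(det, `[[`, numeric(1), "major_axis_px")[found]
    body_length_mm <- if (length(maj))
      stats::median(maj) / geometry$px_per_mm else 2.5
  }
  x_out <- pmin(pmax(filled$x, 0), geometry$length_mm)
  y_out <- pmin(pmax(filled$y, 0), geometry$width_mm)
  trajectory(t_s = t_s, x_mm = x_out, y_mm = y_out, detected = filled$valid,
             fly_id = fly_id, chamber_id = chamber_id,
             body_length_mm = body_length_mm, geometry = geometry)
}

fill_gaps <- function(found, x, y, max_gap_s) {
  valid <- found
  if (any(found) && !all(found)) {
    r <- rle(found)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$lengths)) {
      if (r$values[k]) next
      a <- starts[k] - 1L; b <- ends[k] + 1L   # flanking detections
      if (a < 1L || b > length(found)) next    # leading/trailing gap
      if (r$lengths[k] > max_gap_s) next
      idx <- starts[k]:ends[k]
      frac <- (idx - a) / (b - a)
      x[idx] <- x[a] + frac * (x[b] - x[a])
      y[idx] <- y[a] + frac * (y[b] - y[a])
      valid[idx] <- TRUE
    }
  }
  list(x = x, y = y, valid = valid)
}
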