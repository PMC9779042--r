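#' Per-fly trajectory record
#'
#' The pipeline's central record: one row per second, chamber coordinates in
#' millimetres with the origin at the food end and x along the 80 mm axis.
#' Undetected seconds keep their row (with `detected = FALSE` and `NA`
#' coordinates) so the time base stays gapless.
#'
#' @param t_s integer seconds from experiment start, strictly increasing with
#'   unit step.
#' @param x_mm,y_mm coordinates (mm); `NA` where not detected.
#' @param detected logical detection flag per sample.
#' @param fly_id,chamber_id identifiers.
#' @param body_length_mm fly body length estimate (mm), used as the
#'   significant-activity threshold downstream.
#' @param geometry a [chamber_geometry()] (optional but recommended).
#' @return a `data.frame` of class `trajectory` with attributes
#'   `body_length_mm` and `geometry`.
#' @export
trajectory <- function(t_s, x_mm, y_mm, detected = !is.na(x_mm),
                       fly_id = "fly1", chamber_id = 1L,
                       body_length_mm = 2.5, geometry = NULL) {
  t_s <- as.integer(t_s)
  n <- length(t_s)
  stopifnot(length(x_mm) == n, length(y_mm) == n, length(detected) == n,
            body_length_mm > 0)
  if (n > 1L && any(diff(t_s) != 1L))
    stop("trajectory time base must be strictly increasing with unit step")
  if (!is.null(geometry)) {
    ok <- !detected |
      (x_mm >= 0 & x_mm <= geometry$length_mm &
       y_mm >= 0 & y_mm <= geometry$width_mm)
    if (!all(ok, na.rm = TRUE))
      stop("detected positions fall outside the chamber")
  }
  out <- data.frame(
    fly_id = rep(as.character(fly_id), n),
    chamber_id = rep(as.integer(chamber_id), n),
    t_s = t_s,
    x_mm = as.numeric(x_mm),
    y_mm = as.numeric(y_mm),
    detected = as.logical(detected),
    stringsAsFactors = FALSE
  )
  out$x_mm[!out$detected] <- NA_real_
  out$y_mm[!out$detected] <- NA_real_
  attr(out, "body_length_mm") <- body_length_mm
  attr(out, "geometry") <- geometry
  class(out) <- c("trajectory", "data.frame")
  out
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s (chamber %d): %d s, %.1f%% detected, body %.2f mm\n",
              x$fly_id[1], x$chamber_id[1], nrow(x),
              100 * mean(x$detected), attr(x, "body_length_mm")))
  invisible(x)
}

body_length <- function(traj) attr(traj, "body_length_mm")

#' Total path length of a trajectory
#'
#' Sum of Euclidean displacements between consecutive detected samples,
#' i.e. the sum of the per-second displacement series.
#'
#' @param traj a [trajectory()].
#' @return total distance in mm.
#' @export
total_distance <- function(traj) {
  d <- displacement_series(traj)
  sum(d$d_mm[d$valid])
}
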