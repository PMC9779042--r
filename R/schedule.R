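#' Light-dark schedule
#'
#' Maps experiment time (integer seconds from recording start) to Zeitgeber
#' time (ZT, hours since lights-on) and to a day index. ZT0 is lights-on and,
#' under the default 12:12 LD regime, ZT12 is lights-off.
#'
#' @param lights_on_s experiment time (seconds) of the first lights-on event.
#'   0 (default) means the recording starts exactly at lights-on; a positive
#'   value shifts ZT0 later into the recording, a negative one means lights
#'   came on before recording started.
#' @param photoperiod_h hours of light per cycle (default 12).
#' @param period_h full cycle length in hours (default 24).
#' @return an object of class `ld_schedule`.
#' @export
ld_schedule <- function(lights_on_s = 0, photoperiod_h = 12, period_h = 24) {
  stopifnot(is.numeric(lights_on_s), length(lights_on_s) == 1L,
            photoperiod_h > 0, photoperiod_h < period_h)
  structure(
    list(lights_on_s = as.numeric(lights_on_s),
         photoperiod_h = as.numeric(photoperiod_h),
         period_h = as.numeric(period_h)),
    class = "ld_schedule"
  )
}

#' Zeitgeber time of experiment seconds
#'
#' @param t_s experiment time in seconds (numeric vector).
#' @param schedule an [ld_schedule()].
#' @return ZT in hours, in `[0, period_h)`.
#' @export
zt_hours <- function(t_s, schedule) {
  ((t_s - schedule$lights_on_s) / 3600) %% schedule$period_h
}

#' Day index of experiment seconds
#'
#' Day 1 starts at the first lights-on. Seconds before the first lights-on
#' get day index 0 (or negative).
#'
#' @inheritParams zt_hours
#' @return integer day index (1-based from first lights-on).
#' @export
day_index <- function(t_s, schedule) {
  as.integer(floor((t_s - schedule$lights_on_s) / (schedule$period_h * 3600))) + 1L
}

#' Is the light on at a given experiment second?
#' @inheritParams zt_hours
#' @return logical vector.
#' @export
lights_on <- function(t_s, schedule) {
  zt_hours(t_s, schedule) < schedule$photoperiod_h
}

#' @export
print.ld_schedule <- function(x, ...) {
  cat(sprintf("<ld_schedule> lights-on at t=%gs, %g:%g LD\n",
              x$lights_on_s, x$photoperiod_h, x$period_h - x$photoperiod_h))
  invisible(x)
}

#' Arena chamber geometry
#'
#' Single-fly chamber of the video-tracking rig, 80 x 8 x 8 mm by default,
#' with the pixel calibration needed to map frame coordinates to chamber
#' millimetres and the position of the virtual infrared beam used by the
#' monitor emulator.
#'
#' @param length_mm chamber long axis (mm).
#' @param width_mm chamber short axis (mm).
#' @param height_mm chamber height (mm); informational only.
#' @param px_per_mm pixel calibration (pixels per mm).
#' @param roi_px chamber region in frame coordinates,
#'   `c(x0, y0)` = pixel offset of the chamber origin (food end, top wall).
#' @param beam_x_mm position of the virtual beam along the long axis;
#'   defaults to the chamber midpoint.
#' @return an object of class `chamber_geometry`.
#' @export
chamber_geometry <- function(length_mm = 80, width_mm = 8, height_mm = 8,
                             px_per_mm = 4, roi_px = c(0, 0),
                             beam_x_mm = length_mm / 2) {
  stopifnot(length_mm > 0, width_mm > 0, px_per_mm > 0,
            beam_x_mm > 0, beam_x_mm < length_mm, length(roi_px) == 2L)
  structure(
    list(length_mm = length_mm, width_mm = width_mm, height_mm = height_mm,
         px_per_mm = px_per_mm, roi_px = as.numeric(roi_px),
         beam_x_mm = beam_x_mm),
    class = "chamber_geometry"
  )
}

#' @export
print.chamber_geometry <- function(x, ...) {
  cat(sprintf("<chamber_geometry> %g x %g x %g mm, %g px/mm, beam at x=%g mm\n",
              x$length_mm, x$width_mm, x$height_mm, x$px_per_mm, x$beam_x_mm))
  invisible(x)
}
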