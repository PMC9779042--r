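#' Per-second displacement activity series
#'
#' Activity is the distance travelled per second: the Euclidean displacement
#' between consecutive detected positions. A second is valid only when both
#' of its endpoints were detected; invalid seconds carry `NA` and are
#' excluded from all downstream sums.
#'
#' @param traj a [trajectory()].
#' @return an `activity_series`: data.frame with `t_s` (second end time),
#'   `d_mm` (displacement, mm), `valid`; attributes `body_length_mm`,
#'   `fly_id`.
#' @export
displacement_series <- function(traj) {
  if (nrow(traj) < 2L) stop("need at least 2 trajectory samples")
  dx <- diff(traj$x_mm)
  dy <- diff(traj$y_mm)
  d <- sqrt(dx^2 + dy^2)
  valid <- traj$detected[-1L] & traj$detected[-nrow(traj)]
  d[!valid] <- NA_real_
  out <- data.frame(t_s = traj$t_s[-1L], d_mm = d, valid = valid)
  attr(out, "body_length_mm") <- attr(traj, "body_length_mm")
  attr(out, "fly_id") <- traj$fly_id[1]
  class(out) <- c("activity_series", "data.frame")
  out
}

#' Score sleep bouts from an activity series
#'
#' Sleep is the absence of significant activity -- a displacement of at least
#' one body length per second -- for at least 5 consecutive minutes. Maximal
#' runs of valid sub-threshold seconds lasting `min_bout_s` or more become
#' bouts; invalid seconds break runs, so tracking dropouts never count as
#' sleep.
#'
#' @param series an [displacement_series()] output.
#' @param body_length_mm significant-activity threshold (mm/s); defaults to
#'   the series' recorded body length.
#' @param min_bout_s minimum bout duration, default 300 s (5 min).
#' @return a `sleep_record`: data.frame of bouts with `start_s`, `end_s`
#'   (the bout covers seconds `(start_s, end_s]` of the record) and
#'   `duration_s`.
#' @export
score_sleep <- function(series, body_length_mm = attr(series, "body_length_mm"),
                        min_bout_s = 300L) {
  if (is.null(body_length_mm) || body_length_mm <= 0)
    stop("body length threshold must be positive")
  quiescent <- series$valid & series$d_mm < body_length_mm
  r <- rle(as.vector(quiescent))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_bout_s
  bouts <- data.frame(
    start_s = series$t_s[starts[keep]] - 1L,
    end_s = series$t_s[ends[keep]],
    duration_s = r$lengths[keep]
  )
  structure(bouts, class = c("sleep_record", "data.frame"),
            min_bout_s = min_bout_s)
}

split_bouts_at <- function(bouts, boundaries_s) {
  # split bouts at ZT window boundaries so window totals are exact
  if (nrow(bouts) == 0L) return(bouts)
  pieces <- list()
  for (i in seq_len(nrow(bouts))) {
    cuts <- boundaries_s[boundaries_s > bouts$start_s[i] &
                           boundaries_s < bouts$end_s[i]]
    edges <- c(bouts$start_s[i], cuts, bouts$end_s[i])
    pieces[[i]] <- data.frame(start_s = edges[-length(edges)],
                              end_s = edges[-1L])
  }
  out <- do.call(rbind, pieces)
  out$duration_s <- out$end_s - out$start_s
  out
}

#' Summarize sleep by day and light phase
#'
#' Bouts are split at lights-on/lights-off boundaries before summation, so a
#' bout straddling ZT12 contributes exactly its overlap to each phase.
#'
#' @param record a [score_sleep()] result.
#' @param schedule an [ld_schedule()].
#' @param bin_width_min width of the binned sleep profile (default 30 min).
#' @return list with `by_day` (data.frame: day, daytime_sleep_min ZT0-12,
#'   nighttime_sleep_min ZT12-24, bout_count, mean_bout_min), totals, and
#'   `binned` (per-bin sleep minutes across the ZT day, averaged over days).
#' @export
sleep_summary <- function(record, schedule = ld_schedule(),
                          bin_width_min = 30) {
  period_s <- schedule$period_h * 3600
  half_s <- schedule$photoperiod_h * 3600
  if (nrow(record) == 0L) {
    by_day <- data.frame(day = integer(), daytime_sleep_min = numeric(),
                         nighttime_sleep_min = numeric(),
                         bout_count = integer(), mean_bout_min = numeric())
    binned <- data.frame(zt_bin_start_h = seq(0, schedule$period_h,
                                              by = bin_width_min / 60))
    binned <- binned[-nrow(binned), , drop = FALSE]
    binned$sleep_min <- 0
    return(list(by_day = by_day, binned = binned,
                total_daytime_min = 0, total_nighttime_min = 0))
  }
  max_t <- max(record$end_s)
  bounds <- seq(schedule$lights_on_s - period_s,
                max_t + period_s, by = half_s)
  split <- split_bouts_at(record, bounds)
  mid <- (split$start_s + split$end_s) / 2
  split$day <- day_index(mid, schedule)
  split$daytime <- lights_on(mid, schedule)

  days <- sort(unique(split$day))
  by_day <- do.call(rbind, lapply(days, function(d) {
    sd_ <- split[split$day == d, ]
    orig <- record[day_index((record$start_s + record$end_s) / 2,
                             schedule) == d, ]
    data.frame(day = d,
               daytime_sleep_min = sum(sd_$duration_s[sd_$daytime]) / 60,
               nighttime_sleep_min = sum(sd_$duration_s[!sd_$daytime]) / 60,
               bout_count = nrow(orig),
               mean_bout_min = if (nrow(orig)) mean(orig$duration_s) / 60
                               else NA_real_)
  }))

  bin_s <- bin_width_min * 60
  bin_bounds <- seq(schedule$lights_on_s - period_s, max_t + period_s,
                    by = bin_s)
  fine <- split_bouts_at(record, bin_bounds)
  zt_bin <- floor(zt_hours((fine$start_s + fine$end_s) / 2, schedule) *
                    3600 / bin_s)
  n_days_obs <- max(1L, length(days))
  bin_starts <- seq(0, schedule$period_h * 3600 - bin_s, by = bin_s) / 3600
  sleep_min <- vapply(seq_along(bin_starts) - 1L, function(b)
    sum(fine$duration_s[zt_bin == b]) / 60 / n_days_obs, numeric(1))
  binned <- data.frame(zt_bin_start_h = bin_starts, sleep_min = sleep_min)

  list(by_day = by_day, binned = binned,
       total_daytime_min = sum(by_day$daytime_sleep_min),
       total_nighttime_min = sum(by_day$nighttime_sleep_min))
}

window_sum <- function(series, schedule, day, zt_from, zt_to) {
  period_s <- schedule$period_h * 3600
  t0 <- schedule$lights_on_s + (day - 1L) * period_s
  lo <- t0 + zt_from * 3600
  hi <- t0 + zt_to * 3600
  # displacement second t covers (t-1, t]
  sel <- series$t_s > lo & series$t_s <= hi
  list(sum = sum(series$d_mm[sel & series$valid]),
       n = sum(sel), n_valid = sum(sel & series$valid))
}

#' Morning anticipation index of one day
#'
#' MAI = total activity in ZT21-24 divided by total activity in ZT18-24 of
#' the same cycle. Time-uniform activity gives 0.5; activity rising into
#' dawn pushes the index toward 1. The day must be complete: the full
#' ZT18-24 window must be covered with at least `min_valid_frac` valid
#' seconds. A zero denominator yields an undefined (NA) index.
#'
#' @param series an [displacement_series()] output.
#' @param schedule an [ld_schedule()].
#' @param day 1-based day index.
#' @param min_valid_frac completeness threshold for the ZT18-24 window.
#' @return list `(mai, defined, reason)`; `mai` is `NA` when undefined.
#' @export
morning_anticipation_index <- function(series, schedule = ld_schedule(),
                                       day = 1L, min_valid_frac = 0.95) {
  full <- window_sum(series, schedule, day, 18, 24)
  late <- window_sum(series, schedule, day, 21, 24)
  if (full$n < 6 * 3600)
    return(list(mai = NA_real_, defined = FALSE, reason = "incomplete day"))
  if (full$n_valid < min_valid_frac * full$n)
    return(list(mai = NA_real_, defined = FALSE,
                reason = "too many invalid samples"))
  if (full$sum == 0)
    return(list(mai = NA_real_, defined = FALSE, reason = "zero denominator"))
  list(mai = late$sum / full$sum, defined = TRUE, reason = NA_character_)
}

#' Per-day MAI table for a whole record
#'
#' @inheritParams morning_anticipation_index
#' @return data.frame with `day`, `mai`, `defined`, `reason`.
#' @export
mai_by_day <- function(series, schedule = ld_schedule(),
                       min_valid_frac = 0.95) {
  period_s <- schedule$period_h * 3600
  days <- seq_len(max(0L, floor((max(series$t_s) - schedule$lights_on_s) /
                                  period_s)))
  if (!length(days)) stop("record holds no complete day")
  rows <- lapply(days, function(d) {
    m <- morning_anticipation_index(series, schedule, d, min_valid_frac)
    data.frame(day = d, mai = m$mai, defined = m$defined,
               reason = if (is.na(m$reason)) "" else m$reason)
  })
  do.call(rbind, rows)
}

#' Three-day mean MAI
#'
#' Averages the MAI of the first three complete days (days whose index is
#' defined); single-day MAIs are noisy, so the multi-day mean is the per-fly
#' statistic used for group comparisons.
#'
#' @param per_day data.frame from [mai_by_day()], or a numeric vector of
#'   per-day MAI values (NA = undefined).
#' @param n_required number of complete days averaged (default 3).
#' @return mean of the first `n_required` defined values.
#' @export
mai_mean <- function(per_day, n_required = 3L) {
  vals <- if (is.data.frame(per_day)) per_day$mai else as.numeric(per_day)
  usable <- which(!is.na(vals))
  if (length(usable) < n_required)
    stop(sprintf("need %d complete days with defined MAI, have %d (days %s)",
                 n_required, length(usable),
                 paste(usable, collapse = ", ")))
  mean(vals[usable[seq_len(n_required)]])
}

#' Average activity (or sleep) profile across a cohort
#'
#' Per fly: activity summed into ZT bins, averaged over complete days.
#' Across flies: mean and SEM per bin.
#'
#' @param series_list list of [displacement_series()] outputs (one per fly).
#' @param bin_width_min bin width, default 30 min.
#' @param schedule an [ld_schedule()].
#' @return a `binned_profile` data.frame: `zt_bin_start_h`, `mean`, `sem`,
#'   `n_flies`; per-fly matrix in attribute `per_fly`.
#' @export
average_activity_profile <- function(series_list, bin_width_min = 30,
                                     schedule = ld_schedule()) {
  stopifnot(length(series_list) >= 1L)
  bin_s <- bin_width_min * 60
  n_bins <- as.integer(schedule$period_h * 3600 / bin_s)
  per_fly <- vapply(series_list, function(s) {
    day <- day_index(s$t_s - 1L, schedule)  # label by second start
    keep <- s$valid & day >= 1L
    n_days <- max(1L, max(day[keep], 0L))
    zt_bin <- floor(((s$t_s - 1L - schedule$lights_on_s) %%
                       (schedule$period_h * 3600)) / bin_s)
    sums <- vapply(seq_len(n_bins) - 1L, function(b)
      sum(s$d_mm[keep & zt_bin == b]), numeric(1))
    sums / n_days
  }, numeric(n_bins))
  per_fly <- matrix(per_fly, nrow = n_bins)
  m <- rowMeans(per_fly)
  sem <- if (ncol(per_fly) > 1)
    apply(per_fly, 1, stats::sd) / sqrt(ncol(per_fly)) else rep(0, n_bins)
  out <- data.frame(zt_bin_start_h = (seq_len(n_bins) - 1L) * bin_s / 3600,
                    mean = m, sem = sem, n_flies = ncol(per_fly))
  attr(out, "per_fly") <- per_fly
  class(out) <- c("binned_profile", "data.frame")
  out
}

#' Per-fly behavioral metrics table for a cohort
#'
#' The canonical hand-off from trajectories to group statistics: one row per
#' fly with its 3-day mean MAI, day/night sleep, and total distance.
#'
#' @param cohort list of trajectories from [simulate_cohort()] (or any list
#'   of [trajectory()] objects with `group` attributes).
#' @param schedule an [ld_schedule()].
#' @param n_required_days days entering the MAI mean.
#' @return data.frame: fly_id, group, mai_mean3, daytime_sleep_min,
#'   nighttime_sleep_min, total_distance_mm, n_defined_days.
#' @export
cohort_metrics <- function(cohort, schedule = ld_schedule(),
                           n_required_days = 3L) {
  rows <- lapply(cohort, function(tr) {
    s <- displacement_series(tr)
    sl <- sleep_summary(score_sleep(s), schedule)
    md <- mai_by_day(s, schedule)
    m3 <- tryCatch(mai_mean(md, n_required_days), error = function(e) NA_real_)
    data.frame(fly_id = tr$fly_id[1],
               group = attr(tr, "group") %||% "all",
               mai_mean3 = m3,
               n_defined_days = sum(md$defined),
               daytime_sleep_min = sl$total_daytime_min,
               nighttime_sleep_min = sl$total_nighttime_min,
               total_distance_mm = sum(s$d_mm[s$valid]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
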