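#' Virtual infrared-beam crossing counts
#'
#' Emulates a single-beam activity monitor from a trajectory: a crossing is
#' counted at second t when the fly's x position moves to the other side of
#' the beam between consecutive detected samples. With the default dead band
#' of 0 mm this is exactly a sign change of `x - beam_x`; a positive dead
#' band adds hysteresis (the fly must leave the band on the other side),
#' modelling finite beam width. Counts are aggregated per experiment minute.
#'
#' @param traj a [trajectory()].
#' @param geometry a [chamber_geometry()] providing `beam_x_mm`.
#' @param dead_band_mm hysteresis band width (default 0).
#' @return a `beam_count_series`: data.frame with `minute` (0-based index
#'   from experiment start), `count`, and `valid` (FALSE when the minute
#'   contains an undetected gap longer than 5 s).
#' @export
beam_counts <- function(traj, geometry = attr(traj, "geometry") %||%
                          chamber_geometry(), dead_band_mm = 0) {
  beam <- geometry$beam_x_mm
  x <- traj$x_mm
  det <- traj$detected
  n <- nrow(traj)
  cross <- logical(n)           # crossing attributed to second t (index i)
  if (dead_band_mm <= 0) {
    p1 <- x[-n] - beam
    p2 <- x[-1L] - beam
    cross[-1L] <- det[-n] & det[-1L] & !is.na(p1) & !is.na(p2) & (p1 * p2 < 0)
  } else {
    half <- dead_band_mm / 2
    side <- 0L
    for (i in seq_len(n)) {
      if (!det[i]) next
      s <- if (x[i] < beam - half) -1L else if (x[i] > beam + half) 1L else 0L
      if (s != 0L) {
        if (side != 0L && s != side && det[i - 1L]) cross[i] <- TRUE
        side <- s
      }
    }
  }
  # displacement second t covers (t-1, t], so it belongs to minute (t-1)%/%60
  minute <- (traj$t_s - 1L) %/% 60L
  minutes <- sort(unique(minute[traj$t_s >= 1L]))
  cnt <- vapply(minutes, function(m)
    sum(cross[minute == m]), integer(1))
  # a minute is invalid if it contains an undetected run longer than 5 s
  bad_gap <- logical(length(minutes))
  if (any(!det)) {
    r <- rle(det)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(!r$values & r$lengths > 5L)) {
      mm <- unique((traj$t_s[starts[k]:ends[k]] - 1L) %/% 60L)
      bad_gap[minutes %in% mm] <- TRUE
    }
  }
  structure(data.frame(minute = minutes, count = cnt, valid = !bad_gap),
            class = c("beam_count_series", "data.frame"))
}

#' Sleep scored the single-beam monitor way
#'
#' The monitor convention: maximal runs of minutes with zero crossing counts
#' lasting at least `min_bout_min` minutes are sleep. Invalid minutes (long
#' tracking gaps) break runs.
#'
#' @param counts a [beam_counts()] result.
#' @param min_bout_min minimum bout length in minutes (default 5).
#' @return a `sleep_record` (bout times in seconds, minute resolution).
#' @export
dam_sleep <- function(counts, min_bout_min = 5L) {
  zero <- counts$count == 0L & counts$valid
  r <- rle(as.vector(zero))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_bout_min
  bouts <- data.frame(
    start_s = counts$minute[starts[keep]] * 60L,
    end_s = (counts$minute[ends[keep]] + 1L) * 60L
  )
  bouts$duration_s <- bouts$end_s - bouts$start_s
  structure(bouts, class = c("sleep_record", "data.frame"),
            min_bout_s = min_bout_min * 60L)
}

#' Per-minute beam MAI helper
#'
#' MAI computed from beam counts instead of displacement: total counts in
#' ZT21-24 over total counts in ZT18-24.
#' @param counts a [beam_counts()] result.
#' @param schedule an [ld_schedule()].
#' @param day 1-based day index.
#' @return list `(mai, defined)`.
#' @export
dam_mai <- function(counts, schedule = ld_schedule(), day = 1L) {
  t_mid <- counts$minute * 60 + 30
  d <- day_index(t_mid, schedule)
  zt <- zt_hours(t_mid, schedule)
  full <- d == day & zt >= 18
  late <- full & zt >= 21
  denom <- sum(counts$count[full])
  if (sum(full) < 6 * 60 || denom == 0)
    return(list(mai = NA_real_, defined = FALSE))
  list(mai = sum(counts$count[late]) / denom, defined = TRUE)
}

#' Video-versus-beam system comparison on one cohort
#'
#' Both metric sets are computed from the same trajectories: video activity
#' and sleep from per-second displacement, monitor activity and sleep from
#' emulated beam crossings. Returns the paired per-fly-per-day table plus the
#' test battery used for system comparisons: a Scheirer-Ray-Hare test
#' (system x day) on daily sleep percentage and per-day paired Wilcoxon
#' signed-rank tests with Benjamini-Hochberg correction.
#'
#' @param cohort list of [trajectory()] objects.
#' @param geometry a [chamber_geometry()].
#' @param schedule an [ld_schedule()].
#' @return list with `per_fly_day` (fly_id, day, video_sleep_pct,
#'   dam_sleep_pct, video_mai, dam_mai), `srh` ([scheirer_ray_hare()] result
#'   on sleep), `wilcoxon_by_day` ([wilcoxon_bh()] table), and
#'   `mean_sleep_diff_pct` (dam - video).
#' @export
compare_systems <- function(cohort, geometry = chamber_geometry(),
                            schedule = ld_schedule()) {
  stopifnot(length(cohort) >= 2L)
  period_s <- schedule$period_h * 3600
  rows <- list()
  for (tr in cohort) {
    s <- displacement_series(tr)
    vid <- score_sleep(s)
    cts <- beam_counts(tr, geometry)
    dam <- dam_sleep(cts)
    n_days <- floor((max(tr$t_s) - schedule$lights_on_s) / period_s)
    for (d in seq_len(n_days)) {
      t0 <- schedule$lights_on_s + (d - 1L) * period_s
      in_day <- function(b) pmax(0, pmin(b$end_s, t0 + period_s) -
                                   pmax(b$start_s, t0))
      vmai <- morning_anticipation_index(s, schedule, d)
      dmai <- dam_mai(cts, schedule, d)
      rows[[length(rows) + 1L]] <- data.frame(
        fly_id = tr$fly_id[1], day = d,
        video_sleep_pct = 100 * sum(in_day(vid)) / period_s,
        dam_sleep_pct = 100 * sum(in_day(dam)) / period_s,
        video_mai = vmai$mai, dam_mai = dmai$mai,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, c(rows, make.row.names = FALSE))

  long_val <- c(tab$video_sleep_pct, tab$dam_sleep_pct)
  long_sys <- rep(c("video", "dam"), each = nrow(tab))
  long_day <- factor(c(tab$day, tab$day))
  # the system x day rank test needs at least two recorded days
  srh <- if (nlevels(long_day) >= 2 && stats::var(long_val) > 0)
    scheirer_ray_hare(long_val, factor(long_sys), long_day) else NULL

  days <- sort(unique(tab$day))
  pairs <- lapply(days, function(d) {
    sub <- tab[tab$day == d, ]
    list(x = sub$dam_sleep_pct, y = sub$video_sleep_pct)
  })
  wbd <- wilcoxon_bh(pairs, paired = TRUE)
  wbd$day <- days

  list(per_fly_day = tab, srh = srh, wilcoxon_by_day = wbd,
       mean_sleep_diff_pct = mean(tab$dam_sleep_pct - tab$video_sleep_pct))
}
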