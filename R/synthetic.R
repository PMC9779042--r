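#' Simulation configuration for synthetic fly trajectories
#'
#' Describes a fly's expected locomotor program over the 24 h Zeitgeber cycle:
#' piecewise-constant baseline displacement rates, a linear pre-dawn
#' anticipation ramp ending at lights-on, a lights-on startle spike, a linear
#' evening ramp ending at lights-off, and a two-state (wake/sleep) chain with
#' per-phase transition probabilities. Each second of the simulated record is
#' labelled by the ZT at its end; intervals are matched half-open `(from, to]`
#' with ZT 0 treated as 24, so the last second before lights-on carries the
#' full ramp amplitude.
#'
#' @param n_days number of simulated LD days.
#' @param body_length_mm fly body length (mm); the downstream
#'   significant-activity threshold. Default 2.5 mm, typical for adult
#'   D. melanogaster.
#' @param phase_rates data.frame with columns `zt_from`, `zt_to`, `rate`
#'   (mm/s expected displacement while awake); intervals must tile `[0, 24)`
#'   without overlap.
#' @param anticipation_ramp list `(onset_zt, amplitude)`: linear rise from 0
#'   at `onset_zt` to `amplitude` (mm/s) at lights-on. Amplitude 0 disables.
#' @param startle list `(amplitude, duration_s)`: added to the expected rate
#'   for `duration_s` seconds after lights-on.
#' @param evening_peak list `(onset_zt, amplitude)`: linear rise ending at
#'   lights-off (ZT12).
#' @param sleep_dynamics data.frame with columns `zt_from`, `zt_to`,
#'   `p_fall_asleep`, `p_wake` (per-second transition probabilities);
#'   intervals must tile `[0, 24)`.
#' @param micro_move_mm amplitude bound of sub-threshold jitter while in the
#'   sleep state (mm); consecutive sleeping positions are never further apart
#'   than this.
#' @param confine_mm if non-NULL, restrict the walk to `[0, confine_mm]`
#'   along the long axis (models a fly foraging in one chamber half).
#' @param seed default master seed carried with the config (can be overridden
#'   at simulation time).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_days = 3,
                       body_length_mm = 2.5,
                       phase_rates = data.frame(zt_from = 0, zt_to = 24,
                                                rate = 1.5),
                       anticipation_ramp = list(onset_zt = 21, amplitude = 0),
                       startle = list(amplitude = 0, duration_s = 60),
                       evening_peak = list(onset_zt = 10, amplitude = 0),
                       sleep_dynamics = data.frame(zt_from = 0, zt_to = 24,
                                                   p_fall_asleep = 0.002,
                                                   p_wake = 0.02),
                       micro_move_mm = 0.2,
                       confine_mm = NULL,
                       seed = 1L) {
  check_phase_table(phase_rates, "phase_rates", value_cols = "rate")
  check_phase_table(sleep_dynamics, "sleep_dynamics",
                    value_cols = c("p_fall_asleep", "p_wake"))
  stopifnot(n_days >= 1, body_length_mm > 0,
            anticipation_ramp$amplitude >= 0,
            anticipation_ramp$onset_zt >= 0, anticipation_ramp$onset_zt < 24,
            startle$amplitude >= 0, startle$duration_s >= 0,
            evening_peak$amplitude >= 0,
            evening_peak$onset_zt >= 0, evening_peak$onset_zt < 24,
            micro_move_mm >= 0)
  if (any(sleep_dynamics$p_fall_asleep < 0 | sleep_dynamics$p_fall_asleep > 1 |
          sleep_dynamics$p_wake < 0 | sleep_dynamics$p_wake > 1))
    stop("sleep transition probabilities must lie in [0, 1]")
  if (evening_peak$amplitude > 0 && evening_peak$onset_zt >= 12)
    stop("evening peak must start before lights-off (ZT12)")
  if (anticipation_ramp$amplitude > 0 && anticipation_ramp$onset_zt < 12)
    stop("anticipation ramp must start after lights-off (ZT12)")
  structure(
    list(n_days = as.integer(n_days), body_length_mm = body_length_mm,
         phase_rates = phase_rates, anticipation_ramp = anticipation_ramp,
         startle = startle, evening_peak = evening_peak,
         sleep_dynamics = sleep_dynamics, micro_move_mm = micro_move_mm,
         confine_mm = confine_mm, seed = as.integer(seed)),
    class = "sim_config"
  )
}

check_phase_table <- function(tab, name, value_cols) {
  need <- c("zt_from", "zt_to", value_cols)
  if (!all(need %in% names(tab)))
    stop(sprintf("%s must have columns %s", name, paste(need, collapse = ", ")))
  tab <- tab[order(tab$zt_from), , drop = FALSE]
  if (tab$zt_from[1] != 0 || tab$zt_to[nrow(tab)] != 24 ||
      any(tab$zt_to <= tab$zt_from) ||
      (nrow(tab) > 1 && any(tab$zt_from[-1] != tab$zt_to[-nrow(tab)])))
    stop(sprintf("overlapping or non-tiling phase definitions in %s", name))
  invisible(tab)
}

#' Built-in simulation presets
#'
#' Qualitative activity programs emulating the groups a circadian behavior
#' screen compares. `"male"`: bimodal profile with pre-dawn anticipation,
#' a siesta, an evening ramp and consolidated night rest. `"virgin"`: higher
#' daytime activity, weaker anticipation. `"mated"`: sustained daytime
#' activity, a high-amplitude lights-on startle, and no anticipation ramp
#' (flat expected pre-dawn rate, the agnostic reading of anticipation
#' suppression). `"mated_declining"`: as `"mated"` but pre-dawn activity
#' declining into dawn, the below-0.5 MAI reading. `"flat"`: time-uniform
#' rates and sleep pressure, the MAI = 0.5 null. `"confined"`: as `"flat"`
#' but with supra-threshold micro-foraging confined to one chamber half, the
#' preset that exposes single-beam monitor sleep overestimation.
#'
#' @param name preset name.
#' @param n_days number of simulated days.
#' @param seed master seed stored in the config.
#' @return a [sim_config()].
#' @export
sim_preset <- function(name = c("male", "virgin", "mated", "mated_declining",
                                "flat", "confined"),
                       n_days = 3, seed = 1L) {
  name <- match.arg(name)
  active_dyn <- function(zt_from, zt_to, pf, pw)
    data.frame(zt_from = zt_from, zt_to = zt_to,
               p_fall_asleep = pf, p_wake = pw)
  switch(name,
    male = sim_config(
      n_days = n_days, seed = seed,
      phase_rates = data.frame(
        zt_from = c(0, 1, 4, 10, 12, 13, 21),
        zt_to   = c(1, 4, 10, 12, 13, 21, 24),
        rate    = c(2.5, 1.8, 0.8, 1.8, 1.5, 0.6, 0.8)),
      anticipation_ramp = list(onset_zt = 21, amplitude = 2.0),
      startle = list(amplitude = 3.0, duration_s = 60),
      evening_peak = list(onset_zt = 10, amplitude = 2.0),
      sleep_dynamics = rbind(
        active_dyn(0, 4,  0.002, 0.020),
        active_dyn(4, 10, 0.008, 0.004),   # siesta
        active_dyn(10, 13, 0.002, 0.020),
        active_dyn(13, 21, 0.012, 0.002),  # consolidated night rest
        active_dyn(21, 24, 0.003, 0.010)), # pre-dawn arousal
      micro_move_mm = 0.2),
    virgin = sim_config(
      n_days = n_days, seed = seed,
      phase_rates = data.frame(
        zt_from = c(0, 1, 4, 10, 12, 13, 21),
        zt_to   = c(1, 4, 10, 12, 13, 21, 24),
        rate    = c(2.8, 2.4, 1.6, 2.2, 1.5, 0.6, 0.8)),
      anticipation_ramp = list(onset_zt = 21, amplitude = 1.2),
      startle = list(amplitude = 3.0, duration_s = 60),
      evening_peak = list(onset_zt = 10, amplitude = 1.6),
      sleep_dynamics = rbind(
        active_dyn(0, 4,  0.002, 0.025),
        active_dyn(4, 10, 0.005, 0.008),
        active_dyn(10, 13, 0.002, 0.025),
        active_dyn(13, 21, 0.012, 0.002),
        active_dyn(21, 24, 0.004, 0.008)),
      micro_move_mm = 0.2),
    mated = sim_config(
      n_days = n_days, seed = seed,
      phase_rates = data.frame(
        zt_from = c(0, 12, 13, 18),
        zt_to   = c(12, 13, 18, 24),
        rate    = c(3.0, 1.5, 0.6, 0.7)),
      anticipation_ramp = list(onset_zt = 21, amplitude = 0),
      startle = list(amplitude = 4.0, duration_s = 60),
      evening_peak = list(onset_zt = 10, amplitude = 1.0),
      sleep_dynamics = rbind(
        active_dyn(0, 12, 0.001, 0.040),   # daytime sleep loss
        active_dyn(12, 13, 0.002, 0.020),
        active_dyn(13, 24, 0.012, 0.002)),
      micro_move_mm = 0.2),
    mated_declining = sim_config(
      n_days = n_days, seed = seed,
      phase_rates = data.frame(
        zt_from = c(0, 12, 13, 18, 21),
        zt_to   = c(12, 13, 18, 21, 24),
        rate    = c(3.0, 1.5, 0.6, 1.0, 0.5)),
      anticipation_ramp = list(onset_zt = 21, amplitude = 0),
      startle = list(amplitude = 4.0, duration_s = 60),
      evening_peak = list(onset_zt = 10, amplitude = 1.0),
      sleep_dynamics = rbind(
        active_dyn(0, 12, 0.001, 0.040),
        active_dyn(12, 13, 0.002, 0.020),
        active_dyn(13, 24, 0.012, 0.002)),
      micro_move_mm = 0.2),
    flat = sim_config(n_days = n_days, seed = seed),
    confined = sim_config(
      n_days = n_days, seed = seed,
      phase_rates = data.frame(zt_from = 0, zt_to = 24, rate = 2.0),
      sleep_dynamics = data.frame(zt_from = 0, zt_to = 24,
                                  p_fall_asleep = 0.004, p_wake = 0.015),
      confine_mm = 35)
  )
}

phase_lookup <- function(zt_end, tab, col) {
  # second labelled by end-of-second ZT; intervals matched (from, to]
  out <- numeric(length(zt_end))
  hit <- logical(length(zt_end))
  for (i in seq_len(nrow(tab))) {
    in_i <- zt_end > tab$zt_from[i] & zt_end <= tab$zt_to[i]
    out[in_i] <- tab[[col]][i]
    hit <- hit | in_i
  }
  if (!all(hit)) stop("phase table does not cover all ZT values")
  out
}

#' Expected per-second displacement series
#'
#' Deterministic expected displacement (mm/s) for every second of the
#' simulated record: baseline phase rate, plus the anticipation ramp, the
#' lights-on startle, and the evening ramp.
#'
#' @param config a [sim_config()].
#' @param schedule an [ld_schedule()]; must cover `config$n_days`.
#' @return numeric vector of length `86400 * n_days`.
#' @export
simulate_intensity <- function(config, schedule = ld_schedule()) {
  n <- 86400L * config$n_days
  t_end <- seq_len(n)                       # second i covers (i-1, i]
  zt <- zt_hours(t_end, schedule)
  zt_end <- ifelse(zt == 0, 24, zt)         # end exactly at lights-on -> 24
  rate <- phase_lookup(zt_end, config$phase_rates, "rate")

  ar <- config$anticipation_ramp
  if (ar$amplitude > 0) {
    on <- zt_end > ar$onset_zt & zt_end <= 24
    rate[on] <- rate[on] +
      ar$amplitude * (zt_end[on] - ar$onset_zt) / (24 - ar$onset_zt)
  }
  ep <- config$evening_peak
  if (ep$amplitude > 0) {
    lights_off <- schedule$photoperiod_h
    on <- zt_end > ep$onset_zt & zt_end <= lights_off
    rate[on] <- rate[on] +
      ep$amplitude * (zt_end[on] - ep$onset_zt) / (lights_off - ep$onset_zt)
  }
  st <- config$startle
  if (st$amplitude > 0 && st$duration_s > 0) {
    on <- zt > 0 & zt <= st$duration_s / 3600
    rate[on] <- rate[on] + st$amplitude
  }
  rate
}

fold_range <- function(z, lo, hi) {
  # reflecting boundaries: fold the free walk onto [lo, hi]
  r <- hi - lo
  w <- (z - lo) %% (2 * r)
  lo + ifelse(w <= r, w, 2 * r - w)
}

#' Simulate a bounded two-state random-walk trajectory
#'
#' A reflecting random walk at 1 Hz. While awake, each second's step has an
#' exponential length with mean equal to the expected intensity at that
#' second and a uniform heading. While asleep the fly jitters within
#' `micro_move_mm / 2` of the position where it fell asleep, so consecutive
#' sleeping positions are never more than `micro_move_mm` apart. The
#' wake/sleep state evolves by the configured two-state chain.
#'
#' @param config a [sim_config()].
#' @param geometry a [chamber_geometry()].
#' @param seed integer seed; defaults to `config$seed`.
#' @param schedule an [ld_schedule()].
#' @param intensity optional precomputed [simulate_intensity()] series.
#' @param fly_id,chamber_id identifiers for the output record.
#' @return a [trajectory()], with the true wake/sleep state in attribute
#'   `awake` (logical per second, ground truth for testing).
#' @export
simulate_trajectory <- function(config, geometry = chamber_geometry(),
                                seed = config$seed,
                                schedule = ld_schedule(),
                                intensity = NULL,
                                fly_id = "sim1", chamber_id = 1L) {
  if (is.null(intensity)) intensity <- simulate_intensity(config, schedule)
  n <- length(intensity)
  zt <- zt_hours(seq_len(n), schedule)
  zt_end <- ifelse(zt == 0, 24, zt)
  pf <- phase_lookup(zt_end, config$sleep_dynamics, "p_fall_asleep")
  pw <- phase_lookup(zt_end, config$sleep_dynamics, "p_wake")

  xmax <- if (is.null(config$confine_mm)) geometry$length_mm else
    min(config$confine_mm, geometry$length_mm)
  ymax <- geometry$width_mm

  set.seed(as.integer(seed))
  u <- stats::runif(n)
  awake <- logical(n)
  cur <- TRUE
  for (i in seq_len(n)) {
    cur <- if (cur) u[i] >= pf[i] else u[i] < pw[i]
    awake[i] <- cur
  }

  # vectorized within wake/sleep runs; sequential only across runs
  x <- numeric(n + 1L); y <- numeric(n + 1L)
  x[1] <- xmax / 2; y[1] <- ymax / 2
  r <- numeric(n); theta <- stats::runif(n, 0, 2 * pi)
  iw <- which(awake & intensity > 0)
  r[iw] <- stats::rexp(length(iw), rate = 1 / intensity[iw])
  is <- which(!awake)
  r[is] <- stats::runif(length(is), 0, config$micro_move_mm / 2)

  runs <- rle(awake)
  pos <- 1L
  for (k in seq_along(runs$lengths)) {
    idx <- pos:(pos + runs$lengths[k] - 1L)
    if (runs$values[k]) {
      x[idx + 1L] <- fold_range(x[pos] + cumsum(r[idx] * cos(theta[idx])), 0, xmax)
      y[idx + 1L] <- fold_range(y[pos] + cumsum(r[idx] * sin(theta[idx])), 0, ymax)
    } else {
      ax <- x[pos]; ay <- y[pos]   # anchor: position at sleep onset
      x[idx + 1L] <- fold_range(ax + r[idx] * cos(theta[idx]), 0, xmax)
      y[idx + 1L] <- fold_range(ay + r[idx] * sin(theta[idx]), 0, ymax)
    }
    pos <- pos + runs$lengths[k]
  }

  traj <- trajectory(t_s = 0:n, x_mm = x, y_mm = y,
                     detected = rep(TRUE, n + 1L),
                     fly_id = fly_id, chamber_id = chamber_id,
                     body_length_mm = config$body_length_mm,
                     geometry = geometry)
  attr(traj, "awake") <- c(TRUE, awake)
  traj
}

#' Simulate a labelled cohort of flies
#'
#' Per-fly seeds are derived deterministically from the master seed
#' (`seed + global fly index`), so a cohort is reproducible and extensible.
#'
#' @param group_configs named list of [sim_config()] objects, one per group.
#' @param n_flies_per_group flies per group (recycled across groups).
#' @param seed master seed.
#' @param geometry a [chamber_geometry()].
#' @param schedule an [ld_schedule()].
#' @return list of [trajectory()] objects; each carries attribute `group`,
#'   and the list carries a `manifest` attribute (fly_id, group, seed).
#' @export
simulate_cohort <- function(group_configs, n_flies_per_group = 30,
                            seed = 1L, geometry = chamber_geometry(),
                            schedule = ld_schedule()) {
  if (length(group_configs) == 0) stop("empty group list")
  if (is.null(names(group_configs)) || any(names(group_configs) == ""))
    names(group_configs) <- paste0("group", seq_along(group_configs))
  n_per <- rep_len(as.integer(n_flies_per_group), length(group_configs))
  if (any(n_per < 1)) stop("need at least one fly per group")

  out <- list()
  manifest <- list()
  fly_idx <- 0L
  for (g in seq_along(group_configs)) {
    cfg <- group_configs[[g]]
    gname <- names(group_configs)[g]
    intensity <- simulate_intensity(cfg, schedule)
    for (i in seq_len(n_per[g])) {
      fly_idx <- fly_idx + 1L
      fid <- sprintf("%s_f%02d", gname, i)
      fseed <- as.integer(seed) + fly_idx
      tr <- simulate_trajectory(cfg, geometry = geometry, seed = fseed,
                                schedule = schedule, intensity = intensity,
                                fly_id = fid, chamber_id = fly_idx)
      attr(tr, "group") <- gname
      out[[fid]] <- tr
      manifest[[fid]] <- data.frame(fly_id = fid, group = gname, seed = fseed,
                                    stringsAsFactors = FALSE)
    }
  }
  attr(out, "manifest") <- do.call(rbind, c(manifest, make.row.names = FALSE))
  out
}

#' Rendering parameters for synthetic video frames
#'
#' @param px_per_mm pixel calibration (should match the chamber geometry used
#'   for tracking).
#' @param frame_height_px,frame_width_px frame dimensions.
#' @param background_gray,fly_gray 8-bit gray levels; the fly is dark on a
#'   light background (backlit arena).
#' @param noise_sd Gaussian pixel noise, gray levels.
#' @param fly_radius_px rendered body radius in pixels.
#' @return an object of class `render_params`.
#' @export
render_params <- function(px_per_mm = 4, frame_height_px = 48,
                          frame_width_px = 336, background_gray = 200,
                          fly_gray = 30, noise_sd = 0, fly_radius_px = 3) {
  stopifnot(fly_gray < background_gray, noise_sd >= 0, fly_radius_px > 0,
            frame_height_px > 0, frame_width_px > 0, px_per_mm > 0)
  structure(list(px_per_mm = px_per_mm,
                 frame_height_px = as.integer(frame_height_px),
                 frame_width_px = as.integer(frame_width_px),
                 background_gray = background_gray, fly_gray = fly_gray,
                 noise_sd = noise_sd, fly_radius_px = fly_radius_px),
            class = "render_params")
}

#' Render a trajectory into synthetic grayscale frames
#'
#' One frame per trajectory sample: an anti-aliased dark disc at the mapped
#' pixel position over a light background, plus optional Gaussian noise,
#' quantized to 8 bits. Chamber mm map to frame pixels through
#' `geometry$px_per_mm` and `geometry$roi_px`.
#'
#' @param traj a [trajectory()] (undetected samples render as empty frames).
#' @param params a [render_params()].
#' @param geometry a [chamber_geometry()].
#' @param seed seed for the pixel noise.
#' @return a `frame_sequence`: list with `frames` (array h x w x n) and
#'   `t_s` (timestamps, = `traj$t_s`).
#' @export
render_frames <- function(traj, params = render_params(),
                          geometry = chamber_geometry(), seed = 1L) {
  h <- params$frame_height_px; w <- params$frame_width_px
  n <- nrow(traj)
  cx <- geometry$roi_px[1] + traj$x_mm * geometry$px_per_mm
  cy <- geometry$roi_px[2] + traj$y_mm * geometry$px_per_mm
  rad <- params$fly_radius_px
  ok <- !traj$detected |
    (cx >= rad & cx <= w - rad & cy >= rad & cy <= h - rad)
  if (!all(ok, na.rm = TRUE))
    stop("trajectory position maps outside the frame; enlarge frame or roi_px")

  set.seed(as.integer(seed))
  frames <- array(params$background_gray, dim = c(h, w, n))
  if (params$noise_sd > 0)
    frames <- frames + array(stats::rnorm(h * w * n, 0, params$noise_sd),
                             dim = c(h, w, n))
  half <- ceiling(rad) + 1L
  contrast <- params$fly_gray - params$background_gray
  for (i in seq_len(n)) {
    if (!traj$detected[i]) next
    rows <- max(1L, floor(cy[i]) - half):min(h, ceiling(cy[i]) + half)
    cols <- max(1L, floor(cx[i]) - half):min(w, ceiling(cx[i]) + half)
    # pixel (r, c) has center (c - 0.5, r - 0.5) in continuous px coordinates
    dx <- (cols - 0.5) - cx[i]
    dy <- (rows - 0.5) - cy[i]
    dist <- sqrt(outer(dy^2, dx^2, `+`))
    cov <- pmin(pmax(rad + 0.5 - dist, 0), 1)   # anti-aliased edge
    frames[rows, cols, i] <- frames[rows, cols, i] + contrast * cov
  }
  frames[frames < 0] <- 0
  frames[frames > 255] <- 255
  frames <- round(frames)
  structure(list(frames = frames, t_s = traj$t_s), class = "frame_sequence")
}

#' Ground truth for a synthetic fluorescence z-stack
#'
#' A bright axonal-terminal-like blob (hard-edged disc) over uniform
#' background, spread across slices so that the maximum-intensity projection
#' of the noise-free stack equals `blob_mean_intensity` at every blob pixel.
#'
#' @param n_slices number of z slices (about 10 in a typical acquisition).
#' @param dims `c(rows, cols)` of each slice.
#' @param blob_center_px `c(x, y)` center in pixels.
#' @param blob_radius_px blob radius in pixels.
#' @param blob_mean_intensity absolute intensity of blob pixels in the
#'   projection (a.u.).
#' @param background_intensity background level (a.u.).
#' @param noise_sd per-slice Gaussian noise (a.u.); SNR =
#'   `(blob_mean_intensity - background_intensity) / noise_sd`.
#' @return an object of class `stack_truth`.
#' @export
stack_truth <- function(n_slices = 10, dims = c(64, 64),
                        blob_center_px = dims / 2, blob_radius_px = 6,
                        blob_mean_intensity = 250, background_intensity = 50,
                        noise_sd = 0) {
  stopifnot(n_slices >= 1, blob_mean_intensity > background_intensity,
            noise_sd >= 0, blob_radius_px > 0)
  structure(list(n_slices = as.integer(n_slices), dims = as.integer(dims),
                 blob_center_px = blob_center_px,
                 blob_radius_px = blob_radius_px,
                 blob_mean_intensity = blob_mean_intensity,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd),
            class = "stack_truth")
}

#' Simulate a confocal-like image stack
#'
#' Slice k carries the blob at `background + contrast * 0.5^|k - k0|`
#' (k0 = middle slice), so the noise-free max projection reproduces
#' `blob_mean_intensity` exactly inside the blob and `background_intensity`
#' outside. Gaussian noise is added per slice.
#'
#' @param truth a [stack_truth()].
#' @param seed noise seed.
#' @return an `image_stack`: list of slice matrices with attribute `truth`.
#' @export
simulate_stack <- function(truth, seed = 1L) {
  h <- truth$dims[1]; w <- truth$dims[2]
  dx <- (seq_len(w) - 0.5) - truth$blob_center_px[1]
  dy <- (seq_len(h) - 0.5) - truth$blob_center_px[2]
  blob <- outer(dy^2, dx^2, `+`) <= truth$blob_radius_px^2
  contrast <- truth$blob_mean_intensity - truth$background_intensity
  k0 <- ceiling(truth$n_slices / 2)
  set.seed(as.integer(seed))
  slices <- lapply(seq_len(truth$n_slices), function(k) {
    sl <- matrix(truth$background_intensity, h, w)
    sl[blob] <- truth$background_intensity + contrast * 0.5^abs(k - k0)
    if (truth$noise_sd > 0)
      sl <- sl + matrix(stats::rnorm(h * w, 0, truth$noise_sd), h, w)
    sl
  })
  structure(slices, class = "image_stack", truth = truth)
}
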