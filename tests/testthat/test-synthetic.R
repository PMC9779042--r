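sched <- ld_schedule()

test_that("intensity series: degenerate config is constant, ramp hits its endpoint", {
  flat <- sim_config(n_days = 1)
  i1 <- simulate_intensity(flat, sched)
  expect_length(i1, 86400L)
  expect_true(all(i1 == 1.5))

  a <- 0.8
  cfg <- sim_config(n_days = 1,
                    anticipation_ramp = list(onset_zt = 21, amplitude = a))
  i2 <- simulate_intensity(cfg, sched)
  # second ending at ZT24 (lights-on) carries the full amplitude
  expect_equal(i2[86400] - i2[21 * 3600], a)
  # ramp is linear: halfway point carries half the amplitude
  expect_equal(i2[22.5 * 3600] - i2[21 * 3600], a / 2, tolerance = 1e-9)
})

test_that("intensity integral over ZT18-24 matches the analytic construction sum", {
  a <- 1.3; base_night <- 0.6; base_pre <- 0.9
  cfg <- sim_config(
    n_days = 2,
    phase_rates = data.frame(zt_from = c(0, 12, 21), zt_to = c(12, 21, 24),
                             rate = c(2, base_night, base_pre)),
    anticipation_ramp = list(onset_zt = 21, amplitude = a))
  intensity <- simulate_intensity(cfg, sched)
  got <- sum(intensity[(18 * 3600 + 1):(24 * 3600)])
  # analytic: 3 h of night baseline + 3 h of pre-dawn baseline + the ramp,
  # which contributes a * mean((k/10800) for k = 1..10800) * 10800
  ramp_sum <- a * sum(seq_len(10800)) / 10800
  expected <- base_night * 10800 + base_pre * 10800 + ramp_sum
  expect_equal(got, expected, tolerance = 1e-9)
})

test_that("overlapping or non-tiling phase tables are a configuration error", {
  expect_error(sim_config(phase_rates = data.frame(
    zt_from = c(0, 10), zt_to = c(12, 24), rate = c(1, 2))),
    "overlapping|non-tiling")
  expect_error(sim_config(phase_rates = data.frame(
    zt_from = c(0, 14), zt_to = c(12, 24), rate = c(1, 2))),
    "overlapping|non-tiling")
  expect_error(sim_config(sleep_dynamics = data.frame(
    zt_from = 0, zt_to = 24, p_fall_asleep = 1.2, p_wake = 0)),
    "probabilities")
})

test_that("absorbing sleep bounds displacement by the micro-move amplitude", {
  cfg <- sim_config(n_days = 1, micro_move_mm = 0.3,
                    sleep_dynamics = data.frame(zt_from = 0, zt_to = 24,
                                                p_fall_asleep = 1, p_wake = 0))
  tr <- simulate_trajectory(cfg, seed = 8,
                            intensity = simulate_intensity(cfg, sched)[1:2000])
  d <- displacement_series(tr)
  expect_true(all(d$d_mm <= 0.3 + 1e-12))
})

test_that("trajectories are deterministic in the seed and stay in the chamber", {
  cfg <- sim_config(n_days = 1)
  geom <- chamber_geometry()
  int <- simulate_intensity(cfg, sched)[1:3000]
  t1 <- simulate_trajectory(cfg, geom, seed = 5, intensity = int)
  t2 <- simulate_trajectory(cfg, geom, seed = 5, intensity = int)
  t3 <- simulate_trajectory(cfg, geom, seed = 6, intensity = int)
  expect_identical(t1$x_mm, t2$x_mm)
  expect_false(identical(t1$x_mm, t3$x_mm))
  expect_true(all(t1$x_mm >= 0 & t1$x_mm <= geom$length_mm))
  expect_true(all(t1$y_mm >= 0 & t1$y_mm <= geom$width_mm))
})

test_that("awake mean displacement tracks the configured rate within 5%", {
  rate <- 1.8
  cfg <- sim_config(n_days = 1,
                    phase_rates = data.frame(zt_from = 0, zt_to = 24,
                                             rate = rate),
                    sleep_dynamics = data.frame(zt_from = 0, zt_to = 24,
                                                p_fall_asleep = 0,
                                                p_wake = 1))
  geom <- chamber_geometry(length_mm = 300, width_mm = 300)  # negligible walls
  int <- simulate_intensity(cfg, sched)[1:10000]
  tr <- simulate_trajectory(cfg, geom, seed = 11, intensity = int)
  d <- displacement_series(tr)
  expect_true(all(attr(tr, "awake")))
  expect_lt(abs(mean(d$d_mm) - rate) / rate, 0.05)
})

test_that("path-length conservation holds to 1e-9", {
  cfg <- sim_preset("male", n_days = 1)
  tr <- simulate_trajectory(cfg, seed = 2,
                            intensity = simulate_intensity(cfg, sched)[1:5000])
  d <- displacement_series(tr)
  step_sum <- sum(sqrt(diff(tr$x_mm)^2 + diff(tr$y_mm)^2))
  expect_equal(total_distance(tr), step_sum, tolerance = 1e-9)
  expect_equal(sum(d$d_mm), step_sum, tolerance = 1e-9)
})

test_that("cohorts are reproducible, labelled, and respect group structure", {
  cfg <- sim_config(n_days = 1)
  expect_error(simulate_cohort(list(), 3), "empty")
  c1 <- simulate_cohort(list(g = cfg), n_flies_per_group = 1, seed = 3)
  expect_length(c1, 1L)
  manifest <- attr(c1, "manifest")
  expect_equal(manifest$seed, 4L)  # master + fly index

  # byte-identical export under a fixed master seed
  coh_a <- simulate_cohort(list(a = cfg), 2, seed = 9)
  coh_b <- simulate_cohort(list(a = cfg), 2, seed = 9)
  f1 <- tempfile(); f2 <- tempfile()
  write_trajectory(coh_a[[2]], f1)
  write_trajectory(coh_b[[2]], f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  unlink(c(f1, f2))
})

test_that("rendered frames reproduce position, constancy, and bounds errors", {
  geom <- chamber_geometry(px_per_mm = 4, roi_px = c(8, 8))
  rp <- render_params()
  still <- trajectory(t_s = 0:4, x_mm = rep(40, 5), y_mm = rep(4, 5),
                      geometry = geom)
  fs <- render_frames(still, rp, geom)
  expect_equal(dim(fs$frames)[3], 5L)
  expect_identical(fs$frames[, , 1], fs$frames[, , 5])

  # noiseless disc centroid lands within 0.5 px of the mapped position
  bg <- matrix(rp$background_gray, rp$frame_height_px, rp$frame_width_px)
  det <- detect_fly(fs$frames[, , 1], bg, geom)
  expect_true(det$found)
  expect_lt(abs(det$cx_px - (8 + 40 * 4)), 0.5)
  expect_lt(abs(det$cy_px - (8 + 4 * 4)), 0.5)

  far <- trajectory(t_s = 0:1, x_mm = c(79.9, 79.9), y_mm = c(4, 4),
                    geometry = geom)
  expect_error(render_frames(far, render_params(frame_width_px = 100), geom),
               "outside the frame")
})

test_that("synthetic stacks: exact projection recovery at zero noise", {
  tt <- stack_truth(noise_sd = 0)
  st <- simulate_stack(tt, seed = 1)
  q <- quantify_stack(st)
  expect_equal(q$roi_mean_intensity, tt$blob_mean_intensity)
  # background-only: constant projection cannot be thresholded
  flat_slices <- lapply(1:5, function(k) matrix(7, 16, 16))
  proj <- max_projection(structure(flat_slices, class = "image_stack"))
  expect_true(all(proj == 7))
  expect_error(threshold_roi(proj), "constant")
  # noisy recovery within 5%
  ttn <- stack_truth(noise_sd = 20)
  qn <- quantify_stack(simulate_stack(ttn, seed = 4))
  expect_lt(abs(qn$roi_mean_intensity - 250) / 250, 0.05)
})
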