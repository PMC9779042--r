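sched <- ld_schedule()

test_that("displacement series: constant, unit-step, conservation, validity", {
  still <- trajectory(t_s = 0:10, x_mm = rep(3, 11), y_mm = rep(2, 11))
  expect_true(all(displacement_series(still)$d_mm == 0))

  steps <- trajectory(t_s = 0:10, x_mm = 0:10, y_mm = rep(2, 11))
  expect_true(all(displacement_series(steps)$d_mm == 1))

  set.seed(1)
  x <- cumsum(rnorm(500)); y <- cumsum(rnorm(500))
  tr <- trajectory(t_s = seq_len(500) - 1L, x_mm = x - min(x),
                   y_mm = y - min(y))
  d <- displacement_series(tr)
  expect_equal(sum(d$d_mm), sum(sqrt(diff(x)^2 + diff(y)^2)),
               tolerance = 1e-9)

  # undetected endpoints invalidate the adjoining seconds
  det <- rep(TRUE, 500); det[100] <- FALSE
  tr2 <- trajectory(t_s = seq_len(500) - 1L, x_mm = x - min(x),
                    y_mm = y - min(y), detected = det)
  d2 <- displacement_series(tr2)
  expect_false(any(d2$valid[99:100]))
  expect_error(displacement_series(still[1, ]), "at least 2")
})

test_that("sleep scoring enforces the 5-minute rule and breaks on invalid samples", {
  # all-zero series: one bout spanning the record
  s <- make_series(rep(0, 3600))
  b <- score_sleep(s)
  expect_equal(nrow(b), 1L)
  expect_equal(b$duration_s, 3600L)

  # 299 s of quiescence flanked by movement: no bout
  s299 <- make_series(c(5, rep(0, 299), 5))
  expect_equal(nrow(score_sleep(s299)), 0L)
  s300 <- make_series(c(5, rep(0, 300), 5))
  expect_equal(nrow(score_sleep(s300)), 1L)

  # invalid seconds break a quiescent run
  v <- rep(TRUE, 700); v[350] <- FALSE
  sv <- make_series(rep(0, 700), valid = v)
  bb <- score_sleep(sv)
  expect_equal(nrow(bb), 2L)
  expect_equal(bb$duration_s, c(349L, 350L))
  expect_error(score_sleep(s, body_length_mm = 0), "positive")
})

test_that("sleep scorer equals the quadratic enumeration oracle on random series", {
  set.seed(77)
  for (rep_i in 1:25) {
    q <- runif(900) < 0.7
    d <- ifelse(q, runif(900, 0, 2.4), runif(900, 2.6, 9))
    got <- score_sleep(make_series(d))
    expect_bouts_equal(got, oracle_sleep_quadratic(q, 300L))
  }
})

test_that("sleep summary splits bouts at the light transition", {
  # bout ZT11:50 - ZT12:10 -> 10 min day + 10 min night
  bout <- structure(data.frame(start_s = 11 * 3600 + 50 * 60,
                               end_s = 12 * 3600 + 10 * 60,
                               duration_s = 1200),
                    class = c("sleep_record", "data.frame"))
  ss <- sleep_summary(bout, sched)
  expect_equal(ss$total_daytime_min, 10)
  expect_equal(ss$total_nighttime_min, 10)
  expect_equal(ss$by_day$bout_count, 1L)

  empty <- structure(data.frame(start_s = numeric(), end_s = numeric(),
                                duration_s = numeric()),
                     class = c("sleep_record", "data.frame"))
  se <- sleep_summary(empty, sched)
  expect_equal(se$total_daytime_min, 0)
  expect_equal(se$total_nighttime_min, 0)
})

test_that("siesta-configured flies sleep more by day than night only when built to", {
  cfg_night <- sim_preset("male", n_days = 1)   # consolidated night rest
  tr <- simulate_trajectory(cfg_night, seed = 13)
  ss <- sleep_summary(score_sleep(displacement_series(tr)), sched)
  expect_gt(ss$total_nighttime_min, ss$total_daytime_min)
  # generator ground truth agrees: more asleep seconds at night
  awake <- attr(tr, "awake")[-1]
  zt <- zt_hours(seq_len(86400), sched)
  expect_gt(sum(!awake[zt > 12 | zt == 0]), sum(!awake[zt <= 12 & zt > 0]))
})

test_that("MAI analytics: half-window ratio, concentration, crafted 0.75 profile", {
  n <- 86400L
  zt <- zt_hours(seq_len(n), sched)
  zte <- ifelse(zt == 0, 24, zt)

  uniform <- make_series(rep(2, n))
  expect_equal(morning_anticipation_index(uniform, sched, 1)$mai, 0.5)

  late <- make_series(ifelse(zte > 21, 3, 0))
  expect_equal(morning_anticipation_index(late, sched, 1)$mai, 1.0)

  crafted <- make_series(ifelse(zte > 21, 3, ifelse(zte > 18, 1, 0)))
  expect_equal(morning_anticipation_index(crafted, sched, 1)$mai, 0.75)

  # rescale invariance
  scaled <- make_series(crafted$d_mm * 17.3)
  expect_equal(morning_anticipation_index(scaled, sched, 1)$mai, 0.75)

  # zero denominator and incompleteness are undefined, not errors
  none <- make_series(ifelse(zte > 18, 0, 1))
  expect_false(morning_anticipation_index(none, sched, 1)$defined)
  short <- make_series(rep(1, 1000))
  expect_false(morning_anticipation_index(short, sched, 1)$defined)
  mostly_invalid <- make_series(rep(1, n),
                                valid = zte < 22 | zte > 23.9)
  expect_false(morning_anticipation_index(mostly_invalid, sched, 1)$defined)
})

test_that("three-day MAI mean uses the first three complete days", {
  expect_equal(mai_mean(c(0.5, 0.5, 0.5, 0.9)), 0.5)
  expect_equal(mai_mean(c(0.2, 0.4, 0.6)), 0.4)
  # an undefined day is skipped, later complete days fill in
  expect_equal(mai_mean(c(NA, 0.2, 0.4, 0.6)), 0.4)
  expect_error(mai_mean(c(NA, 0.3, 0.4)), "complete days")
})

test_that("average profile: identical flies have zero SEM, constant rate is flat", {
  n <- 86400L
  s1 <- make_series(rep(1.2, n))
  prof <- average_activity_profile(list(s1, s1, s1), 30, sched)
  expect_true(all(prof$sem == 0))
  expect_true(all(abs(prof$mean - 1.2 * 1800) < 1e-9))
  expect_equal(nrow(prof), 48L)

  # two flies with known profiles average by hand
  s2 <- make_series(rep(2.4, n))
  prof2 <- average_activity_profile(list(s1, s2), 30, sched)
  expect_true(all(abs(prof2$mean - 1.8 * 1800) < 1e-9))
})
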