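# Synthetic cohort generator: determinism, configured distributions,
# ground-truth plumbing, inverse-IMU consistency.

test_that("generation is bit-identical for a fixed seed", {
  cfg <- quick_walk_config()
  d1 <- simulate_subject_day(cfg, n_events = 1, seed = 13)
  d2 <- simulate_subject_day(cfg, n_events = 1, seed = 13)
  expect_identical(d1$strides, d2$strides)
  expect_identical(d1$trunk, d2$trunk)
  expect_identical(d1$events, d2$events)
  d3 <- simulate_subject_day(cfg, n_events = 1, seed = 14)
  expect_false(identical(d1$strides, d3$strides))
  # cohort-level determinism (events tier keeps this cheap)
  cfgc <- lob_gen_config(day_length_h = 2)
  c1 <- simulate_cohort(cfgc, seed = 2, tier = "events")
  c2 <- simulate_cohort(cfgc, seed = 2, tier = "events")
  expect_identical(c1$events, c2$events)
})

test_that("stride lengths are distributed around the configured mean", {
  cfg <- lob_gen_config(day_length_h = 1400 / 3600,
                        walk_bout_range_s = c(100, 120),
                        rest_bout_range_s = c(3, 5),
                        stride_length_between_sd_m = 0, # isolate within-subject
                        stride_time_between_sd_s = 0)
  day <- simulate_subject_day(cfg, n_events = 0, seed = 17)
  len <- day$strides$length_m
  expect_gt(length(len), 1000)
  # sample mean within 2 effective SEs (AR(1) inflates the naive SE)
  se <- sd(len) / sqrt(length(len)) *
    sqrt((1 + cfg$ar1) / (1 - cfg$ar1))
  expect_lt(abs(mean(len) - cfg$stride_length_mean_m), 2 * se)
  # stride times likewise
  dur <- day$strides$duration_s
  se_t <- sd(dur) / sqrt(length(dur)) * sqrt((1 + cfg$ar1) / (1 - cfg$ar1))
  expect_lt(abs(mean(dur) - cfg$stride_time_mean_s), 2 * se_t)
})

test_that("default cohort reproduces the configured bookkeeping", {
  co <- simulate_cohort(lob_gen_config(), seed = 3, tier = "events")
  expect_length(co$days, 31)
  expect_equal(nrow(co$events), 62)
  per_subject <- table(co$events$subject)[paste0("S", 1:8)]
  expect_equal(unname(as.integer(per_subject)), c(23, 8, 1, 2, 18, 3, 2, 5))
  # every day carries at least one event (event-days by construction)
  event_days <- unique(co$events[c("subject", "day")])
  expect_equal(nrow(event_days), 31)
  # all event durations < 7 s, none non-positive
  d <- co$events$t_end_s - co$events$t_start_s
  expect_true(all(d > 0 & d < 7))
  # events respect the 30 s minimum gap within a day
  by_day <- split(co$events, paste(co$events$subject, co$events$day))
  for (e in by_day) {
    if (nrow(e) < 2) next
    e <- e[order(e$t_start_s), ]
    expect_true(all(e$t_start_s[-1] - e$t_end_s[-nrow(e)] >= 30))
  }
})

test_that("halving day length leaves event counts unchanged", {
  cfg <- lob_gen_config(day_length_h = 4)
  cfg2 <- cfg
  cfg2$day_length_h <- 2
  c1 <- simulate_cohort(cfg, seed = 4, tier = "events")
  c2 <- simulate_cohort(cfg2, seed = 4, tier = "events")
  expect_equal(nrow(c1$events), nrow(c2$events))
  expect_equal(table(c1$events$subject), table(c2$events$subject))
})

test_that("scaled config preserves at least one event per subject", {
  cfg <- scale_gen_config(lob_gen_config(), day_length_h = 1)
  expect_equal(cfg$day_length_h, 1)
  expect_true(all(cfg$events_per_subject >= 1))
  expect_equal(cfg$days_per_subject, lob_gen_config()$days_per_subject)
  expect_equal(cfg$events_per_subject,
               pmax(1L, as.integer(round(c(23, 8, 1, 2, 18, 3, 2, 5) / 11.4))))
})

test_that("zero events yield all-zero window labels downstream", {
  day <- simulate_subject_day(quick_walk_config(), n_events = 0, seed = 19)
  f <- day_features(day)
  expect_true(all(f$meta$label == 0))
})

test_that("window labels equal brute-force interval intersection", {
  cfg <- quick_walk_config(day_length_s = 400)
  day <- simulate_subject_day(cfg, n_events = 3, seed = 23)
  f <- day_features(day)
  brute <- vapply(f$meta$start_s, function(s)
    any(s < day$events$t_end_s & s + 10 > day$events$t_start_s), logical(1))
  expect_equal(f$meta$label, as.integer(brute))
  expect_gt(sum(f$meta$label), 0)
})

test_that("events shorten strides and inflate trunk velocity range", {
  cfg <- lob_gen_config(day_length_h = 0.5, walk_bout_range_s = c(60, 120),
                        rest_bout_range_s = c(10, 20), event_min_gap_s = 20)
  sl_ev <- sl_gait <- twr_ev <- twr_gait <- NULL
  for (seed in 1:6) {
    day <- simulate_subject_day(cfg, n_events = 4, seed = 100 + seed)
    f <- day_features(day)
    gait <- f$x[, "IS_GAIT"] == 1
    ev <- f$meta$label == 1
    sl_ev <- c(sl_ev, f$x[gait & ev, "SL_MEAN"])
    sl_gait <- c(sl_gait, f$x[gait & !ev, "SL_MEAN"])
    twr_ev <- c(twr_ev, f$x[gait & ev, "TW_RANGE_PITCH"])
    twr_gait <- c(twr_gait, f$x[gait & !ev, "TW_RANGE_PITCH"])
  }
  expect_lt(mean(sl_ev), mean(sl_gait))
  expect_gt(mean(twr_ev), mean(twr_gait))
  expect_lt(t.test(sl_ev, sl_gait)$p.value, 1e-4)
  expect_lt(t.test(twr_ev, twr_gait)$p.value, 1e-4)
})

test_that("noise-free stationary inverse IMU equals gravity and zero rates", {
  cfg <- quick_walk_config(day_length_s = 12,
                           walk_bout_range_s = c(5, 6),
                           rest_bout_range_s = c(1, 2))
  day <- simulate_subject_day(cfg, n_events = 0, seed = 29)
  day$strides <- day$strides[0, ] # remove gait: everything is at rest
  day$trunk$pitch[] <- 0; day$trunk$roll[] <- 0
  day$trunk$wpitch[] <- 0; day$trunk$wroll[] <- 0
  rec <- inverse_imu_from_day(day, noise_accel = 0, noise_gyro = 0,
                              accel_bias = 0, gyro_bias = 0, seed = 1)
  for (sensor in c("left_foot", "right_foot", "trunk")) {
    acc <- as.matrix(rec$data[paste0(sensor, c("_acc_x", "_acc_y", "_acc_z"))])
    gyr <- as.matrix(rec$data[paste0(sensor, c("_gyr_x", "_gyr_y", "_gyr_z"))])
    expect_equal(max(abs(acc[, 1:2])), 0)
    expect_true(all(abs(acc[, 3] - 9.80665) < 1e-12))
    expect_equal(max(abs(gyr)), 0)
  }
})

test_that("doubling stride length doubles recovered walked distance", {
  base <- quick_walk_config(day_length_s = 80,
                            walk_bout_range_s = c(62, 68),
                            rest_bout_range_s = c(2, 4),
                            stride_length_within_sd_m = 0.02)
  dist_recovered <- function(sl) {
    cfg <- base
    cfg$stride_length_mean_m <- sl
    cfg$stride_length_between_sd_m <- 0
    day <- simulate_subject_day(cfg, n_events = 0, seed = 37)
    rec <- inverse_imu_from_day(day, seed = 38)
    d <- recording_to_day(rec)
    sum(d$strides$length_m)
  }
  d1 <- dist_recovered(0.6)
  d2 <- dist_recovered(1.2)
  expect_equal(d2 / d1, 2, tolerance = 0.05)
})

test_that("cohort provenance round-trips the generator settings", {
  cfg <- lob_gen_config(day_length_h = 2)
  co <- simulate_cohort(cfg, seed = 8, tier = "events")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_cohort_provenance(co, path)
  back <- yaml::read_yaml(path)
  expect_equal(back$seed, 8)
  expect_equal(back$config$day_length_h, 2)
  expect_equal(back$config$events_per_subject, c(23, 8, 1, 2, 18, 3, 2, 5))
  expect_match(back$note, "stand-ins")
})
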