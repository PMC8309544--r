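# Windowing, gait indicator, the 32-feature descriptor, labeling.

test_that("window counts follow the discard-partial rule", {
  expect_equal(nrow(make_windows(60)), 26)
  expect_equal(nrow(make_windows(10)), 1)
  expect_warning(w <- make_windows(9), "shorter than one window")
  expect_equal(nrow(w), 0)
  w <- make_windows(60)
  expect_equal(w$start_s, seq(0, 50, by = 2))
})

test_that("gait indicator applies the five-strides-over-0.1m rule", {
  expect_equal(compute_gait_indicator(rep(0.5, 5)), 1)
  expect_equal(compute_gait_indicator(rep(1.0, 4)), 0)
  expect_equal(compute_gait_indicator(rep(0.05, 6)), 0)
  expect_equal(compute_gait_indicator(numeric()), 0)
  # boundary: strides of exactly 0.1 m do not count
  expect_equal(compute_gait_indicator(rep(0.1, 9)), 0)
})

make_day <- function(strides, duration_s = 20, trunk_rate = 8,
                     events = data.frame(t_start_s = numeric(),
                                         t_end_s = numeric())) {
  n <- round(duration_s * trunk_rate)
  structure(list(subject_id = "S1", day_id = "D01", duration_s = duration_s,
                 strides = strides, events = events,
                 trunk = list(rate_hz = trunk_rate, pitch = numeric(n),
                              roll = numeric(n), wpitch = numeric(n),
                              wroll = numeric(n))),
            class = "lob_day")
}

stride_row <- function(t_mid, len, dur = 1, foot = "R", psv = 3) {
  data.frame(foot = foot, t_start = t_mid - dur / 2, t_end = t_mid + dur / 2,
             t_mid = t_mid, length_m = len, duration_s = dur,
             peak_swing_vel = psv, mean_vel = len / dur, max_vel = psv)
}

test_that("stride statistics match direct computation", {
  s <- rbind(stride_row(2, 0.5, dur = 1.0), stride_row(4, 0.6, dur = 1.1),
             stride_row(6, 0.7, dur = 1.2))
  f <- day_features(make_day(s, duration_s = 10))
  x <- f$x[1, ]
  expect_equal(unname(x["SL_MEAN"]), 0.6)
  expect_equal(unname(x["SL_MAX"]), 0.7)
  expect_equal(unname(x["SL_MIN"]), 0.5)
  expect_equal(unname(x["SL_MEDIAN"]), 0.6)
  expect_equal(unname(x["GAIT_DISTANCE"]), 1.8)
  expect_equal(unname(x["SL_RMS"]), sqrt(mean(c(.5, .6, .7)^2)))
  expect_equal(unname(x["SL_VAR"]), var(c(.5, .6, .7)))
  expect_equal(unname(x["IS_GAIT"]), 0) # only 3 strides
  # linear-interpolation quartile convention for the IQR
  expect_equal(unname(x["ST_IQR"]),
               quantile(c(1, 1.1, 1.2), .75, type = 7, names = FALSE) -
                 quantile(c(1, 1.1, 1.2), .25, type = 7, names = FALSE))
  expect_equal(unname(x["ST_IQR"]), 0.1)
})

test_that("windows without strides get zero stride features but live trunk features", {
  day <- make_day(stride_row(2, 0.5)[0, ], duration_s = 10)
  day$trunk$pitch <- rep(3, 80)
  f <- day_features(day)
  x <- f$x[1, ]
  expect_true(all(x[grep("^(SL|ST|RF|LF|RS|LS|GAIT|IS)", names(x))] == 0))
  expect_equal(unname(x["TRUNK_RMS_PITCH"]), 3)
  expect_true(all(is.finite(f$x)))
})

test_that("per-foot velocity features split by foot side", {
  s <- rbind(stride_row(2, 0.6, foot = "R", psv = 3),
             stride_row(3, 0.6, foot = "R", psv = 4),
             stride_row(4, 0.6, foot = "L", psv = 5))
  f <- day_features(make_day(s, duration_s = 10))
  x <- f$x[1, ]
  expect_equal(unname(x["RS_MAX_VEL"]), 4)
  expect_equal(unname(x["RS_MIN_VEL"]), 3)
  expect_equal(unname(x["RS_MEAN_VEL"]), 3.5)
  expect_equal(unname(x["LS_MAX_VEL"]), 5)
  expect_equal(unname(x["RF_MAX_VEL"]), 4)
  expect_equal(unname(x["LF_MEAN_VEL"]), 0.6)
})

test_that("event overlap labels exactly the windows intersecting the event", {
  w <- make_windows(68)
  lab <- label_windows(w$start_s, 10, data.frame(t_start_s = 15, t_end_s = 17))
  expect_equal(w$start_s[lab == 1], c(6, 8, 10, 12, 14, 16))
  expect_equal(label_windows(w$start_s, 10,
                             data.frame(t_start_s = numeric(),
                                        t_end_s = numeric())),
               integer(nrow(w)))
})

test_that("every short event is fully contained in at least one window", {
  # an event of duration <= 8 s ending before the last window's end is
  # always fully inside some window of the 10 s / 2 s grid
  set.seed(91)
  dur <- 120
  w <- make_windows(dur)
  last_end <- max(w$start_s) + 10
  for (i in 1:200) {
    d <- runif(1, 0.2, 8)
    a <- runif(1, 0, last_end - d)
    contained <- any(w$start_s <= a & w$start_s + 10 >= a + d)
    expect_true(contained)
  }
  # and a 3 s event in particular
  d <- 3
  for (a in seq(0, last_end - d, by = 0.37))
    expect_true(any(w$start_s <= a & w$start_s + 10 >= a + d))
})

test_that("labels are monotone under event extension", {
  set.seed(92)
  w <- make_windows(100)
  for (i in 1:30) {
    a <- runif(1, 0, 80); b <- a + runif(1, 0.5, 5)
    lab1 <- label_windows(w$start_s, 10, data.frame(t_start_s = a, t_end_s = b))
    lab2 <- label_windows(w$start_s, 10,
                          data.frame(t_start_s = a - 1, t_end_s = b + 2))
    expect_true(all(lab2 >= lab1))
  }
})

test_that("feature names, groups and standardization are consistent", {
  nm <- lob_feature_names()
  expect_length(nm, 32)
  g <- lob_feature_groups()
  expect_length(g, 6)
  expect_setequal(unlist(g), nm)
  expect_equal(sum(lengths(g)), 32)
  expect_equal(lengths(g)[["foot_velocity"]], 10L)
  expect_equal(lengths(g)[["trunk"]], 6L)
  # standardization from training subjects only
  cfg <- quick_walk_config()
  co <- simulate_cohort(lob_gen_config(n_subjects = 2,
                                       days_per_subject = c(1, 1),
                                       events_per_subject = c(0, 0),
                                       day_length_h = 60 / 3600,
                                       walk_bout_range_s = c(40, 50),
                                       rest_bout_range_s = c(2, 4)),
                        seed = 5)
  feat <- cohort_features(co)
  feat$x[feat$meta$subject == "S2", ] <- feat$x[feat$meta$subject == "S2", ] + 100
  std1 <- feature_standardizer(feat, "S1")
  std12 <- feature_standardizer(feat, c("S1", "S2"))
  expect_false(isTRUE(all.equal(std1$center, std12$center)))
  only_s1 <- feat$x[feat$meta$subject == "S1", , drop = FALSE]
  expect_equal(unname(std1$center), unname(colMeans(only_s1)))
})

test_that("feature matrix export writes one row per window", {
  co <- simulate_cohort(lob_gen_config(n_subjects = 2,
                                       days_per_subject = c(1, 1),
                                       events_per_subject = c(1, 0),
                                       day_length_h = 100 / 3600,
                                       walk_bout_range_s = c(60, 70),
                                       rest_bout_range_s = c(3, 5)),
                        seed = 6)
  feat <- cohort_features(co)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(feat, path)
  d <- utils::read.csv(path)
  expect_equal(nrow(d), nrow(feat$meta))
  expect_equal(ncol(d), 4 + 32 + 1)
  expect_equal(sum(d$label), sum(feat$meta$label))
})
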