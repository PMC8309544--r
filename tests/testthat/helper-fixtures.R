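# Shared fixtures and independent brute-force oracles.

# a recording in which all sensors are at rest (accel = gravity on z)
stationary_recording <- function(duration_s = 2, sample_rate = 128,
                                 subject = "S1", day = "D01") {
  n <- round(duration_s * sample_rate)
  d <- data.frame(t_s = (seq_len(n) - 1) / sample_rate)
  for (ch in imu_channel_names())
    d[[ch]] <- if (grepl("acc_z$", ch)) rep(9.80665, n) else rep(0, n)
  imu_recording(subject, day, d, sample_rate = sample_rate)
}

random_recording <- function(duration_s = 1, sample_rate = 128,
                             subject = "S1", day = "D01") {
  n <- round(duration_s * sample_rate)
  d <- data.frame(t_s = (seq_len(n) - 1) / sample_rate)
  for (ch in imu_channel_names()) d[[ch]] <- round(rnorm(n), 6)
  imu_recording(subject, day, d, sample_rate = sample_rate)
}

# six-channel foot matrix helpers (acc x,y,z then gyr x,y,z)
foot_channels <- function(rec, side = c("right", "left")) {
  side <- match.arg(side)
  sensor <- paste0(side, "_foot")
  as.matrix(rec$data[paste(sensor, rep(c("acc", "gyr"), each = 3),
                           rep(c("x", "y", "z"), 2), sep = "_")])
}

trunk_channels <- function(rec) {
  as.matrix(rec$data[paste("trunk", rep(c("acc", "gyr"), each = 3),
                           rep(c("x", "y", "z"), 2), sep = "_")])
}

# interval-union oracle: merge half-open intervals by sweeping endpoints
oracle_merge_intervals <- function(s, e) {
  o <- order(s)
  s <- s[o]; e <- e[o]
  out_s <- s[1]; out_e <- e[1]; res <- NULL
  for (i in seq_along(s)[-1]) {
    if (s[i] <= out_e) out_e <- max(out_e, e[i])
    else { res <- rbind(res, c(out_s, out_e)); out_s <- s[i]; out_e <- e[i] }
  }
  rbind(res, c(out_s, out_e))
}

# brute-force event-level metrics by direct interval enumeration
oracle_event_metrics <- function(scores, starts, window_s, ev_start, ev_end,
                                 threshold = 0.5) {
  pred <- scores >= threshold
  overlaps <- function(ws, a, b) ws < b & ws + window_s > a
  detected <- vapply(seq_along(ev_start), function(i)
    any(pred & overlaps(starts, ev_start[i], ev_end[i])), logical(1))
  win_hit <- rep(FALSE, length(starts))
  for (i in seq_along(ev_start))
    win_hit <- win_hit | overlaps(starts, ev_start[i], ev_end[i])
  list(reduction = 100 * mean(!pred),
       sensitivity = if (length(ev_start)) 100 * mean(detected) else NA_real_,
       precision = if (sum(pred) > 0) 100 * sum(pred & win_hit) / sum(pred) else 0)
}

# a small walking day for pipeline tests (short, mostly walking)
quick_walk_config <- function(day_length_s = 120,
                              walk_bout_range_s = c(55, 65),
                              rest_bout_range_s = c(3, 6),
                              event_min_gap_s = 10, ...) {
  lob_gen_config(day_length_h = day_length_s / 3600,
                 walk_bout_range_s = walk_bout_range_s,
                 rest_bout_range_s = rest_bout_range_s,
                 event_min_gap_s = event_min_gap_s, ...)
}
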