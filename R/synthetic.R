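# Synthetic cohort generator.
#
# Tier 1 (fast): per subject-day stride tables and trunk angle/rate streams
# with ground-truth LOB events, emulating multi-hour real-world recording
# days in which walking alternates with other activities and rare short
# balance perturbations occur during gait (shortened strides, a burst of
# trunk rotation). Tier 2: analytic inverse-IMU synthesis of raw 128 Hz
# recordings from the tier-1 streams, used to exercise the ZUPT kinematics.

#' Generator configuration
#'
#' Defaults emulate the in-scope cohort regime: 8 subjects whose per-subject
#' event-day and event counts total 31 event-days and 62 events; day lengths
#' drawn from normal(11.4 h, 1.8 h) truncated to 6-16 h; events mostly 1-3 s
#' and never 7 s or longer; events placed strictly inside walking bouts with
#' a 30 s minimum gap. During an event and the following two strides, stride
#' length is halved, trunk angular-velocity range is quadrupled and trunk
#' sway RMS doubled (compensatory trunk rotation with shortened strides).
#'
#' @param n_subjects number of subjects.
#' @param days_per_subject,events_per_subject integer vectors, one entry per
#'   subject.
#' @param day_length_mean_h,day_length_sd_h,day_length_range_h truncated
#'   normal for day length (hours).
#' @param day_length_h fixed day length in hours overriding the draw (used
#'   by scaled-down cohorts); `NULL` to sample.
#' @param walking_fraction target fraction of the day spent walking.
#' @param walk_bout_range_s uniform range of walking-bout durations, s.
#' @param rest_bout_range_s uniform range of non-walking bouts, s; `NULL`
#'   derives it from `walking_fraction`.
#' @param stride_time_mean_s,stride_time_between_sd_s,stride_time_within_sd_s
#'   stride-time model: subject baseline ~ normal(mean, between-SD), strides
#'   fluctuate around the baseline with the within-SD and AR(1) correlation.
#' @param stride_length_mean_m,stride_length_between_sd_m,stride_length_within_sd_m
#'   stride-length model, same structure.
#' @param ar1 lag-1 autocorrelation of within-bout stride fluctuations.
#' @param trunk_rms_deg baseline trunk sway RMS during gait, degrees.
#' @param trunk_rate_hz sampling rate of the tier-1 trunk streams.
#' @param event_frac_short fraction of events with short durations.
#' @param event_short_range_s,event_long_range_s uniform duration ranges, s.
#' @param event_min_gap_s minimum gap between events in a day, s.
#' @param effect_stride_length multiplier on stride length during an event
#'   (and `effect_carry_strides` strides after it).
#' @param effect_trunk_velocity multiplier on the trunk angular-velocity
#'   range during an event.
#' @param effect_trunk_angle multiplier on trunk sway RMS during an event.
#' @param effect_carry_strides how many stride times the effect persists
#'   past the event end.
#' @param stance_duty fraction of the stride cycle the foot is on the
#'   ground (used by stance-fraction ground truth and tier-2 synthesis).
#' @return list of class `lob_gen_config`.
#' @export
lob_gen_config <- function(n_subjects = 8,
                           days_per_subject = c(10, 5, 1, 1, 5, 3, 2, 4),
                           events_per_subject = c(23, 8, 1, 2, 18, 3, 2, 5),
                           day_length_mean_h = 11.4, day_length_sd_h = 1.8,
                           day_length_range_h = c(6, 16),
                           day_length_h = NULL,
                           walking_fraction = 0.12,
                           walk_bout_range_s = c(30, 120),
                           rest_bout_range_s = NULL,
                           stride_time_mean_s = 1.1,
                           stride_time_between_sd_s = 0.05,
                           stride_time_within_sd_s = 0.08,
                           stride_length_mean_m = 1.25,
                           stride_length_between_sd_m = 0.08,
                           stride_length_within_sd_m = 0.10,
                           ar1 = 0.3,
                           trunk_rms_deg = 2, trunk_rate_hz = 8,
                           event_frac_short = 0.8,
                           event_short_range_s = c(1, 3),
                           event_long_range_s = c(3, 7),
                           event_min_gap_s = 30,
                           effect_stride_length = 0.5,
                           effect_trunk_velocity = 4,
                           effect_trunk_angle = 2,
                           effect_carry_strides = 2,
                           stance_duty = 0.6) {
  stopifnot(length(days_per_subject) == n_subjects,
            length(events_per_subject) == n_subjects,
            all(events_per_subject >= 0), walking_fraction > 0,
            walking_fraction < 1)
  cfg <- as.list(environment())
  if (is.null(cfg$rest_bout_range_s)) {
    mean_walk <- mean(walk_bout_range_s)
    mean_rest <- mean_walk * (1 - walking_fraction) / walking_fraction
    cfg$rest_bout_range_s <- mean_rest * c(0.4, 1.6)
  }
  structure(cfg, class = "lob_gen_config")
}

#' Rescale a configuration to a shorter day
#'
#' Sets a fixed day length and scales per-subject event counts by the
#' day-length ratio so the class-imbalance regime is approximately
#' preserved, flooring at one event per subject so every held-out subject
#' remains evaluable at the event level. Day counts are unchanged.
#'
#' @param cfg a [lob_gen_config()].
#' @param day_length_h new fixed day length, hours.
#' @return modified config.
#' @export
scale_gen_config <- function(cfg, day_length_h = 1) {
  sc <- day_length_h / cfg$day_length_mean_h
  cfg$day_length_h <- day_length_h
  cfg$events_per_subject <- pmax(1L, as.integer(round(cfg$events_per_subject * sc)))
  cfg
}

sample_day_length_s <- function(cfg) {
  if (!is.null(cfg$day_length_h)) return(cfg$day_length_h * 3600)
  for (i in 1:1000) {
    x <- stats::rnorm(1, cfg$day_length_mean_h, cfg$day_length_sd_h)
    if (x >= cfg$day_length_range_h[1] && x <= cfg$day_length_range_h[2])
      return(x * 3600)
  }
  cfg$day_length_mean_h * 3600
}

# alternating rest/walk bouts; returns matrix of walk bouts (start, end)
sample_bouts <- function(duration_s, cfg) {
  wl <- cfg$walk_bout_range_s; rl <- cfg$rest_bout_range_s
  starts <- ends <- numeric()
  t <- stats::runif(1, rl[1], rl[2])
  repeat {
    w <- stats::runif(1, wl[1], wl[2])
    if (t + w > duration_s - 5) break
    starts <- c(starts, t); ends <- c(ends, t + w)
    t <- t + w + stats::runif(1, rl[1], rl[2])
  }
  if (length(starts) == 0 && duration_s > wl[1] + 10) {
    w <- min(wl[2], duration_s - 10)
    starts <- (duration_s - w) / 2; ends <- starts + w
  }
  cbind(start = starts, end = ends)
}

sample_event_durations <- function(n, cfg) {
  short <- stats::runif(n) < cfg$event_frac_short
  ifelse(short,
         stats::runif(n, cfg$event_short_range_s[1], cfg$event_short_range_s[2]),
         stats::runif(n, cfg$event_long_range_s[1], cfg$event_long_range_s[2]))
}

place_events <- function(bouts, durations, cfg, margin = 1.5) {
  acc <- NULL
  for (d in durations) {
    room <- pmax(0, bouts[, "end"] - bouts[, "start"] - d - 2 * margin)
    if (all(room == 0)) stop("insufficient walking time to place events")
    ok <- FALSE
    for (try in 1:500) {
      j <- sample.int(nrow(bouts), 1, prob = room)
      t0 <- stats::runif(1, bouts[j, "start"] + margin,
                         bouts[j, "end"] - d - margin)
      if (is.null(acc) ||
          all(t0 >= acc[, 2] + cfg$event_min_gap_s |
              t0 + d <= acc[, 1] - cfg$event_min_gap_s)) {
        acc <- rbind(acc, c(t0, t0 + d)); ok <- TRUE; break
      }
    }
    if (!ok) stop("insufficient walking time to place events")
  }
  acc <- acc[order(acc[, 1]), , drop = FALSE]
  data.frame(t_start_s = acc[, 1], t_end_s = acc[, 2])
}

in_extended_event <- function(t, events, carry_s) {
  hit <- rep(FALSE, length(t))
  for (i in seq_len(NROW(events)))
    hit <- hit | (t >= events$t_start_s[i] & t < events$t_end_s[i] + carry_s)
  hit
}

# AR(1) deviations: rho-correlated, stationary marginal sd
ar1_series <- function(n, rho, sd) {
  if (n == 0) return(numeric())
  e <- numeric(n)
  e[1] <- stats::rnorm(1, 0, sd)
  if (n > 1) for (i in 2:n)
    e[i] <- rho * e[i - 1] + sqrt(1 - rho^2) * stats::rnorm(1, 0, sd)
  e
}

gen_foot_strides <- function(bouts, foot, baseline, events_ext, cfg) {
  offset <- 0.1 + if (foot == "L") baseline$st / 2 else 0
  out <- NULL
  for (j in seq_len(nrow(bouts))) {
    bs <- bouts[j, "start"]; be <- bouts[j, "end"]
    nmax <- ceiling((be - bs) / 0.4)
    durs <- pmax(0.4, baseline$st + ar1_series(nmax, cfg$ar1, cfg$stride_time_within_sd_s))
    lens <- pmax(0.1, baseline$sl + ar1_series(nmax, cfg$ar1, cfg$stride_length_within_sd_m))
    times <- bs + offset + cumsum(c(0, durs))
    keep <- which(times[-1] <= be) # stride i spans times[i]..times[i+1]
    if (length(keep) == 0) next
    st <- data.frame(foot = foot, t_start = times[keep],
                     t_end = times[keep + 1],
                     t_mid = (times[keep] + times[keep + 1]) / 2,
                     length_m = lens[keep], duration_s = durs[keep])
    out <- rbind(out, st)
  }
  if (is.null(out)) return(NULL)
  aff <- in_extended_event(out$t_mid, events_ext$events,
                           events_ext$carry_s)
  out$length_m[aff] <- out$length_m[aff] * cfg$effect_stride_length
  out$peak_swing_vel <- 2.6 * out$length_m / out$duration_s *
    exp(stats::rnorm(nrow(out), 0, 0.05))
  out$mean_vel <- 1.05 * out$length_m / out$duration_s
  out$max_vel <- out$peak_swing_vel
  out
}

gen_trunk <- function(duration_s, bouts, events, baseline, cfg) {
  r <- cfg$trunk_rate_hz
  n <- round(duration_s * r)
  t <- (seq_len(n) - 1) / r
  amp <- cfg$trunk_rms_deg * sqrt(2)
  carry_s <- cfg$effect_carry_strides * baseline$st
  freq_mult <- cfg$effect_trunk_velocity / cfg$effect_trunk_angle
  pitch <- stats::rnorm(n, 0, 0.3); roll <- stats::rnorm(n, 0, 0.3)
  wp <- stats::rnorm(n, 0, 1.5); wr <- stats::rnorm(n, 0, 1.5)
  for (j in seq_len(nrow(bouts))) {
    kk <- which(t >= bouts[j, "start"] & t < bouts[j, "end"])
    if (length(kk) == 0) next
    ext <- in_extended_event(t[kk], events, carry_s)
    m_a <- 1 + (cfg$effect_trunk_angle - 1) * ext
    m_f <- 1 + (freq_mult - 1) * ext
    for (series in c("p", "r")) {
      period <- if (series == "p") baseline$st / 2 else baseline$st
      base_w <- 2 * pi / period
      phase <- stats::runif(1, 0, 2 * pi) + cumsum(base_w * m_f / r)
      ang <- amp * m_a * sin(phase)
      w <- amp * m_a * base_w * m_f * cos(phase)
      if (series == "p") {
        pitch[kk] <- ang + stats::rnorm(length(kk), 0, 0.3)
        wp[kk] <- w + stats::rnorm(length(kk), 0, 2)
      } else {
        roll[kk] <- ang + stats::rnorm(length(kk), 0, 0.3)
        wr[kk] <- w + stats::rnorm(length(kk), 0, 2)
      }
    }
  }
  list(rate_hz = r, pitch = pitch, roll = roll, wpitch = wp, wroll = wr)
}

#' Simulate one subject-day (tier 1)
#'
#' Generates alternating walking/non-walking bouts, per-foot stride tables
#' with AR(1)-correlated stride times and lengths around the subject
#' baseline, a trunk sway stream, and ground-truth LOB events placed
#' strictly inside walking bouts. During each event (and the following
#' `effect_carry_strides` strides) the configured effect-size multipliers
#' are applied. Deterministic given `(cfg, seed)`.
#'
#' @param cfg a [lob_gen_config()].
#' @param subject_id,day_id identifiers.
#' @param n_events number of events to place in this day.
#' @param seed integer seed for this day.
#' @param baseline optional list `(st, sl)` of subject baseline stride time
#'   and length; drawn from the config if `NULL`.
#' @param tier `"stride"` (full stride/trunk streams) or `"events"`
#'   (bouts and events only; cheap, for label-plumbing studies).
#' @return object of class `lob_day`.
#' @export
simulate_subject_day <- function(cfg, subject_id = "S1", day_id = "D01",
                                 n_events = 0, seed = 1, baseline = NULL,
                                 tier = c("stride", "events")) {
  tier <- match.arg(tier)
  with_seed(seed, {
    if (is.null(baseline))
      baseline <- list(st = stats::rnorm(1, cfg$stride_time_mean_s,
                                         cfg$stride_time_between_sd_s),
                       sl = stats::rnorm(1, cfg$stride_length_mean_m,
                                         cfg$stride_length_between_sd_m))
    duration_s <- sample_day_length_s(cfg)
    bouts <- sample_bouts(duration_s, cfg)
    events <- if (n_events > 0) {
      place_events(bouts, sample_event_durations(n_events, cfg), cfg)
    } else data.frame(t_start_s = numeric(), t_end_s = numeric())
    day <- list(subject_id = subject_id, day_id = day_id,
                duration_s = duration_s, bouts = bouts, events = events,
                baseline = baseline, strides = NULL, trunk = NULL,
                stance_duty = cfg$stance_duty)
    if (tier == "stride") {
      carry_s <- cfg$effect_carry_strides * baseline$st
      ev_ext <- list(events = events, carry_s = carry_s)
      strides <- rbind(gen_foot_strides(bouts, "R", baseline, ev_ext, cfg),
                       gen_foot_strides(bouts, "L", baseline, ev_ext, cfg))
      if (is.null(strides))
        strides <- data.frame(foot = character(), t_start = numeric(),
                              t_end = numeric(), t_mid = numeric(),
                              length_m = numeric(), duration_s = numeric(),
                              peak_swing_vel = numeric(),
                              mean_vel = numeric(), max_vel = numeric())
      day$strides <- strides[order(strides$t_mid), , drop = FALSE]
      rownames(day$strides) <- NULL
      day$trunk <- gen_trunk(duration_s, bouts, events, baseline, cfg)
    }
    structure(day, class = "lob_day")
  })
}

#' @export
print.lob_day <- function(x, ...) {
  cat(sprintf("<lob_day> %s %s: %.0f s, %d strides, %d events\n",
              x$subject_id, x$day_id, x$duration_s,
              NROW(x$strides), NROW(x$events)))
  invisible(x)
}

# spread n_events over n_days; every day gets >= 1 when counts allow
distribute_events <- function(n_events, n_days) {
  if (n_events >= n_days) {
    extra <- tabulate(sample.int(n_days, n_events - n_days, replace = TRUE),
                      n_days)
    rep(1L, n_days) + extra
  } else {
    tabulate(sample.int(n_days, n_events), n_days)
  }
}

#' Simulate a cohort (tier 1)
#'
#' Draws per-subject gait baselines, distributes the configured event
#' counts over each subject's days, and simulates every subject-day. The
#' seed hierarchy is master seed -> per-subject -> per-day, so any
#' subject-day regenerates independently and the whole cohort is
#' bit-identical given `(cfg, seed)`.
#'
#' @param cfg a [lob_gen_config()].
#' @param seed master seed.
#' @param tier `"stride"` or `"events"` (see [simulate_subject_day()]).
#' @return object of class `lob_cohort`: `days` (list of `lob_day`),
#'   `events` (data.frame `subject`, `day`, `t_start_s`, `t_end_s`),
#'   `config`, `seed`, `tier`.
#' @export
simulate_cohort <- function(cfg = lob_gen_config(), seed = 1,
                            tier = c("stride", "events")) {
  tier <- match.arg(tier)
  days <- list(); events <- NULL
  for (si in seq_len(cfg$n_subjects)) {
    sid <- sprintf("S%d", si)
    sseed <- derive_seed(seed, si, 0)
    baseline <- with_seed(sseed, list(
      st = stats::rnorm(1, cfg$stride_time_mean_s, cfg$stride_time_between_sd_s),
      sl = stats::rnorm(1, cfg$stride_length_mean_m, cfg$stride_length_between_sd_m)))
    nd <- cfg$days_per_subject[si]
    counts <- with_seed(sseed + 1, distribute_events(cfg$events_per_subject[si], nd))
    for (di in seq_len(nd)) {
      did <- sprintf("D%02d", di)
      day <- simulate_subject_day(cfg, sid, did, n_events = counts[di],
                                  seed = derive_seed(seed, si, di),
                                  baseline = baseline, tier = tier)
      days[[length(days) + 1L]] <- day
      if (NROW(day$events) > 0)
        events <- rbind(events, data.frame(subject = sid, day = did,
                                           t_start_s = day$events$t_start_s,
                                           t_end_s = day$events$t_end_s))
    }
  }
  if (is.null(events))
    events <- data.frame(subject = character(), day = character(),
                         t_start_s = numeric(), t_end_s = numeric())
  structure(list(days = days, events = events, config = cfg, seed = seed,
                 tier = tier),
            class = "lob_cohort")
}

#' @export
print.lob_cohort <- function(x, ...) {
  cat(sprintf("<lob_cohort> %d subjects, %d days, %d events (tier %s, seed %d)\n",
              x$config$n_subjects, length(x$days), nrow(x$events), x$tier,
              x$seed))
  invisible(x)
}

#' Negative:positive window-label ratio of a cohort
#'
#' Segments every day into sliding windows, labels them by event overlap
#' and returns total negatives divided by total positives (the
#' class-imbalance regime of the cohort).
#'
#' @param cohort a `lob_cohort` (any tier).
#' @param cfg a [windowing_config()].
#' @return list `ratio`, `n_windows`, `n_positive`.
#' @export
imbalance_ratio <- function(cohort, cfg = windowing_config()) {
  npos <- 0; ntot <- 0
  for (day in cohort$days) {
    win <- make_windows(day$duration_s, cfg)
    lab <- label_windows(win$start_s, cfg$window_s, day$events)
    npos <- npos + sum(lab); ntot <- ntot + length(lab)
  }
  list(ratio = (ntot - npos) / npos, n_windows = ntot, n_positive = npos)
}

#' Synthesize a raw IMU recording from tier-1 streams (tier 2)
#'
#' Builds continuous ground-truth foot trajectories from the stride table
#' (zero-velocity stance phases, smooth cycloidal swing arcs with a foot
#' pitch oscillation) and the trunk angle stream, differentiates them
#' analytically to body-frame specific force and angular rate, adds white
#' noise and small constant per-axis biases, and packages the result as a
#' 128 Hz [imu_recording()].
#'
#' @param day a tier-`"stride"` `lob_day`.
#' @param sample_rate output rate, Hz.
#' @param noise_accel,noise_gyro white-noise SDs (m/s^2, deg/s).
#' @param accel_bias,gyro_bias per-axis constant bias magnitudes.
#' @param swing_pitch_deg peak foot pitch during swing.
#' @param foot_lift_m peak foot lift during swing.
#' @param seed seed for noise and bias draws.
#' @return an `imu_recording`.
#' @export
inverse_imu_from_day <- function(day, sample_rate = 128, noise_accel = 0.02,
                                 noise_gyro = 0.2, accel_bias = 0.01,
                                 gyro_bias = 0.02, swing_pitch_deg = 25,
                                 foot_lift_m = 0.05, seed = 1) {
  stopifnot(inherits(day, "lob_day"), !is.null(day$strides))
  fs <- sample_rate
  n <- floor(day$duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  duty <- if (!is.null(day$stance_duty)) day$stance_duty else 0.6
  foot_signals <- function(foot) {
    s <- day$strides[day$strides$foot == foot, , drop = FALSE]
    s <- s[order(s$t_start), , drop = FALSE]
    d2s <- numeric(n); d2z <- numeric(n)
    th <- numeric(n); w <- numeric(n)
    for (k in seq_len(nrow(s))) {
      sw0 <- s$t_start[k] + duty * s$duration_s[k]
      sw1 <- s$t_end[k]
      Tsw <- sw1 - sw0
      kk <- which(t >= sw0 & t < sw1)
      if (length(kk) == 0) next
      tau <- (t[kk] - sw0) / Tsw
      L <- s$length_m[k]; h <- foot_lift_m
      # cycloidal advance; lift and pitch profiles are chosen C^1 in rate
      # and acceleration (zero at the swing edges) so that the sampled
      # signals integrate without systematic per-stride discretization error
      d2s[kk] <- L * 2 * pi / Tsw^2 * sin(2 * pi * tau)
      u <- pi * tau # z = h sin^4(u): peaks at h mid-swing, C^2 at edges
      d2z[kk] <- 4 * h * pi^2 / Tsw^2 *
        (3 * sin(u)^2 * cos(u)^2 - sin(u)^4)
      # pitch bump (A/2)(1 - cos 2 pi tau): rate zero at both swing edges
      th[kk] <- swing_pitch_deg * pi / 180 * (1 - cos(2 * pi * tau)) / 2
      w[kk] <- swing_pitch_deg * pi / Tsw * sin(2 * pi * tau) # deg/s
    }
    fz_up <- d2z + GRAVITY
    acc <- cbind(cos(th) * d2s - sin(th) * fz_up,
                 numeric(n),
                 sin(th) * d2s + cos(th) * fz_up)
    gyr <- cbind(numeric(n), w, numeric(n))
    list(acc = acc, gyr = gyr)
  }
  trunk_signals <- function() {
    tt <- (seq_along(day$trunk$pitch) - 1) / day$trunk$rate_hz
    ip <- function(y) stats::approx(tt, y, t, rule = 2)$y
    p <- ip(day$trunk$pitch) * pi / 180
    r <- ip(day$trunk$roll) * pi / 180
    acc <- cbind(-GRAVITY * sin(p),
                 GRAVITY * sin(r) * cos(p),
                 GRAVITY * cos(r) * cos(p))
    gyr <- cbind(ip(day$trunk$wroll), ip(day$trunk$wpitch), numeric(n))
    list(acc = acc, gyr = gyr)
  }
  with_seed(seed, {
    sig <- list(left_foot = foot_signals("L"), right_foot = foot_signals("R"),
                trunk = trunk_signals())
    d <- data.frame(t_s = t)
    for (sensor in names(sig)) {
      ab <- stats::runif(3, -1, 1) * accel_bias
      gb <- stats::runif(3, -1, 1) * gyro_bias
      for (j in 1:3) {
        d[[paste0(sensor, "_acc_", c("x", "y", "z")[j])]] <-
          sig[[sensor]]$acc[, j] + ab[j] + stats::rnorm(n, 0, noise_accel)
        d[[paste0(sensor, "_gyr_", c("x", "y", "z")[j])]] <-
          sig[[sensor]]$gyr[, j] + gb[j] + stats::rnorm(n, 0, noise_gyro)
      }
    }
    imu_recording(day$subject_id, day$day_id, d, sample_rate = fs)
  })
}

#' Write cohort provenance (YAML)
#'
#' Records the generator configuration, master seed and tier alongside a
#' note that effect sizes are synthetic stand-ins, so any cohort can be
#' regenerated bit-identically.
#'
#' @param cohort a `lob_cohort`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_cohort_provenance <- function(cohort, path) {
  yaml::write_yaml(list(
    generator = "lobdetect synthetic cohort",
    note = paste("Synthetic data; event effect sizes are stand-ins, not",
                 "measured real-world LOB kinematics."),
    seed = cohort$seed, tier = cohort$tier,
    config = cohort$config[!vapply(cohort$config, is.null, TRUE)]), path)
  invisible(path)
}
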