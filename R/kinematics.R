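# Strapdown integration with zero-velocity updates (ZUPT).
#
# Pipeline per foot sensor: detect stance samples from gyro/accel
# magnitudes, integrate gyro (quaternion, midpoint rule) for orientation,
# rotate specific force to the world frame and remove gravity, integrate
# to velocity, de-drift velocity between stance phases with a linear ramp
# anchored at stance midpoints, re-integrate to position, then segment
# strides between consecutive footfalls (stance midpoints).

# ---- quaternion helpers (w, x, y, z; body-to-world convention) ----------

quat_mult <- function(q, r) {
  c(q[1] * r[1] - q[2] * r[2] - q[3] * r[3] - q[4] * r[4],
    q[1] * r[2] + q[2] * r[1] + q[3] * r[4] - q[4] * r[3],
    q[1] * r[3] - q[2] * r[4] + q[3] * r[1] + q[4] * r[2],
    q[1] * r[4] + q[2] * r[3] - q[3] * r[2] + q[4] * r[1])
}

quat_normalize <- function(q) q / sqrt(sum(q^2))

# rotation quaternion taking unit vector a to unit vector b
quat_from_two_vectors <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  d <- sum(a * b)
  if (d > 1 - 1e-12) return(c(1, 0, 0, 0))
  if (d < -1 + 1e-12) { # 180 degrees: any axis orthogonal to a
    ax <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- ax - sum(ax * a) * a; v <- v / sqrt(sum(v^2))
    return(c(0, v))
  }
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  quat_normalize(c(1 + d, v))
}

# rotate rows of body-frame matrix v (n x 3) to world frame by quats (n x 4)
quat_rotate_rows <- function(q, v) {
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  vx <- v[, 1]; vy <- v[, 2]; vz <- v[, 3]
  # t = 2 q_vec x v ; v' = v + w t + q_vec x t
  tx <- 2 * (y * vz - z * vy); ty <- 2 * (z * vx - x * vz)
  tz <- 2 * (x * vy - y * vx)
  cbind(vx + w * tx + y * tz - z * ty,
        vy + w * ty + z * tx - x * tz,
        vz + w * tz + x * ty - y * tx)
}

# integrate body-frame angular rate (rad/s, n x 3) with the midpoint rule
integrate_gyro <- function(omega, dt, q0, start = 1L) {
  n <- nrow(omega)
  q <- matrix(0, n, 4)
  q[start, ] <- quat_normalize(q0)
  if (start < n) for (k in seq(start, n - 1L)) {
    wm <- (omega[k, ] + omega[k + 1L, ]) / 2
    ang <- sqrt(sum(wm^2)) * dt
    dq <- if (ang < 1e-12) c(1, 0, 0, 0) else {
      ax <- wm / sqrt(sum(wm^2))
      c(cos(ang / 2), sin(ang / 2) * ax)
    }
    q[k + 1L, ] <- quat_normalize(quat_mult(q[k, ], dq))
  }
  if (start > 1L) for (k in seq(start, 2L)) {
    wm <- (omega[k, ] + omega[k - 1L, ]) / 2
    ang <- sqrt(sum(wm^2)) * dt
    dq <- if (ang < 1e-12) c(1, 0, 0, 0) else {
      ax <- wm / sqrt(sum(wm^2))
      c(cos(ang / 2), -sin(ang / 2) * ax)
    }
    q[k - 1L, ] <- quat_normalize(quat_mult(q[k, ], dq))
  }
  q
}

# all/any over a centered-ish sliding window, via run-length morphology
roll_erode <- function(x, w) {
  if (w <= 1) return(x)
  s <- cumsum(c(0, as.numeric(x)))
  n <- length(x)
  full <- (s[(w + 1):(n + 1)] - s[1:(n - w + 1)]) == w # window starting at i
  out <- logical(n)
  idx <- which(full)
  for (i in idx) out[i:(i + w - 1)] <- TRUE # dilate back: morphological opening
  out
}

#' Detect stationary (stance) samples of a foot sensor
#'
#' A sample is provisionally stationary when the gyro magnitude is below
#' `omega_thr` and the accelerometer magnitude is within `accel_thr` of
#' gravity. The provisional mask is then opened with a sliding test window
#' of `window_s` seconds (runs shorter than the window are removed without
#' eroding genuine stance plateaus), and stance intervals shorter than
#' `min_stance_s` are dropped.
#'
#' @param foot matrix/data.frame with columns `acc_x..gyr_z` (or the six
#'   `<sensor>_...` columns of one foot), accel m/s^2, gyro deg/s.
#' @param sample_rate Hz.
#' @param omega_thr gyro magnitude threshold, deg/s.
#' @param accel_thr allowed deviation of accel magnitude from gravity, m/s^2.
#' @param window_s sliding test window, s.
#' @param min_stance_s minimum stance duration kept, s.
#' @return list of class `zupt_mask`: `mask` (logical per sample) and
#'   `intervals` (data.frame `start`,`end`, half-open sample indices,
#'   1-based start, `end` exclusive).
#' @export
detect_stationary <- function(foot, sample_rate = 128, omega_thr = 20,
                              accel_thr = 0.5, window_s = 0.1,
                              min_stance_s = 0.1) {
  foot <- as.matrix(foot)
  acc <- foot[, 1:3, drop = FALSE]; gyr <- foot[, 4:6, drop = FALSE]
  amag <- sqrt(rowSums(acc^2)); gmag <- sqrt(rowSums(gyr^2))
  cond <- gmag < omega_thr & abs(amag - GRAVITY) < accel_thr
  w <- max(1L, round(window_s * sample_rate))
  mask <- roll_erode(cond, w)
  r <- rle(mask)
  min_n <- max(1L, round(min_stance_s * sample_rate))
  short <- r$values & r$lengths < min_n
  r$values[short] <- FALSE
  mask <- inverse.rle(r)
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- data.frame(start = starts[r$values], end = ends[r$values] + 1L)
  structure(list(mask = mask, intervals = iv, sample_rate = sample_rate),
            class = "zupt_mask")
}

#' Estimate a drift-corrected foot trajectory
#'
#' Orientation by quaternion integration of the gyro (midpoint rule),
#' initialized by aligning the mean specific force of the first stance
#' interval with gravity; world-frame acceleration is the rotated specific
#' force minus gravity; velocity and position by trapezoidal integration.
#' Within each inter-stance segment the velocity drift is removed by
#' subtracting the linear ramp that forces the velocity to zero at the two
#' bounding stance phases (the ZUPT correction); stance samples are pinned
#' to zero velocity and position is re-integrated from the corrected
#' velocity.
#'
#' @param foot six-channel matrix as in [detect_stationary()].
#' @param mask a `zupt_mask` for the same samples.
#' @param sample_rate Hz.
#' @return list of class `foot_trajectory`: `quat` (n x 4, unit), `vel`
#'   (n x 3, m/s, world frame), `pos` (n x 3, m), `sample_rate`.
#' @export
estimate_foot_trajectory <- function(foot, mask, sample_rate = 128) {
  foot <- as.matrix(foot)
  iv <- mask$intervals
  if (nrow(iv) == 0) stop("cannot initialize ZUPT: no stance interval found")
  n <- nrow(foot); dt <- 1 / sample_rate
  acc <- foot[, 1:3, drop = FALSE]
  omega <- foot[, 4:6, drop = FALSE] * pi / 180
  i0 <- iv$start[1]; i1 <- iv$end[1] - 1L
  f_mean <- colMeans(acc[i0:i1, , drop = FALSE])
  q0 <- quat_from_two_vectors(f_mean, c(0, 0, 1))
  q <- integrate_gyro(omega, dt, q0, start = i0)
  a_w <- quat_rotate_rows(q, acc)
  a_w[, 3] <- a_w[, 3] - GRAVITY
  v <- cumtrapz_mat(a_w, dt)
  # anchor velocity error at stance midpoints, subtract linear ramps
  mids <- floor((iv$start + iv$end - 1L) / 2)
  err <- v[mids, , drop = FALSE]
  vc <- v
  for (j in seq_len(nrow(iv))) {
    lo <- if (j == 1) 1L else mids[j - 1L]
    hi <- mids[j]
    if (j == 1) {
      vc[1:hi, ] <- sweep(v[1:hi, , drop = FALSE], 2, err[1, ])
    } else {
      span <- hi - lo
      frac <- (0:span) / span
      ramp <- outer(frac, err[j, ] - err[j - 1L, ]) +
        matrix(err[j - 1L, ], span + 1L, 3, byrow = TRUE)
      vc[lo:hi, ] <- v[lo:hi, , drop = FALSE] - ramp
    }
  }
  if (mids[nrow(iv)] < n) {
    idx <- (mids[nrow(iv)] + 1L):n
    vc[idx, ] <- sweep(v[idx, , drop = FALSE], 2, err[nrow(iv), ])
  }
  for (j in seq_len(nrow(iv))) vc[iv$start[j]:(iv$end[j] - 1L), ] <- 0
  p <- cumtrapz_mat(vc, dt)
  structure(list(quat = q, vel = vc, pos = p, sample_rate = sample_rate),
            class = "foot_trajectory")
}

#' Segment strides from a foot trajectory
#'
#' One footfall per stance interval (at the interval midpoint); one stride
#' per consecutive footfall pair of the same foot. Stride length is the
#' horizontal-plane (x, y) displacement between the footfalls; the peak
#' swing velocity is the maximum velocity magnitude between them.
#'
#' @param traj a `foot_trajectory`.
#' @param mask the matching `zupt_mask`.
#' @param foot `"L"` or `"R"` label carried into the output.
#' @return data.frame with one row per stride: `foot`, `t_start`, `t_end`,
#'   `t_mid` (s), `length_m`, `duration_s`, `peak_swing_vel`, `mean_vel`,
#'   `max_vel` (m/s). Empty when fewer than two stance intervals exist.
#' @export
segment_strides <- function(traj, mask, foot = "R") {
  iv <- mask$intervals
  fs <- traj$sample_rate
  if (nrow(iv) < 2)
    return(data.frame(foot = character(), t_start = numeric(),
                      t_end = numeric(), t_mid = numeric(),
                      length_m = numeric(), duration_s = numeric(),
                      peak_swing_vel = numeric(), mean_vel = numeric(),
                      max_vel = numeric()))
  mids <- floor((iv$start + iv$end - 1L) / 2)
  t_ff <- (mids - 1L) / fs
  k <- length(mids)
  sp <- sqrt(rowSums(traj$vel^2))
  out <- lapply(seq_len(k - 1L), function(j) {
    i1 <- mids[j]; i2 <- mids[j + 1L]
    seg <- sp[i1:i2]
    data.frame(foot = foot, t_start = t_ff[j], t_end = t_ff[j + 1L],
               t_mid = (t_ff[j] + t_ff[j + 1L]) / 2,
               length_m = sqrt(sum((traj$pos[i2, 1:2] - traj$pos[i1, 1:2])^2)),
               duration_s = t_ff[j + 1L] - t_ff[j],
               peak_swing_vel = max(seg), mean_vel = mean(seg),
               max_vel = max(seg))
  })
  do.call(rbind, out)
}

#' Estimate trunk pitch/roll series by complementary filtering
#'
#' Pitch (rotation about the mediolateral y axis) and roll (about the
#' anteroposterior x axis) are obtained by fusing gyro integration with the
#' accelerometer gravity tilt: `angle <- alpha * (angle + gyro * dt) +
#' (1 - alpha) * angle_accel`. Angular velocities are taken directly from
#' the gyro (pitch rate from gyro y, roll rate from gyro x). The filter is
#' initialized at the first sample's accelerometer tilt. Trunk yaw is not
#' estimated (no downstream feature uses it).
#'
#' @param trunk six-channel matrix (acc x/y/z m/s^2, gyr x/y/z deg/s).
#' @param sample_rate Hz.
#' @param alpha complementary-filter coefficient (default 0.98).
#' @return data.frame `pitch_deg`, `roll_deg`, `wpitch_dps`, `wroll_dps`,
#'   one row per sample.
#' @export
estimate_trunk_series <- function(trunk, sample_rate = 128, alpha = 0.98) {
  trunk <- as.matrix(trunk)
  n <- nrow(trunk); dt <- 1 / sample_rate
  acc <- trunk[, 1:3, drop = FALSE]
  if (all(trunk == 0))
    return(data.frame(pitch_deg = numeric(n), roll_deg = numeric(n),
                      wpitch_dps = numeric(n), wroll_dps = numeric(n)))
  wroll <- trunk[, 4]; wpitch <- trunk[, 5]
  pitch_acc <- atan2(-acc[, 1], sqrt(acc[, 2]^2 + acc[, 3]^2)) * 180 / pi
  roll_acc <- atan2(acc[, 2], acc[, 3]) * 180 / pi
  pitch <- numeric(n); roll <- numeric(n)
  pitch[1] <- pitch_acc[1]; roll[1] <- roll_acc[1]
  for (k in 2:n) {
    pitch[k] <- alpha * (pitch[k - 1] + wpitch[k] * dt) + (1 - alpha) * pitch_acc[k]
    roll[k] <- alpha * (roll[k - 1] + wroll[k] * dt) + (1 - alpha) * roll_acc[k]
  }
  data.frame(pitch_deg = pitch, roll_deg = roll,
             wpitch_dps = wpitch, wroll_dps = wroll)
}

#' Reconstruct a gait day from a raw recording
#'
#' Runs stance detection, trajectory estimation and stride segmentation for
#' both feet and the trunk complementary filter, yielding the same per-day
#' structure (`lob_day`) the tier-1 synthetic generator emits, so raw
#' recordings and synthetic stride streams feed one feature extractor.
#'
#' @param rec an `imu_recording`.
#' @param events optional `lob_events` rows for this subject-day.
#' @param ... passed to [detect_stationary()].
#' @return a `lob_day` (see [simulate_subject_day()]).
#' @export
recording_to_day <- function(rec, events = NULL, ...) {
  d <- rec$data
  pick <- function(sensor) as.matrix(d[paste(sensor,
    rep(c("acc", "gyr"), each = 3), rep(c("x", "y", "z"), 2), sep = "_")])
  strides <- NULL
  for (ft in c(L = "left_foot", R = "right_foot")) {
    side <- if (ft == "left_foot") "L" else "R"
    m <- detect_stationary(pick(ft), rec$sample_rate, ...)
    if (nrow(m$intervals) >= 2) {
      tr <- estimate_foot_trajectory(pick(ft), m, rec$sample_rate)
      strides <- rbind(strides, segment_strides(tr, m, foot = side))
    }
  }
  if (is.null(strides))
    strides <- data.frame(foot = character(), t_start = numeric(),
                          t_end = numeric(), t_mid = numeric(),
                          length_m = numeric(), duration_s = numeric(),
                          peak_swing_vel = numeric(), mean_vel = numeric(),
                          max_vel = numeric())
  ts <- estimate_trunk_series(pick("trunk"), rec$sample_rate)
  ev <- if (is.null(events)) data.frame(t_start_s = numeric(), t_end_s = numeric())
        else data.frame(t_start_s = events$t_start_s, t_end_s = events$t_end_s)
  structure(list(subject_id = rec$subject_id, day_id = rec$day_id,
                 duration_s = rec$duration_s,
                 strides = strides[order(strides$t_mid), , drop = FALSE],
                 trunk = list(rate_hz = rec$sample_rate,
                              pitch = ts$pitch_deg, roll = ts$roll_deg,
                              wpitch = ts$wpitch_dps, wroll = ts$wroll_dps),
                 events = ev),
            class = "lob_day")
}

#' Export a foot trajectory for visualization
#' @param traj a `foot_trajectory`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_foot_trajectory <- function(traj, path) {
  n <- nrow(traj$pos)
  d <- data.frame(t_s = (seq_len(n) - 1) / traj$sample_rate,
                  qw = traj$quat[, 1], qx = traj$quat[, 2],
                  qy = traj$quat[, 3], qz = traj$quat[, 4],
                  vx = traj$vel[, 1], vy = traj$vel[, 2], vz = traj$vel[, 3],
                  px = traj$pos[, 1], py = traj$pos[, 2], pz = traj$pos[, 3])
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
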