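# Sliding-window segmentation and the 32-feature gait descriptor.
#
# Each subject-day is cut into 10 s windows every 2 s; a window gets a
# positive label when its half-open interval intersects any annotated LOB
# event. Per window: a binary gait indicator (>= 5 strides longer than
# 0.1 m), total walked distance, seven-number summaries of stride length
# and stride time, foot/swing velocity statistics for each foot, and
# trunk pitch/roll angle and angular-velocity statistics.

#' Names of the 32 window features, in canonical order
#' @return character vector of length 32.
#' @export
lob_feature_names <- function() c(
  "IS_GAIT", "GAIT_DISTANCE",
  "SL_MAX", "SL_MIN", "SL_MEAN", "SL_MEDIAN", "SL_IQR", "SL_VAR", "SL_RMS",
  "ST_MAX", "ST_MIN", "ST_MEAN", "ST_MEDIAN", "ST_IQR", "ST_VAR", "ST_RMS",
  "RF_MAX_VEL", "RF_MEAN_VEL", "LF_MAX_VEL", "LF_MEAN_VEL",
  "RS_MAX_VEL", "RS_MEAN_VEL", "RS_MIN_VEL",
  "LS_MAX_VEL", "LS_MEAN_VEL", "LS_MIN_VEL",
  "TRUNK_RMS_PITCH", "TRUNK_RMS_ROLL",
  "TW_RMS_PITCH", "TW_RMS_ROLL", "TW_RANGE_PITCH", "TW_RANGE_ROLL")

#' Partition of the 32 features into 6 correlated groups
#'
#' Groups used for grouped permutation importance: walked distance, stride
#' length, stride time, trunk angles and angular velocity, swing and foot
#' velocity, and the gait indicator. Disjoint and exhaustive over
#' [lob_feature_names()].
#'
#' @return named list of character vectors.
#' @export
lob_feature_groups <- function() {
  nm <- lob_feature_names()
  list(walked_distance = "GAIT_DISTANCE",
       stride_length = grep("^SL_", nm, value = TRUE),
       stride_time = grep("^ST_", nm, value = TRUE),
       trunk = grep("^(TRUNK|TW)_", nm, value = TRUE),
       foot_velocity = grep("^(RF|LF|RS|LS)_", nm, value = TRUE),
       gait_indicator = "IS_GAIT")
}

#' Windowing configuration
#' @param window_s window length, s (default 10).
#' @param stride_s hop between consecutive window starts, s (default 2).
#' @return list of class `windowing_config`.
#' @export
windowing_config <- function(window_s = 10, stride_s = 2) {
  stopifnot(stride_s > 0, stride_s <= window_s)
  structure(list(window_s = window_s, stride_s = stride_s),
            class = "windowing_config")
}

#' Enumerate window intervals for one day
#'
#' Window starts are `0, stride_s, 2*stride_s, ...`; trailing partial
#' windows are discarded, so the count is
#' `floor((duration - window_s)/stride_s) + 1`.
#'
#' @param duration_s day duration, s.
#' @param cfg a [windowing_config()].
#' @return data.frame with `t` (0-based window index) and `start_s`;
#'   zero rows (with a warning) when the day is shorter than one window.
#' @export
make_windows <- function(duration_s, cfg = windowing_config()) {
  if (duration_s < cfg$window_s) {
    warning("day shorter than one window; no windows produced")
    return(data.frame(t = integer(), start_s = numeric()))
  }
  n <- floor((duration_s - cfg$window_s) / cfg$stride_s) + 1
  data.frame(t = seq_len(n) - 1L, start_s = (seq_len(n) - 1L) * cfg$stride_s)
}

#' Binary gait indicator for a set of strides
#'
#' 1 when at least five strides longer than 0.1 m fall in the window,
#' else 0.
#'
#' @param lengths stride lengths (m) of the strides assigned to a window.
#' @param min_strides,min_length_m rule parameters (defaults 5 and 0.1).
#' @return 0 or 1.
#' @export
compute_gait_indicator <- function(lengths, min_strides = 5, min_length_m = 0.1) {
  as.numeric(sum(lengths > min_length_m) >= min_strides)
}

# seven-number summary in Table-1 order: max, min, mean, median, IQR
# (linear-interpolation quartiles, quantile type 7), variance, RMS.
# Zeros for an empty set; variance 0 for a single value.
stat7 <- function(x) {
  if (length(x) == 0) return(numeric(7))
  c(max(x), min(x), mean(x), stats::median(x),
    stats::quantile(x, 0.75, names = FALSE, type = 7) -
      stats::quantile(x, 0.25, names = FALSE, type = 7),
    if (length(x) > 1) stats::var(x) else 0,
    rms(x))
}

vel3 <- function(x) if (length(x) == 0) numeric(3) else c(max(x), mean(x), min(x))

#' Label windows by event overlap
#'
#' A window is positive iff its half-open interval `[start, start+window)`
#' intersects at least one event interval `[t_start, t_end)`.
#'
#' @param start_s window start times, s.
#' @param window_s window length, s.
#' @param events data.frame with `t_start_s`, `t_end_s` (same subject-day).
#' @return integer 0/1 vector aligned with `start_s`.
#' @export
label_windows <- function(start_s, window_s, events) {
  lab <- integer(length(start_s))
  if (NROW(events) == 0) return(lab)
  for (i in seq_len(nrow(events))) {
    hit <- start_s < events$t_end_s[i] & start_s + window_s > events$t_start_s[i]
    lab[hit] <- 1L
  }
  lab
}

#' Extract the 32-feature descriptor for every window of a day
#'
#' Strides are assigned to every window containing their
#' footfall-to-footfall midpoint time. Stride statistics of a window with
#' no strides are 0 (not missing), so every window is classifiable; trunk
#' statistics are always computed from the window's trunk samples.
#'
#' @param day a `lob_day` (from [simulate_subject_day()] or
#'   [recording_to_day()]).
#' @param cfg a [windowing_config()].
#' @return list: `meta` (data.frame `subject`, `day`, `t`, `start_s`,
#'   `label`) and `x` (matrix, one row per window, 32 named columns).
#' @export
day_features <- function(day, cfg = windowing_config()) {
  win <- make_windows(day$duration_s, cfg)
  nw <- nrow(win)
  nm <- lob_feature_names()
  x <- matrix(0, nw, length(nm), dimnames = list(NULL, nm))
  lab <- label_windows(win$start_s, cfg$window_s, day$events)
  s <- day$strides
  s <- s[order(s$t_mid), , drop = FALSE]
  tm <- s$t_mid
  lo <- findInterval(win$start_s - 1e-9, tm) + 1L
  hi <- findInterval(win$start_s + cfg$window_s - 1e-9, tm)
  tr <- day$trunk
  r <- tr$rate_hz
  wlen <- round(cfg$window_s * r)
  ntr <- length(tr$pitch)
  for (i in seq_len(nw)) {
    idx <- if (lo[i] <= hi[i]) lo[i]:hi[i] else integer()
    len <- s$length_m[idx]; dur <- s$duration_s[idx]
    right <- s$foot[idx] == "R"
    x[i, "IS_GAIT"] <- compute_gait_indicator(len)
    x[i, "GAIT_DISTANCE"] <- sum(len)
    x[i, 3:9] <- stat7(len)
    x[i, 10:16] <- stat7(dur)
    rf <- idx[right]; lf <- idx[!right]
    x[i, "RF_MAX_VEL"] <- if (length(rf)) max(s$max_vel[rf]) else 0
    x[i, "RF_MEAN_VEL"] <- if (length(rf)) mean(s$mean_vel[rf]) else 0
    x[i, "LF_MAX_VEL"] <- if (length(lf)) max(s$max_vel[lf]) else 0
    x[i, "LF_MEAN_VEL"] <- if (length(lf)) mean(s$mean_vel[lf]) else 0
    x[i, 21:23] <- vel3(s$peak_swing_vel[rf])
    x[i, 24:26] <- vel3(s$peak_swing_vel[lf])
    k0 <- round(win$start_s[i] * r) + 1L
    k1 <- min(k0 + wlen - 1L, ntr)
    if (k0 <= k1) {
      kk <- k0:k1
      x[i, "TRUNK_RMS_PITCH"] <- rms(tr$pitch[kk])
      x[i, "TRUNK_RMS_ROLL"] <- rms(tr$roll[kk])
      x[i, "TW_RMS_PITCH"] <- rms(tr$wpitch[kk])
      x[i, "TW_RMS_ROLL"] <- rms(tr$wroll[kk])
      x[i, "TW_RANGE_PITCH"] <- diff(range(tr$wpitch[kk]))
      x[i, "TW_RANGE_ROLL"] <- diff(range(tr$wroll[kk]))
    }
  }
  list(meta = data.frame(subject = day$subject_id, day = day$day_id,
                         t = win$t, start_s = win$start_s, label = lab),
       x = x)
}

#' Extract features for every day of a cohort
#'
#' @param cohort a `lob_cohort` from [simulate_cohort()] (tier
#'   `"stride"`), or a plain list of `lob_day` objects.
#' @param cfg a [windowing_config()].
#' @return object of class `lob_features`: `meta` (window metadata +
#'   labels), `x` (windows x 32 feature matrix), `events` (cohort events),
#'   `window_s`.
#' @export
cohort_features <- function(cohort, cfg = windowing_config()) {
  days <- if (inherits(cohort, "lob_cohort")) cohort$days else cohort
  parts <- lapply(days, day_features, cfg = cfg)
  meta <- do.call(rbind, lapply(parts, `[[`, "meta"))
  x <- do.call(rbind, lapply(parts, `[[`, "x"))
  rownames(meta) <- NULL
  ev <- if (inherits(cohort, "lob_cohort")) cohort$events else
    do.call(rbind, lapply(days, function(d)
      if (NROW(d$events)) data.frame(subject = d$subject_id, day = d$day_id,
                                     t_start_s = d$events$t_start_s,
                                     t_end_s = d$events$t_end_s)))
  structure(list(meta = meta, x = x, events = ev, window_s = cfg$window_s),
            class = "lob_features")
}

#' @export
print.lob_features <- function(x, ...) {
  cat(sprintf("<lob_features> %d windows, %d subjects, %d positive (%.3f%%)\n",
              nrow(x$meta), length(unique(x$meta$subject)),
              sum(x$meta$label), 100 * mean(x$meta$label)))
  invisible(x)
}

#' Per-feature standardization constants from training subjects only
#'
#' Computes z-score center/scale over the windows of the given training
#' subjects; features that are constant in training get scale 1 so they
#' standardize to 0 rather than blowing up.
#'
#' @param feat a `lob_features`.
#' @param train_subjects subject ids whose windows define the statistics.
#' @return list `center`, `scale` (length-32 named vectors).
#' @export
feature_standardizer <- function(feat, train_subjects) {
  rows <- feat$meta$subject %in% train_subjects
  m <- feat$x[rows, , drop = FALSE]
  center <- colMeans(m)
  scale <- apply(m, 2, stats::sd)
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  list(center = center, scale = scale)
}

#' Apply standardization constants to a feature matrix
#' @param x windows x 32 matrix.
#' @param std list from [feature_standardizer()].
#' @return standardized matrix.
#' @export
apply_standardizer <- function(x, std) {
  scale(x, center = std$center, scale = std$scale)[, , drop = FALSE]
}

#' Export the feature matrix as CSV
#'
#' One row per window: subject, day, window index, the 32 features and the
#' label.
#'
#' @param feat a `lob_features`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(feat, path) {
  d <- cbind(feat$meta[c("subject", "day", "t", "start_s")],
             as.data.frame(feat$x), label = feat$meta$label)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
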