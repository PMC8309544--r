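# Reading/writing recordings, event annotations and cohort manifests.
#
# Recording CSV dialect (wide, one file per subject-day): comment header
# lines starting with '#' carry metadata and units, then a header row
# `t_s,<sensor>_<acc|gyr>_<x|y|z>...` with sensors left_foot, right_foot,
# trunk. Accelerations are m/s^2, angular rates deg/s. Axes follow the
# sensor convention x = anteroposterior, y = mediolateral, z = longitudinal.

IMU_SENSORS <- c("left_foot", "right_foot", "trunk")

#' Names of the 18 IMU channels
#'
#' @return character vector `<sensor>_<acc|gyr>_<x|y|z>` for the three
#'   sensors (left foot, right foot, trunk).
#' @export
imu_channel_names <- function() {
  unlist(lapply(IMU_SENSORS, function(s)
    paste(s, rep(c("acc", "gyr"), each = 3), rep(c("x", "y", "z"), 2),
          sep = "_")))
}

#' Construct a validated IMU recording
#'
#' Bundles one subject-day of synchronized three-sensor, six-channel time
#' series sampled at a common rate into an `imu_recording` object. All
#' three sensors share one time base; gaps are an error by construction
#' (the time vector is derived from the sample count).
#'
#' @param subject_id,day_id identifiers.
#' @param data data.frame or matrix with the 18 columns named as in
#'   [imu_channel_names()] (a leading `t_s` column is allowed and checked).
#' @param sample_rate sampling rate in Hz (default 128).
#' @return an object of class `imu_recording` with elements `subject_id`,
#'   `day_id`, `sample_rate`, `n`, `duration_s` and `data` (data.frame with
#'   `t_s` plus the 18 channels).
#' @export
imu_recording <- function(subject_id, day_id, data, sample_rate = 128) {
  data <- as.data.frame(data)
  want <- imu_channel_names()
  missing <- setdiff(want, names(data))
  if (length(missing) > 0)
    stop("missing channel: ", paste(missing, collapse = ", "))
  n <- nrow(data)
  if (n == 0) stop("empty recording")
  if ("t_s" %in% names(data)) {
    t <- data$t_s
    if (any(diff(t) <= 0)) stop("non-monotonic time column")
    dt <- stats::median(diff(t))
    if (abs(dt * sample_rate - 1) > 0.01)
      stop(sprintf("sample-rate mismatch: time step %.6f s vs declared %g Hz",
                   dt, sample_rate))
  }
  d <- data.frame(t_s = (seq_len(n) - 1) / sample_rate)
  d[want] <- data[want]
  structure(list(subject_id = as.character(subject_id),
                 day_id = as.character(day_id),
                 sample_rate = sample_rate, n = n,
                 duration_s = n / sample_rate, data = d),
            class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> subject %s day %s: %.1f s at %g Hz (%d samples)\n",
              x$subject_id, x$day_id, x$duration_s, x$sample_rate, x$n))
  invisible(x)
}

#' Write an IMU recording to CSV
#'
#' Wide CSV with a commented metadata header (subject, day, sample rate,
#' units); inverse of [read_imu_recording()].
#'
#' @param rec an `imu_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_imu_recording <- function(rec, path) {
  stopifnot(inherits(rec, "imu_recording"))
  if (rec$n == 0) stop("empty recording")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# imu_recording v1",
               paste0("# subject: ", rec$subject_id),
               paste0("# day: ", rec$day_id),
               paste0("# sample_rate_hz: ", format(rec$sample_rate)),
               "# units: acc=m/s^2 gyr=deg/s t=s"), con)
  utils::write.csv(rec$data, con, row.names = FALSE)
  invisible(path)
}

#' Read an IMU recording from CSV
#'
#' Parses the dialect written by [write_imu_recording()] and validates the
#' channel set, time monotonicity and sample rate (mismatch beyond 1% is an
#' error).
#'
#' @param path CSV file path.
#' @return an `imu_recording`.
#' @export
read_imu_recording <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- readLines(path, n = 10)
  meta <- hdr[startsWith(hdr, "#")]
  get_meta <- function(key, default = NA_character_) {
    ln <- grep(paste0("^# ", key, ":"), meta, value = TRUE)
    if (length(ln) == 0) return(default)
    trimws(sub(paste0("^# ", key, ":"), "", ln[1]))
  }
  d <- utils::read.csv(path, comment.char = "#")
  rate <- suppressWarnings(as.numeric(get_meta("sample_rate_hz", "128")))
  imu_recording(get_meta("subject", "unknown"), get_meta("day", "unknown"),
                d, sample_rate = rate)
}

#' Construct LOB event annotations
#'
#' Validates a table of loss-of-balance events. Intervals are half-open
#' `[t_start, t_end)` seconds from recording start. Non-positive durations
#' are an error; durations of 7 s or more are accepted with a warning and
#' flagged (the in-scope data regime has all events under 7 s).
#'
#' @param subject,day,t_start,t_end vectors of equal length.
#' @return data.frame of class `lob_events` with columns `subject`, `day`,
#'   `t_start_s`, `t_end_s`, `flag_long`.
#' @export
lob_events <- function(subject, day, t_start, t_end) {
  ev <- data.frame(subject = as.character(subject), day = as.character(day),
                   t_start_s = as.numeric(t_start), t_end_s = as.numeric(t_end))
  bad <- ev$t_end_s <= ev$t_start_s
  if (any(bad))
    stop("negative duration: event(s) ",
         paste(which(bad), collapse = ", "), " have t_end <= t_start")
  ev$flag_long <- (ev$t_end_s - ev$t_start_s) >= 7
  if (any(ev$flag_long))
    warning(sum(ev$flag_long), " event(s) with duration >= 7 s (flagged)")
  ev <- ev[order(ev$subject, ev$day, ev$t_start_s), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("lob_events", "data.frame")
  ev
}

#' Merge overlapping events within each subject-day
#'
#' Annotated events whose half-open intervals overlap (or touch) within one
#' subject-day are merged into their union, so event-level counting is
#' well-defined. Idempotent.
#'
#' @param events a `lob_events` data.frame.
#' @return merged `lob_events`, sorted by (subject, day, t_start).
#' @export
merge_lob_events <- function(events) {
  if (nrow(events) == 0) return(events)
  parts <- split(events, list(events$subject, events$day), drop = TRUE)
  out <- do.call(rbind, lapply(parts, function(e) {
    e <- e[order(e$t_start_s), , drop = FALSE]
    s <- e$t_start_s; t <- e$t_end_s
    keep_s <- s[1]; keep_t <- t[1]; res <- NULL
    for (i in seq_len(nrow(e))[-1]) {
      if (s[i] <= keep_t) keep_t <- max(keep_t, t[i])
      else { res <- rbind(res, c(keep_s, keep_t)); keep_s <- s[i]; keep_t <- t[i] }
    }
    res <- rbind(res, c(keep_s, keep_t))
    data.frame(subject = e$subject[1], day = e$day[1],
               t_start_s = res[, 1], t_end_s = res[, 2],
               flag_long = (res[, 2] - res[, 1]) >= 7)
  }))
  out <- out[order(out$subject, out$day, out$t_start_s), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("lob_events", "data.frame")
  out
}

#' Read LOB event annotations from CSV
#'
#' Expects columns `subject, day, t_start_s, t_end_s` (seconds from
#' recording start). Events are validated, sorted and overlapping events
#' within a subject-day merged.
#'
#' @param path CSV file path.
#' @return merged, sorted `lob_events` (zero rows for an empty file).
#' @export
read_lob_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, comment.char = "#")
  if (nrow(d) == 0)
    return(structure(data.frame(subject = character(), day = character(),
                                t_start_s = numeric(), t_end_s = numeric(),
                                flag_long = logical()),
                     class = c("lob_events", "data.frame")))
  need <- c("subject", "day", "t_start_s", "t_end_s")
  if (!all(need %in% names(d)))
    stop("events file must have columns: ", paste(need, collapse = ", "))
  merge_lob_events(lob_events(d$subject, d$day, d$t_start_s, d$t_end_s))
}

#' Write LOB events to CSV
#' @param events a `lob_events` data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_lob_events <- function(events, path) {
  utils::write.csv(as.data.frame(events)[c("subject", "day", "t_start_s", "t_end_s")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a cohort manifest (YAML)
#'
#' Bookkeeping for a cohort: per subject, the day ids, event counts, and
#' paths to recording and annotation files. Every event must reference a
#' listed recording; subject ids must be unique.
#'
#' @param manifest list with elements `subjects` (list of
#'   `list(subject_id, day_ids, n_events)`), `recordings` (named paths) and
#'   `events_file`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_cohort_manifest <- function(manifest, path) {
  ids <- vapply(manifest$subjects, `[[`, "", "subject_id")
  if (anyDuplicated(ids)) stop("duplicate subject ids in manifest")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Read a cohort manifest (YAML)
#' @param path YAML path written by [write_cohort_manifest()].
#' @return the manifest list.
#' @export
read_cohort_manifest <- function(path) {
  m <- yaml::read_yaml(path)
  ids <- vapply(m$subjects, `[[`, "", "subject_id")
  if (anyDuplicated(ids)) stop("duplicate subject ids in manifest")
  m
}
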