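# Window-level and event-level evaluation.
#
# AUROC via the rank-statistic (Mann-Whitney) formulation with ties
# counted one half; AUPR as the step-wise (non-interpolated) average
# precision, because linear interpolation in precision-recall space is
# biased. Event-level metrics follow the alarm semantics: an event counts
# as detected when at least one overlapping window is predicted positive.

#' Area under the ROC curve
#'
#' Rank-statistic formulation: the probability that a random positive
#' scores above a random negative, ties counted 1/2.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels (both classes required).
#' @return value in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("auroc requires both classes")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise average precision: sum over distinct score thresholds of
#' precision times the recall increment. Baseline for a random scorer is
#' the positive-class incidence.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels (at least one positive required).
#' @return value in `[0, 1]`.
#' @export
aupr <- function(scores, labels) {
  n1 <- sum(labels == 1)
  if (n1 == 0) stop("aupr requires at least one positive")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  grp_end <- which(s != c(s[-1], NA) | seq_along(s) == length(s))
  tp <- cumsum(y)[grp_end]
  np <- grp_end
  prec <- tp / np
  rec <- tp / n1
  sum(prec * diff(c(0, rec)))
}

#' Percentile bootstrap confidence interval for a score metric
#'
#' Resamples (score, label) pairs with replacement `B` times and returns
#' empirical percentiles of the metric. Degenerate resamples on which the
#' metric fails (e.g. single-class for AUROC) are redrawn; the redraw
#' count is attached as attribute `redraws`.
#'
#' @param metric function(scores, labels) -> number.
#' @param scores,labels data.
#' @param B bootstrap resamples (default 200).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return numeric `c(lower, upper)` with attribute `redraws`.
#' @export
bootstrap_ci <- function(metric, scores, labels, B = 200, seed = 1,
                         conf = 0.95) {
  n <- length(scores)
  with_seed(seed, {
    vals <- numeric(B)
    redraws <- 0L
    for (b in seq_len(B)) {
      for (tries in 1:100) {
        idx <- sample.int(n, n, replace = TRUE)
        v <- tryCatch(metric(scores[idx], labels[idx]), error = function(e) NA)
        if (is.finite(v)) break
        redraws <- redraws + 1L
      }
      if (!is.finite(v)) stop("bootstrap resample degenerate after 100 redraws")
      vals[b] <- v
    }
    a <- (1 - conf) / 2
    structure(stats::quantile(vals, c(a, 1 - a), names = FALSE),
              redraws = redraws)
  })
}

#' Event-level detection metrics at a score threshold
#'
#' Thresholds window scores (predicted positive when `score >= threshold`)
#' and computes, per the alarm semantics: overall data reduction = share
#' of windows predicted negative; event sensitivity = share of (merged)
#' events with at least one predicted-positive overlapping window;
#' precision = share of predicted-positive windows that overlap any event
#' (window-level numerator). All three in percent.
#'
#' @param scores window scores aligned with `meta` rows.
#' @param meta data.frame with `subject`, `day`, `start_s` per window.
#' @param events data.frame with `subject`, `day`, `t_start_s`, `t_end_s`.
#' @param window_s window length, s.
#' @param threshold classification threshold (default 0.5).
#' @return list of class `lob_event_metrics`: `data_reduction_pct`,
#'   `event_sensitivity_pct`, `precision_pct`, `n_events`, `n_windows`,
#'   `n_positive_pred`, `precision_defined`.
#' @export
event_level_metrics <- function(scores, meta, events, window_s = 10,
                                threshold = 0.5) {
  stopifnot(length(scores) == nrow(meta))
  if (NROW(events) > 0 && !all(c("subject", "day") %in% names(events)))
    events <- data.frame(subject = meta$subject[1], day = meta$day[1],
                         t_start_s = events$t_start_s,
                         t_end_s = events$t_end_s)
  if (NROW(events) > 0)
    events <- merge_lob_events(lob_events(events$subject, events$day,
                                          events$t_start_s, events$t_end_s))
  pred <- scores >= threshold
  nw <- length(scores)
  win_key <- paste(meta$subject, meta$day, sep = "\r")
  win_hits_event <- rep(FALSE, nw)
  detected <- rep(FALSE, NROW(events))
  for (i in seq_len(NROW(events))) {
    in_day <- win_key == paste(events$subject[i], events$day[i], sep = "\r")
    ov <- in_day & meta$start_s < events$t_end_s[i] &
      meta$start_s + window_s > events$t_start_s[i]
    win_hits_event <- win_hits_event | ov
    detected[i] <- any(ov & pred)
  }
  npp <- sum(pred)
  structure(list(
    data_reduction_pct = 100 * mean(!pred),
    event_sensitivity_pct = if (NROW(events) > 0) 100 * mean(detected) else NA_real_,
    precision_pct = if (npp > 0) 100 * sum(pred & win_hits_event) / npp else 0,
    n_events = NROW(events), n_windows = nw, n_positive_pred = npp,
    precision_defined = npp > 0), class = "lob_event_metrics")
}

#' @export
print.lob_event_metrics <- function(x, ...) {
  cat(sprintf(
    "<event metrics> reduction %.1f%%, sensitivity %s, precision %.2f%%%s (%d events, %d windows)\n",
    x$data_reduction_pct,
    if (is.na(x$event_sensitivity_pct)) "NA" else
      sprintf("%.1f%%", x$event_sensitivity_pct),
    x$precision_pct,
    if (x$precision_defined) "" else " [no positive predictions]",
    x$n_events, x$n_windows))
  invisible(x)
}

#' Grouped permutation feature importance
#'
#' Permutes each feature group's columns jointly across examples (one
#' example permutation applied to every context step of every feature in
#' the group) and reports the mean drop in AUROC and AUPR over repeats,
#' with ranks under each metric (rank 1 = largest drop). Grouping
#' correlated features avoids the importance-dampening that per-feature
#' permutation suffers when the same information survives in correlated,
#' unpermuted columns.
#'
#' @param model a fitted `lob_model` (predict must accept the flat
#'   sequence matrix).
#' @param x flat sequence matrix (already standardized like the training
#'   data).
#' @param labels 0/1 labels.
#' @param groups named list of feature-name vectors
#'   (default [lob_feature_groups()]).
#' @param feature_names per-step feature names (default
#'   [lob_feature_names()]).
#' @param repeats permutations per group (default 10).
#' @param seed integer seed.
#' @return data.frame of class `lob_importance`: `group`, `d_auroc`,
#'   `d_aupr`, `rank_auroc`, `rank_aupr`.
#' @export
grouped_permutation_importance <- function(model, x, labels,
                                           groups = lob_feature_groups(),
                                           feature_names = lob_feature_names(),
                                           repeats = 10, seed = 1) {
  if (length(unique(labels)) < 2) stop("test set must contain both classes")
  nf <- length(feature_names)
  steps <- ncol(x) %/% nf
  base_roc <- auroc(predict(model, x), labels)
  base_pr <- aupr(predict(model, x), labels)
  n <- nrow(x)
  res <- with_seed(seed, {
    lapply(names(groups), function(g) {
      cols <- as.vector(outer((seq_len(steps) - 1) * nf,
                              match(groups[[g]], feature_names), `+`))
      dr <- dp <- numeric(repeats)
      for (r in seq_len(repeats)) {
        perm <- sample.int(n)
        xp <- x
        xp[, cols] <- x[perm, cols]
        sc <- predict(model, xp)
        dr[r] <- base_roc - auroc(sc, labels)
        dp[r] <- base_pr - aupr(sc, labels)
      }
      data.frame(group = g, d_auroc = mean(dr), d_aupr = mean(dp))
    })
  })
  out <- do.call(rbind, res)
  out$rank_auroc <- rank(-out$d_auroc, ties.method = "first")
  out$rank_aupr <- rank(-out$d_aupr, ties.method = "first")
  class(out) <- c("lob_importance", "data.frame")
  out
}

#' Paired comparison of two models' per-subject scores
#'
#' Two-sided paired Wilcoxon signed-rank test over per-held-out-subject
#' metric values (exact when the differences are tie-free).
#'
#' @param metric_a,metric_b paired per-subject values (same subjects, same
#'   order).
#' @return two-sided p-value.
#' @export
compare_models <- function(metric_a, metric_b) {
  stopifnot(length(metric_a) == length(metric_b))
  d <- metric_a - metric_b
  if (all(d == 0)) return(1)
  suppressWarnings(
    stats::wilcox.test(metric_a, metric_b, paired = TRUE,
                       exact = TRUE)$p.value)
}
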