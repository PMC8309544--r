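# Leave-one-participant-out training and evaluation pipeline.

#' Run the full leave-one-subject-out protocol
#'
#' For each fold: feature standardization constants are computed from the
#' training subjects' windows only, context sequences are built per
#' subject-day, the classifier is trained on the training subjects'
#' sequences (up-sampled to 1:1 balance), and the held-out subject's
#' sequences are scored. Reports per fold the window-level AUROC/AUPR with
#' 200-resample bootstrap confidence intervals, the positive-label
#' incidence, and the event-level metrics at the given threshold. The
#' held-out subject contributes to neither standardization nor training.
#'
#' @param feat a `lob_features` for the whole cohort (with `events`).
#' @param architecture `"bilstm"` or `"logistic"`.
#' @param cells,l1,l2,learning_rate,epochs,batch_size model configuration
#'   (defaults are the selected-model settings for each architecture).
#' @param context context windows per side (default 5).
#' @param threshold event-level classification threshold (default 0.5).
#' @param bootstrap_B bootstrap resamples for CIs (default 200).
#' @param seed master seed; per-fold seeds are derived from it.
#' @return object of class `lob_loso`: `summary` (one row per held-out
#'   subject), `folds` (per-fold details incl. scores), `architecture`,
#'   `threshold`, `seed`.
#' @export
run_loso <- function(feat, architecture = c("bilstm", "logistic"),
                     cells = 2L, l1 = NULL, l2 = NULL,
                     learning_rate = 1e-4, epochs = 50L, batch_size = 256L,
                     context = 5L, threshold = 0.5, bootstrap_B = 200L,
                     seed = 1) {
  architecture <- match.arg(architecture)
  if (is.null(l1)) l1 <- if (architecture == "bilstm") 0.1 else 0.01
  if (is.null(l2)) l2 <- if (architecture == "bilstm") 0.001 else 1e-5
  folds <- loso_folds(feat$meta$subject)
  fold_out <- list()
  rows <- list()
  for (fi in seq_along(folds)) {
    f <- folds[[fi]]
    std <- feature_standardizer(feat, f$train)
    sfeat <- feat
    sfeat$x <- apply_standardizer(feat$x, std)
    seqs <- build_context_sequences(sfeat, context = context)
    tr <- seqs$meta$subject %in% f$train
    te <- seqs$meta$subject == f$test
    fseed <- derive_seed(seed, fi, 0)
    model <- if (architecture == "bilstm") {
      lob_bilstm(seqs$x[tr, , drop = FALSE], seqs$meta$label[tr],
                 n_features = seqs$n_features, cells = cells, l1 = l1,
                 l2 = l2, learning_rate = learning_rate, epochs = epochs,
                 batch_size = batch_size, seed = fseed)
    } else {
      lob_logistic(seqs$x[tr, , drop = FALSE], seqs$meta$label[tr],
                   l1 = l1, l2 = l2, seed = fseed)
    }
    scores <- predict(model, seqs$x[te, , drop = FALSE])
    yte <- seqs$meta$label[te]
    meta_te <- seqs$meta[te, , drop = FALSE]
    ev <- feat$events[feat$events$subject == f$test, , drop = FALSE]
    roc <- auroc(scores, yte)
    pr <- aupr(scores, yte)
    ci_roc <- bootstrap_ci(auroc, scores, yte, B = bootstrap_B,
                           seed = derive_seed(seed, fi, 1))
    ci_pr <- bootstrap_ci(aupr, scores, yte, B = bootstrap_B,
                          seed = derive_seed(seed, fi, 2))
    evm <- event_level_metrics(scores, meta_te, ev,
                               window_s = feat$window_s,
                               threshold = threshold)
    rows[[fi]] <- data.frame(
      subject = f$test, n_windows = sum(te), incidence = mean(yte),
      auroc = roc, auroc_lo = ci_roc[1], auroc_hi = ci_roc[2],
      aupr = pr, aupr_lo = ci_pr[1], aupr_hi = ci_pr[2],
      data_reduction_pct = evm$data_reduction_pct,
      event_sensitivity_pct = evm$event_sensitivity_pct,
      precision_pct = evm$precision_pct, n_events = evm$n_events)
    fold_out[[fi]] <- list(test = f$test, model = model, scores = scores,
                           labels = yte, meta = meta_te, events = ev,
                           standardizer = std, event_metrics = evm)
  }
  summary_df <- do.call(rbind, rows)
  rownames(summary_df) <- NULL
  structure(list(summary = summary_df, folds = fold_out,
                 architecture = architecture, threshold = threshold,
                 seed = seed),
            class = "lob_loso")
}

#' @export
print.lob_loso <- function(x, ...) {
  cat(sprintf("<lob_loso> %s, %d held-out subjects (threshold %.2f)\n",
              x$architecture, nrow(x$summary), x$threshold))
  df <- x$summary
  df$incidence <- sprintf("%.3f%%", 100 * df$incidence)
  print(df[, c("subject", "incidence", "auroc", "aupr",
               "data_reduction_pct", "event_sensitivity_pct",
               "precision_pct")],
        digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
summary.lob_loso <- function(object, ...) {
  s <- object$summary
  out <- list(
    architecture = object$architecture,
    min_auroc = min(s$auroc), mean_auroc = mean(s$auroc),
    mean_aupr = mean(s$aupr),
    mean_event_sensitivity_pct = mean(s$event_sensitivity_pct, na.rm = TRUE),
    min_data_reduction_pct = min(s$data_reduction_pct),
    mean_precision_pct = mean(s$precision_pct))
  class(out) <- "summary.lob_loso"
  out
}

#' @export
print.summary.lob_loso <- function(x, ...) {
  cat(sprintf(
    paste0("%s across held-out subjects:\n",
           "  AUROC            min %.3f  mean %.3f\n",
           "  AUPR             mean %.4f\n",
           "  event sensitivity mean %.1f%%\n",
           "  data reduction    min %.1f%%\n",
           "  precision         mean %.2f%%\n"),
    x$architecture, x$min_auroc, x$mean_auroc, x$mean_aupr,
    x$mean_event_sensitivity_pct, x$min_data_reduction_pct,
    x$mean_precision_pct))
  invisible(x)
}

#' Export a per-fold evaluation report (JSON) and cross-fold summary (CSV)
#'
#' @param res a `lob_loso`.
#' @param json_path,csv_path output paths (either may be `NULL`).
#' @return invisibly, a list of written paths.
#' @export
write_eval_report <- function(res, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    obj <- list(architecture = res$architecture, threshold = res$threshold,
                seed = res$seed, folds = res$summary)
    jsonlite::write_json(obj, json_path, digits = NA, auto_unbox = TRUE,
                         dataframe = "rows")
  }
  if (!is.null(csv_path))
    utils::write.csv(res$summary, csv_path, row.names = FALSE)
  invisible(list(json = json_path, csv = csv_path))
}
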