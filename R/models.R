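# Context sequences, class re-balancing and the two classifiers.
#
# Each training/evaluation example is the feature-vector sequence of the
# 11 windows t-5 .. t+5 around a center window; the label is the center
# window's. The linear model consumes the flat 352-entry concatenation,
# the BiLSTM the 11 x 32 sequence. Sequences are stored flat, time-major
# (block 0 = window t-5), and reshaped inside the BiLSTM.

#' Build context sequences for labeled windows
#'
#' One sequence per center window with `context` full neighbors on each
#' side within the same subject-day; the first and last `context` windows
#' of every day produce no sequence (no kinematics is fabricated by
#' padding). Days with fewer than `2*context + 1` windows yield no
#' sequences, with a warning.
#'
#' @param feat a `lob_features` (optionally standardized via
#'   [apply_standardizer()] on `feat$x`).
#' @param context neighbors per side (default 5).
#' @return list of class `lob_sequences`: `x` (N x (2*context+1)*32 flat
#'   matrix, time-major), `meta` (center-window metadata incl. `label`),
#'   `context`, `n_features`.
#' @export
build_context_sequences <- function(feat, context = 5L) {
  steps <- -context:context
  xs <- list(); metas <- list()
  key <- paste(feat$meta$subject, feat$meta$day, sep = "\r")
  for (k in unique(key)) {
    rows <- which(key == k)
    nw <- length(rows)
    if (nw < 2 * context + 1) {
      warning("day with ", nw, " windows yields no context sequences")
      next
    }
    centers <- rows[(context + 1):(nw - context)]
    blocks <- lapply(steps, function(o) feat$x[centers + o, , drop = FALSE])
    xs[[k]] <- do.call(cbind, blocks)
    metas[[k]] <- feat$meta[centers, , drop = FALSE]
  }
  if (length(xs) == 0) {
    nf <- ncol(feat$x)
    return(structure(list(x = matrix(0, 0, (2 * context + 1) * nf),
                          meta = feat$meta[0, , drop = FALSE],
                          context = context, n_features = nf),
                     class = "lob_sequences"))
  }
  meta <- do.call(rbind, metas)
  rownames(meta) <- NULL
  structure(list(x = do.call(rbind, xs), meta = meta, context = context,
                 n_features = ncol(feat$x)),
            class = "lob_sequences")
}

#' Flatten a single context sequence
#'
#' Concatenates the per-step feature vectors in time order (t-5 first)
#' into one flat vector, the linear model's input layout.
#'
#' @param seq_mat matrix with one row per time step.
#' @return numeric vector of length `nrow * ncol`.
#' @export
flatten_for_linear <- function(seq_mat) as.vector(t(seq_mat))

#' Reshape a flat sequence back to steps x features
#' @param flat flat vector from [flatten_for_linear()].
#' @param n_features features per step.
#' @return matrix with one row per time step.
#' @export
unflatten_sequence <- function(flat, n_features) {
  matrix(flat, ncol = n_features, byrow = TRUE)
}

#' Up-sample positives to a 1:1 class balance
#'
#' Returns example indices in which every negative appears once and the
#' positives are duplicated by whole cycles, with the remainder drawn
#' without replacement by a seeded RNG, until the positive count equals
#' the negative count. Negatives are never subsampled. Already-balanced
#' (or positive-heavy) inputs are returned unchanged.
#'
#' @param labels 0/1 vector.
#' @param seed integer seed for the remainder draw.
#' @return integer vector of indices into `labels`.
#' @export
upsample_balance <- function(labels, seed = 1) {
  pos <- which(labels == 1); neg <- which(labels != 1)
  if (length(pos) == 0) stop("cannot balance: no positive examples")
  if (length(neg) == 0) stop("cannot balance: no negative examples")
  if (length(pos) >= length(neg)) return(seq_along(labels))
  reps <- length(neg) %/% length(pos)
  rem <- length(neg) - reps * length(pos)
  extra <- if (rem > 0) with_seed(seed, sample(pos, rem)) else integer()
  c(neg, rep(pos, reps), extra)
}

clamp_prob <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)

bce_loss <- function(p, y) {
  p <- clamp_prob(p)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Fit the regularized logistic-regression classifier
#'
#' Minimizes mean binary cross-entropy plus `l1*|w|_1 + l2*|w|_2^2` on the
#' flat 352-entry context vectors (elastic-net logistic regression; the
#' penalty pair maps exactly onto glmnet's `(lambda, alpha)`
#' parameterization). Training data are up-sampled to 1:1 class balance
#' first.
#'
#' @param x flat sequence matrix (rows = examples), already standardized.
#' @param y 0/1 labels.
#' @param l1,l2 penalty weights (defaults are the selected-model values
#'   0.01 and 1e-5).
#' @param upsample balance classes before fitting.
#' @param seed seed for the up-sampling remainder draw.
#' @return object of class `c("lob_logistic", "lob_model")`.
#' @export
lob_logistic <- function(x, y, l1 = 0.01, l2 = 1e-5, upsample = TRUE,
                         seed = 1) {
  stopifnot(l1 >= 0, l2 >= 0)
  idx <- if (upsample) upsample_balance(y, seed) else seq_along(y)
  xt <- x[idx, , drop = FALSE]; yt <- y[idx]
  # all-constant predictors: the penalized optimum is intercept-only at the
  # class prior (glmnet refuses such inputs outright)
  if (all(apply(xt, 2, function(col) max(col) == min(col)))) {
    return(structure(list(fit = NULL, intercept = stats::qlogis(mean(yt)),
                          l1 = l1, l2 = l2, n_inputs = ncol(x), seed = seed),
                     class = c("lob_logistic", "lob_model")))
  }
  lambda <- l1 + 2 * l2
  alpha <- if (lambda > 0) l1 / lambda else 0
  fit <- glmnet::glmnet(xt, yt, family = "binomial", alpha = alpha,
                        lambda = max(lambda, 1e-10), standardize = FALSE)
  if (!all(is.finite(as.numeric(fit$beta))))
    stop("non-finite loss in logistic fit")
  structure(list(fit = fit, l1 = l1, l2 = l2, n_inputs = ncol(x),
                 seed = seed),
            class = c("lob_logistic", "lob_model"))
}

#' @export
predict.lob_logistic <- function(object, newx, ...) {
  if (is.null(object$fit))
    return(rep(stats::plogis(object$intercept), nrow(newx)))
  as.numeric(predict(object$fit, newx, type = "response"))
}

#' @export
coef.lob_logistic <- function(object, ...) {
  cf <- if (is.null(object$fit)) c(object$intercept, numeric(object$n_inputs))
        else as.numeric(stats::coef(object$fit))
  names(cf) <- c("(Intercept)", paste0("x", seq_len(object$n_inputs)))
  cf
}

#' @export
print.lob_logistic <- function(x, ...) {
  cf <- coef(x)[-1]
  cat(sprintf("<lob_logistic> %d inputs, l1=%g l2=%g, %d nonzero weights\n",
              x$n_inputs, x$l1, x$l2, sum(cf != 0)))
  invisible(x)
}

#' Fit the bidirectional LSTM classifier
#'
#' A forward and a backward LSTM (each with `cells` hidden units) read the
#' 11-step context sequence; their final hidden states are concatenated
#' and mapped through one dense sigmoid unit. Training minimizes mean
#' binary cross-entropy plus L1/L2 penalties on the input, recurrent and
#' dense weights (biases excluded) with Adam. The positive class is
#' re-up-sampled to 1:1 balance each epoch with a fresh seeded draw;
#' batches are reshuffled each epoch. Fully deterministic given
#' `(data, config, seed)`.
#'
#' @param x flat sequence matrix, time-major (rows = examples), already
#'   standardized.
#' @param y 0/1 labels.
#' @param n_features features per time step (default 32; the number of
#'   steps is inferred as `ncol(x)/n_features`).
#' @param cells hidden units per direction (selected model: 2).
#' @param l1,l2 penalty weights (selected model: 0.1 and 0.001).
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param epochs training epochs (default 50).
#' @param batch_size minibatch size (default 256).
#' @param bidirectional `FALSE` fits a forward-only LSTM baseline.
#' @param upsample balance classes each epoch.
#' @param seed integer seed for initialization, shuffling and up-sampling.
#' @param restarts maximum deterministic re-initializations if training
#'   collapses to the dead all-zero-weight solution of the L1 penalty
#'   (constant 0.5 output, balanced-loss at log 2); each restart derives
#'   its seed from `seed`, so the fit remains reproducible.
#' @return object of class `c("lob_bilstm", "lob_model")` with elements
#'   `weights` (named list), `log` (per-epoch training loss), `restarts`
#'   (re-initializations used) and the configuration.
#' @export
lob_bilstm <- function(x, y, n_features = 32L, cells = 2L, l1 = 0.1,
                       l2 = 0.001, learning_rate = 1e-4, epochs = 50L,
                       batch_size = 256L, bidirectional = TRUE,
                       upsample = TRUE, seed = 1, restarts = 5L) {
  stopifnot(ncol(x) %% n_features == 0, l1 >= 0, l2 >= 0, cells >= 1)
  steps <- ncol(x) %/% n_features
  # with a strong L1 penalty the all-zero weight vector is a stationary
  # point (constant 0.5 output); an unlucky initialization can converge
  # there, which the final balanced loss pinning at log(2) reveals
  collapsed <- function(res) {
    wmax <- max(vapply(res$weights[grep("^W|^w", names(res$weights))],
                       function(w) max(abs(w)), numeric(1)))
    tail(res$loss, 1) >= log(2) - 1e-3 && wmax < 1e-2
  }
  used_seed <- as.integer(seed)
  for (attempt in 0:restarts) {
    res <- bilstm_train_cpp(as.matrix(x), as.numeric(y), as.integer(steps),
                            as.integer(n_features), as.integer(cells),
                            l1, l2, learning_rate, as.integer(epochs),
                            as.integer(batch_size), isTRUE(bidirectional),
                            isTRUE(upsample), used_seed)
    if (!(isTRUE(upsample) && l1 > 0 && collapsed(res))) break
    if (attempt < restarts)
      used_seed <- derive_seed(seed, attempt + 1L, 0L)
  }
  if (attempt > 0 && isTRUE(upsample) && l1 > 0 && collapsed(res))
    warning("training collapsed to the dead L1 solution in every restart")
  structure(list(weights = res$weights,
                 log = data.frame(epoch = seq_len(epochs), loss = res$loss),
                 n_features = n_features, steps = steps, cells = cells,
                 l1 = l1, l2 = l2, learning_rate = learning_rate,
                 epochs = epochs, batch_size = batch_size,
                 bidirectional = isTRUE(bidirectional), seed = seed,
                 restarts = attempt),
            class = c("lob_bilstm", "lob_model"))
}

#' @export
predict.lob_bilstm <- function(object, newx, ...) {
  as.numeric(bilstm_predict_cpp(object$weights, as.matrix(newx),
                                as.integer(object$steps),
                                as.integer(object$n_features),
                                as.integer(object$cells),
                                object$bidirectional))
}

#' @export
print.lob_bilstm <- function(x, ...) {
  cat(sprintf(
    "<lob_bilstm> %s, %d cells, %d steps x %d features, l1=%g l2=%g, final loss %.4f\n",
    if (x$bidirectional) "bidirectional" else "forward-only",
    x$cells, x$steps, x$n_features, x$l1, x$l2,
    tail(x$log$loss, 1)))
  invisible(x)
}

#' Serialize a trained model to JSON
#'
#' Portable checkpoint: architecture tag, configuration, weights and
#' (optionally) the feature-standardization constants.
#'
#' @param model a `lob_bilstm` or `lob_logistic`.
#' @param path output path.
#' @param standardizer optional list from [feature_standardizer()].
#' @return `path`, invisibly.
#' @export
write_lob_model <- function(model, path, standardizer = NULL) {
  if (inherits(model, "lob_bilstm")) {
    obj <- list(architecture = "bilstm",
                config = model[c("n_features", "steps", "cells", "l1", "l2",
                                 "learning_rate", "epochs", "batch_size",
                                 "bidirectional", "seed")],
                weights = model$weights, standardizer = standardizer)
  } else if (inherits(model, "lob_logistic")) {
    obj <- list(architecture = "logistic",
                config = model[c("l1", "l2", "n_inputs", "seed")],
                coef = coef(model), standardizer = standardizer)
  } else stop("unsupported model class")
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a BiLSTM checkpoint written by [write_lob_model()]
#'
#' @param path JSON path.
#' @return for a BiLSTM checkpoint, a `lob_bilstm` usable with `predict`;
#'   for a logistic checkpoint, a list with the coefficients and config.
#' @export
read_lob_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (obj$architecture == "bilstm") {
    w <- lapply(obj$weights, function(m) if (is.list(m)) unlist(m) else m)
    w <- lapply(w, as.matrix)
    cfg <- obj$config
    structure(list(weights = w, log = NULL,
                   n_features = cfg$n_features, steps = cfg$steps,
                   cells = cfg$cells, l1 = cfg$l1, l2 = cfg$l2,
                   learning_rate = cfg$learning_rate, epochs = cfg$epochs,
                   batch_size = cfg$batch_size,
                   bidirectional = cfg$bidirectional, seed = cfg$seed,
                   standardizer = obj$standardizer),
              class = c("lob_bilstm", "lob_model"))
  } else obj
}

#' Leave-one-subject-out folds
#'
#' @param subjects vector of subject ids (>= 2 distinct).
#' @return list of folds, each `list(test, train)`; every subject is the
#'   test subject exactly once.
#' @export
loso_folds <- function(subjects) {
  u <- unique(as.character(subjects))
  if (length(u) < 2) stop("leave-one-subject-out requires at least 2 subjects")
  lapply(u, function(s) list(test = s, train = setdiff(u, s)))
}

#' The hyperparameter search grid
#'
#' L1 and L2 penalties over 1e-5..1e-1 (decades) and, for the BiLSTM, cell
#' counts 2, 5, 10, enumerated deterministically.
#'
#' @param architecture `"bilstm"` or `"logistic"`.
#' @return data.frame with columns `l1`, `l2` and (bilstm) `cells`.
#' @export
hyperparameter_grid <- function(architecture = c("bilstm", "logistic")) {
  architecture <- match.arg(architecture)
  pen <- 10^(-5:-1)
  if (architecture == "bilstm")
    expand.grid(l1 = pen, l2 = pen, cells = c(2L, 5L, 10L))
  else expand.grid(l1 = pen, l2 = pen)
}

#' Select hyperparameters by inner leave-one-subject-out validation
#'
#' For every grid row, trains on all-but-one training subject and scores
#' the held-out subject's examples, cycling through the training subjects;
#' returns the configuration with the lowest mean validation binary
#' cross-entropy. Ties break toward larger penalties, then fewer cells.
#'
#' @param x example matrix (rows aligned with `y` and `subjects`).
#' @param y 0/1 labels.
#' @param subjects subject id per example (>= 2 distinct).
#' @param grid data.frame of candidate configurations.
#' @param trainer `function(x, y, cfg, seed)` returning an object whose
#'   `predict(model, x)` yields probabilities.
#' @param seed base seed passed to the trainer.
#' @return list `config` (the winning grid row), `losses` (per-config mean
#'   validation loss).
#' @export
select_hyperparameters <- function(x, y, subjects, grid, trainer, seed = 1) {
  folds <- loso_folds(subjects)
  losses <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cfg <- grid[g, , drop = FALSE]
    fold_loss <- vapply(seq_along(folds), function(fi) {
      f <- folds[[fi]]
      tr <- subjects %in% f$train
      if (sum(y[tr] == 1) == 0 || sum(y[!tr]) == length(y[!tr])) return(NA_real_)
      m <- trainer(x[tr, , drop = FALSE], y[tr], cfg,
                   seed = derive_seed(seed, g, fi))
      bce_loss(predict(m, x[!tr, , drop = FALSE]), y[!tr])
    }, numeric(1))
    losses[g] <- mean(fold_loss, na.rm = TRUE)
  }
  ord <- order(losses, -grid$l1, -grid$l2,
               if ("cells" %in% names(grid)) grid$cells else seq_len(nrow(grid)))
  list(config = grid[ord[1], , drop = FALSE],
       losses = cbind(grid, loss = losses))
}
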