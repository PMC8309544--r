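# Context sequences, up-sampling, the two classifiers, LOSO machinery.

feat_stub <- function(n_windows, subject = "S1", day = "D01", nf = 3) {
  list(meta = data.frame(subject = subject, day = day,
                         t = seq_len(n_windows) - 1L,
                         start_s = (seq_len(n_windows) - 1L) * 2,
                         label = rep(0L, n_windows)),
       x = matrix(seq_len(n_windows * nf), n_windows, nf))
}

test_that("context-sequence counts drop edge windows", {
  expect_equal(nrow(build_context_sequences(feat_stub(26))$x), 16)
  s <- build_context_sequences(feat_stub(11))
  expect_equal(nrow(s$x), 1)
  expect_equal(s$meta$t, 5L) # centered at t = 5
  expect_warning(s0 <- build_context_sequences(feat_stub(10)),
                 "no context sequences")
  expect_equal(nrow(s0$x), 0)
})

test_that("sequences are flat, time-major, with block 0 = window t-5", {
  f <- feat_stub(11, nf = 3)
  s <- build_context_sequences(f)
  expect_equal(ncol(s$x), 11 * 3)
  expect_equal(s$x[1, 1:3], f$x[1, ]) # block 0 is the t-5 window
  expect_equal(s$x[1, 31:33], f$x[11, ]) # last block is t+5
  # 32 features x 11 steps gives the 352-entry linear input
  f32 <- feat_stub(15, nf = 32)
  expect_equal(ncol(build_context_sequences(f32)$x), 352)
  # flatten/unflatten round trip preserves step order
  m <- matrix(rnorm(33), 11, 3)
  expect_equal(unflatten_sequence(flatten_for_linear(m), 3), m)
  rep_vec <- flatten_for_linear(matrix(rep(c(1, 2, 3), each = 11), 11, 3))
  expect_equal(rep_vec, rep(c(1, 2, 3), times = 11))
})

test_that("sequences never span subject-day boundaries", {
  fa <- feat_stub(15, subject = "S1")
  fb <- feat_stub(15, subject = "S2")
  f <- list(meta = rbind(fa$meta, fb$meta), x = rbind(fa$x, fb$x + 1000))
  s <- build_context_sequences(f)
  expect_equal(nrow(s$x), 10)
  # every sequence's 11 blocks come from one subject's matrix
  expect_true(all(s$x[s$meta$subject == "S1", ] <= 45))
  expect_true(all(s$x[s$meta$subject == "S2", ] > 1000))
})

test_that("up-sampling duplicates positives to exact 1:1 balance", {
  y <- c(rep(1, 3), rep(0, 9))
  idx <- upsample_balance(y, seed = 1)
  expect_equal(sum(y[idx] == 1), 9)
  expect_equal(sum(y[idx] == 0), 9)
  expect_equal(as.integer(table(idx[y[idx] == 1])), rep(3L, 3)) # each original x3
  # negatives are untouched: each appears exactly once
  expect_equal(sort(idx[y[idx] == 0]), which(y == 0))
  # already balanced: unchanged
  expect_equal(upsample_balance(c(1, 0), seed = 1), 1:2)
  expect_error(upsample_balance(c(0, 0)), "cannot balance")
})

test_that("logistic classifier separates a separable toy set", {
  set.seed(101)
  n <- 60; p <- 8
  x <- rbind(matrix(rnorm(n * p, 1), n, p), matrix(rnorm(n * p, -1), n, p))
  y <- rep(c(1, 0), each = n)
  m <- lob_logistic(x, y, l1 = 1e-6, l2 = 1e-6)
  expect_equal(auroc(predict(m, x), y), 1.0)
})

test_that("logistic on uninformative inputs falls back to the class prior", {
  x <- matrix(1, 40, 5)
  y <- rep(c(1, 0, 0, 0), 10)
  m <- lob_logistic(x, y, l1 = 0.01, l2 = 1e-5, upsample = FALSE)
  cf <- coef(m)
  expect_true(all(abs(cf[-1]) < 1e-8))
  expect_equal(unname(predict(m, x)[1]), 0.25, tolerance = 1e-6)
})

test_that("stronger l1 never reduces sparsity", {
  set.seed(102)
  x <- matrix(rnorm(200 * 10), 200, 10)
  y <- as.numeric(x[, 1] + 0.5 * x[, 2] + rnorm(200, 0, 0.5) > 0)
  nz <- function(l1) {
    m <- lob_logistic(x, y, l1 = l1, l2 = 1e-5, upsample = FALSE)
    sum(coef(m)[-1] == 0)
  }
  zeros <- vapply(c(0.01, 0.02, 0.04, 0.08), nz, numeric(1))
  expect_true(all(diff(zeros) >= 0))
})

test_that("BPTT gradients agree with finite differences", {
  set.seed(103)
  T <- 4; D <- 3; H <- 2; B <- 6
  x <- matrix(rnorm(B * T * D), B, T * D)
  y <- c(1, 0, 1, 0, 0, 1)
  m <- lob_bilstm(x, y, n_features = D, cells = H, l1 = 0, l2 = 0,
                  learning_rate = 1e-3, epochs = 1, batch_size = B, seed = 2)
  w <- m$weights
  g <- bilstm_grad_cpp(w, x, y, T, D, H, TRUE)
  lossfn <- function(w) {
    p <- bilstm_predict_cpp(w, x, T, D, H, TRUE)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
  eps <- 1e-6
  for (nm in c("WxF", "WhF", "bF", "WxB", "WhB", "bB", "wout")) {
    num <- w[[nm]] * 0
    for (i in seq_along(w[[nm]])) {
      wp <- w; wp[[nm]][i] <- wp[[nm]][i] + eps
      wm <- w; wm[[nm]][i] <- wm[[nm]][i] - eps
      num[i] <- (lossfn(wp) - lossfn(wm)) / (2 * eps)
    }
    expect_lt(max(abs(num - g[[paste0("d", nm)]])), 1e-6)
  }
})

test_that("BiLSTM training is bit-identical for a fixed seed", {
  set.seed(104)
  x <- matrix(rnorm(80 * 22), 80, 22)
  y <- rep(c(0, 1), 40)
  m1 <- lob_bilstm(x, y, n_features = 2, cells = 2, epochs = 3,
                   batch_size = 16, seed = 9)
  m2 <- lob_bilstm(x, y, n_features = 2, cells = 2, epochs = 3,
                   batch_size = 16, seed = 9)
  expect_identical(m1$weights, m2$weights)
  expect_identical(predict(m1, x), predict(m2, x))
  m3 <- lob_bilstm(x, y, n_features = 2, cells = 2, epochs = 3,
                   batch_size = 16, seed = 10)
  expect_false(identical(m1$weights, m3$weights))
  # healthy fits use the primary initialization, no collapse restarts
  expect_equal(m1$restarts, 0)
})

test_that("BiLSTM learns a center-step rule through the sequence", {
  set.seed(105)
  T <- 11; D <- 4; N <- 2600
  x <- matrix(rnorm(N * T * D), N, T * D)
  y <- as.numeric(x[, 5 * D + 1] > 0) # center window, first feature
  tr <- 1:2000; te <- 2001:2600
  m <- lob_bilstm(x[tr, ], y[tr], n_features = D, cells = 2, l1 = 0,
                  l2 = 1e-5, learning_rate = 0.01, epochs = 500,
                  batch_size = 128, seed = 3)
  expect_gt(auroc(predict(m, x[te, ]), y[te]), 0.95)
})

test_that("the backward direction captures early-context signal", {
  set.seed(106)
  T <- 11; D <- 4; N <- 1600
  x <- matrix(rnorm(N * T * D), N, T * D)
  y <- as.numeric(x[, 1] > 0) # first step (t-5): read last by the backward pass
  tr <- 1:1000; te <- 1001:1600
  args <- list(n_features = D, cells = 2, l1 = 0, l2 = 1e-5,
               learning_rate = 0.01, epochs = 200, batch_size = 128, seed = 3)
  bi <- do.call(lob_bilstm, c(list(x[tr, ], y[tr]), args))
  fw <- do.call(lob_bilstm, c(list(x[tr, ], y[tr]), args,
                              list(bidirectional = FALSE)))
  a_bi <- auroc(predict(bi, x[te, ]), y[te])
  a_fw <- auroc(predict(fw, x[te, ]), y[te])
  expect_gt(a_bi, 0.9)
  expect_lte(a_fw, a_bi)
})

test_that("BiLSTM checkpoints round-trip through JSON", {
  set.seed(107)
  x <- matrix(rnorm(40 * 22), 40, 22)
  y <- rep(c(0, 1), 20)
  m <- lob_bilstm(x, y, n_features = 2, cells = 2, epochs = 2,
                  batch_size = 8, seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_lob_model(m, path, standardizer = list(center = 1:2, scale = c(1, 1)))
  back <- read_lob_model(path)
  expect_equal(predict(back, x), predict(m, x), tolerance = 1e-12)
})

test_that("LOSO folds hold each subject out exactly once", {
  f <- loso_folds(rep(paste0("S", 1:8), each = 3))
  expect_length(f, 8)
  expect_setequal(vapply(f, `[[`, "", "test"), paste0("S", 1:8))
  for (fi in f) {
    expect_length(fi$train, 7)
    expect_length(intersect(fi$test, fi$train), 0)
  }
  expect_length(loso_folds(c("a", "b")), 2)
  expect_error(loso_folds("a"), "at least 2 subjects")
})

test_that("the hyperparameter grid contains the selected configurations", {
  g <- hyperparameter_grid("bilstm")
  expect_equal(nrow(g), 75)
  expect_true(any(g$l1 == 0.1 & g$l2 == 0.001 & g$cells == 2))
  gl <- hyperparameter_grid("logistic")
  expect_equal(nrow(gl), 25)
  expect_true(any(gl$l1 == 0.01 & gl$l2 == 1e-5))
})

test_that("hyperparameter selection minimizes inner validation loss", {
  set.seed(108)
  n <- 120
  x <- matrix(rnorm(n * 2), n, 2)
  y <- rep(c(0, 1), n / 2)
  subjects <- rep(c("A", "B", "C"), each = n / 3)
  # stub trainer: predicts the truth when cfg$l1 equals a magic value,
  # else a constant 0.5
  trainer <- function(x, y, cfg, seed) {
    structure(list(magic = cfg$l1 == 1e-3), class = "stub_model")
  }
  assign("predict.stub_model",
         function(object, newx, ...) {
           if (object$magic) rep(c(0.02, 0.98), nrow(newx) / 2)
           else rep(0.5, nrow(newx))
         },
         envir = globalenv())
  on.exit(rm("predict.stub_model", envir = globalenv()), add = TRUE)
  grid <- expand.grid(l1 = 10^(-5:-1), l2 = 1e-3)
  sel <- select_hyperparameters(x, y, subjects, grid, trainer)
  expect_equal(sel$config$l1, 1e-3)
  # a one-row grid returns that row
  sel1 <- select_hyperparameters(x, y, subjects, grid[3, , drop = FALSE],
                                 trainer)
  expect_equal(sel1$config$l1, grid$l1[3])
})
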