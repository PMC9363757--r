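test_that("feature row <-> input matrix mapping is symmetric and invertible", {
  expect_equal(reshape_to_input(rep(0, 528)), matrix(0, 32, 32),
               ignore_attr = TRUE)
  set.seed(61)
  row <- c(runif(32), runif(496))
  m <- reshape_to_input(row)
  expect_equal(m, t(m))
  expect_equal(input_to_row(m), row)
  # planted pair value lands symmetrically
  chans <- montage32_channels()
  pr <- channel_pairs(chans)
  k <- which(pr$i == 3 & pr$j == 7)
  row2 <- rep(0, 528); row2[32 + k] <- 0.9
  m2 <- reshape_to_input(row2)
  expect_equal(m2[3, 7], 0.9)
  expect_equal(m2[7, 3], 0.9)
  expect_error(reshape_to_input(rep(0, 527)), "528")
})

test_that("MCNN and LeNet-5 build with consistent shape chains", {
  for (k in 2:3) {
    model <- build_mcnn(mcnn_config(n_classes = k, seed = 62))
    x <- array(0, dim = c(32, 32, 4, 1))
    fw <- mpeeg:::nn_forward(model, x)
    expect_equal(dim(fw$probs), c(4L, k))
    expect_true(all(is.finite(fw$probs)))
    lenet <- build_lenet5(k)
    fwl <- mpeeg:::nn_forward(lenet, x)
    expect_equal(dim(fwl$probs), c(4L, k))
  }
  # LeNet-5 is the smaller network
  expect_lt(mpeeg:::nn_count_params(build_lenet5(2)),
            mpeeg:::nn_count_params(build_mcnn(mcnn_config(seed = 62))))
  # a broken shape chain is reported at construction/probe time
  expect_error(mpeeg:::.probe_width(list(mpeeg:::nn_conv(1, 4, 40, 40)), 32),
               "shape chain")
})

test_that("residual block reduces to identity with zeroed weights", {
  set.seed(63)
  model <- build_mcnn(mcnn_config(seed = 63))
  res_idx <- which(vapply(model$branches[[1]], `[[`, character(1), "type") ==
                     "residual")
  for (j in seq_along(model$branches[[1]][[res_idx]]$body)) {
    model$branches[[1]][[res_idx]]$body[[j]]$W[] <- 0
    model$branches[[1]][[res_idx]]$body[[j]]$b[] <- 0
  }
  x <- array(rnorm(12 * 12 * 2 * 16), dim = c(12, 12, 2, 16))
  r <- mpeeg:::nn_seq_forward(list(model$branches[[1]][[res_idx]]), x)
  expect_equal(r$out, x)
  # and the skip path is enforced shape-preserving
  bad <- mpeeg:::nn_residual(list(mpeeg:::nn_conv(16, 8, 5, 5, pad = 2)))
  expect_error(mpeeg:::nn_seq_forward(list(bad), x), "preserve shape")
})

test_that("one SGD step on nonzero-gradient data moves every tensor", {
  set.seed(64)
  cfg <- mcnn_config(max_epochs = 1, batch_size = 16, dropout_rate = 0,
                     seed = 64)
  model <- build_mcnn(cfg)
  before <- mpeeg:::nn_model_params(model)
  sep <- separable_rows(8, seed = 64)
  nrm <- normalize_features(sep$x)
  fit <- train_mcnn(model, nrm$x, sep$y, nrm$x[1:2, ], sep$y[1:2], cfg)
  after <- mpeeg:::nn_model_params(fit$model)
  moved <- mapply(function(a, b) max(abs(a - b)) > 0, before, after)
  expect_true(all(moved))
})

test_that("training is reproducible under a fixed seed", {
  sep <- separable_rows(10, seed = 65)
  nrm <- normalize_features(sep$x)
  cfg <- mcnn_config(max_epochs = 2, seed = 66)
  run <- function() {
    train_mcnn(build_mcnn(cfg), nrm$x[1:16, ], sep$y[1:16],
               nrm$x[17:20, ], sep$y[17:20], cfg)$history
  }
  expect_identical(run(), run())
})

test_that("MCNN reaches high validation accuracy on separable data", {
  sep <- separable_rows(40, seed = 67)
  nrm <- normalize_features(sep$x)
  set.seed(68)
  idx <- sample(80, 20)
  cfg <- mcnn_config(max_epochs = 3, seed = 68)
  fit <- train_mcnn(build_mcnn(cfg), nrm$x[-idx, ], sep$y[-idx],
                    nrm$x[idx, ], sep$y[idx], cfg)
  expect_gte(max(fit$history$val_acc), 0.95)
  expect_equal(nrow(fit$history), 3)
})

test_that("permuted labels keep MCNN at chance", {
  # validation set large enough that the binomial noise of a chance-level
  # classifier stays inside the 40-60% band with ~2 sigma to spare
  set.seed(69)
  sep <- separable_rows(100, seed = 69)
  y_perm <- sample(sep$y)
  nrm <- normalize_features(sep$x)
  idx <- sample(200, 100)
  cfg <- mcnn_config(max_epochs = 2, seed = 70)
  fit <- train_mcnn(build_mcnn(cfg), nrm$x[-idx, ], y_perm[-idx],
                    nrm$x[idx, ], y_perm[idx], cfg)
  final <- tail(fit$history$val_acc, 1)
  expect_gte(final, 0.40)
  expect_lte(final, 0.60)
})

test_that("max_epochs = 0 returns the untrained model and empty history", {
  cfg <- mcnn_config(max_epochs = 0, seed = 71)
  model <- build_mcnn(cfg)
  sep <- separable_rows(4, seed = 71)
  fit <- train_mcnn(model, sep$x, sep$y, sep$x, sep$y, cfg)
  expect_equal(nrow(fit$history), 0)
  expect_identical(mpeeg:::nn_model_params(fit$model),
                   mpeeg:::nn_model_params(model))
})

test_that("crossval_mcnn shares fold bookkeeping with svm_crossval", {
  sep <- separable_rows(30, seed = 72)
  fm <- fake_fm(sep$x, sep$y, mode = "PSD_PLV")
  cfg <- mcnn_config(max_epochs = 1, seed = 73)
  cv_nn <- crossval_mcnn(fm, k = 3, cfg = cfg)
  folds_svm <- stratified_folds(fm$y, 3, seed = 73)
  expect_identical(cv_nn$fold_assignments, folds_svm)
  expect_length(cv_nn$sensitivity, 1)
  expect_true(is.finite(cv_nn$auc))
})

test_that("three-class MCNN reports per-class sensitivities", {
  set.seed(74)
  n <- 20
  mk <- function(s) separable_rows(n, shift_psd = s, shift_plv = 0.1 * s,
                                   seed = 74 + s)$x[1:n, ]
  x <- rbind(mk(0), mk(2), mk(4))
  y <- rep(0:2, each = n)
  fm <- fake_fm(x, y, mode = "PSD_PLV")
  fm$groups <- c("HC", "PD_OFF", "PD_ON")
  cfg <- mcnn_config(n_classes = 3, max_epochs = 2, seed = 75)
  cv <- crossval_mcnn(fm, k = 3, cfg = cfg)
  expect_length(cv$sensitivity, 3)
  expect_length(cv$specificity, 3)
  expect_true(is.na(cv$auc))
})

test_that("diagonal-only inputs cannot beat full multi-pattern inputs when
           the signal lives off-diagonal", {
  # discriminative signal purely in the PLV (off-diagonal) block
  set.seed(76)
  n <- 30
  mkrows <- function(n, shift) {
    t(vapply(seq_len(n), function(i) {
      c(rnorm(32, 5, 1), pmin(pmax(rnorm(496, 0.3, 0.05) + shift * 0.2, 0), 1))
    }, numeric(528)))
  }
  x <- rbind(mkrows(n, 0), mkrows(n, 1))
  y <- rep(0:1, each = n)
  x_diag <- x; x_diag[, 33:528] <- 0   # connectivity block removed
  cfg <- mcnn_config(max_epochs = 2, seed = 77)
  cv_full <- crossval_mcnn(fake_fm(x, y, mode = "PSD_PLV"), k = 3, cfg = cfg)
  cv_diag <- suppressWarnings(  # zero-variance PLV block warns, by design
    crossval_mcnn(fake_fm(x_diag, y, mode = "PSD_PLV"), k = 3, cfg = cfg))
  expect_gte(cv_full$accuracy, cv_diag$accuracy)
})

test_that("LeNet-5 trains on the strongly separated cohort", {
  sep <- separable_rows(30, seed = 78)
  nrm <- normalize_features(sep$x)
  set.seed(79)
  idx <- sample(60, 15)
  # the small LeNet-5 needs more of the lr-0.001 SGD epochs than the MCNN
  cfg <- mcnn_config(max_epochs = 25, seed = 79)
  fit <- train_mcnn(build_lenet5(2, cfg), nrm$x[-idx, ], sep$y[-idx],
                    nrm$x[idx, ], sep$y[idx], cfg)
  expect_gte(max(fit$history$val_acc), 0.90)
})
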