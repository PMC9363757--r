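test_that("assemble_features builds the documented layouts", {
  set.seed(41)
  chans <- montage32_channels()
  mk <- function(id, grp, n_ep = 3) {
    psd <- structure(list(
      subject_id = id, group = grp,
      values = array(runif(n_ep * 32), c(n_ep, 32, 1),
                     dimnames = list(NULL, chans, "gamma")),
      band_defs = eeg_bands("gamma"), channels = chans), class = "psd_features")
    plv <- structure(list(
      subject_id = id, group = grp,
      values = array(runif(n_ep * 496), c(n_ep, 496, 1),
                     dimnames = list(NULL, channel_pairs(chans)$name, "gamma")),
      band_defs = eeg_bands("gamma"), channels = chans,
      pair_index = channel_pairs(chans), edge_trim = 0.1,
      average = "within_epoch"), class = "plv_features")
    list(psd = psd, plv = plv)
  }
  subs <- list(mk("h1", "HC"), mk("h2", "HC"), mk("p1", "PD"))
  psd <- lapply(subs, `[[`, "psd"); plv <- lapply(subs, `[[`, "plv")
  fm_psd <- assemble_features(psd, NULL, "PSD", "gamma", c("HC", "PD"))
  expect_equal(dim(fm_psd$x), c(9, 32))
  expect_equal(fm_psd$y, rep(c(0L, 1L), c(6, 3)))
  fm_plv <- assemble_features(NULL, plv, "PLV", "gamma", c("HC", "PD"))
  expect_equal(dim(fm_plv$x), c(9, 496))
  fm_both <- assemble_features(psd, plv, "PSD_PLV", "gamma", c("HC", "PD"))
  expect_equal(dim(fm_both$x), c(9, 528))
  # concatenation order: PSD block then PLV block
  expect_identical(fm_both$x[, 1:32], fm_psd$x)
  expect_identical(unname(fm_both$x[, 33:528]), unname(fm_plv$x))
  expect_error(assemble_features(psd, NULL, "PSD", "gamma", c("HC", "XX")),
               "XX")
  expect_error(assemble_features(NULL, plv, "PSD", "gamma", c("HC", "PD")),
               class = "mpeeg_validation_error")
})

test_that("normalisation is a per-feature z-score with a leakage guard", {
  set.seed(42)
  x <- matrix(rnorm(50 * 6, 10, 3), 50)
  x[, 6] <- 7  # constant column
  expect_warning(nrm <- normalize_features(x), "zero-variance")
  expect_lt(max(abs(colMeans(nrm$x))), 1e-9)
  expect_lt(max(abs(apply(nrm$x[, 1:5], 2, sd) - 1)), 1e-9)
  expect_equal(max(abs(nrm$x[, 6])), 0)
  # held-out rows transformed with training stats are not centred
  xt <- matrix(rnorm(20 * 6, 12, 3), 20)
  held <- normalize_features(xt, nrm$stats)$x
  expect_gt(max(abs(colMeans(held[, 1:5]))), 0.1)
  expect_error(normalize_features(x[1, , drop = FALSE]), ">= 2 rows")
})

test_that("stratified folds partition observations and classes", {
  y <- rep(c(0L, 1L), c(30, 24))
  folds <- stratified_folds(y, 6, seed = 43)
  expect_setequal(unique(folds), 1:6)
  for (f in 1:6) {
    expect_equal(sum(folds == f & y == 0), 5)
    expect_equal(sum(folds == f & y == 1), 4)
  }
  expect_error(stratified_folds(rep(0:1, c(3, 50)), 5), "at least k")
})

test_that("linear SVM separates well-separated Gaussians (>= 99%)", {
  set.seed(44)
  d <- 30; n <- 400
  x <- rbind(matrix(rnorm(n / 2 * d), ncol = d),
             matrix(rnorm(n / 2 * d, mean = 10 / sqrt(d)), ncol = d))
  fm <- fake_fm(x, rep(0:1, each = n / 2))
  cv <- svm_crossval(fm, k = 10, seed = 44)
  expect_gte(cv$accuracy, 99)
  expect_gte(cv$auc, 0.99)
  # every row tested exactly once
  expect_setequal(unique(cv$fold_assignments), 1:10)
  expect_equal(length(cv$fold_assignments), n)
})

test_that("label permutation drives the SVM to chance", {
  set.seed(45)
  x <- matrix(rnorm(200 * 20), 200)
  accs <- vapply(1:10, function(s) {
    set.seed(1000 + s)
    fm <- fake_fm(x, sample(rep(0:1, each = 100)))
    svm_crossval(fm, k = 10, seed = s)$accuracy
  }, numeric(1))
  expect_gte(mean(accs), 45)
  expect_lte(mean(accs), 55)
  set.seed(46)
  fm <- fake_fm(x, sample(rep(0:1, each = 100)))
  auc <- svm_crossval(fm, k = 10, seed = 47)$auc
  expect_gte(auc, 0.40)
  expect_lte(auc, 0.60)
})

test_that("two-fold CV on 4 rows tests every row exactly once", {
  x <- matrix(rnorm(4 * 3), 4)
  fm <- fake_fm(x, c(0L, 1L, 0L, 1L))
  cv <- svm_crossval(fm, k = 2, seed = 48)
  expect_equal(as.numeric(table(cv$fold_assignments)), c(2, 2))
  expect_equal(sum(Reduce(`+`, cv$confusions)), 4)
})

test_that("normalisation statistics never see test-fold rows", {
  # instrumented check: poison one fold's rows with a huge offset; the
  # training statistics of that fold must be unaffected by the poisoned rows
  set.seed(49)
  x <- matrix(rnorm(60 * 4), 60)
  y <- rep(0:1, 30)
  folds <- stratified_folds(y, 3, seed = 50)
  poison <- folds == 2
  x2 <- x; x2[poison, ] <- x2[poison, ] + 1e6
  tr <- !poison
  stats_clean <- normalize_features(x[tr, ])$stats
  stats_poisoned <- normalize_features(x2[tr, ])$stats
  expect_equal(stats_clean, stats_poisoned)
})

test_that("metrics arithmetic matches the definitions", {
  m <- compute_metrics(list(matrix(c(9, 1, 1, 9), 2, byrow = TRUE)))
  expect_equal(c(m$accuracy, m$sensitivity, m$specificity), c(90, 90, 90))
  m2 <- compute_metrics(list(matrix(c(5, 0, 0, 5), 2, byrow = TRUE)))
  expect_equal(c(m2$accuracy, m2$sensitivity, m2$specificity), c(100, 100, 100))
  m3 <- compute_metrics(list(matrix(c(10, 0, 10, 0), 2, byrow = TRUE)))
  expect_equal(c(m3$accuracy, m3$sensitivity, m3$specificity), c(50, 0, 100))
  # empty folds are excluded with a warning
  expect_warning(
    m4 <- compute_metrics(list(matrix(0L, 2, 2),
                               matrix(c(9, 1, 1, 9), 2, byrow = TRUE))),
    "empty")
  expect_equal(m4$accuracy, 90)
  # three-class: per-class one-vs-rest vectors
  cm3 <- matrix(c(8, 1, 1, 0, 9, 1, 1, 1, 8), 3, byrow = TRUE)
  m5 <- compute_metrics(list(cm3))
  expect_length(m5$sensitivity, 3)
  expect_equal(m5$accuracy, 100 * 25 / 30)
})

test_that("ROC/AUC behaves under perfection, reversal and ties", {
  lab <- c(0, 0, 1, 1, 0, 1)
  expect_equal(roc_auc(lab, lab)$auc, 1)
  set.seed(51)
  sc <- rnorm(200)
  lb <- rbinom(200, 1, 0.5)
  a <- roc_auc(sc, lb)$auc
  expect_equal(roc_auc(-sc, lb)$auc, 1 - a, tolerance = 1e-12)
  expect_error(roc_auc(sc, rep(1, 200)), class = "mpeeg_validation_error")
  # chance scores on a big sample
  set.seed(52)
  sc2 <- rnorm(2000); lb2 <- rbinom(2000, 1, 0.5)
  a2 <- roc_auc(sc2, lb2)$auc
  expect_gte(a2, 0.47); expect_lte(a2, 0.53)
})

test_that("AUC equals the normalised Mann-Whitney U on random sets", {
  for (i in 1:50) {
    set.seed(600 + i)
    n <- sample(20:80, 1)
    sc <- sample(rnorm(10), n, replace = TRUE)  # heavy ties
    lb <- rbinom(n, 1, 0.5)
    if (length(unique(lb)) < 2) next
    np <- sum(lb == 1); nn <- sum(lb == 0)
    r <- rank(sc)
    u <- (sum(r[lb == 1]) - np * (np + 1) / 2) / (np * nn)
    expect_equal(roc_auc(sc, lb)$auc, u, tolerance = 1e-12)
  }
})

test_that("subject-level splitting keeps subjects out of their train folds", {
  set.seed(53)
  n_sub <- 12
  x <- matrix(rnorm(n_sub * 10 * 5), n_sub * 10)
  y <- rep(rep(0:1, each = 6), each = 10)
  sid <- rep(sprintf("s%02d", 1:n_sub), each = 10)
  fm <- fake_fm(x, y, subject_id = sid)
  cv <- svm_crossval(fm, k = 5, seed = 54, split = "subject")
  for (f in 1:5) {
    test_subs <- unique(sid[cv$fold_assignments == f])
    train_subs <- unique(sid[cv$fold_assignments != f])
    expect_length(intersect(test_subs, train_subs), 0)
  }
})
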