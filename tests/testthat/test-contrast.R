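test_that("null simulation holds the nominal type-I error rate", {
  set.seed(31)
  A <- list(fake_psd(matrix(rnorm(40 * 1000, 10, 2), 40), "HC"))
  B <- list(fake_psd(matrix(rnorm(40 * 1000, 10, 2), 40), "PD"))
  cm <- group_contrast(A, B, "gamma", alpha = 0.05)
  expect_gte(mean(cm$significant), 0.03)
  expect_lte(mean(cm$significant), 0.07)
  expect_true(all(cm$significant == (cm$p_value <= 0.05)))
})

test_that("a planted constant shift is detected with ratio > 1", {
  set.seed(32)
  A <- list(fake_psd(matrix(rnorm(40 * 10, 10, 1), 40), "PD"))
  B <- list(fake_psd(matrix(rnorm(40 * 10, 10, 1), 40), "HC"))
  A[[1]]$values[, 3, 1] <- A[[1]]$values[, 3, 1] + 8
  cm <- group_contrast(A, B, "gamma")
  expect_true(cm$significant[3])
  expect_gt(cm$ratio[3], 1)
})

test_that("degenerate one-observation groups warn and return p = 1", {
  A <- list(fake_psd(matrix(5, 1, 4), "PD"))
  B <- list(fake_psd(matrix(5, 1, 4), "HC"))
  expect_warning(cm <- group_contrast(A, B, "gamma"), "degenerate")
  expect_true(all(cm$p_value == 1))
})

test_that("swapping groups inverts ratios and keeps p-values", {
  set.seed(33)
  A <- list(fake_psd(matrix(rexp(30 * 25) + 1, 30), "PD"))
  B <- list(fake_psd(matrix(rexp(30 * 25) + 1, 30), "HC"))
  ab <- group_contrast(A, B, "gamma")
  ba <- group_contrast(B, A, "gamma")
  expect_equal(ab$ratio, 1 / ba$ratio, tolerance = 1e-12)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
})

test_that("t-test p-values agree with a permutation oracle", {
  set.seed(34)
  A <- matrix(rnorm(30 * 20, 5), 30)
  B <- matrix(rnorm(30 * 20, 5), 30)
  B[, 1] <- B[, 1] + 1   # one real effect among the 20 units
  p_perm <- permutation_pvalues(A, B, n_perm = 10000, seed = 35)
  p_t <- group_contrast(list(fake_psd(A, "HC")), list(fake_psd(B, "PD")),
                        "gamma")$p_value
  expect_lt(max(abs(p_perm - p_t)), 0.02)
})

test_that("BH adjustment and subject-level observations are available", {
  set.seed(36)
  A <- lapply(1:5, function(i) fake_psd(matrix(rnorm(20 * 8, 10), 20), "PD",
                                        subject_id = paste0("a", i)))
  B <- lapply(1:5, function(i) fake_psd(matrix(rnorm(20 * 8, 10), 20), "HC",
                                        subject_id = paste0("b", i)))
  cm_bh <- group_contrast(A, B, "gamma", p_adjust = "BH")
  cm_raw <- group_contrast(A, B, "gamma")
  expect_true(all(cm_bh$p_value >= cm_raw$p_value - 1e-12))
  cm_subj <- group_contrast(A, B, "gamma", observation = "subject")
  expect_identical(unname(cm_subj$n_obs), c(5L, 5L))
})

test_that("rendering blanks exactly the non-significant units", {
  set.seed(37)
  n_ch <- 32
  mk <- function(grp, shift_ch = NULL) {
    v <- matrix(rnorm(30 * n_ch, 10, 1), 30)
    if (!is.null(shift_ch)) v[, shift_ch] <- v[, shift_ch] + 10
    f <- fake_psd(v, grp)
    f$channels <- montage32_channels()
    dimnames(f$values)[[2]] <- f$channels
    f
  }
  cm <- group_contrast(list(mk("PD", shift_ch = 5)), list(mk("HC")), "gamma",
                       p_adjust = "BH")
  f <- tempfile(fileext = ".png")
  shown <- render_contrast(cm, f)
  expect_true(file.exists(f))
  expect_identical(unname(which(!is.na(shown))), which(cm$significant))
  # all-null map renders fully blank
  cm0 <- cm; cm0$significant[] <- FALSE
  shown0 <- render_contrast(cm0, tempfile(fileext = ".png"))
  expect_true(all(is.na(shown0)))
  # all-significant map has no blanks
  cm1 <- cm; cm1$significant[] <- TRUE
  shown1 <- render_contrast(cm1, tempfile(fileext = ".png"))
  expect_false(any(is.na(shown1)))
  # missing coordinates error
  bad <- cm; bad$channels[1] <- "nope"; bad$unit_names[1] <- "nope"
  expect_error(render_contrast(bad, tempfile(fileext = ".png")),
               class = "mpeeg_validation_error")
})

test_that("PLV contrast maps use Fisher-domain group means", {
  set.seed(38)
  mkplv <- function(grp, val) {
    v <- matrix(pmin(pmax(rnorm(20 * 3, val, 0.03), 0), 1), 20)
    structure(list(
      subject_id = grp, group = grp,
      values = array(v, c(20, 3, 1),
                     dimnames = list(NULL, c("a-b", "a-c", "b-c"), "beta")),
      band_defs = eeg_bands("beta"), channels = c("a", "b", "c"),
      pair_index = channel_pairs(c("a", "b", "c")),
      edge_trim = 0.1, average = "within_epoch"), class = "plv_features")
  }
  A <- list(mkplv("PD", 0.6)); B <- list(mkplv("HC", 0.3))
  cm <- group_contrast(A, B, "beta")
  manual <- fisher_mean_plv(A[[1]]$values[, 1, 1]) /
    fisher_mean_plv(B[[1]]$values[, 1, 1])
  expect_equal(unname(cm$ratio[1]), manual, tolerance = 1e-12)
  expect_identical(cm$unit, "channel_pair")
})
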