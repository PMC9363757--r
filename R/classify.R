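# Feature assembly, z-score normalisation with leakage guard, linear SVM
# baseline (dual coordinate descent), stratified cross-validation and
# accuracy/sensitivity/specificity/ROC-AUC metrics.

#' Assemble a per-epoch feature matrix for classification
#'
#' One row per subject-epoch. `"PSD"` rows are the 32 per-channel band
#' powers, `"PLV"` rows the 496 per-pair phase-locking values, and
#' `"PSD_PLV"` their concatenation (528 columns), all for a single band.
#' Class labels are integers in listing order of `groups` (0 for the first
#' group, 1 for the second, 2 for a third).
#'
#' @param psd List of `psd_features` (one per subject), or `NULL`.
#' @param plv List of `plv_features` (one per subject), or `NULL`.
#' @param mode `"PSD"`, `"PLV"` or `"PSD_PLV"`.
#' @param band Band name.
#' @param groups Character vector (length 2 or 3) of group labels defining
#'   the classes and their label order.
#' @return A `feature_matrix` object: `x` (rows x features), `y` (integer
#'   labels), `meta` (subject_id, epoch), `feature_names`, `band`, `mode`.
#' @export
assemble_features <- function(psd = NULL, plv = NULL,
                              mode = c("PSD", "PLV", "PSD_PLV"),
                              band, groups) {
  mode <- match.arg(mode)
  if (mode %in% c("PSD", "PSD_PLV") && is.null(psd)) {
    .mp_validation_error("mode ", mode, " requires PSD features")
  }
  if (mode %in% c("PLV", "PSD_PLV") && is.null(plv)) {
    .mp_validation_error("mode ", mode, " requires PLV features")
  }
  src <- if (!is.null(psd)) psd else plv
  grp_of <- vapply(src, `[[`, character(1), "group")
  sid_of <- vapply(src, `[[`, character(1), "subject_id")
  rows <- list(); labs <- integer(0); meta_sid <- character(0); meta_ep <- integer(0)
  for (g in seq_along(groups)) {
    sel <- which(grp_of == groups[g])
    if (!length(sel)) .mp_validation_error("no subjects in group ", groups[g])
    for (s in sel) {
      blocks <- list()
      if (mode %in% c("PSD", "PSD_PLV")) {
        blocks$psd <- .pool_band(psd[s], band)
      }
      if (mode %in% c("PLV", "PSD_PLV")) {
        if (!identical(sid_of[s], plv[[s]]$subject_id)) {
          .mp_validation_error("psd/plv subject order mismatch at index ", s)
        }
        blocks$plv <- .pool_band(plv[s], band)
      }
      m <- do.call(cbind, blocks)
      rows[[length(rows) + 1L]] <- m
      labs <- c(labs, rep(g - 1L, nrow(m)))
      meta_sid <- c(meta_sid, rep(sid_of[s], nrow(m)))
      meta_ep <- c(meta_ep, seq_len(nrow(m)))
    }
  }
  x <- do.call(rbind, rows)
  fn <- character(0)
  if (mode %in% c("PSD", "PSD_PLV")) fn <- c(fn, paste0("psd_", psd[[1]]$channels))
  if (mode %in% c("PLV", "PSD_PLV")) fn <- c(fn, paste0("plv_", plv[[1]]$pair_index$name))
  colnames(x) <- fn
  structure(
    list(x = x, y = labs,
         meta = data.frame(subject_id = meta_sid, epoch = meta_ep,
                           stringsAsFactors = FALSE),
         feature_names = fn, band = band, mode = mode, groups = groups),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix %s/%s: %d rows x %d features, classes {%s}>\n",
              x$mode, x$band, nrow(x$x), ncol(x$x),
              paste(x$groups, collapse = ", ")))
  invisible(x)
}

#' Per-feature z-score normalisation with a leakage guard
#'
#' Fits column means/SDs on the supplied rows, or applies previously fitted
#' statistics (so test rows are always scaled with training statistics).
#' Zero-variance features are mapped to 0 with a warning.
#'
#' @param x Numeric matrix (rows = observations).
#' @param stats Optional list with `center` and `scale` from a previous fit.
#' @return List: `x` (normalised matrix) and `stats`.
#' @export
normalize_features <- function(x, stats = NULL) {
  if (is.null(stats)) {
    if (nrow(x) < 2) .mp_validation_error("need >= 2 rows to fit normalisation")
    center <- colMeans(x)
    scale <- apply(x, 2, sd)
    if (any(scale == 0)) {
      warning(sum(scale == 0), " zero-variance feature(s) scaled to 0")
      scale[scale == 0] <- Inf
    }
    stats <- list(center = center, scale = scale)
  }
  xs <- sweep(sweep(x, 2, stats$center, "-"), 2, stats$scale, "/")
  list(x = xs, stats = stats)
}

#' Stratified k-fold assignment
#'
#' @param y Integer class labels.
#' @param k Number of folds.
#' @param seed RNG seed for the shuffle.
#' @return Integer vector of fold ids in `1..k`, one per observation; each
#'   class is spread as evenly as possible across folds.
#' @export
stratified_folds <- function(y, k, seed = 1) {
  if (k < 2) .mp_validation_error("k must be >= 2")
  if (any(table(y) < k)) {
    .mp_validation_error("every class needs at least k = ", k, " rows")
  }
  set.seed(seed)
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Train a linear SVM (hinge loss, L2 regularisation)
#'
#' Dual coordinate descent on the L1-loss SVM dual; equivalent to a
#' linear-kernel C-SVM. A bias term is included through an appended
#' constant column.
#'
#' @param x Training matrix.
#' @param y Labels in `{0, 1}`.
#' @param C Regularisation constant (default 1).
#' @param max_iter Maximum outer iterations.
#' @param tol Projected-gradient stopping tolerance.
#' @param seed Seed for the coordinate shuffling.
#' @return An `svm_model` with weights `w` and bias `b`.
#' @export
svm_train <- function(x, y, C = 1, max_iter = 200, tol = 1e-3, seed = 1) {
  uy <- sort(unique(y))
  if (!all(uy %in% c(0, 1)) || length(uy) != 2) {
    .mp_validation_error("svm_train expects binary labels 0/1 (both present)")
  }
  ypm <- ifelse(y == 1, 1, -1)
  xb <- cbind(x, bias = 1)
  w <- .svm_dcd_cpp(xb, ypm, C, as.integer(max_iter), tol, as.integer(seed))
  structure(list(w = w[-length(w)], b = w[length(w)], C = C),
            class = "svm_model")
}

#' Decision scores of a linear SVM
#'
#' @param model An `svm_model`.
#' @param x Matrix of observations.
#' @return Numeric vector of signed decision values (positive = class 1).
#' @export
svm_decision <- function(model, x) {
  as.numeric(x %*% model$w + model$b)
}

#' Confusion counts for one fold
#' @noRd
.confusion <- function(truth, pred, n_classes) {
  m <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(truth)) {
    m[truth[i] + 1L, pred[i] + 1L] <- m[truth[i] + 1L, pred[i] + 1L] + 1L
  }
  m
}

#' Accuracy, sensitivity and specificity from per-fold confusion matrices
#'
#' Binary problems treat class 1 (the disease class by convention) as
#' positive: sensitivity = TP/(TP+FN), specificity = TN/(TN+FP). Multi-class
#' problems report overall accuracy (trace/total) and one-vs-rest
#' sensitivity/specificity per class. All values are percentages, averaged
#' over folds.
#'
#' @param confusions List of square confusion-count matrices
#'   (rows = truth, columns = prediction).
#' @return List with `accuracy`, `sensitivity`, `specificity` (the latter
#'   two vectors for multi-class), plus `per_fold`.
#' @export
compute_metrics <- function(confusions) {
  keep <- vapply(confusions, sum, numeric(1)) > 0
  if (!all(keep)) {
    warning(sum(!keep), " empty fold(s) excluded from metrics")
    confusions <- confusions[keep]
  }
  if (!length(confusions)) .mp_validation_error("no non-empty folds")
  nc <- nrow(confusions[[1]])
  per_fold <- lapply(confusions, function(cm) {
    acc <- 100 * sum(diag(cm)) / sum(cm)
    sens <- numeric(nc); spec <- numeric(nc)
    for (c in seq_len(nc)) {
      tp <- cm[c, c]; fn <- sum(cm[c, -c]); fp <- sum(cm[-c, c])
      tn <- sum(cm) - tp - fn - fp
      sens[c] <- 100 * tp / max(tp + fn, 1)
      spec[c] <- 100 * tn / max(tn + fp, 1)
    }
    list(accuracy = acc, sensitivity = sens, specificity = spec)
  })
  acc <- mean(vapply(per_fold, `[[`, numeric(1), "accuracy"))
  sens <- rowMeans(vapply(per_fold, `[[`, numeric(nc), "sensitivity"))
  spec <- rowMeans(vapply(per_fold, `[[`, numeric(nc), "specificity"))
  if (nc == 2) {
    # class 1 (disease) positive: sensitivity = class-1 recall,
    # specificity = class-0 recall (= one-vs-rest specificity of class 1)
    sens <- sens[2]; spec <- spec[2]
  }
  list(accuracy = acc, sensitivity = sens, specificity = spec,
       per_fold = per_fold)
}

#' ROC curve and AUC by threshold sweep
#'
#' The ROC is traced over the unique score thresholds; the AUC is the
#' trapezoid-rule area, which with tie-averaging equals the normalised
#' Mann-Whitney U statistic.
#'
#' @param scores Numeric decision scores (larger = more class-1-like).
#' @param labels Binary labels in `{0, 1}`; both classes must be present.
#' @return List with `roc_points` (data.frame FPR/TPR) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  if (length(unique(labels)) < 2) {
    .mp_validation_error("both classes must be present for ROC")
  }
  np <- sum(labels == 1); nn <- sum(labels == 0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  # cumulative counts at each distinct threshold
  dup <- duplicated(s)
  tp <- cumsum(l == 1); fp <- cumsum(l == 0)
  keep <- !c(dup[-1], FALSE)
  roc <- data.frame(FPR = c(0, fp[keep] / nn), TPR = c(0, tp[keep] / np))
  auc <- sum(diff(roc$FPR) * (head(roc$TPR, -1) + tail(roc$TPR, -1)) / 2)
  list(roc_points = roc, auc = auc)
}

#' Stratified k-fold cross-validation of the linear SVM
#'
#' Epoch-level stratified folds (the conventional 9:1 split at k = 10);
#' normalisation statistics are fitted on each training fold only. ROC is
#' computed from decision scores pooled over test folds.
#'
#' @param fm A `feature_matrix` (binary labels).
#' @param k Number of folds (default 10).
#' @param seed Fold-shuffle seed.
#' @param C SVM regularisation constant.
#' @param split `"epoch"` (default) or `"subject"`: subject-level splitting
#'   keeps all epochs of a subject in the same fold (no identity leakage).
#' @return A `cv_result`: per-fold confusions, aggregate metrics, ROC points,
#'   AUC and the fold assignment.
#' @export
svm_crossval <- function(fm, k = 10, seed = 1, C = 1,
                         split = c("epoch", "subject")) {
  split <- match.arg(split)
  stopifnot(inherits(fm, "feature_matrix"))
  if (length(unique(fm$y)) != 2) {
    .mp_validation_error("svm_crossval handles binary problems only")
  }
  folds <- .make_folds(fm, k, seed, split)
  confusions <- vector("list", k)
  scores <- numeric(nrow(fm$x)); preds <- integer(nrow(fm$x))
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    nrm <- normalize_features(fm$x[tr, , drop = FALSE])
    xte <- normalize_features(fm$x[te, , drop = FALSE], nrm$stats)$x
    model <- svm_train(nrm$x, fm$y[tr], C = C, seed = seed + f)
    sc <- svm_decision(model, xte)
    scores[te] <- sc
    preds[te] <- as.integer(sc > 0)
    confusions[[f]] <- .confusion(fm$y[te], preds[te], 2L)
  }
  metrics <- compute_metrics(confusions)
  roc <- roc_auc(scores, fm$y)
  structure(
    list(model = "svm", confusions = confusions, accuracy = metrics$accuracy,
         sensitivity = metrics$sensitivity, specificity = metrics$specificity,
         per_fold = metrics$per_fold, roc_points = roc$roc_points,
         auc = roc$auc, fold_assignments = folds, seed = seed, k = k,
         split = split, groups = fm$groups, band = fm$band, mode = fm$mode),
    class = "cv_result"
  )
}

.make_folds <- function(fm, k, seed, split) {
  if (split == "epoch") return(stratified_folds(fm$y, k, seed))
  # subject-level: assign whole subjects to folds, stratified by group
  sid <- fm$meta$subject_id
  subj <- unique(sid)
  ysub <- fm$y[match(subj, sid)]
  for (attempt in 0:4) {
    fs <- stratified_folds(ysub, k, seed + attempt)
    folds <- fs[match(sid, subj)]
    ok <- all(vapply(seq_len(k), function(f) {
      length(unique(fm$y[folds != f])) == length(unique(fm$y))
    }, logical(1)))
    if (ok) return(folds)
  }
  .mp_validation_error("could not stratify subjects into ", k, " folds")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result %s %s/%s (%s vs %s%s): acc %.2f%%, sens %s, spec %s, AUC %.3f>\n",
              x$model, x$mode, x$band, x$groups[1], x$groups[2],
              if (length(x$groups) > 2) paste0(" vs ", x$groups[3]) else "",
              x$accuracy,
              paste(sprintf("%.2f%%", x$sensitivity), collapse = "/"),
              paste(sprintf("%.2f%%", x$specificity), collapse = "/"),
              x$auc))
  invisible(x)
}
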