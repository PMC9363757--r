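# The multi-scale CNN: two parallel sub-networks over the same 32 x 32
# multi-pattern input (2-d convolutions with a residual block; 1-d
# convolutions along the channel axis), flattened, concatenated and fed to a
# dense head. Plus the LeNet-5 ablation baseline and the 528-feature ->
# 32 x 32 input assembly.

#' MCNN configuration
#'
#' @param n_classes 2 or 3.
#' @param input_side Input matrix side (default 32).
#' @param dropout_rate Dropout after each dense layer (default 0.5).
#' @param learning_rate Initial SGD learning rate (default 0.001).
#' @param decay Learning-rate decay: `lr_t = lr / (1 + decay * t)` with t the
#'   completed-epoch count (default 0.1). Set `decay_mode = "weight"` to read
#'   the rate as L2 weight decay instead.
#' @param max_epochs Training epochs (default 50).
#' @param batch_size Mini-batch size (default 64).
#' @param seed RNG seed controlling initialisation, shuffling and dropout.
#' @param decay_mode `"lr"` (default) or `"weight"`.
#' @return An `mcnn_config` list.
#' @export
mcnn_config <- function(n_classes = 2, input_side = 32, dropout_rate = 0.5,
                        learning_rate = 0.001, decay = 0.1, max_epochs = 50,
                        batch_size = 64, seed = 1,
                        decay_mode = c("lr", "weight")) {
  if (!n_classes %in% c(2, 3)) .mp_validation_error("n_classes must be 2 or 3")
  structure(list(n_classes = n_classes, input_side = input_side,
                 dropout_rate = dropout_rate, learning_rate = learning_rate,
                 decay = decay, max_epochs = max_epochs,
                 batch_size = batch_size, seed = seed,
                 decay_mode = match.arg(decay_mode)),
            class = "mcnn_config")
}

#' Assemble one 528-feature row into the 32 x 32 multi-pattern input
#'
#' The feature vector is `[PSD(32) || PLV(496)]` (canonical pair order). The
#' output matrix carries each channel's (normalised) band power on the
#' diagonal and the pair's phase-locking value symmetrically off the
#' diagonal, so the 2-d sub-network sees the connectivity structure and the
#' diagonal the activation pattern. The mapping is deterministic and
#' invertible.
#'
#' @param row Numeric vector of length 528.
#' @param channels The 32 montage labels (defines the pair order).
#' @return A 32 x 32 symmetric matrix.
#' @export
reshape_to_input <- function(row, channels = montage32_channels()) {
  n_ch <- length(channels)
  n_pair <- n_ch * (n_ch - 1) / 2
  if (length(row) != n_ch + n_pair) {
    .mp_validation_error("feature row must have length ", n_ch + n_pair,
                         " (PSD ", n_ch, " + PLV ", n_pair, "), got ",
                         length(row))
  }
  pairs <- channel_pairs(channels)
  m <- matrix(0, n_ch, n_ch, dimnames = list(channels, channels))
  diag(m) <- row[seq_len(n_ch)]
  plv <- row[-seq_len(n_ch)]
  m[cbind(pairs$i, pairs$j)] <- plv
  m[cbind(pairs$j, pairs$i)] <- plv
  m
}

#' Recover the 528-feature row from a multi-pattern input matrix
#' @param m A 32 x 32 matrix from [reshape_to_input()].
#' @param channels Montage labels.
#' @return Numeric vector of length 528.
#' @export
input_to_row <- function(m, channels = montage32_channels()) {
  pairs <- channel_pairs(channels)
  unname(c(diag(m), m[cbind(pairs$i, pairs$j)]))
}

# batch of rows -> (H, W, B, 1) input tensor
.rows_to_tensor <- function(x, channels) {
  B <- nrow(x)
  side <- length(channels)
  out <- array(0, dim = c(side, side, B, 1))
  for (b in seq_len(B)) out[, , b, 1] <- reshape_to_input(x[b, ], channels)
  out
}

#' Build the multi-scale CNN
#'
#' Sub-network 1 (2-d scale): conv 6@5x5 same -> maxpool 2x2 -> conv 16@5x5
#' -> residual block of two shape-preserving conv 16@5x5 (pad 2) with an
#' identity skip -> maxpool 2x2 -> conv 120@5x5 -> maxpool 2x2. Sub-network
#' 2 (1-d scale along the channel axis): conv 32@7x1 same -> maxpool 2x1 ->
#' conv 64@5x1 -> maxpool 2x1. Branch outputs are flattened, concatenated
#' and passed through dropout -> dense 84 -> dropout -> dense
#' `n_classes` (sigmoid for 2 classes, softmax for 3). All convolutions use
#' ReLU.
#'
#' @param cfg An [mcnn_config()].
#' @return An `nn_model` object.
#' @export
build_mcnn <- function(cfg = mcnn_config()) {
  set.seed(cfg$seed)
  side <- cfg$input_side
  sub1 <- list(
    nn_conv(1, 6, 5, 5, pad = "same"),
    nn_pool(2, 2),
    nn_conv(6, 16, 5, 5, pad = 0),
    nn_residual(list(
      nn_conv(16, 16, 5, 5, pad = 2),
      nn_conv(16, 16, 5, 5, pad = 2)
    )),
    nn_pool(2, 2),
    nn_conv(16, 120, 5, 5, pad = 0),
    nn_pool(2, 2),
    nn_flatten()
  )
  sub2 <- list(
    nn_conv(1, 32, 7, 1, pad = c(3, 0)),
    nn_pool(2, 1),
    nn_conv(32, 64, 5, 1, pad = 0),
    nn_pool(2, 1),
    nn_flatten()
  )
  n1 <- .probe_width(sub1, side)
  n2 <- .probe_width(sub2, side)
  head <- list(
    nn_dropout(cfg$dropout_rate),
    nn_dense(n1 + n2, 84, activation = "linear"),
    nn_dropout(cfg$dropout_rate),
    nn_dense(84, cfg$n_classes, activation = "linear")
  )
  structure(list(branches = list(sub1, sub2), head = head,
                 out_activation = if (cfg$n_classes == 2) "sigmoid" else "softmax",
                 n_classes = cfg$n_classes, cfg = cfg, kind = "mcnn"),
            class = "nn_model")
}

#' Build the LeNet-5 baseline
#'
#' Classic topology adapted to the 32 x 32 single-channel multi-pattern
#' input: conv 6@5x5 -> pool -> conv 16@5x5 -> pool -> conv 120@5x5 ->
#' dense 84 -> dense `n_classes`.
#'
#' @param n_classes 2 or 3.
#' @param cfg Optional [mcnn_config()] supplying training hyper-parameters.
#' @return An `nn_model` object.
#' @export
build_lenet5 <- function(n_classes = 2, cfg = mcnn_config(n_classes = n_classes)) {
  set.seed(cfg$seed)
  side <- cfg$input_side
  trunk <- list(
    nn_conv(1, 6, 5, 5, pad = 0),
    nn_pool(2, 2),
    nn_conv(6, 16, 5, 5, pad = 0),
    nn_pool(2, 2),
    nn_conv(16, 120, 5, 5, pad = 0),
    nn_flatten()
  )
  n1 <- .probe_width(trunk, side)
  head <- list(
    nn_dense(n1, 84, activation = "relu"),
    nn_dense(84, n_classes, activation = "linear")
  )
  structure(list(branches = list(trunk), head = head,
                 out_activation = if (n_classes == 2) "sigmoid" else "softmax",
                 n_classes = n_classes, cfg = cfg, kind = "lenet5"),
            class = "nn_model")
}

# run a zero batch through a branch to get the flattened width, validating
# the layer shape chain in the process
.probe_width <- function(layers, side) {
  probe <- array(0, dim = c(side, side, 1, 1))
  r <- tryCatch(nn_seq_forward(layers, probe, train = FALSE),
                error = function(e) {
                  .mp_stop("layer shape chain invalid: ", conditionMessage(e))
                })
  ncol(r$out)
}

#' @export
print.nn_model <- function(x, ...) {
  cat(sprintf("<nn_model %s: %d branches, %d classes, %d parameters>\n",
              x$kind, length(x$branches), x$n_classes, nn_count_params(x)))
  invisible(x)
}

# forward through the full model; x is (H, W, B, 1)
nn_forward <- function(model, x, train = FALSE) {
  outs <- vector("list", length(model$branches))
  for (i in seq_along(model$branches)) {
    r <- nn_seq_forward(model$branches[[i]], x, train)
    model$branches[[i]] <- r$layers
    outs[[i]] <- r$out
  }
  h <- do.call(cbind, outs)
  model$.split <- vapply(outs, ncol, numeric(1))
  rh <- nn_seq_forward(model$head, h, train)
  model$head <- rh$layers
  logits <- rh$out
  probs <- if (model$out_activation == "sigmoid") {
    1 / (1 + exp(-logits))
  } else {
    e <- exp(logits - apply(logits, 1, max))
    e / rowSums(e)
  }
  list(model = model, logits = logits, probs = probs)
}

# backward from dlogits, updating gradients in place
nn_backward <- function(model, dlogits) {
  rh <- nn_seq_backward(model$head, dlogits)
  model$head <- rh$layers
  dh <- rh$dx
  off <- 0
  for (i in seq_along(model$branches)) {
    w <- model$.split[i]
    dbr <- dh[, off + seq_len(w), drop = FALSE]
    off <- off + w
    rb <- nn_seq_backward(model$branches[[i]], dbr)
    model$branches[[i]] <- rb$layers
  }
  model
}

nn_update <- function(model, lr) {
  for (i in seq_along(model$branches)) {
    model$branches[[i]] <- nn_seq_update(model$branches[[i]], lr)
  }
  model$head <- nn_seq_update(model$head, lr)
  model
}

.one_hot <- function(y, k) {
  m <- matrix(0, length(y), k)
  m[cbind(seq_along(y), y + 1L)] <- 1
  m
}

# loss value for monitoring: BCE (sigmoid head) or CE (softmax head)
.nn_loss <- function(probs, t, activation) {
  p <- pmin(pmax(probs, 1e-12), 1 - 1e-12)
  if (activation == "sigmoid") {
    -mean(rowSums(t * log(p) + (1 - t) * log(1 - p)))
  } else {
    -mean(rowSums(t * log(p)))
  }
}

#' Train a network with mini-batch SGD
#'
#' Plain SGD with an inverse-time learning-rate schedule
#' `lr_t = lr0 / (1 + decay * t)` over epochs (or constant learning rate
#' with L2 weight decay when `decay_mode = "weight"`). Cross-entropy loss:
#' binary (per-unit sigmoid) for 2 classes, categorical (softmax) for 3.
#' The per-epoch training/validation loss and accuracy are recorded, and the
#' weights from the best validation epoch are returned.
#'
#' @param model An `nn_model` from [build_mcnn()] or [build_lenet5()].
#' @param x,y Training rows (observations x 528 features) and integer labels
#'   in `[0, n_classes)`.
#' @param val_x,val_y Validation rows/labels (disjoint from training).
#' @param cfg An [mcnn_config()]; defaults to the model's.
#' @param channels Montage labels for the input assembly.
#' @return List: `model` (best-validation weights), `history` (data.frame
#'   with epoch, train_loss, train_acc, val_loss, val_acc).
#' @export
train_mcnn <- function(model, x, y, val_x, val_y, cfg = model$cfg,
                       channels = montage32_channels()) {
  if (length(intersect(rownames(x), rownames(val_x))) > 0 &&
      !is.null(rownames(x))) {
    .mp_validation_error("train and validation rows overlap")
  }
  if (any(y < 0 | y >= model$n_classes)) {
    .mp_validation_error("labels must lie in [0, n_classes)")
  }
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     train_acc = numeric(0), val_loss = numeric(0),
                     val_acc = numeric(0))
  if (cfg$max_epochs < 1) return(list(model = model, history = hist))
  xt <- .rows_to_tensor(x, channels)
  xv <- .rows_to_tensor(val_x, channels)
  tv <- .one_hot(val_y, model$n_classes)
  set.seed(cfg$seed + 1L)
  best <- list(acc = -Inf, model = model)
  n <- nrow(x)
  for (epoch in seq_len(cfg$max_epochs)) {
    lr <- if (cfg$decay_mode == "lr") {
      cfg$learning_rate / (1 + cfg$decay * (epoch - 1))
    } else cfg$learning_rate
    ord <- sample.int(n)
    tl <- 0; tc <- 0
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, n)]
      xb <- xt[, , idx, , drop = FALSE]
      tb <- .one_hot(y[idx], model$n_classes)
      fw <- nn_forward(model, xb, train = TRUE)
      model <- fw$model
      if (!all(is.finite(fw$logits))) {
        .mp_stop("training diverged: non-finite logits at epoch ", epoch)
      }
      tl <- tl + .nn_loss(fw$probs, tb, model$out_activation) * length(idx)
      tc <- tc + sum(max.col(fw$probs) - 1L == y[idx])
      dlogits <- (fw$probs - tb) / length(idx)
      model <- nn_backward(model, dlogits)
      if (cfg$decay_mode == "weight") model <- .nn_weight_decay(model, lr * cfg$decay)
      model <- nn_update(model, lr)
    }
    ev <- nn_forward(model, xv, train = FALSE)
    vl <- .nn_loss(ev$probs, tv, model$out_activation)
    va <- mean(max.col(ev$probs) - 1L == val_y)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tl / n,
                                   train_acc = tc / n, val_loss = vl,
                                   val_acc = va))
    if (va > best$acc) best <- list(acc = va, model = model)
  }
  list(model = best$model, history = hist)
}

.nn_weight_decay <- function(model, lambda) {
  shrink <- function(layers) {
    for (i in seq_along(layers)) {
      l <- layers[[i]]
      if (l$type %in% c("conv", "dense")) l$W <- l$W * (1 - lambda)
      if (l$type == "residual") l$body <- shrink(l$body)
      layers[[i]] <- l
    }
    layers
  }
  model$branches <- lapply(model$branches, shrink)
  model$head <- shrink(model$head)
  model
}

#' Predict class probabilities for feature rows
#'
#' @param model A trained `nn_model`.
#' @param x Observations x 528 feature matrix.
#' @param channels Montage labels.
#' @return Matrix of class probabilities (rows sum to ~1 for softmax).
#' @export
nn_predict <- function(model, x, channels = montage32_channels()) {
  xt <- .rows_to_tensor(x, channels)
  nn_forward(model, xt, train = FALSE)$probs
}

#' Stratified k-fold cross-validation of a CNN
#'
#' Same fold bookkeeping as [svm_crossval()] (identical splitter and seed
#' semantics); the model is re-initialised and the normalisation refitted in
#' every fold. ROC uses predicted class-1 probabilities (binary case).
#'
#' @param fm A `feature_matrix` in PSD_PLV mode.
#' @param k Number of folds.
#' @param cfg An [mcnn_config()].
#' @param builder `build_mcnn` (default) or `build_lenet5`-compatible
#'   function taking a config.
#' @param split `"epoch"` or `"subject"` (see [svm_crossval()]).
#' @param channels Montage labels.
#' @return A `cv_result`.
#' @export
crossval_mcnn <- function(fm, k = 10, cfg = mcnn_config(), builder = build_mcnn,
                          split = c("epoch", "subject"),
                          channels = NULL) {
  split <- match.arg(split)
  stopifnot(inherits(fm, "feature_matrix"))
  n_classes <- length(unique(fm$y))
  if (cfg$n_classes != n_classes) {
    .mp_validation_error("cfg$n_classes (", cfg$n_classes,
                         ") != classes present (", n_classes, ")")
  }
  if (is.null(channels)) {
    side <- floor((-1 + sqrt(1 + 8 * ncol(fm$x))) / 2)  # 528 -> 32
    channels <- if (side == 32) montage32_channels() else paste0("ch", seq_len(side))
  }
  folds <- .make_folds(fm, k, cfg$seed, split)
  confusions <- vector("list", k)
  probs1 <- numeric(nrow(fm$x))
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    nrm <- normalize_features(fm$x[tr, , drop = FALSE])
    xte <- normalize_features(fm$x[te, , drop = FALSE], nrm$stats)$x
    fold_cfg <- cfg; fold_cfg$seed <- cfg$seed + f
    model <- builder(fold_cfg)
    fit <- train_mcnn(model, nrm$x, fm$y[tr], xte, fm$y[te], fold_cfg,
                      channels = channels)
    p <- nn_predict(fit$model, xte, channels)
    pred <- max.col(p) - 1L
    confusions[[f]] <- .confusion(fm$y[te], pred, n_classes)
    if (n_classes == 2) probs1[te] <- p[, 2] / pmax(rowSums(p), 1e-12)
  }
  metrics <- compute_metrics(confusions)
  roc <- if (n_classes == 2) roc_auc(probs1, fm$y) else {
    # macro-averaged one-vs-rest AUC is not reported for 3 classes here
    list(roc_points = NULL, auc = NA_real_)
  }
  structure(
    list(model = "mcnn", confusions = confusions, accuracy = metrics$accuracy,
         sensitivity = metrics$sensitivity, specificity = metrics$specificity,
         per_fold = metrics$per_fold, roc_points = roc$roc_points,
         auc = roc$auc, fold_assignments = folds, seed = cfg$seed, k = k,
         split = split, groups = fm$groups, band = fm$band, mode = fm$mode),
    class = "cv_result"
  )
}
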