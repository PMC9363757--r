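# A compact CNN engine (forward + backprop + SGD) sufficient for the
# multi-scale CNN and the LeNet-5 baseline. No deep-learning framework is
# available in the target environment, so the layers are implemented here
# with vectorised matrix algebra.
#
# Tensor layout: activations are 4-d arrays (H, W, B, C) — batch third so a
# kernel-offset slice flattens directly to a (H*W*B) x C matrix; dense-layer
# activations are (B, features) matrices.

.he_init <- function(n, fan_in) rnorm(n, 0, sqrt(2 / fan_in))

nn_conv <- function(in_ch, out_ch, kh, kw, pad = 0, activation = "relu") {
  # pad: integer (symmetric), or "same" (odd kernels only)
  list(type = "conv", in_ch = in_ch, out_ch = out_ch, kh = kh, kw = kw,
       pad = pad, activation = activation,
       W = array(.he_init(kh * kw * in_ch * out_ch, kh * kw * in_ch),
                 dim = c(kh, kw, in_ch, out_ch)),
       b = rep(0, out_ch))
}

nn_pool <- function(ph, pw) list(type = "pool", ph = ph, pw = pw)

nn_flatten <- function() list(type = "flatten")

nn_dense <- function(n_in, n_out, activation = "linear") {
  list(type = "dense", n_in = n_in, n_out = n_out, activation = activation,
       W = matrix(.he_init(n_in * n_out, n_in), n_in, n_out),
       b = rep(0, n_out))
}

nn_dropout <- function(rate) list(type = "dropout", rate = rate)

nn_residual <- function(layers) {
  # identity skip around a shape-preserving body
  list(type = "residual", body = layers)
}

.pad_hw <- function(x, ph, pw) {
  if (ph == 0 && pw == 0) return(x)
  d <- dim(x)
  out <- array(0, dim = c(d[1] + 2 * ph, d[2] + 2 * pw, d[3], d[4]))
  out[ph + seq_len(d[1]), pw + seq_len(d[2]), , ] <- x
  out
}

.conv_pad <- function(layer) {
  if (identical(layer$pad, "same")) {
    c((layer$kh - 1) / 2, (layer$kw - 1) / 2)
  } else {
    p <- as.numeric(layer$pad)
    if (length(p) == 1) c(p, p) else p
  }
}

.conv_forward <- function(layer, x) {
  d <- dim(x)
  pd <- .conv_pad(layer)
  if (d[4] != layer$in_ch) {
    .mp_validation_error("conv expects ", layer$in_ch, " input channels, got ", d[4])
  }
  xp <- .pad_hw(x, pd[1], pd[2])
  dp <- dim(xp)
  Ho <- dp[1] - layer$kh + 1
  Wo <- dp[2] - layer$kw + 1
  if (Ho < 1 || Wo < 1) {
    .mp_validation_error("conv kernel ", layer$kh, "x", layer$kw,
                         " larger than padded input ", dp[1], "x", dp[2])
  }
  B <- d[3]
  Xcol <- .conv_gather_cpp(xp, dim(xp), layer$kh, layer$kw)
  Wfull <- matrix(layer$W, ncol = layer$out_ch)
  out <- sweep(Xcol %*% Wfull, 2, layer$b, "+")
  pre <- out
  if (layer$activation == "relu") out <- pmax(out, 0)
  layer$cache <- list(Xcol = Xcol, pre = pre, Ho = Ho, Wo = Wo, B = B,
                      din = d, dimp = dim(xp))
  dim(out) <- c(Ho, Wo, B, layer$out_ch)
  list(layer = layer, out = out)
}

.conv_backward <- function(layer, dout) {
  cc <- layer$cache
  Ho <- cc$Ho; Wo <- cc$Wo; B <- cc$B
  dO <- dout
  dim(dO) <- c(Ho * Wo * B, layer$out_ch)
  if (layer$activation == "relu") dO <- dO * (cc$pre > 0)
  pd <- .conv_pad(layer)
  Wfull <- matrix(layer$W, ncol = layer$out_ch)
  dW <- crossprod(cc$Xcol, dO)
  dim(dW) <- dim(layer$W)
  dXcol <- dO %*% t(Wfull)
  dxp <- .conv_scatter_cpp(dXcol, cc$dimp, layer$kh, layer$kw)
  db <- colSums(dO)
  dx <- if (pd[1] > 0 || pd[2] > 0) {
    dxp[pd[1] + seq_len(cc$din[1]), pd[2] + seq_len(cc$din[2]), , , drop = FALSE]
  } else dxp
  layer$grad <- list(W = dW, b = db)
  list(layer = layer, dx = dx)
}

.pool_forward <- function(layer, x) {
  d <- dim(x)
  if (d[1] < layer$ph || d[2] < layer$pw) {
    .mp_validation_error("pooling window larger than input")
  }
  r <- .maxpool_cpp(x, d, layer$ph, layer$pw)
  layer$cache <- list(amax = r$amax, din = d)
  list(layer = layer, out = r$out)
}

.pool_backward <- function(layer, dout) {
  cc <- layer$cache
  dx <- .maxpool_back_cpp(dout, cc$amax, cc$din, layer$ph, layer$pw)
  list(layer = layer, dx = dx)
}

.flatten_forward <- function(layer, x) {
  d <- dim(x)
  out <- aperm(x, c(3, 1, 2, 4))
  dim(out) <- c(d[3], d[1] * d[2] * d[4])
  layer$cache <- list(din = d)
  list(layer = layer, out = out)
}

.flatten_backward <- function(layer, dout) {
  d <- layer$cache$din
  dim(dout) <- c(d[3], d[1], d[2], d[4])
  list(layer = layer, dx = aperm(dout, c(2, 3, 1, 4)))
}

.dense_forward <- function(layer, x) {
  pre <- sweep(x %*% layer$W, 2, layer$b, "+")
  out <- switch(layer$activation,
                linear = pre,
                relu = pmax(pre, 0),
                sigmoid = 1 / (1 + exp(-pre)),
                softmax = {
                  e <- exp(pre - apply(pre, 1, max))
                  e / rowSums(e)
                })
  layer$cache <- list(x = x, pre = pre, out = out)
  list(layer = layer, out = out)
}

.dense_backward <- function(layer, dout, through_activation = TRUE) {
  cc <- layer$cache
  dpre <- dout
  if (through_activation) {
    dpre <- switch(layer$activation,
                   linear = dout,
                   relu = dout * (cc$pre > 0),
                   sigmoid = dout * cc$out * (1 - cc$out),
                   softmax = .mp_stop("softmax backward must fuse with the loss"))
  }
  layer$grad <- list(W = crossprod(cc$x, dpre), b = colSums(dpre))
  list(layer = layer, dx = dpre %*% t(layer$W))
}

.dropout_forward <- function(layer, x, train) {
  if (!train || layer$rate <= 0) {
    layer$cache <- list(mask = NULL)
    return(list(layer = layer, out = x))
  }
  mask <- (matrix(runif(length(x)), nrow(x)) >= layer$rate) / (1 - layer$rate)
  layer$cache <- list(mask = mask)
  list(layer = layer, out = x * mask)
}

.dropout_backward <- function(layer, dout) {
  m <- layer$cache$mask
  list(layer = layer, dx = if (is.null(m)) dout else dout * m)
}

# forward through a list of layers; returns list(layers, out)
nn_seq_forward <- function(layers, x, train = FALSE) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    r <- switch(l$type,
      conv = .conv_forward(l, x),
      pool = .pool_forward(l, x),
      flatten = .flatten_forward(l, x),
      dense = .dense_forward(l, x),
      dropout = .dropout_forward(l, x, train),
      residual = {
        rb <- nn_seq_forward(l$body, x, train)
        if (!identical(dim(rb$out), dim(x))) {
          .mp_validation_error("residual body must preserve shape (",
                               paste(dim(x), collapse = "x"), " -> ",
                               paste(dim(rb$out), collapse = "x"), ")")
        }
        l$body <- rb$layers
        list(layer = l, out = rb$out + x)
      })
    layers[[i]] <- r$layer
    x <- r$out
  }
  list(layers = layers, out = x)
}

nn_seq_backward <- function(layers, dout) {
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    r <- switch(l$type,
      conv = .conv_backward(l, dout),
      pool = .pool_backward(l, dout),
      flatten = .flatten_backward(l, dout),
      dense = .dense_backward(l, dout),
      dropout = .dropout_backward(l, dout),
      residual = {
        rb <- nn_seq_backward(l$body, dout)
        l$body <- rb$layers
        list(layer = l, dx = rb$dx + dout)
      })
    layers[[i]] <- r$layer
    dout <- r$dx
  }
  list(layers = layers, dx = dout)
}

nn_seq_update <- function(layers, lr) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type %in% c("conv", "dense") && !is.null(l$grad)) {
      l$W <- l$W - lr * l$grad$W
      l$b <- l$b - lr * l$grad$b
      l$grad <- NULL
    } else if (l$type == "residual") {
      l$body <- nn_seq_update(l$body, lr)
    }
    l$cache <- NULL
    layers[[i]] <- l
  }
  layers
}

nn_seq_params <- function(layers, prefix = "") {
  out <- list()
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    nm <- paste0(prefix, i, "_", l$type)
    if (l$type %in% c("conv", "dense")) {
      out[[paste0(nm, "_W")]] <- l$W
      out[[paste0(nm, "_b")]] <- l$b
    } else if (l$type == "residual") {
      out <- c(out, nn_seq_params(l$body, paste0(nm, "_")))
    }
  }
  out
}

nn_count_params <- function(model) {
  sum(vapply(nn_model_params(model), length, numeric(1)))
}

nn_model_params <- function(model) {
  c(nn_seq_params(model$branches[[1]], "b1_"),
    if (length(model$branches) > 1) nn_seq_params(model$branches[[2]], "b2_"),
    nn_seq_params(model$head, "head_"))
}
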