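# Minimal feed-forward CNN engine used by the posture network.
#
# Activations are stored as dense matrices with one column per sample in the
# batch. A 1-D feature map (C channels x L positions) occupies C*L rows with
# channel fastest: index(c, l) = c + (l-1)*C. A 2-D map (C x H x W) occupies
# C*H*W rows: index(c, h, w) = c + (h-1)*C + (w-1)*C*H. Convolutions are
# evaluated by gathering im2col patch matrices with precomputed index
# vectors, so each layer's forward/backward pass is a handful of dense
# matrix products plus one indexed gather/scatter. Layers are environments
# (mutable parameter/optimizer state).

relu <- function(x) (x > 0) * x

he_uniform <- function(nrow, ncol, fan_in) {
  s <- sqrt(6 / fan_in)
  matrix(runif(nrow * ncol, -s, s), nrow, ncol)
}

same_padding <- function(L, k, s) {
  Lout <- ceiling(L / s)
  pad <- max((Lout - 1L) * s + k - L, 0L)
  list(Lout = as.integer(Lout), before = pad %/% 2L, total = pad)
}

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  e
}

make_conv1d <- function(in_shape, filters, kernel, stride, name) {
  C <- in_shape[1]; L <- in_shape[2]
  p <- same_padding(L, kernel, stride)
  Lp <- L + p$total
  pidx <- as.vector(outer(seq_len(C), (seq_len(L) - 1L + p$before) * C, "+"))
  # gather rows ordered (channel, tap) fastest, output position slowest
  gidx <- integer(C * kernel * p$Lout)
  i <- 1L
  for (j in seq_len(p$Lout)) for (q in seq_len(kernel)) for (c in seq_len(C)) {
    gidx[i] <- c + ((j - 1L) * stride + q - 1L) * C
    i <- i + 1L
  }
  new_layer("conv1d", name = name, C = C, L = L, Lp = Lp, k = kernel,
            stride = stride, Lout = p$Lout, filters = filters,
            pidx = pidx, gidx = gidx, np = C * Lp,
            W = he_uniform(filters, C * kernel, C * kernel),
            b = numeric(filters),
            out_shape = c(filters, p$Lout))
}

make_conv2d <- function(in_shape, filters, kernel, stride, padding, name) {
  C <- in_shape[1]; H <- in_shape[2]; W_in <- in_shape[3]
  kh <- kernel[1]; kw <- kernel[2]; sh <- stride[1]; sw <- stride[2]
  if (padding == "same") {
    ph <- same_padding(H, kh, sh); pw <- same_padding(W_in, kw, sw)
  } else {
    ph <- list(Lout = as.integer((H - kh) %/% sh + 1L), before = 0L, total = 0L)
    pw <- list(Lout = as.integer((W_in - kw) %/% sw + 1L), before = 0L, total = 0L)
  }
  if (ph$Lout < 1 || pw$Lout < 1)
    abort_bad_arg(paste0("layer ", name, ": spatial extent vanishes"))
  Hp <- H + ph$total; Wp <- W_in + pw$total
  pidx <- integer(C * H * W_in)
  i <- 1L
  for (w in seq_len(W_in)) for (h in seq_len(H)) for (c in seq_len(C)) {
    pidx[i] <- c + (h - 1L + ph$before) * C + (w - 1L + pw$before) * C * Hp
    i <- i + 1L
  }
  n_out <- ph$Lout * pw$Lout
  gidx <- integer(C * kh * kw * n_out)
  i <- 1L
  for (wo in seq_len(pw$Lout)) for (ho in seq_len(ph$Lout))
    for (qw in seq_len(kw)) for (qh in seq_len(kh)) for (c in seq_len(C)) {
      h <- (ho - 1L) * sh + qh
      w <- (wo - 1L) * sw + qw
      gidx[i] <- c + (h - 1L) * C + (w - 1L) * C * Hp
      i <- i + 1L
    }
  new_layer("conv2d", name = name, C = C, H = H, W_in = W_in,
            Hp = Hp, Wp = Wp, k = kh * kw, Hout = ph$Lout, Wout = pw$Lout,
            filters = filters, pidx = pidx, gidx = gidx, np = C * Hp * Wp,
            W = he_uniform(filters, C * kh * kw, C * kh * kw),
            b = numeric(filters),
            out_shape = c(filters, ph$Lout, pw$Lout))
}

# candidate-index matrix for max pooling over flattened activations
pool_candidates <- function(C, dims, pool, stride) {
  if (length(dims) == 1) {
    Lout <- (dims - pool) %/% stride + 1L
    cand <- matrix(0L, C * Lout, pool)
    for (q in seq_len(pool)) {
      cand[, q] <- as.vector(outer(seq_len(C),
                                   ((seq_len(Lout) - 1L) * stride + q - 1L) * C, "+"))
    }
    list(cand = cand, out_shape = c(C, Lout))
  } else {
    H <- dims[1]; W_in <- dims[2]; ph <- pool[1]; pw <- pool[2]
    sh <- stride[1]; sw <- stride[2]
    Hout <- (H - ph) %/% sh + 1L; Wout <- (W_in - pw) %/% sw + 1L
    cand <- matrix(0L, C * Hout * Wout, ph * pw)
    q <- 1L
    for (qw in seq_len(pw)) for (qh in seq_len(ph)) {
      col <- integer(C * Hout * Wout)
      i <- 1L
      for (wo in seq_len(Wout)) for (ho in seq_len(Hout)) for (c in seq_len(C)) {
        col[i] <- c + ((ho - 1L) * sh + qh - 1L) * C +
          ((wo - 1L) * sw + qw - 1L) * C * H
        i <- i + 1L
      }
      cand[, q] <- col
      q <- q + 1L
    }
    list(cand = cand, out_shape = c(C, Hout, Wout))
  }
}

make_maxpool <- function(in_shape, pool, stride, name) {
  C <- in_shape[1]
  pc <- pool_candidates(C, in_shape[-1], pool, stride)
  new_layer("maxpool", name = name, C = C, n_in = prod(in_shape),
            cand = pc$cand, out_shape = pc$out_shape)
}

make_gap1d <- function(in_shape, name) {
  new_layer("gap1d", name = name, C = in_shape[1], L = in_shape[2],
            group = rep(seq_len(in_shape[1]), in_shape[2]),
            out_shape = in_shape[1])
}

make_dense <- function(d_in, units, activation, name) {
  new_layer("dense", name = name, d_in = d_in, units = units,
            activation = activation,
            W = he_uniform(units, d_in, d_in), b = numeric(units),
            out_shape = units)
}

make_dropout <- function(d_in, rate, name) {
  new_layer("dropout", name = name, rate = rate, out_shape = d_in)
}

layer_forward <- function(layer, X, train = FALSE) {
  switch(layer$type,
    conv1d = , conv2d = {
      B <- ncol(X)
      if (is.null(layer$cache) || !.conv_cache_ok(layer$cache))
        layer$cache <- .conv_cache_new()
      A <- .conv_fw_cpp(X, layer$pidx, layer$gidx, layer$W, layer$b,
                        layer$np, layer$cache)
      dim(A) <- c(length(A) / B, B)
      A
    },
    maxpool = {
      res <- .maxpool_fw_cpp(X, layer$cand)
      layer$win <- res$win
      layer$n_batch <- ncol(X)
      res$A
    },
    gap1d = {
      rowsum(X, layer$group, reorder = TRUE) / layer$L
    },
    dense = {
      Y <- layer$W %*% X + layer$b
      layer$X <- X
      if (layer$activation == "relu") {
        layer$mask <- Y > 0
        relu(Y)
      } else Y  # linear; softmax applied by the head
    },
    dropout = {
      if (train && layer$rate > 0) {
        keep <- 1 - layer$rate
        m <- matrix(rbinom(length(X), 1, keep) / keep, nrow(X))
        layer$mask <- m
        X * m
      } else {
        layer$mask <- NULL
        X
      }
    })
}

layer_backward <- function(layer, dOut) {
  switch(layer$type,
    conv1d = , conv2d = {
      res <- .conv_bw_cpp(dOut, layer$W, layer$gidx, layer$pidx,
                          layer$np, layer$cache)
      layer$dW <- res$dW
      layer$db <- as.vector(res$db)
      res$dX
    },
    maxpool = {
      .maxpool_bw_cpp(dOut, layer$win, layer$cand, layer$n_in)
    },
    gap1d = {
      dOut[rep(seq_len(layer$C), layer$L), , drop = FALSE] / layer$L
    },
    dense = {
      dY <- if (layer$activation == "relu") dOut * layer$mask else dOut
      layer$dW <- tcrossprod(dY, layer$X)
      layer$db <- rowSums(dY)
      crossprod(layer$W, dY)
    },
    dropout = {
      if (is.null(layer$mask)) dOut else dOut * layer$mask
    })
}

layer_params <- function(layer) {
  if (!is.null(layer$W)) list(W = layer$W, b = layer$b) else NULL
}

# Adam update with decoupled-style L2 weight decay folded into the gradient
# and an L1 subgradient on dense-layer weights
adam_step <- function(layer, lr, t, weight_decay, l1, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  if (is.null(layer$W)) return(invisible(NULL))
  if (is.null(layer$mW)) {
    layer$mW <- layer$W * 0; layer$vW <- layer$W * 0
    layer$mb <- layer$b * 0; layer$vb <- layer$b * 0
  }
  gW <- layer$dW + weight_decay * layer$W
  if (layer$type == "dense" && l1 > 0) gW <- gW + l1 * sign(layer$W)
  gb <- layer$db
  layer$mW <- beta1 * layer$mW + (1 - beta1) * gW
  layer$vW <- beta2 * layer$vW + (1 - beta2) * gW^2
  layer$mb <- beta1 * layer$mb + (1 - beta1) * gb
  layer$vb <- beta2 * layer$vb + (1 - beta2) * gb^2
  c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
  layer$W <- layer$W - lr * (layer$mW / c1) / (sqrt(layer$vW / c2) + eps)
  layer$b <- layer$b - lr * (layer$mb / c1) / (sqrt(layer$vb / c2) + eps)
  invisible(NULL)
}

softmax_cols <- function(Z) {
  Z <- sweep(Z, 2, apply(Z, 2, max))
  E <- exp(Z)
  sweep(E, 2, colSums(E), "/")
}
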