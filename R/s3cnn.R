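#' Configuration of the four-branch spatiotemporal posture network
#'
#' Holds the architecture and training hyperparameters of the posture
#' classifier: two 1-D convolutional branches for the respiration (2 x 90)
#' and heartbeat (2 x 180) amplitude/interval matrices, two 2-D branches for
#' the respiratory and cardiac activity maps (fed long-axis-first as
#' 32 x 16), each branch ending in a 32-long feature vector; the four
#' vectors are stacked (32 x 4), flattened and passed through fully
#' connected layers of width 64 and 96 with dropout, then a softmax over the
#' three postures.
#'
#' @param branches Character subset of `c("M1", "M2", "N1", "N2")`; the
#'   temporal-only and spatial-only ablation variants use the first or last
#'   pair.
#' @param head Widths of the two fully connected layers (default `c(64, 96)`).
#' @param classes Number of posture classes (3).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param batch_size Mini-batch size (default 48).
#' @param epochs Maximum training epochs (default 100).
#' @param weight_decay L2 penalty applied through the optimizer (0.0005).
#' @param dropout Dropout rate after each head layer (0.5).
#' @param l1 L1 penalty coefficient on dense-layer weights (1e-5).
#' @return An `s3cnn_config` object.
#' @export
s3cnn_config <- function(branches = c("M1", "M2", "N1", "N2"),
                         head = c(64, 96), classes = 3,
                         learning_rate = 0.001, batch_size = 48,
                         epochs = 100, weight_decay = 5e-4, dropout = 0.5,
                         l1 = 1e-5) {
  branches <- match.arg(branches, c("M1", "M2", "N1", "N2"), several.ok = TRUE)
  structure(list(branches = branches, head = head, classes = classes,
                 learning_rate = learning_rate, batch_size = batch_size,
                 epochs = epochs, weight_decay = weight_decay,
                 dropout = dropout, l1 = l1),
            class = "s3cnn_config")
}

branch_layers <- function(name) {
  switch(name,
    M1 = function() {
      l1 <- make_conv1d(c(2L, 90L), 16L, 11L, 1L, "conv1d1_l1")
      l2 <- make_conv1d(l1$out_shape, 24L, 11L, 2L, "conv1d1_l2")
      l3 <- make_conv1d(l2$out_shape, 32L, 11L, 2L, "conv1d1_l3")
      list(l1, l2, l3, make_gap1d(l3$out_shape, "gap1"))
    },
    M2 = function() {
      l1 <- make_conv1d(c(2L, 180L), 16L, 11L, 2L, "conv1d2_l1")
      l2 <- make_conv1d(l1$out_shape, 24L, 11L, 2L, "conv1d2_l2")
      p <- make_maxpool(l2$out_shape, 3L, 1L, "maxpool1d")
      l3 <- make_conv1d(p$out_shape, 32L, 11L, 1L, "conv1d2_l3")
      list(l1, l2, p, l3, make_gap1d(l3$out_shape, "gap2"))
    },
    N1 = function() {
      l1 <- make_conv2d(c(1L, 32L, 16L), 6L, c(3L, 3L), c(2L, 2L), "same", "conv2d1_l1")
      l2 <- make_conv2d(l1$out_shape, 16L, c(3L, 3L), c(2L, 2L), "same", "conv2d1_l2")
      p <- make_maxpool(l2$out_shape, c(2L, 2L), c(2L, 2L), "maxpool2d1")
      l3 <- make_conv2d(p$out_shape, 32L, c(4L, 2L), c(1L, 1L), "valid", "conv2d1_l3")
      list(l1, l2, p, l3,
           make_maxpool(l3$out_shape, l3$out_shape[2:3], l3$out_shape[2:3],
                        "adapt_max1"))
    },
    N2 = function() {
      l1 <- make_conv2d(c(1L, 32L, 16L), 12L, c(3L, 3L), c(2L, 2L), "same", "conv2d2_l1")
      p1 <- make_maxpool(l1$out_shape, c(2L, 2L), c(2L, 2L), "maxpool2d2")
      l2 <- make_conv2d(p1$out_shape, 24L, c(3L, 3L), c(1L, 1L), "same", "conv2d2_l2")
      p2 <- make_maxpool(l2$out_shape, c(2L, 2L), c(2L, 2L), "maxpool2d3")
      l3 <- make_conv2d(p2$out_shape, 32L, c(4L, 2L), c(1L, 1L), "valid", "conv2d2_l3")
      list(l1, p1, l2, p2, l3,
           make_maxpool(l3$out_shape, l3$out_shape[2:3], l3$out_shape[2:3],
                        "adapt_max2"))
    })
}

#' Build the posture network
#'
#' Constructs the branch and head layers with fan-in-uniform initial
#' weights. Construction fails, naming the offending layer, if any branch
#' does not end in a 32-long feature vector.
#'
#' @param config An [s3cnn_config()].
#' @param seed Integer seed for weight initialization.
#' @return An `s3cnn` model object.
#' @export
build_s3cnn <- function(config = s3cnn_config(), seed = 1) {
  stopifnot(inherits(config, "s3cnn_config"))
  with_seed(seed, {
    branches <- lapply(config$branches, function(nm) branch_layers(nm)())
    names(branches) <- config$branches
    for (nm in names(branches)) {
      last <- branches[[nm]][[length(branches[[nm]])]]
      if (prod(last$out_shape) != 32)
        abort_bad_arg(paste0("branch ", nm, ": layer ", last$name,
                             " yields a ", prod(last$out_shape),
                             "-long feature vector, expected 32"))
    }
    d_in <- 32L * length(branches)
    head <- list(
      make_dense(d_in, config$head[1], "relu", "fc1"),
      make_dropout(config$head[1], config$dropout, "drop1"),
      make_dense(config$head[1], config$head[2], "relu", "fc2"),
      make_dropout(config$head[2], config$dropout, "drop2"),
      make_dense(config$head[2], config$classes, "linear", "fc_out")
    )
    structure(list(branches = branches, head = head, config = config,
                   norm = NULL, classes = posture_levels()),
              class = "s3cnn")
  })
}

#' Number of trainable parameters of a posture network
#' @param model An `s3cnn`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "s3cnn"))
  layers <- c(unlist(model$branches, use.names = FALSE), model$head)
  sum(vapply(layers, function(l)
    if (is.null(l$W)) 0L else length(l$W) + length(l$b), 0L))
}

# z-score the two temporal feature rows with training-set statistics
normalize_batch <- function(model, batch) {
  nz <- model$norm
  for (nm in intersect(c("M1", "M2"), names(batch))) {
    X <- batch[[nm]]
    rows <- rep(1:2, length.out = nrow(X))
    for (r in 1:2) {
      sel <- rows == r
      X[sel, ] <- (X[sel, ] - nz[[nm]]$center[r]) / nz[[nm]]$scale[r]
    }
    batch[[nm]] <- X
  }
  batch
}

forward_s3cnn <- function(model, batch, train = FALSE) {
  outs <- lapply(names(model$branches), function(nm) {
    A <- batch[[nm]]
    for (layer in model$branches[[nm]]) A <- layer_forward(layer, A, train)
    A
  })
  S <- do.call(rbind, outs)
  A <- S
  for (layer in model$head) A <- layer_forward(layer, A, train)
  list(probs = softmax_cols(A), stacked = S,
       branch_rows = vapply(outs, nrow, 0L))
}

backward_s3cnn <- function(model, fwd, y_idx) {
  B <- length(y_idx)
  dZ <- fwd$probs
  dZ[cbind(y_idx, seq_len(B))] <- dZ[cbind(y_idx, seq_len(B))] - 1
  dZ <- dZ / B
  dA <- dZ
  for (layer in rev(model$head)) dA <- layer_backward(layer, dA)
  offs <- c(0L, cumsum(fwd$branch_rows))
  for (i in seq_along(model$branches)) {
    dBr <- dA[(offs[i] + 1):offs[i + 1], , drop = FALSE]
    for (layer in rev(model$branches[[i]])) dBr <- layer_backward(layer, dBr)
  }
  invisible(NULL)
}

#' Train the posture network
#'
#' Mini-batch Adam training with cross-entropy loss, optimizer weight decay,
#' an L1 penalty on dense-layer weights and dropout in the head. Training is
#' deterministic given `seed` (shuffling, dropout and initialization all
#' flow from the R RNG). Temporal feature rows are z-scored with statistics
#' computed from the training set and stored in the model.
#'
#' @param model An `s3cnn` from [build_s3cnn()].
#' @param batch Input list from [assemble_batch()] (elements `M1`, `M2`,
#'   `N1`, `N2`; columns are samples).
#' @param labels Factor (or character) of posture labels, all three classes
#'   present.
#' @param config Training configuration; defaults to the model's.
#' @param seed Integer seed.
#' @return The fitted model, with a `history` tibble (epoch, loss, accuracy)
#'   attached as `model$history`.
#' @export
train_s3cnn <- function(model, batch, labels, config = model$config, seed = 1) {
  stopifnot(inherits(model, "s3cnn"))
  y <- factor(as.character(labels), levels = model$classes)
  if (anyNA(y)) abort_bad_arg("labels outside the known posture classes")
  if (nlevels(droplevels(y)) < length(model$classes))
    abort_bad_arg("all posture classes must be present in the training set")
  y_idx <- as.integer(y)
  n <- length(y_idx)
  model$norm <- lapply(batch[intersect(c("M1", "M2"), names(batch))],
                       function(X) {
    rows <- rep(1:2, length.out = nrow(X))
    center <- c(mean(X[rows == 1, ]), mean(X[rows == 2, ]))
    scl <- c(sd(X[rows == 1, ]), sd(X[rows == 2, ]))
    scl[scl == 0 | !is.finite(scl)] <- 1
    list(center = center, scale = scl)
  })
  nb <- normalize_batch(model, batch)
  hist_rows <- vector("list", config$epochs)
  with_seed(seed, {
    t_step <- 0L
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      ep_loss <- 0; ep_correct <- 0
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1, n)]
        mb <- lapply(nb, function(X) X[, idx, drop = FALSE])
        fwd <- forward_s3cnn(model, mb, train = TRUE)
        p <- fwd$probs[cbind(y_idx[idx], seq_along(idx))]
        ep_loss <- ep_loss - sum(log(pmax(p, 1e-12)))
        ep_correct <- ep_correct +
          sum(apply(fwd$probs, 2, which.max) == y_idx[idx])
        backward_s3cnn(model, fwd, y_idx[idx])
        t_step <- t_step + 1L
        for (layer in c(unlist(model$branches, use.names = FALSE), model$head))
          adam_step(layer, config$learning_rate, t_step,
                    config$weight_decay, config$l1)
      }
      hist_rows[[epoch]] <- tibble::tibble(
        epoch = epoch, loss = ep_loss / n, accuracy = ep_correct / n)
    }
  })
  model$history <- dplyr::bind_rows(hist_rows)
  model
}

#' Predict posture probabilities and labels
#'
#' @param object A fitted `s3cnn`.
#' @param newdata Input list from [assemble_batch()].
#' @param ... Unused.
#' @return A list with `prob` (samples x 3 matrix, columns named by posture,
#'   rows summing to 1) and `class` (factor of argmax labels).
#' @export
predict.s3cnn <- function(object, newdata, ...) {
  need <- names(object$branches)
  if (!all(need %in% names(newdata)))
    abort_bad_arg("`newdata` lacks inputs for branches: ",
                  paste(setdiff(need, names(newdata)), collapse = ", "))
  for (nm in need) {
    expected <- switch(nm, M1 = 180L, M2 = 360L, N1 = 512L, N2 = 512L)
    if (nrow(newdata[[nm]]) != expected)
      abort_bad_arg(paste0("branch ", nm, " expects ", expected, " rows"))
  }
  nb <- normalize_batch(object, newdata)
  fwd <- forward_s3cnn(object, nb, train = FALSE)
  prob <- t(fwd$probs)
  colnames(prob) <- object$classes
  list(prob = prob,
       class = factor(object$classes[apply(prob, 1, which.max)],
                      levels = object$classes))
}
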