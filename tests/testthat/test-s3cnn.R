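random_batch <- function(B, branches = c("M1", "M2", "N1", "N2")) {
  full <- list(M1 = matrix(rnorm(180 * B), 180),
               M2 = matrix(rnorm(360 * B), 360),
               N1 = matrix(abs(rnorm(512 * B)), 512),
               N2 = matrix(abs(rnorm(512 * B)), 512))
  full[branches]
}

test_that("each branch ends in a 32-long vector and the stack is 32x4", {
  mdl <- build_s3cnn(s3cnn_config(), seed = 1)
  for (nm in names(mdl$branches)) {
    last <- mdl$branches[[nm]][[length(mdl$branches[[nm]])]]
    expect_equal(prod(last$out_shape), 32)
  }
  set.seed(1)
  batch <- random_batch(5)
  mdl$norm <- list(M1 = list(center = c(0, 0), scale = c(1, 1)),
                   M2 = list(center = c(0, 0), scale = c(1, 1)))
  fwd <- sleepmat:::forward_s3cnn(mdl, batch)
  expect_equal(dim(fwd$stacked), c(128, 5))  # 32 x 4 branches, flattened
  expect_equal(fwd$branch_rows, rep(32L, 4))
  # softmax normalization exact
  expect_equal(colSums(fwd$probs), rep(1, 5), tolerance = 1e-6)
})

test_that("the first temporal convolution matches its stated geometry", {
  mdl <- build_s3cnn(s3cnn_config(), seed = 1)
  l1 <- mdl$branches$M1[[1]]
  expect_equal(l1$filters, 16L)
  expect_equal(l1$k, 11L)
  expect_equal(l1$stride, 1L)
  expect_equal(l1$out_shape, c(16L, 90L))  # "same" padding keeps length
  # head widths 64 -> 96 -> 3
  expect_equal(mdl$head[[1]]$units, 64)
  expect_equal(mdl$head[[3]]$units, 96)
  expect_equal(mdl$head[[5]]$units, 3)
})

test_that("parameter count is tens of thousands, not millions", {
  mdl <- build_s3cnn(s3cnn_config(), seed = 1)
  expect_lt(n_parameters(mdl), 1e6)
  expect_gt(n_parameters(mdl), 1e4)
})

test_that("an infeasible architecture fails naming the offending layer", {
  bad <- s3cnn_config()
  expect_error(
    with(list(), {
      # a 16 x 32-oriented map cannot reach 1 x 1 through the stated strides
      layers <- sleepmat:::branch_layers("N1")
      l1 <- sleepmat:::make_conv2d(c(1L, 16L, 32L), 6L, c(3L, 3L),
                                   c(2L, 2L), "same", "conv2d1_l1")
      l2 <- sleepmat:::make_conv2d(l1$out_shape, 16L, c(3L, 3L),
                                   c(2L, 2L), "same", "conv2d1_l2")
      p <- sleepmat:::make_maxpool(l2$out_shape, c(2L, 2L), c(2L, 2L), "mp")
      sleepmat:::make_conv2d(p$out_shape, 32L, c(4L, 2L), c(1L, 1L),
                             "valid", "conv2d1_l3")
    }),
    "conv2d1_l3")
})

test_that("backpropagation matches finite differences", {
  cfg <- s3cnn_config(dropout = 0)
  mdl <- build_s3cnn(cfg, seed = 3)
  mdl$norm <- list(M1 = list(center = c(0, 0), scale = c(1, 1)),
                   M2 = list(center = c(0, 0), scale = c(1, 1)))
  set.seed(9)
  B <- 3
  batch <- random_batch(B)
  y <- c(1L, 2L, 3L)
  loss_fn <- function() {
    fwd <- sleepmat:::forward_s3cnn(mdl, batch, train = FALSE)
    -mean(log(fwd$probs[cbind(y, seq_len(B))]))
  }
  fwd <- sleepmat:::forward_s3cnn(mdl, batch, train = TRUE)
  sleepmat:::backward_s3cnn(mdl, fwd, y)
  layers <- c(unlist(mdl$branches, use.names = FALSE), mdl$head)
  for (L in layers) {
    if (is.null(L$W)) next
    for (trial in 1:3) {
      i <- sample(length(L$W), 1)
      eps <- 1e-6
      w0 <- L$W[i]
      L$W[i] <- w0 + eps; lp <- loss_fn()
      L$W[i] <- w0 - eps; lm <- loss_fn()
      L$W[i] <- w0
      num <- (lp - lm) / (2 * eps)
      expect_equal(L$dW[i], num, tolerance = 1e-4)
    }
  }
})

test_that("training overfits a single memorizable batch", {
  set.seed(11)
  B <- 48
  batch <- random_batch(B)
  y <- factor(sample(posture_levels(), B, replace = TRUE),
              levels = posture_levels())
  cfg <- s3cnn_config(epochs = 100, dropout = 0.2)
  fit <- train_s3cnn(build_s3cnn(cfg, seed = 1), batch, y, cfg, seed = 1)
  expect_equal(mean(predict(fit, batch)$class == y), 1)
  expect_lte(nrow(fit$history), 100)  # epoch cap honored
  # loss decreased from the first epoch
  expect_lt(fit$history$loss[nrow(fit$history)], fit$history$loss[1])
})

test_that("one optimizer step on a fixed batch decreases the loss", {
  set.seed(13)
  B <- 16
  batch <- random_batch(B)
  y <- factor(rep(posture_levels(), length.out = B), levels = posture_levels())
  cfg <- s3cnn_config(epochs = 1, dropout = 0)
  mdl <- build_s3cnn(cfg, seed = 5)
  mdl$norm <- list(M1 = list(center = c(0, 0), scale = c(1, 1)),
                   M2 = list(center = c(0, 0), scale = c(1, 1)))
  loss0 <- -mean(log(sleepmat:::forward_s3cnn(mdl, batch)$probs[
    cbind(as.integer(y), seq_len(B))]))
  fit <- train_s3cnn(mdl, batch, y, cfg, seed = 5)
  loss1 <- fit$history$loss[1]
  expect_lt(loss1, loss0 + 1e-9)
})

test_that("training is deterministic given the seed", {
  set.seed(17)
  B <- 24
  batch <- random_batch(B)
  y <- factor(rep(posture_levels(), length.out = B), levels = posture_levels())
  cfg <- s3cnn_config(epochs = 3)
  f1 <- train_s3cnn(build_s3cnn(cfg, seed = 2), batch, y, cfg, seed = 2)
  f2 <- train_s3cnn(build_s3cnn(cfg, seed = 2), batch, y, cfg, seed = 2)
  expect_identical(f1$head[[5]]$W, f2$head[[5]]$W)
  expect_identical(f1$branches$M1[[1]]$W, f2$branches$M1[[1]]$W)
  expect_identical(f1$history, f2$history)
})

test_that("prediction is stateless under batch permutation", {
  set.seed(19)
  B <- 10
  batch <- random_batch(B)
  y <- factor(rep(posture_levels(), length.out = B), levels = posture_levels())
  cfg <- s3cnn_config(epochs = 2)
  fit <- train_s3cnn(build_s3cnn(cfg, seed = 4), batch, y, cfg, seed = 4)
  p1 <- predict(fit, batch)
  perm <- sample(B)
  p2 <- predict(fit, lapply(batch, function(X) X[, perm, drop = FALSE]))
  expect_equal(p2$prob, p1$prob[perm, ], tolerance = 1e-12)
  expect_equal(rowSums(p1$prob), rep(1, B), tolerance = 1e-9)
  # missing class in training errors
  expect_error(train_s3cnn(build_s3cnn(cfg, seed = 4), batch,
                           factor(rep("supine", B), posture_levels()),
                           cfg, seed = 1),
               "classes")
  # shape mismatch errors
  bad <- batch
  bad$M1 <- bad$M1[1:100, ]
  expect_error(predict(fit, bad), "180")
})
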