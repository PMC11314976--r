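test_that("energy entropy matches hand-enumerated and analytic values", {
  # two windows with energies 2 and 8: p = (0.2, 0.8), H = 0.5004 nats
  expect_equal(energy_entropy(c(1, 1, 2, 2), 2, 2), 0.5004024, tolerance = 1e-6)
  # identical windows maximize entropy at log(K)
  x <- rep(c(1, -2, 3), 10)
  expect_equal(energy_entropy(x, 3, 3), log(10), tolerance = 1e-12)
  # all-zero signal is defined as zero entropy
  expect_equal(energy_entropy(numeric(100), 10, 5), 0)
  # partial trailing windows are dropped
  expect_equal(energy_entropy(c(1, 1, 1, 1, 9), 2, 2), log(2), tolerance = 1e-12)
  expect_error(energy_entropy(1:3, 5, 1), "window")
})

test_that("ApEn agrees with the naive reference to 1e-9", {
  set.seed(2024)
  for (k in 1:12) {
    n <- sample(150:300, 1)
    x <- switch(1 + k %% 3,
                rnorm(n),
                sin(seq(0, 20, length.out = n)) + rnorm(n, 0, 0.2),
                cumsum(rnorm(n)))
    r <- 0.2 * sd(x)
    expect_equal(approx_entropy(x, 2, r), apen_reference(x, 2, r),
                 tolerance = 1e-9)
  }
})

test_that("ApEn handles degenerate and regular inputs", {
  expect_equal(approx_entropy(rep(3.7, 100)), 0)
  # a clean sinusoid is more regular than white noise of equal variance
  set.seed(31)
  sines <- replicate(20, {
    ph <- runif(1, 0, 2 * pi)
    s <- sin(seq(0, 30, length.out = 300) + ph)
    approx_entropy(s / sd(s))
  })
  noises <- replicate(20, approx_entropy(rnorm(300)))
  expect_lt(median(sines), median(noises))
})

test_that("channel features are ordered, finite and zero for zero input", {
  d <- fx_decomp()
  f <- channel_features(d, 1)
  expect_named(f, c("resp_ent_energy", "bcg_ent_energy", "dev_ent_energy",
                    "resp_ent_approx", "bcg_ent_approx", "dev_ent_approx"))
  expect_true(all(is.finite(f)))
  dz <- decompose_minute(matrix(0, 1, 6000))
  expect_equal(unname(channel_features(dz, 1)), rep(0, 6))
  expect_error(channel_features(d, 40), "channel")
})

test_that("burst contamination shifts the deviation entropies consistently", {
  # bursts concentrate variance in short windows, so both the deviation
  # energy entropy and (radius scaling with the inflated SD) the deviation
  # ApEn drop for contaminated channels
  set.seed(64)
  prof <- default_profile()
  tpl <- spatial_template("supine")
  lower_apen <- 0
  lower_ee <- 0
  n_try <- 25
  for (i in seq_len(n_try)) {
    clean <- synth_minute(prof, tpl)
    cont <- synth_minute(prof, tpl, movement = TRUE)
    ch <- which(cont$per_channel_movement)[1]
    fc <- channel_features(decompose_minute(clean), ch)
    fb <- channel_features(decompose_minute(cont), ch)
    lower_apen <- lower_apen + (fb["dev_ent_approx"] < fc["dev_ent_approx"])
    lower_ee <- lower_ee + (fb["dev_ent_energy"] < fc["dev_ent_energy"])
  }
  expect_gte(lower_apen / n_try, 0.9)
  expect_gte(lower_ee / n_try, 0.9)
})

test_that("the channel MLP separates linearly separable toy features", {
  set.seed(8)
  X <- rbind(matrix(rnorm(60 * 6, 0), ncol = 6),
             matrix(rnorm(60 * 6, 4), ncol = 6))
  y <- rep(c(FALSE, TRUE), each = 60)
  fit <- train_artifact_mlp(X, y, seed = 2)
  expect_equal(mean((predict(fit, X) > 0.5) == y), 1)
  expect_error(train_artifact_mlp(X, rep(TRUE, 120)), "both classes")
})

test_that("channel classifier reaches ROC area >= 0.9 on held-out channels", {
  am <- fx_artifact_model()
  coh <- simulate_cohort(2, 30, master_seed = 2718, movement_rate = 0.5)
  dec <- lapply(coh$minutes, decompose_minute)
  td <- sleepmat:::artifact_training_data(dec)
  p <- predict(am$model, td$features)
  roc <- pROC::roc(response = td$labels, predictor = p, quiet = TRUE,
                   direction = "<", levels = c(FALSE, TRUE))
  expect_gte(as.numeric(pROC::auc(roc)), 0.9)
})

test_that("minute flagging follows the >= 7 channel rule monotonically", {
  expect_true(flag_sample(c(rep(TRUE, 7), rep(FALSE, 25)))$sample_flag)
  expect_false(flag_sample(c(rep(TRUE, 6), rep(FALSE, 26)))$sample_flag)
  expect_false(flag_sample(rep(FALSE, 32))$sample_flag)
  expect_true(flag_sample(rep(TRUE, 32))$sample_flag)
  expect_error(flag_sample(rep(TRUE, 16)), "32")
  # adding a flagged channel never un-flags the minute
  set.seed(12)
  for (i in 1:20) {
    flags <- runif(32) < runif(1)
    dec0 <- flag_sample(flags)
    if (!all(flags)) {
      flags2 <- flags
      flags2[which(!flags2)[1]] <- TRUE
      expect_gte(flag_sample(flags2)$sample_flag, dec0$sample_flag)
    }
  }
  expect_equal(flag_sample(rep(c(TRUE, FALSE), c(5, 27)))$interfered_count, 5)
})

test_that("decision threshold sits at probability 0.5", {
  am <- fx_artifact_model()$model
  d <- fx_decomp()
  p <- predict(am, sleepmat:::minute_feature_matrix(d))
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(flag_sample(p > 0.5)$channel_flags, unname(p > 0.5))
})
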