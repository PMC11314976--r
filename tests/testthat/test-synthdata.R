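test_that("sensor transfer follows the amplifier model", {
  p <- piezo_params()
  # zero force gives zero voltage, any frequency
  expect_equal(sensor_transfer(0, 2 * pi * 0.25, p), 0)
  expect_equal(sensor_transfer(0, 2 * pi * 10, p), 0)
  # closed form at omega*RM*CM = 1
  omega <- 1 / (p$RM * p$CM)
  expect_equal(sensor_transfer(1, omega, p),
               p$beta * p$d33 * p$RM * omega / sqrt(2))
  # high-frequency limit: within 1% of beta*d33*Fm/CM when (wRC)^2 >= 100
  omega_hi <- 10.5 / (p$RM * p$CM)
  expect_lt(abs(sensor_transfer(2, omega_hi, p) - p$beta * p$d33 * 2 / p$CM) /
              (p$beta * p$d33 * 2 / p$CM), 0.01)
  # monotone increasing in force amplitude
  u <- sensor_transfer(c(1, 2, 5), 2 * pi, p)
  expect_true(all(diff(u) > 0))
  expect_error(sensor_transfer(1, -3, p), "omega")
  expect_error(piezo_params(d33 = 700e-12), "d33")
})

test_that("posture schedules conserve time and bound the change count", {
  s <- make_posture_schedule(420, rng_seed = 1)
  expect_s3_class(s, "posture_schedule")
  expect_equal(sum(s$duration), 420)
  for (seed in 1:20) {
    s <- make_posture_schedule(420, rng_seed = seed)
    expect_gte(nrow(s), 16)
    expect_lte(nrow(s), 26)
    # consecutive segments always change posture
    expect_true(all(diff(as.integer(s$posture)) != 0))
  }
  s60 <- make_posture_schedule(60, rng_seed = 3)
  expect_gte(nrow(s60), 1)
  expect_equal(sum(s60$duration), 60)
  expect_error(make_posture_schedule(30), "60")
})

test_that("long-run posture mix approximates the cohort's 50/34/17 split", {
  set.seed(99)
  frac <- replicate(400, {
    s <- make_posture_schedule(420)
    sum(s$duration[s$posture == "supine"]) / 420
  })
  expect_lt(abs(mean(frac) - 0.4978), 0.05)
})

test_that("spatial templates encode the lateral centroid/peak opposition", {
  sup <- spatial_template("supine")
  geo_sup <- template_geometry(sup$resp_weights)
  for (side in c("left_lateral", "right_lateral")) {
    tpl <- spatial_template(side)
    expect_equal(max(tpl$resp_weights), 1)
    expect_equal(max(tpl$bcg_weights), 1)
    expect_true(all(tpl$resp_weights >= 0))
    g <- template_geometry(tpl$resp_weights)
    # centroid and maximum on opposite sides of the column midline
    expect_lt(sign(g$centroid_col - 4.5) * sign(g$argmax_col - 4.5), 0)
    # supine has strictly more channels above half-max
    expect_gt(geo_sup$n_above_half, g$n_above_half)
  }
  # the two lateral templates mirror each other
  l <- spatial_template("left_lateral")
  r <- spatial_template("right_lateral")
  expect_equal(l$resp_weights[, 8:1], r$resp_weights)
})

test_that("clean minutes put the respiratory DFT peak at fres", {
  hits <- 0
  set.seed(5)
  prof <- default_profile()
  tpl <- spatial_template("supine")
  n_try <- 40
  for (i in seq_len(n_try)) {
    m <- synth_minute(prof, tpl)
    xbar <- colMeans(m$voltages)
    n <- length(xbar)
    spec <- Mod(fft(xbar - mean(xbar)))[1:(n / 2)]
    f <- (0:(n / 2 - 1)) * 100 / n
    sel <- f >= 0.1 & f <= 0.8
    fpk <- f[sel][which.max(spec[sel])]
    if (abs(fpk - prof$fres) <= 100 / n + 1e-9) hits <- hits + 1
    expect_false(any(m$per_channel_movement))
  }
  expect_gte(hits / n_try, 0.95)
})

test_that("zero-modulation, noiseless BCG is a pure carrier at 5*fhea", {
  prof <- subject_profile(mbcg = 1e-9, noise_sd = 0, resp_amp = 0,
                          freq_jitter_sd = 0, amp_jitter_sd = 0)
  m <- synth_minute(prof, spatial_template("supine"), rng_seed = 1)
  x <- m$voltages[which.max(spatial_template("supine")$bcg_weights[1, ]), ]
  n <- length(x)
  spec <- Mod(fft(x))[2:(n / 2)]
  f <- (1:(n / 2 - 1)) * 100 / n
  # truth holds the effective (posture-adjusted) heart rate
  expect_lt(abs(f[which.max(spec)] - 5 * m$truth$fhea), 100 / n + 1e-9)
})

test_that("movement minutes contaminate at least seven channels", {
  for (seed in 1:5) {
    m <- fx_movement_minute(seed)
    expect_gte(sum(m$per_channel_movement), 7)
    expect_true(m$movement)
    expect_true(all(is.finite(m$voltages)))
  }
})

test_that("generator is deterministic given the seed", {
  a <- synth_minute(default_profile(), spatial_template("supine"),
                    rng_seed = 123)
  b <- synth_minute(default_profile(), spatial_template("supine"),
                    rng_seed = 123)
  expect_identical(a$voltages, b$voltages)
  c1 <- simulate_cohort(2, 10, master_seed = 9)
  c2 <- simulate_cohort(2, 10, master_seed = 9)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$minutes[[5]]$voltages, c2$minutes[[5]]$voltages)
})

test_that("datasets on disk have byte-identical manifests across reruns", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- synth_dataset(d1, 2, 10, master_seed = 4)
  m2 <- synth_dataset(d2, 2, 10, master_seed = 4)
  expect_equal(nrow(m1), 20)
  expect_identical(readLines(file.path(d1, "manifest.csv")),
                   readLines(file.path(d2, "manifest.csv")))
  man <- read_manifest(file.path(d1, "manifest.csv"))
  expect_silent(validate_manifest(man, d1))
  x <- read_matrix_bin(file.path(d1, man$file[1]))
  expect_equal(dim(x), c(32, 6000))
})

test_that("movement-minute fraction tracks the configured rate", {
  coh <- simulate_cohort(6, 80, master_seed = 17, movement_rate = 0.11)
  expect_lt(abs(mean(coh$manifest$movement) - 0.11), 0.02)
})
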