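test_that("noiseless sinusoid fit recovers the generating parameters", {
  t <- (0:5999) / 100
  x <- sin(2 * pi * 0.25 * t + 0.7)
  f <- fit_respiration(x)
  expect_lt(abs(f$Ares - 1), 0.01)
  expect_lt(abs(f$fres - 0.25), 0.005)
  expect_gte(f$r_squared, 0.999)
  # scaling the input scales the amplitude, not the frequency
  f2 <- fit_respiration(2 * x)
  expect_equal(f2$Ares, 2 * f$Ares, tolerance = 1e-6)
  expect_equal(f2$fres, f$fres, tolerance = 1e-9)
  expect_equal(f2$r_squared, f$r_squared, tolerance = 1e-9)
})

test_that("fits are rejected outside the physiological bands", {
  t <- (0:5999) / 100
  expect_error(fit_respiration(sin(2 * pi * 2 * t)),
               class = "sleepmat_rejected_fit")
  expect_error(fit_bcg_am(sin(2 * pi * 0.1 * t)),
               class = "sleepmat_rejected_fit")
})

test_that("default jittered respiration fits with high R-squared", {
  d <- fx_decomp()
  agg <- sleepmat:::aggregate_components(d)
  f <- fit_respiration(agg$resp)
  expect_gte(f$r_squared, 0.85)
  expect_s3_class(tidy(f), "tbl_df")
  expect_equal(glance(f)$r.squared, f$r_squared)
})

test_that("exact AM input is recovered within 5%", {
  t <- (0:5999) / 100
  x <- 0.26 * (1 + 0.4 * cos(2 * pi * 1.2 * t)) * cos(2 * pi * 6 * t)
  f <- fit_bcg_am(x)
  expect_lt(abs(f$UAm - 0.26) / 0.26, 0.05)
  expect_lt(abs(f$Mbcg - 0.4) / 0.4, 0.05)
  expect_lt(abs(f$fhea - 1.2) / 1.2, 0.05)
  expect_lt(abs(f$fbcg - 6) / 6, 0.05)
  expect_gte(f$r_squared, 0.99)
})

test_that("default BCG component fits the AM model with R2 >= 0.7 and a
           five-to-one carrier ratio", {
  d <- fx_decomp()
  agg <- sleepmat:::aggregate_components(d)
  f <- fit_bcg_am(agg$bcg)
  expect_gte(f$r_squared, 0.7)
  expect_gte(f$fbcg / f$fhea, 4.5)
  expect_lte(f$fbcg / f$fhea, 5.5)
})

test_that("envelope detection is exact on constants and AM modulators", {
  t <- (0:5999) / 100
  # pure cosine: envelope constant at the amplitude away from edges
  env <- envelope(2 * cos(2 * pi * 5 * t))
  core <- env[500:5500]
  expect_lt(max(abs(core - 2)) / 2, 0.05)
  expect_equal(envelope(numeric(4000)), numeric(4000))
  # AM signal: envelope's dominant frequency is the modulation rate
  x <- (1 + 0.4 * cos(2 * pi * 1.2 * t)) * cos(2 * pi * 6 * t)
  env <- envelope(x)
  n <- length(env)
  spec <- Mod(fft(env - mean(env)))[2:(n / 2)]
  fpk <- ((2:(n / 2)) - 1)[which.max(spec)] * 100 / n
  expect_lt(abs(fpk - 1.2), 100 / n + 1e-9)
  expect_true(all(env >= 0))
})

test_that("total variation recovers sinusoid amplitude within 1%", {
  t <- (0:5999) / 100
  s <- sin(2 * pi * 0.25 * t)
  tv <- sum(abs(diff(s)))
  expect_lt(abs(tv - 60) / 60, 0.01)  # 4*A*f*T = 60
  p <- piezo_params()
  intensity <- estimate_intensity(s, 0.25, p, "resp")
  # converts back through the sensor relation
  expect_lt(abs(intensity - p$CM / (p$beta * p$d33)) /
              (p$CM / (p$beta * p$d33)), 0.01)
  expect_equal(estimate_intensity(numeric(6000), 0.25, p, "resp"), 0)
  # linearity of the summed-variation estimator
  expect_equal(estimate_intensity(2 * s, 0.25, p, "resp"),
               2 * estimate_intensity(s, 0.25, p, "resp"), tolerance = 1e-9)
  expect_error(estimate_intensity(s, -1, p, "resp"), "f")
  expect_error(estimate_intensity(s, 1.2, p, "bcg_envelope"), "mbcg")
})

test_that("maps upsample 4x with constant and monotone preservation", {
  m <- matrix(runif(32), 4, 8)
  maps <- build_maps(m, m)
  expect_equal(dim(maps$upsampled_resp), c(16, 32))
  expect_true(all(maps$upsampled_resp >= 0))
  # constants are reproduced exactly
  cm <- build_maps(matrix(2, 4, 8), matrix(2, 4, 8))
  expect_equal(cm$upsampled_resp, matrix(2, 16, 32), tolerance = 1e-12)
  # a linear column ramp stays column-monotone
  ramp <- matrix(rep(1:8, each = 4), 4, 8)
  up <- build_maps(ramp, ramp)$upsampled_resp
  expect_true(all(apply(up, 1, function(r) all(diff(r) >= -1e-9))))
  expect_error(build_maps(matrix(-1, 4, 8), matrix(1, 4, 8)), "non-negative")
})

test_that("per-minute spatial maps separate postures as the templates do", {
  set.seed(404)
  prof <- default_profile()
  mean_map <- function(posture) {
    tpl <- spatial_template(posture)
    maps <- lapply(1:4, function(i)
      spatial_features(decompose_minute(synth_minute(prof, tpl))))
    Reduce(`+`, lapply(maps, function(m) m$fres_map / max(m$fres_map))) / 4
  }
  sup <- mean_map("supine")
  lef <- mean_map("left_lateral")
  rig <- mean_map("right_lateral")
  expect_gt(mean(abs(sup - lef)), 0.02)
  # centroid/peak opposition survives the signal round trip
  gl <- template_geometry(lef)
  gr <- template_geometry(rig)
  expect_lt(sign(gl$centroid_col - 4.5) * sign(gl$argmax_col - 4.5), 0)
  expect_lt(sign(gr$centroid_col - 4.5) * sign(gr$argmax_col - 4.5), 0)
})

test_that("parameter recovery holds at the single-channel level", {
  # strongest-coupling channels carry unit weights, so the aggregated fits
  # recover the generating physiology
  set.seed(777)
  prof <- default_profile()
  tpl <- spatial_template("supine")
  errs <- t(replicate(15, {
    d <- decompose_minute(synth_minute(prof, tpl))
    agg <- sleepmat:::aggregate_components(d)
    fr <- fit_respiration(agg$resp)
    fb <- fit_bcg_am(agg$bcg)
    c(fres = abs(fr$fres - d$truth$fres) / d$truth$fres,
      fhea = abs(fb$fhea - d$truth$fhea) / d$truth$fhea)
  }))
  expect_lte(median(errs[, "fres"]), 0.05)
  expect_lte(median(errs[, "fhea"]), 0.05)
})
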