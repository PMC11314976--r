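test_that("FIR design yields symmetric band-pass coefficients", {
  h <- design_fir_bandpass(fir_spec(0.1, 0.8, 999, 100))
  expect_length(h, 1000)
  expect_equal(as.numeric(h), rev(as.numeric(h)))
  # DC lies in the stopband: coefficient sum vanishes
  expect_lt(abs(sum(h)), 1e-3)
  # spec'd attenuation at 2 Hz: magnitude <= 1% of passband gain
  pass <- mean(fir_response(h, c(0.25, 0.45, 0.6)))
  expect_lte(fir_response(h, 2) / pass, 0.01)
  # one octave above the upper edge: >= 40 dB down
  expect_lte(fir_response(h, 1.6) / pass, 10^(-40 / 20))
  # passband interior flat within 1 dB
  gains <- fir_response(h, seq(0.2, 0.7, by = 0.05))
  expect_true(all(gains / pass > 10^(-1 / 20) & gains / pass < 10^(1 / 20)))
  expect_error(fir_spec(0.8, 0.1), "band edges")
  expect_error(fir_spec(1, 60, fs = 100), "band edges")
})

test_that("BCG filter passes its band and rejects an octave below", {
  h <- design_fir_bandpass(fir_spec(0.8, 15, 999, 100))
  pass <- mean(fir_response(h, c(1.2, 3, 6, 10)))
  expect_gt(pass, 0.97)
  expect_lte(fir_response(h, 0.4) / pass, 10^(-40 / 20))
})

test_that("frequency response matches direct coefficient evaluation", {
  h <- design_fir_bandpass(fir_spec(0.1, 0.8))
  f <- c(0.05, 0.25, 0.5, 1.0, 2.0, 5.0)
  direct <- vapply(f, function(ff)
    abs(sum(h * exp(-2i * pi * ff / 100 * (seq_along(h) - 1)))), 0)
  expect_equal(fir_response(h, f), direct, tolerance = 1e-12)
})

test_that("group delay compensation time-aligns the components", {
  imp <- numeric(6000)
  imp[3000] <- 1
  # the 1000-tap filter's true delay is 499.5 samples, so the impulse
  # response peak may land on either neighbour of the impulse position
  h <- design_fir_bandpass(fir_spec(0.8, 15))
  y <- apply_fir(imp, h)
  expect_lte(abs(which.max(abs(y)) - 3000), 1)
  hr <- design_fir_bandpass(fir_spec(0.1, 0.8))
  expect_lte(abs(which.max(abs(apply_fir(imp, hr))) - 3000), 1)
})

test_that("decomposition recovers closed-form sinusoid energy", {
  t <- (0:5999) / 100
  s <- sin(2 * pi * 0.25 * t)
  d <- decompose_minute(matrix(s, 1))
  # A^2 * N / 2 = 3000 within 2%
  expect_lt(abs(d$resp_energy - 3000) / 3000, 0.02)
  expect_lt(d$bcg_energy / d$composite_energy, 0.01)
})

test_that("all-zero input decomposes to zero everywhere", {
  d <- decompose_minute(matrix(0, 2, 6000))
  expect_true(all(d$resp == 0) && all(d$bcg == 0) && all(d$dev == 0))
  expect_equal(d$composite_energy, c(0, 0))
  expect_equal(d$dev_energy, c(0, 0))
})

test_that("decomposition is linear and respects the residual definition", {
  m <- fx_minute()
  d1 <- decompose_minute(m$voltages)
  d3 <- decompose_minute(3 * m$voltages)
  expect_equal(d3$resp, 3 * d1$resp, tolerance = 1e-10)
  expect_equal(d3$bcg, 3 * d1$bcg, tolerance = 1e-10)
  expect_equal(d1$dev_energy,
               d1$composite_energy - d1$resp_energy - d1$bcg_energy)
  expect_equal(d1$dev, m$voltages - d1$resp - d1$bcg)
})

test_that("band selection is idempotent and near-orthogonal", {
  d <- fx_decomp()
  h <- design_fir_bandpass(fir_spec(0.1, 0.8))
  again <- apply_fir(d$resp[1, ], h)
  e1 <- sum(d$resp[1, ]^2)
  expect_lt(abs(sum(again^2) - e1) / e1, 0.01)
  # residual-definition energy vs energy of the dev signal: the two agree
  # up to finite-window cross terms between in-band and out-of-band content
  # of the jittered sources (typically ~1%, occasionally up to a few % on a
  # single minute)
  set.seed(77)
  gap <- replicate(8, {
    di <- decompose_minute(synth_minute(default_profile(),
                                        spatial_template("supine")))
    abs(sum(rowSums(di$dev^2)) - sum(di$dev_energy)) /
      sum(di$composite_energy)
  })
  expect_lte(median(gap), 0.02)
  expect_lte(max(gap), 0.04)
})

test_that("a default clean minute splits energy roughly 90/6/2", {
  ef <- energy_fractions(fx_decomp())
  expect_lt(abs(ef$resp_frac - 0.90), 0.04)
  expect_gt(ef$bcg_frac, 0.04)
  expect_lt(ef$bcg_frac, 0.09)
  expect_lt(ef$dev_frac, 0.03)
})

test_that("minutes shorter than the filter are rejected", {
  expect_error(decompose_minute(matrix(rnorm(500), 1)), "filter")
})
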