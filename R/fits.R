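# location of the dominant DFT peak within [lo, hi] Hz (bin resolution)
dft_peak <- function(x, fs, lo, hi) {
  n <- length(x)
  spec <- Mod(fft(x - mean(x)))[seq_len(floor(n / 2))]
  f <- (seq_len(floor(n / 2)) - 1) * fs / n
  sel <- f >= lo & f <= hi
  if (!any(sel) || all(spec[sel] == 0)) return(NA_real_)
  f[sel][which.max(spec[sel])]
}

# least-squares single-sinusoid fit A*sin(2 pi f t + phi); frequency refined
# by golden-section search around f0 (one DFT bin each way)
sinusoid_fit <- function(x, f0, fs, halfwidth = NULL) {
  n <- length(x)
  if (is.null(halfwidth)) halfwidth <- fs / n
  tt <- (seq_len(n) - 1) / fs
  rss_at <- function(f) {
    B <- cbind(sin(2 * pi * f * tt), cos(2 * pi * f * tt))
    fit <- stats::lm.fit(B, x)
    list(rss = sum(fit$residuals^2), coef = fit$coefficients)
  }
  op <- optimize(function(f) rss_at(f)$rss,
                 c(max(f0 - halfwidth, 1e-4), f0 + halfwidth), tol = 1e-7)
  best <- rss_at(op$minimum)
  sst <- sum((x - mean(x))^2)
  list(amplitude = sqrt(sum(best$coef^2)),
       frequency = op$minimum,
       phase = atan2(best$coef[2], best$coef[1]),
       r_squared = if (sst > 0) 1 - best$rss / sst else NA_real_)
}

rejected_fit <- function(msg) {
  stop(structure(class = c("sleepmat_rejected_fit", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Fit a single sinusoid to a respiratory component
#'
#' Least-squares fit of `A * sin(2 pi f t + phi)` to one minute of the
#' band-passed respiratory signal, with the frequency initialized at the DFT
#' peak in 0.1-0.8 Hz and refined by line search. A single sinusoidal term
#' suffices for undisturbed chest-mat respiration; the attained coefficient
#' of determination is reported against the input.
#'
#' @param resp Numeric vector: one-minute respiratory component of an
#'   uninterfered sample.
#' @param fs Sampling rate (Hz).
#' @return A `resp_fit`: list with `Ares` (amplitude, >= 0), `fres` (Hz) and
#'   `r_squared`.
#' @section Errors: a DFT peak outside 0.1-0.8 Hz (or a degenerate input)
#'   signals a `sleepmat_rejected_fit` condition.
#' @export
fit_respiration <- function(resp, fs = 100) {
  f0 <- dft_peak(resp, fs, 0.1, 0.8)
  full <- dft_peak(resp, fs, 1e-6, fs / 2)
  if (is.na(f0) || is.na(full) || full < 0.1 || full > 0.8)
    rejected_fit("respiratory DFT peak outside 0.1-0.8 Hz")
  sf <- sinusoid_fit(resp, f0, fs)
  structure(list(Ares = sf$amplitude, fres = sf$frequency,
                 r_squared = sf$r_squared),
            class = "resp_fit")
}

#' Envelope of a band-limited signal
#'
#' Magnitude of the analytic signal (Hilbert transform via FFT) followed by
#' low-pass smoothing at `cutoff_hz`. The result has the same length as the
#' input and is non-negative apart from small smoothing undershoot, which is
#' clipped at zero.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate (Hz).
#' @param cutoff_hz Smoothing low-pass cutoff (default 3 Hz, above any
#'   plausible heart rate).
#' @return Envelope vector, same length as `x`.
#' @export
envelope <- function(x, fs = 100, cutoff_hz = 3) {
  n <- length(x)
  if (n == 0) abort_bad_arg("empty series")
  if (all(x == 0)) return(numeric(n))
  M <- stats::nextn(n, 2)
  X <- fft(c(x, numeric(M - n)))
  mask <- numeric(M)
  mask[1] <- 1
  mask[M / 2 + 1] <- 1
  mask[2:(M / 2)] <- 2
  env <- Mod(fft(X * mask, inverse = TRUE) / M)[seq_len(n)]
  key <- paste0("envlp_", fs, "_", cutoff_hz)
  if (is.null(the[[key]]))
    the[[key]] <- as.numeric(signal::fir1(200, cutoff_hz / (fs / 2), type = "low"))
  pmax(apply_fir(env, the[[key]]), 0)
}

#' Fit the amplitude-modulation model to a BCG component
#'
#' Two-stage fit of the AM form
#' `UAm * (1 + Mbcg * cos(2 pi fhea t)) * cos(2 pi fbcg t)`:
#' the heart rate `fhea` is estimated from the DFT peak of the detected
#' envelope (refined by a sinusoid fit to the envelope, which also yields
#' `UAm` as the envelope mean and `Mbcg` as modulation amplitude over mean);
#' the carrier `fbcg` starts at the raw-signal DFT peak, and carrier plus
#' sidebands at `fbcg +- fhea` are then fit linearly with the two frequencies
#' refined numerically. The reported `r_squared` compares that reconstruction
#' with the input. The envelope route is used for the amplitude parameters
#' because it is insensitive to carrier phase jitter.
#'
#' @param bcg Numeric vector: one-minute BCG component of an uninterfered
#'   sample.
#' @param fs Sampling rate (Hz).
#' @return A `bcg_fit`: list with `UAm`, `Mbcg`, `fhea`, `fbcg`, `r_squared`
#'   and the three-cosine stage amplitudes `Abcg`, `Bbcg`, `Cbcg`.
#' @section Errors: an envelope DFT peak outside 0.8-3 Hz signals a
#'   `sleepmat_rejected_fit` condition.
#' @export
fit_bcg_am <- function(bcg, fs = 100) {
  env <- envelope(bcg, fs)
  fh0 <- dft_peak(env, fs, 0.8, 3)
  env_full <- dft_peak(env, fs, 0.2, 10)
  if (is.na(fh0) || is.na(env_full) || env_full < 0.8 || env_full > 3)
    rejected_fit("envelope DFT peak outside 0.8-3 Hz")
  ef <- sinusoid_fit(env - mean(env), fh0, fs)
  UAm <- mean(env)
  Mbcg <- min(ef$amplitude / UAm, 1)
  fhea <- ef$frequency
  fb0 <- dft_peak(bcg, fs, 2, min(15, fs / 2 - 1))
  tt <- (seq_along(bcg) - 1) / fs
  sb_fit <- function(p) {
    B <- cbind(sin(2 * pi * p[1] * tt), cos(2 * pi * p[1] * tt),
               sin(2 * pi * (p[1] + p[2]) * tt), cos(2 * pi * (p[1] + p[2]) * tt),
               sin(2 * pi * (p[1] - p[2]) * tt), cos(2 * pi * (p[1] - p[2]) * tt))
    fit <- stats::lm.fit(B, bcg)
    list(rss = sum(fit$residuals^2), coef = fit$coefficients)
  }
  op <- optim(c(fb0, fhea), function(p) sb_fit(p)$rss,
              control = list(reltol = 1e-10, maxit = 400))
  best <- sb_fit(op$par)
  cf <- best$coef
  sst <- sum((bcg - mean(bcg))^2)
  structure(list(
    UAm = UAm, Mbcg = Mbcg, fhea = fhea, fbcg = op$par[1],
    r_squared = if (sst > 0) 1 - best$rss / sst else NA_real_,
    Abcg = sqrt(cf[3]^2 + cf[4]^2), Bbcg = sqrt(cf[5]^2 + cf[6]^2),
    Cbcg = sqrt(cf[1]^2 + cf[2]^2)
  ), class = "bcg_fit")
}

#' @export
tidy.resp_fit <- function(x, ...) {
  tibble::tibble(term = c("Ares", "fres"),
                 estimate = c(x$Ares, x$fres))
}

#' @export
glance.resp_fit <- function(x, ...) tibble::tibble(r.squared = x$r_squared)

#' @export
tidy.bcg_fit <- function(x, ...) {
  tibble::tibble(term = c("UAm", "Mbcg", "fhea", "fbcg"),
                 estimate = c(x$UAm, x$Mbcg, x$fhea, x$fbcg))
}

#' @export
glance.bcg_fit <- function(x, ...) tibble::tibble(r.squared = x$r_squared)
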