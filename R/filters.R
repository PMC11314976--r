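#' Band-pass filter specification
#'
#' @param low_hz,high_hz Band edges (Hz), `0 < low_hz < high_hz < fs/2`.
#' @param order Filter order; the coefficient vector has `order + 1` taps.
#'   Default 999 (1000 taps), giving linear phase with a 499.5-sample delay.
#' @param fs Sampling rate (Hz).
#' @return A `fir_spec` object.
#' @export
fir_spec <- function(low_hz, high_hz, order = 999, fs = 100) {
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2))
    abort_bad_arg("band edges must satisfy 0 < low_hz < high_hz < fs/2")
  if (order < 2) abort_bad_arg("`order` must be at least 2")
  structure(list(low_hz = low_hz, high_hz = high_hz,
                 order = as.integer(order), fs = fs),
            class = "fir_spec")
}

#' Design a linear-phase FIR band-pass filter
#'
#' Windowed-sinc band-pass design using a Dolph-Chebyshev window
#' (`sidelobe_db` equiripple sidelobes). The ideal band edges are stretched
#' outward by `edge_stretch` Hz so that the printed edges sit near the
#' half-gain point and the passband interior is flat; a window-weighted
#' correction forces an exact null at DC. Coefficients are symmetric
#' (linear phase).
#'
#' @param spec A [fir_spec()].
#' @param sidelobe_db Stopband sidelobe attenuation of the window (dB).
#' @param edge_stretch Outward stretch of the design edges (Hz).
#' @return Numeric coefficient vector of length `order + 1`, with the spec
#'   attached as attribute `"spec"`.
#' @examples
#' h <- design_fir_bandpass(fir_spec(0.1, 0.8))
#' length(h)
#' @export
design_fir_bandpass <- function(spec, sidelobe_db = 50, edge_stretch = 0.07) {
  stopifnot(inherits(spec, "fir_spec"))
  L <- spec$order + 1L
  fs <- spec$fs
  n <- seq_len(L) - (L + 1) / 2
  lo <- max(spec$low_hz - edge_stretch, 0.005)
  hi <- min(spec$high_hz + edge_stretch, fs / 2 - 1e-6)
  w <- as.numeric(signal::chebwin(L, sidelobe_db))
  ideal_lp <- function(fc) {
    x <- 2 * fc / fs * n
    2 * fc / fs * ifelse(x == 0, 1, sin(pi * x) / (pi * x))
  }
  h <- (ideal_lp(hi) - ideal_lp(lo)) * w
  h <- h - sum(h) * w / sum(w)
  attr(h, "spec") <- spec
  h
}

#' Frequency response magnitude of an FIR filter
#'
#' Direct evaluation of `|sum_k h_k exp(-2 pi i f k / fs)|` at the requested
#' frequencies.
#'
#' @param h Coefficient vector.
#' @param f Frequencies (Hz), vectorized.
#' @param fs Sampling rate (Hz).
#' @return Magnitude response at `f`.
#' @export
fir_response <- function(h, f, fs = 100) {
  vapply(f, function(ff)
    abs(sum(h * exp(-2i * pi * ff / fs * (seq_along(h) - 1)))), 0)
}

#' Apply an FIR filter with group-delay compensation
#'
#' Single-pass FFT convolution of each row of `x` with `h`, with
#' point-symmetric (slope-preserving) edge extension and a shift of
#' `round((length(h)-1)/2)` samples so the output is time-aligned with the
#' input. For the symmetric (linear-phase) designs produced by
#' [design_fir_bandpass()] this is equivalent to zero-phase filtering up to
#' half a sample.
#'
#' @param x Numeric vector or matrix (channels in rows, samples in columns).
#' @param h FIR coefficient vector; the signal must be at least as long.
#' @return Filtered signal, same shape as `x`.
#' @export
apply_fir <- function(x, h) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  L <- length(h)
  n <- ncol(x)
  if (n < L) abort_bad_arg("signal shorter than the filter: need >= ", L, " samples")
  pad <- ceiling((L - 1) / 2)
  left <- 2 * x[, 1] - x[, (pad + 1):2, drop = FALSE]
  right <- 2 * x[, n] - x[, (n - 1):(n - pad), drop = FALSE]
  xp <- cbind(left, x, right)
  np <- ncol(xp)
  M <- stats::nextn(np + L, 2)
  Hf <- fft(c(h, numeric(M - L)))
  Xf <- mvfft(t(cbind(xp, matrix(0, nrow(x), M - np))))
  y <- Re(t(mvfft(Xf * Hf, inverse = TRUE))) / M
  shift <- pad + round((L - 1) / 2)
  out <- y[, (shift + 1):(shift + n), drop = FALSE]
  if (vec) as.vector(out) else out
}

# apply several FIR filters sharing one forward FFT of the padded signal;
# returns a list of filtered matrices, same shape as x
apply_fir_bank <- function(x, filters) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  L <- max(vapply(filters, length, 0L))
  n <- ncol(x)
  if (n < L) abort_bad_arg("signal shorter than the filter: need >= ", L, " samples")
  pad <- ceiling((L - 1) / 2)
  left <- 2 * x[, 1] - x[, (pad + 1):2, drop = FALSE]
  right <- 2 * x[, n] - x[, (n - 1):(n - pad), drop = FALSE]
  xp <- cbind(left, x, right)
  np <- ncol(xp)
  M <- stats::nextn(np + L, 2)
  Xf <- mvfft(t(cbind(xp, matrix(0, nrow(x), M - np))))
  lapply(filters, function(h) {
    Hf <- fft(c(h, numeric(M - length(h))))
    y <- Re(t(mvfft(Xf * Hf, inverse = TRUE))) / M
    shift <- pad + round((length(h) - 1) / 2)
    out <- y[, (shift + 1):(shift + n), drop = FALSE]
    if (vec) as.vector(out) else out
  })
}

# memoised default respiratory / BCG filter bank
default_filters <- function(fs = 100) {
  key <- paste0("filters_", fs)
  if (is.null(the[[key]])) {
    the[[key]] <- list(
      resp = design_fir_bandpass(fir_spec(0.1, 0.8, 999, fs)),
      bcg = design_fir_bandpass(fir_spec(0.8, 15, 999, fs))
    )
  }
  the[[key]]
}
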