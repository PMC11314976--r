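#' Centered moving average
#'
#' Mean over a centered window of odd width `w`, with point-symmetric edge
#' extension so the output has the same length as the input. Constant inputs
#' and the interior of affine ramps are unchanged.
#'
#' @param x Numeric vector.
#' @param w Odd window width, `w <= length(x)`.
#' @return Smoothed vector, same length as `x`.
#' @export
moving_average <- function(x, w = 5) {
  if (w %% 2 == 0) abort_bad_arg("`w` must be odd")
  if (w > length(x)) abort_bad_arg("`w` must not exceed length(x)")
  if (w == 1) return(x)
  half <- (w - 1) / 2
  n <- length(x)
  xp <- c(2 * x[1] - x[(half + 1):2], x, 2 * x[n] - x[(n - 1):(n - half)])
  cs <- c(0, cumsum(xp))
  (cs[(w + 1):(n + w)] - cs[1:n]) / w
}

#' Peak train by the zero-crossing method
#'
#' Splits a zero-mean series into positive half-cycles (maximal runs of
#' non-negative values delimited by upward/downward zero crossings, including
#' runs touching the series boundaries) and records one peak per half-cycle:
#' its maximum value and sample index. Positive runs separated by dips
#' shorter than `min_gap` samples are merged, so isolated noise glitches do
#' not split a half-cycle.
#'
#' @param x Numeric vector (mean-removed or zero-mean band-passed).
#' @param min_gap Dips below zero shorter than this many samples are ignored
#'   (default 5).
#' @return A `peak_train`: list with `indices` (strictly increasing),
#'   `amplitudes` and `intervals` (successor gaps in samples,
#'   `length(indices) - 1` of them). Fewer than one positive half-cycle
#'   yields an empty train.
#' @export
zero_crossing_peaks <- function(x, min_gap = 5) {
  n <- length(x)
  pos <- x > 0
  if (!any(pos)) {
    return(structure(list(indices = integer(0), amplitudes = numeric(0),
                          intervals = numeric(0)), class = "peak_train"))
  }
  r <- rle(pos)
  # merge short negative dips into the surrounding positive runs
  if (length(r$lengths) > 2) {
    interior <- seq(2, length(r$lengths) - 1)
    r$values[interior][!r$values[interior] & r$lengths[interior] < min_gap] <- TRUE
    r <- rle(inverse.rle(r))
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  idx <- which(r$values)
  peaks <- vapply(idx, function(i) {
    seg <- starts[i]:ends[i]
    seg[which.max(x[seg])]
  }, 0L)
  structure(list(indices = peaks, amplitudes = x[peaks],
                 intervals = diff(peaks)), class = "peak_train")
}

#' Expand a peak train into uniform amplitude/interval feature rows
#'
#' Feature-based interpolation: between consecutive peaks, the amplitude row
#' holds the left peak's amplitude and the interval row holds that gap (in
#' seconds), i.e. as many feature points are inserted between two peaks as
#' there are samples in their interval. Head and tail are extended with the
#' nearest value, so the output is exactly `2 x length`.
#'
#' @param train A `peak_train` with at least two peaks.
#' @param length Output length in samples (default 6000).
#' @param fs Sampling rate (Hz), for converting gaps to seconds.
#' @return A 2-row matrix, rownames `amplitude` and `interval`.
#' @export
peak_series <- function(train, length = 6000, fs = 100) {
  stopifnot(inherits(train, "peak_train"))
  k <- base::length(train$indices)
  if (k < 2)
    stop(structure(class = c("sleepmat_unusable_minute", "error", "condition"),
                   list(message = "fewer than two peaks: minute unusable",
                        call = NULL)))
  amp <- numeric(length)
  itv <- numeric(length)
  bounds <- pmin(pmax(train$indices, 1L), length)
  amp[seq_len(bounds[1])] <- train$amplitudes[1]
  itv[seq_len(bounds[1])] <- train$intervals[1] / fs
  for (i in seq_len(k - 1)) {
    span <- bounds[i]:bounds[i + 1]
    amp[span] <- train$amplitudes[i]
    itv[span] <- train$intervals[i] / fs
  }
  if (bounds[k] < length) {
    tail_span <- (bounds[k] + 1):length
    amp[tail_span] <- train$amplitudes[k]
    itv[tail_span] <- train$intervals[k - 1] / fs
  }
  out <- rbind(amplitude = amp, interval = itv)
  out
}

#' Resample feature rows to the network input length
#'
#' Linear interpolation of each row at uniformly spaced query points;
#' constant rows are preserved exactly.
#'
#' @param series A 2 x N feature matrix.
#' @param target Output length (90 for respiration, 180 for heartbeat).
#' @return A 2 x `target` matrix with the same rownames.
#' @export
resample_features <- function(series, target) {
  if (!is.numeric(target) || target <= 0) abort_bad_arg("`target` must be positive")
  n <- ncol(series)
  q <- seq(1, n, length.out = target)
  out <- t(apply(series, 1, function(row) approx(seq_len(n), row, xout = q)$y))
  rownames(out) <- rownames(series)
  out
}

#' Temporal amplitude/interval features of one decomposed minute
#'
#' Forms energy-weighted mean respiratory and BCG series across the 32
#' channels, then follows the two extraction paths: respiration is smoothed
#' (window 5), peak-detected by the zero-crossing method, expanded by
#' feature-based interpolation to 2 x 6000 and resampled to 2 x 90;
#' the heartbeat path detects peaks on the mean-removed BCG envelope and
#' resamples to 2 x 180.
#'
#' @param d A `decomposed_sample`.
#' @return A `temporal_feature_set`: list with `M1` (2 x 90 respiration
#'   amplitude/interval matrix) and `M2` (2 x 180 heartbeat matrix).
#' @section Errors: a minute without detectable peaks on either path signals
#'   a `sleepmat_unusable_minute` condition.
#' @export
extract_temporal <- function(d) {
  stopifnot(inherits(d, "decomposed_sample"))
  agg <- aggregate_components(d)
  if (sd(agg$resp) == 0 || sd(agg$bcg) == 0)
    stop(structure(class = c("sleepmat_unusable_minute", "error", "condition"),
                   list(message = "zero-variance minute", call = NULL)))
  n <- ncol(d$resp)
  resp_train <- zero_crossing_peaks(moving_average(agg$resp, 5))
  env <- envelope(agg$bcg, d$fs)
  bcg_train <- zero_crossing_peaks(env - mean(env))
  M1 <- resample_features(peak_series(resp_train, n, d$fs), 90)
  M2 <- resample_features(peak_series(bcg_train, n, d$fs), 180)
  structure(list(M1 = M1, M2 = M2), class = "temporal_feature_set")
}
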