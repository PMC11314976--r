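#' Activity intensity from summed instantaneous variation
#'
#' Estimates the driving-force intensity of a periodic component from its
#' total variation over the minute. For a sinusoid of amplitude `A` and
#' frequency `f`, the summed absolute sample-to-sample variation over `N`
#' samples at interval `dt` approaches `4 * A * f * N * dt` (4 amplitudes per
#' cycle), so the effective voltage amplitude is `sum(|diff(U)|) / (4 f N
#' dt)`. The force intensity then inverts the high-frequency sensor relation:
#' `intensity = amplitude * CM / (beta * d33)`.
#'
#' For `kind = "bcg_envelope"` the input is the detected BCG envelope, whose
#' oscillating part has amplitude `UAm * Mbcg` at the heart rate; the
#' recovered amplitude is therefore divided by the separately estimated
#' modulation index `mbcg` to yield the cardiac intensity.
#'
#' @param component Numeric vector (respiratory component, or BCG envelope).
#' @param f Characteristic frequency (Hz): respiration rate, or heart rate
#'   for the envelope. Must be positive.
#' @param params A [piezo_params()].
#' @param kind `"resp"` or `"bcg_envelope"`.
#' @param mbcg Modulation index estimate, required for `kind =
#'   "bcg_envelope"`.
#' @return Non-negative scalar intensity (force units of the model).
#' @export
estimate_intensity <- function(component, f, params = piezo_params(),
                               kind = c("resp", "bcg_envelope"), mbcg = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(f) || length(f) != 1 || !is.finite(f) || f <= 0)
    abort_bad_arg("`f` must be a positive frequency")
  n <- length(component)
  tv <- sum(abs(diff(component)))
  amp <- tv / (4 * f * n * params$dt)
  if (kind == "bcg_envelope") {
    if (is.null(mbcg) || mbcg <= 0)
      abort_bad_arg("`mbcg` must be supplied (and positive) for the envelope kind")
    amp <- amp / mbcg
  }
  voltage_to_force(amp, params)
}

# 1-D Catmull-Rom (Keys, a = -0.5) interpolation weights from `n_src` source
# cells to `factor * n_src` target positions, pixel-centre aligned with
# clamped edges; rows sum to 1 so constants are reproduced exactly
cubic_weights <- function(n_src, factor) {
  a <- -0.5
  kern <- function(x) {
    x <- abs(x)
    ifelse(x <= 1, (a + 2) * x^3 - (a + 3) * x^2 + 1,
           ifelse(x < 2, a * x^3 - 5 * a * x^2 + 8 * a * x - 4 * a, 0))
  }
  n_out <- n_src * factor
  W <- matrix(0, n_out, n_src)
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) / factor - 0.5 + 1  # 1-based source coordinate
    base <- floor(src)
    for (k in (base - 1):(base + 2)) {
      w <- kern(src - k)
      kc <- min(max(k, 1), n_src)  # clamp at the borders
      W[i, kc] <- W[i, kc] + w
    }
  }
  W / rowSums(W)
}

# truncated, per-position renormalized Gaussian smoothing weights (constants
# are preserved exactly)
gaussian_weights <- function(n, sigma, radius = ceiling(3 * sigma)) {
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    k <- max(1, i - radius):min(n, i + radius)
    w <- dnorm(k - i, sd = sigma)
    W[i, k] <- w / sum(w)
  }
  W
}

#' Assemble upsampled cardiorespiratory activity maps
#'
#' Takes the per-channel respiratory and cardiac intensity estimates on the
#' 4 x 8 sensor grid and produces the network-resolution maps: bicubic
#' (Catmull-Rom) interpolation enlarges each grid by a factor of 4 in both
#' dimensions to 16 x 32, Gaussian smoothing (sigma = 1 target-grid unit)
#' reduces sensor-to-sensor variability, and negative interpolation
#' overshoot is clipped at zero.
#'
#' @param resp_intensity,bcg_intensity 4 x 8 matrices of non-negative
#'   intensities.
#' @return An `intensity_map_pair`: list with `fres_map`, `fbcg_map` (the
#'   4 x 8 inputs) and `upsampled_resp`, `upsampled_bcg` (16 x 32).
#' @export
build_maps <- function(resp_intensity, bcg_intensity) {
  chk <- function(m) {
    stopifnot(is.matrix(m), nrow(m) == 4, ncol(m) == 8)
    if (any(!is.finite(m)) || any(m < 0))
      abort_bad_arg("intensities must be finite and non-negative")
  }
  chk(resp_intensity); chk(bcg_intensity)
  if (is.null(the$map_ops)) {
    the$map_ops <- list(R = cubic_weights(4, 4), C = t(cubic_weights(8, 4)),
                        SR = gaussian_weights(16, 1), SC = t(gaussian_weights(32, 1)))
  }
  ops <- the$map_ops
  up <- function(m) pmax(ops$SR %*% (ops$R %*% m %*% ops$C) %*% ops$SC, 0)
  structure(list(fres_map = resp_intensity, fbcg_map = bcg_intensity,
                 upsampled_resp = up(resp_intensity),
                 upsampled_bcg = up(bcg_intensity)),
            class = "intensity_map_pair")
}

#' Model-based spatial features of one decomposed minute
#'
#' Estimates the minute's respiration rate from the DFT peak of the
#' energy-weighted mean respiratory channel, the heart rate and modulation
#' index from the aggregated BCG envelope, then computes per-channel
#' respiratory and cardiac intensities via [estimate_intensity()] and
#' assembles the upsampled activity maps with [build_maps()].
#'
#' @param d A `decomposed_sample`.
#' @param params A [piezo_params()].
#' @return An `intensity_map_pair`, with the estimated `fres`, `fhea`,
#'   `mbcg` attached as attribute `"rates"`.
#' @section Errors: signals `sleepmat_rejected_fit` when no credible
#'   respiratory or cardiac peak exists.
#' @export
spatial_features <- function(d, params = piezo_params()) {
  stopifnot(inherits(d, "decomposed_sample"))
  agg <- aggregate_components(d)
  fres <- dft_peak(agg$resp, d$fs, 0.1, 0.8)
  if (is.na(fres)) rejected_fit("no respiratory peak in 0.1-0.8 Hz")
  env <- envelope(agg$bcg, d$fs)
  fhea <- dft_peak(env, d$fs, 0.8, 3)
  if (is.na(fhea)) rejected_fit("no cardiac peak in envelope 0.8-3 Hz")
  ef <- sinusoid_fit(env - mean(env), fhea, d$fs)
  mbcg <- max(min(ef$amplitude / mean(env), 1), 0.05)
  resp_int <- vapply(seq_len(32), function(ch)
    estimate_intensity(d$resp[ch, ], fres, params, "resp"), 0)
  bcg_int <- vapply(seq_len(32), function(ch)
    estimate_intensity(envelope(d$bcg[ch, ], d$fs), fhea, params,
                       "bcg_envelope", mbcg = mbcg), 0)
  maps <- build_maps(matrix(resp_int, 4, 8, byrow = TRUE),
                     matrix(bcg_int, 4, 8, byrow = TRUE))
  attr(maps, "rates") <- c(fres = fres, fhea = ef$frequency, mbcg = mbcg)
  maps
}

# energy-weighted mean respiratory and BCG series across channels
aggregate_components <- function(d) {
  wr <- d$resp_energy / max(sum(d$resp_energy), .Machine$double.eps)
  wb <- d$bcg_energy / max(sum(d$bcg_energy), .Machine$double.eps)
  list(resp = colSums(d$resp * wr), bcg = colSums(d$bcg * wb))
}

#' @export
autoplot.intensity_map_pair <- function(object, ...) {
  df <- dplyr::bind_rows(
    map_to_df(object$upsampled_resp, "respiratory"),
    map_to_df(object$upsampled_bcg, "cardiac")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~source) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "column (toward subject's left)", y = "row",
                  fill = "intensity") +
    ggplot2::theme_minimal()
}

map_to_df <- function(m, source) {
  tibble::tibble(row = as.vector(row(m)), col = as.vector(col(m)),
                 intensity = as.vector(m), source = source)
}
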