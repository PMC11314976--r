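#' Energy entropy of a signal
#'
#' Shannon entropy (natural log) of the normalized per-window energy
#' distribution: the signal is cut into windows of `window` samples every
#' `step` samples (windows overrunning the end are dropped), each window's
#' energy is its sum of squares, energies are normalized to a probability
#' vector and the entropy `-sum(p * log(p))` is returned. Bursty signals
#' concentrate energy in few windows and score low; stationary signals
#' approach the maximum `log(K)` for `K` windows. An all-zero signal is
#' defined to have entropy 0.
#'
#' @param x Numeric vector.
#' @param window Window length in samples (`<= length(x)`).
#' @param step Hop between window starts in samples (`>= 1`).
#' @return Entropy in nats, in `[0, log(K)]`.
#' @examples
#' energy_entropy(c(1, 1, 2, 2), window = 2, step = 2)  # 0.5004 nats
#' @export
energy_entropy <- function(x, window, step) {
  if (window > length(x)) abort_bad_arg("`window` must not exceed length(x)")
  if (step < 1) abort_bad_arg("`step` must be >= 1")
  starts <- seq.int(1L, length(x) - window + 1L, by = step)
  cs <- c(0, cumsum(x^2))
  e <- cs[starts + window] - cs[starts]
  tot <- sum(e)
  if (tot <= 0) return(0)
  p <- e / tot
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Approximate entropy (ApEn)
#'
#' Pincus' approximate entropy `Phi_m(r) - Phi_{m+1}(r)` with Chebyshev
#' distance and self-matches included, computed in compiled code. A constant
#' series (zero spread) is defined to have ApEn 0.
#'
#' @param x Numeric vector, `length(x) > m + 1`.
#' @param m Embedding dimension (default 2).
#' @param r Similarity radius; defaults to `0.2 * sd(x)`.
#' @return Non-negative scalar (up to floating tolerance).
#' @examples
#' approx_entropy(sin(seq(0, 20, by = 0.2)))
#' @export
approx_entropy <- function(x, m = 2, r = 0.2 * sd(x)) {
  if (length(x) <= m + 1) abort_bad_arg("series too short for embedding dimension")
  if (!is.finite(r) || r <= 0) return(0)
  .apen_cpp(as.numeric(x), as.integer(m), r)
}

# mean-pooled decimation by an integer factor (length must divide exactly
# after truncation); anti-aliases by boxcar averaging
decimate_mean <- function(x, factor) {
  n <- (length(x) %/% factor) * factor
  colMeans(matrix(x[seq_len(n)], nrow = factor))
}

# ApEn decimation factors per component: entropy of a heavily oversampled
# band-limited series is dominated by trivial sample-to-sample continuity,
# so each component is decimated to a few times its band edge first
apen_decimation <- function() c(resp = 20L, bcg = 5L, dev = 10L)

#' Entropy feature vector for one channel of a decomposed minute
#'
#' The six artifact-detection features of one channel, in fixed order:
#' energy entropies of the respiratory (window 400, step 40), BCG (100, 10)
#' and deviation (10, 1) components, followed by the approximate entropies
#' (m = 2, r = 0.2 sd) of the three components. For ApEn each component is
#' first mean-pool decimated (respiration to 5 Hz, BCG to 20 Hz, deviation to
#' 10 Hz) so the statistic reflects cycle-scale regularity.
#'
#' @param d A `decomposed_sample`.
#' @param channel Channel index, 1-32.
#' @return Named numeric vector of length 6: `resp_ent_energy`,
#'   `bcg_ent_energy`, `dev_ent_energy`, `resp_ent_approx`, `bcg_ent_approx`,
#'   `dev_ent_approx`.
#' @export
channel_features <- function(d, channel) {
  stopifnot(inherits(d, "decomposed_sample"))
  if (channel < 1 || channel > nrow(d$resp)) abort_bad_arg("invalid channel index")
  dec <- apen_decimation()
  resp <- d$resp[channel, ]; bcg <- d$bcg[channel, ]; dev <- d$dev[channel, ]
  ap <- function(x, f) {
    xd <- decimate_mean(x, f)
    s <- sd(xd)
    if (!is.finite(s) || s == 0) 0 else .apen_cpp(xd, 2L, 0.2 * s)
  }
  c(resp_ent_energy = energy_entropy(resp, 400L, 40L),
    bcg_ent_energy = energy_entropy(bcg, 100L, 10L),
    dev_ent_energy = energy_entropy(dev, 10L, 1L),
    resp_ent_approx = ap(resp, dec[["resp"]]),
    bcg_ent_approx = ap(bcg, dec[["bcg"]]),
    dev_ent_approx = ap(dev, dec[["dev"]]))
}

# all 32 channels at once: 32 x 6 feature matrix
minute_feature_matrix <- function(d) {
  t(vapply(seq_len(nrow(d$resp)), function(ch) channel_features(d, ch),
           numeric(6)))
}
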