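#' Decompose a minute into respiratory, BCG and deviation components
#'
#' Applies the respiratory (0.1-0.8 Hz) and BCG (0.8-15 Hz) band-pass filters
#' to every channel of a one-minute sample, forms the deviation component as
#' the pointwise remainder `dev = composite - (resp + bcg)`, and computes
#' per-channel energies as sums of squares. The deviation *energy* uses the
#' residual definition `dev_energy = composite_energy - (resp_energy +
#' bcg_energy)`, which may differ slightly from the energy of the deviation
#' signal itself and can be marginally negative on nearly noise-free input.
#'
#' @param sample A `minute_sample` or a numeric channels-by-samples matrix.
#' @param resp_filter,bcg_filter FIR coefficient vectors; defaults are the
#'   order-999 designs of [design_fir_bandpass()] for a 100 Hz sampling rate.
#' @param fs Sampling rate (Hz), used only to build the default filters.
#' @return A `decomposed_sample`: list with matrices `resp`, `bcg`, `dev`
#'   (same shape as the input) and per-channel energy vectors
#'   `composite_energy`, `resp_energy`, `bcg_energy`, `dev_energy`, plus the
#'   carried-over `posture`/`movement` metadata when present.
#' @examples
#' m <- synth_minute(subject_profile(), rng_seed = 1)
#' d <- decompose_minute(m)
#' sum(d$resp_energy) / sum(d$composite_energy)
#' @export
decompose_minute <- function(sample, resp_filter = NULL, bcg_filter = NULL,
                             fs = 100) {
  x <- if (inherits(sample, "minute_sample")) sample$voltages else sample
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (is.null(resp_filter) || is.null(bcg_filter)) {
    flt <- default_filters(fs)
    if (is.null(resp_filter)) resp_filter <- flt$resp
    if (is.null(bcg_filter)) bcg_filter <- flt$bcg
  }
  if (ncol(x) < max(length(resp_filter), length(bcg_filter)))
    abort_bad_arg("minute shorter than the filter length is not accepted")
  flt <- apply_fir_bank(x, list(resp = resp_filter, bcg = bcg_filter))
  resp <- flt$resp
  bcg <- flt$bcg
  dev <- x - resp - bcg
  comp_e <- rowSums(x^2)
  resp_e <- rowSums(resp^2)
  bcg_e <- rowSums(bcg^2)
  out <- list(resp = resp, bcg = bcg, dev = dev,
              composite_energy = comp_e, resp_energy = resp_e,
              bcg_energy = bcg_e, dev_energy = comp_e - (resp_e + bcg_e),
              fs = fs)
  if (inherits(sample, "minute_sample")) {
    out$posture <- sample$posture
    out$movement <- sample$movement
    out$per_channel_movement <- sample$per_channel_movement
    out$truth <- sample$truth
  }
  structure(out, class = "decomposed_sample")
}

#' Energy fractions of a decomposed sample
#'
#' Energy-weighted (pooled across channels) fractions of composite energy in
#' the respiratory, BCG and residual components.
#'
#' @param d A `decomposed_sample`.
#' @return A tibble with one row: `resp_frac`, `bcg_frac`, `dev_frac` (sum 1).
#' @export
energy_fractions <- function(d) {
  stopifnot(inherits(d, "decomposed_sample"))
  tot <- sum(d$composite_energy)
  tibble::tibble(resp_frac = sum(d$resp_energy) / tot,
                 bcg_frac = sum(d$bcg_energy) / tot,
                 dev_frac = sum(d$dev_energy) / tot)
}
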