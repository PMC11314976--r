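#' Simulate a night's posture schedule
#'
#' Draws an ordered sequence of (posture, duration) segments summing to
#' `total_minutes`. Full-night schedules (>= 360 min) have between 15 and 25
#' posture changes; consecutive segments always differ in posture. The
#' long-run time share of the three postures matches the cohort mix of
#' roughly 50% supine, 34% right-lateral and 17% left-lateral: the posture
#' sequence follows a no-repeat Markov chain whose stationary segment
#' frequencies, combined with posture-specific mean segment durations,
#' reproduce that time share in expectation.
#'
#' @param total_minutes Whole minutes in the schedule, `>= 60`.
#' @param rng_seed Optional integer seed; `NULL` uses the ambient RNG stream.
#' @return A `posture_schedule`: tibble with columns `posture` (factor) and
#'   `duration` (whole minutes), one row per segment.
#' @examples
#' sched <- make_posture_schedule(420, rng_seed = 1)
#' sum(sched$duration)
#' @export
make_posture_schedule <- function(total_minutes, rng_seed = NULL) {
  if (!is.numeric(total_minutes) || total_minutes < 60)
    abort_bad_arg("`total_minutes` must be at least 60")
  total_minutes <- as.integer(round(total_minutes))
  with_seed(rng_seed, {
    mix <- c(supine = 0.4978, right_lateral = 0.3356, left_lateral = 0.1666)
    # no-repeat chain P(i -> j) = mix_j / (1 - mix_i); stationary segment
    # frequencies are then proportional to mix * (1 - mix)
    seg_freq <- mix * (1 - mix); seg_freq <- seg_freq / sum(seg_freq)
    n_seg <- round(total_minutes / 21) + sample(-2:2, 1)
    n_seg <- max(2L, n_seg)
    if (total_minutes >= 360) n_seg <- min(max(n_seg, 16L), 26L)
    n_seg <- min(n_seg, total_minutes)  # at least 1 minute per segment

    postures <- character(n_seg)
    postures[1] <- sample(names(mix), 1, prob = seg_freq)
    for (i in seq_len(n_seg - 1)) {
      others <- setdiff(names(mix), postures[i])
      postures[i + 1] <- sample(others, 1, prob = mix[others])
    }
    # mean durations proportional to mix / segment-frequency reproduce the
    # target time share; gamma draws give realistic spread
    rel <- (mix / seg_freq)[postures]
    mean_dur <- rel / mean(rel)
    dur <- stats::rgamma(n_seg, shape = 6, rate = 6 / mean_dur)
    dur <- pmax(dur, 0.15)
    dur <- dur / sum(dur) * total_minutes
    # largest-remainder rounding to whole minutes (min 1) summing exactly
    base <- pmax(1L, floor(dur))
    deficit <- total_minutes - sum(base)
    if (deficit > 0) {
      extra <- order(dur - floor(dur), decreasing = TRUE)
      idx <- rep_len(extra, deficit)
      base <- base + tabulate(idx, nbins = n_seg)
    } else if (deficit < 0) {
      while (deficit < 0) {
        i <- which.max(base)
        take <- min(base[i] - 1L, -deficit)
        base[i] <- base[i] - take
        deficit <- deficit + take
      }
    }
    structure(tibble::tibble(
      posture = factor(postures, levels = posture_levels()),
      duration = as.integer(base)
    ), class = c("posture_schedule", class(tibble::tibble())))
  })
}

# expand a schedule to one posture label per minute
schedule_to_minutes <- function(schedule) {
  rep(as.character(schedule$posture), schedule$duration)
}
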