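#' Subject-level physiological profile for the simulator
#'
#' Parameters of one subject's cardiorespiratory signal model: a sinusoidal
#' respiration source at `fres`, and an amplitude-modulated BCG source whose
#' carrier runs at five times the heart rate `fhea` (five IJKL waves per
#' heartbeat envelope cycle) with modulation index `mbcg`. Per-cycle jitter is
#' stationary: cycle onsets are perturbed around a regular clock
#' (`freq_jitter_sd`, relative), and each cycle's amplitude is scaled by
#' `1 + N(0, amp_jitter_sd)`.
#'
#' Default amplitudes (`resp_amp = 1`, `bcg_amp = 0.26`, `mbcg = 0.4`,
#' `noise_sd = 0.12`) are calibrated by closed-form sinusoid/AM power
#' arithmetic so band-pass decomposition attributes roughly 90% of the
#' composite energy to respiration, 5-8% to the BCG and under 3% to the
#' residual, matching undisturbed chest-mat recordings.
#'
#' @param subject_id Subject identifier string.
#' @param fres Respiration frequency (Hz), in `[0.1, 0.8]`.
#' @param fhea Heart rate (Hz), in `[0.8, 3]` (carrier `5*fhea <= 15` Hz).
#' @param resp_amp Respiration voltage amplitude (arbitrary units).
#' @param bcg_amp BCG carrier amplitude `UAm` (same units).
#' @param mbcg Modulation index, in `(0, 1)`.
#' @param freq_jitter_sd Relative SD of per-cycle onset jitter.
#' @param amp_jitter_sd Relative SD of per-cycle amplitude jitter.
#' @param noise_sd Deviation-noise scale; each channel receives white noise
#'   with SD `noise_sd` times its respiratory coupling weight.
#' @param movement_rate Fraction of minutes contaminated by movement, `[0,1)`.
#' @return A `subject_profile` object (named list).
#' @export
subject_profile <- function(subject_id = "S01", fres = 0.25, fhea = 1.2,
                            resp_amp = 1.0, bcg_amp = 0.26, mbcg = 0.4,
                            freq_jitter_sd = 0.01, amp_jitter_sd = 0.05,
                            noise_sd = 0.12, movement_rate = 0.12) {
  if (fres < 0.1 || fres > 0.8) abort_bad_arg("`fres` must lie in [0.1, 0.8] Hz")
  if (fhea < 0.8 || fhea > 3) abort_bad_arg("`fhea` must lie in [0.8, 3] Hz")
  if (mbcg <= 0 || mbcg >= 1) abort_bad_arg("`mbcg` must lie in (0, 1)")
  if (movement_rate < 0 || movement_rate >= 1)
    abort_bad_arg("`movement_rate` must lie in [0, 1)")
  if (resp_amp < 0 || bcg_amp < 0 || noise_sd < 0)
    abort_bad_arg("amplitudes and `noise_sd` must be non-negative")
  structure(list(subject_id = subject_id, fres = fres, fhea = fhea,
                 resp_amp = resp_amp, bcg_amp = bcg_amp, mbcg = mbcg,
                 freq_jitter_sd = freq_jitter_sd, amp_jitter_sd = amp_jitter_sd,
                 noise_sd = noise_sd, movement_rate = movement_rate),
            class = "subject_profile")
}

# cohort draw: physiologically plausible spread around the defaults
draw_subject_profile <- function(subject_id, movement_rate = 0.12) {
  subject_profile(
    subject_id = subject_id,
    fres = runif(1, 0.18, 0.35),
    fhea = runif(1, 0.9, 1.5),
    resp_amp = exp(rnorm(1, 0, 0.25)),
    bcg_amp = 0.26 * exp(rnorm(1, 0, 0.25)),
    mbcg = runif(1, 0.3, 0.5),
    movement_rate = movement_rate
  )
}

# apply posture-specific effort/heart-rate factors to a profile
within_posture <- function(profile, eff) {
  profile$resp_amp <- profile$resp_amp * eff[["resp"]]
  profile$bcg_amp <- profile$bcg_amp * eff[["bcg"]]
  profile$fhea <- min(max(profile$fhea * eff[["hr"]], 0.8), 3)
  profile$fres <- min(max(profile$fres * eff[["rr"]], 0.1), 0.8)
  profile
}

# stationary per-cycle jitter: cycle onsets perturbed around a regular clock;
# returns instantaneous phase (rad) and the per-cycle amplitude factor
jitter_cycles <- function(f0, freq_jitter_sd, amp_jitter_sd, n, dt) {
  K <- ceiling(n * dt * f0) + 3L
  eps <- c(0, rnorm(K, 0, freq_jitter_sd), 0)[seq_len(K + 1)]
  onsets <- sort((0:K + eps) / f0)
  onsets[1] <- 0
  tt <- (seq_len(n) - 1) * dt
  ph <- approx(onsets, 2 * pi * (0:K), xout = tt, rule = 2)$y
  # amplitude varies smoothly (C2 spline) between cycle midpoints: step or
  # kinked changes would inject subject-dependent click trains into the
  # deviation band
  mids <- (onsets[-1] + onsets[-(K + 1)]) / 2
  amp <- stats::spline(mids, 1 + amp_jitter_sd * rnorm(K), xout = tt,
                       method = "natural")$y
  list(phase = ph, amp = amp)
}

# movement artifact: 1-4 saturating broadband bursts (clipped random-walk
# baseline shift plus white vibration), added to a single channel's signal
add_bursts <- function(x, windows, clip, step_frac = 0.05, white_frac = 0.2) {
  for (w in seq_len(nrow(windows))) {
    idx <- windows[w, 1]:windows[w, 2]
    len <- length(idx)
    burst <- cumsum(rnorm(len, 0, step_frac * clip)) +
      rnorm(len, 0, white_frac * clip)
    x[idx] <- x[idx] + pmax(pmin(burst, clip), -clip)
  }
  x
}

#' Simulate one minute of 32-channel mat voltages
#'
#' Generates a one-minute (6000-sample at 100 Hz) recording of the mat: each
#' channel receives the shared respiration sinusoid and AM-modulated BCG
#' scaled by its template weights, plus white deviation noise scaled by the
#' channel's respiratory weight. If `movement = TRUE`, between one and four
#' saturating broadband bursts (2-10 s each; random-walk baseline plus white
#' vibration, hard-clipped at three times the channel's clean range) are added
#' to at least seven randomly chosen channels, whose ground-truth
#' `per_channel_movement` flags are set.
#'
#' @param profile A [subject_profile()].
#' @param template A [spatial_template()] (optionally subject-perturbed).
#' @param movement Logical: contaminate this minute with motion artifacts?
#' @param rng_seed Optional integer seed; `NULL` uses the ambient RNG stream.
#' @param fs Sampling rate (Hz); one minute is `60 * fs` samples.
#' @return A `minute_sample`: list with `voltages` (32 x 6000 matrix,
#'   channels row-major over the 4 x 8 grid), `posture`, `movement`,
#'   `per_channel_movement` (32 logicals) and a `truth` list holding the
#'   generating parameters.
#' @export
synth_minute <- function(profile, template = spatial_template("supine"),
                         movement = FALSE, rng_seed = NULL, fs = 100) {
  stopifnot(inherits(profile, "subject_profile"),
            inherits(template, "spatial_template"))
  with_seed(rng_seed, {
    n <- 60L * fs
    dt <- 1 / fs
    # posture-dependent physiology relative to the supine baseline: lateral
    # postures transmit less breathing/cardiac effort to the mat (smaller
    # contact) and run slightly faster heart and breathing rates
    eff <- switch(template$posture,
                  supine = c(resp = 1.00, bcg = 1.00, hr = 1.00, rr = 1.00),
                  right_lateral = c(resp = 0.80, bcg = 0.92, hr = 1.05, rr = 1.05),
                  left_lateral = c(resp = 0.72, bcg = 0.84, hr = 1.05, rr = 1.07))
    profile <- within_posture(profile, eff)
    r <- jitter_cycles(profile$fres, profile$freq_jitter_sd,
                       profile$amp_jitter_sd, n, dt)
    ures <- profile$resp_amp * r$amp * sin(r$phase)
    b <- jitter_cycles(profile$fhea, profile$freq_jitter_sd,
                       profile$amp_jitter_sd, n, dt)
    # carrier phase-locked at five IJKL waves per heartbeat cycle
    ubcg <- profile$bcg_amp * b$amp *
      (1 + profile$mbcg * cos(b$phase)) * cos(5 * b$phase)

    wr <- as.vector(t(template$resp_weights))  # row-major channel order
    wb <- as.vector(t(template$bcg_weights))
    volt <- outer(wr, ures) + outer(wb, ubcg) +
      matrix(rnorm(32L * n, 0, profile$noise_sd), nrow = 32L) * wr

    per_channel <- rep(FALSE, 32L)
    if (movement) {
      k <- sample(7:32, 1)
      channels <- sample(32L, k)
      nb <- sample(1:4, 1)
      lens <- round(runif(nb, 2, 10) * fs)
      starts <- sapply(lens, function(l) sample.int(n - l, 1))
      windows <- cbind(starts, starts + lens - 1L)
      for (ch in channels) {
        clip <- 3 * max(abs(volt[ch, ]))
        volt[ch, ] <- add_bursts(volt[ch, ], windows, clip)
      }
      per_channel[channels] <- TRUE
    }
    structure(list(
      voltages = volt,
      posture = template$posture,
      movement = movement,
      per_channel_movement = per_channel,
      truth = list(fres = profile$fres, fhea = profile$fhea,
                   resp_amp = profile$resp_amp, bcg_amp = profile$bcg_amp,
                   mbcg = profile$mbcg, subject_id = profile$subject_id)
    ), class = "minute_sample")
  })
}

#' Simulate a cohort of labelled mat recordings in memory
#'
#' Draws `n_subjects` subject profiles, per-subject perturbed posture
#' templates and a full-night posture schedule each, then generates
#' `minutes_per_subject` labelled minute samples per subject. Movement
#' minutes are Bernoulli-drawn at the profile's `movement_rate`.
#'
#' @param n_subjects Number of subjects, `>= 2`.
#' @param minutes_per_subject Minutes recorded per subject, `>= 60`.
#' @param master_seed Integer seed governing every random draw.
#' @param movement_rate Fraction of contaminated minutes (default 0.12).
#' @param fixed_profile Optional [subject_profile()] used for every subject
#'   (cohort heterogeneity off); mainly for calibration runs.
#' @param transform Optional function applied to each `minute_sample` as it
#'   is generated; its (typically much smaller) return value is stored in
#'   place of the raw minute, so full-night cohorts can be processed without
#'   holding all raw voltages in memory.
#' @return A `mat_cohort`: list with `minutes` (list of [synth_minute()]
#'   results, or of `transform`'s outputs) and `manifest` (tibble:
#'   `subject_id`, `minute_index`, `posture`, `movement`).
#' @export
simulate_cohort <- function(n_subjects, minutes_per_subject, master_seed = 1,
                            movement_rate = 0.12, fixed_profile = NULL,
                            transform = NULL) {
  if (n_subjects < 2) abort_bad_arg("`n_subjects` must be at least 2")
  if (minutes_per_subject < 10)
    abort_bad_arg("`minutes_per_subject` must be at least 10")
  with_seed(master_seed, {
    templates <- lapply(posture_levels(), spatial_template)
    names(templates) <- posture_levels()
    minutes <- vector("list", n_subjects * minutes_per_subject)
    rows <- vector("list", n_subjects)
    k <- 0L
    for (s in seq_len(n_subjects)) {
      sid <- sprintf("S%02d", s)
      prof <- if (is.null(fixed_profile)) {
        draw_subject_profile(sid, movement_rate)
      } else {
        p <- fixed_profile; p$subject_id <- sid; p$movement_rate <- movement_rate; p
      }
      subj_tpl <- lapply(templates, perturb_template, sdlog = 0.45)
      sched <- make_posture_schedule(max(60L, minutes_per_subject))
      night <- schedule_to_minutes(sched)
      # short recordings sample the whole night's pattern, not its first
      # minutes, so several postures are still represented
      posture_by_min <- if (minutes_per_subject < length(night)) {
        night[round(seq(1, length(night), length.out = minutes_per_subject))]
      } else {
        night[seq_len(minutes_per_subject)]
      }
      mov <- runif(minutes_per_subject) < movement_rate
      for (m in seq_len(minutes_per_subject)) {
        k <- k + 1L
        # per-minute breathing-effort drift on top of the subject scale
        pm <- prof
        pm$resp_amp <- prof$resp_amp * exp(rnorm(1, 0, 0.1))
        pm$bcg_amp <- prof$bcg_amp * exp(rnorm(1, 0, 0.1))
        # within-posture body movement: cell-level wobble plus occasional
        # lateral displacement of the whole contact pattern
        tpl_m <- perturb_template(subj_tpl[[posture_by_min[m]]], sdlog = 0.25)
        tpl_m <- shift_template(tpl_m, sample(c(-1L, 0L, 1L), 1,
                                              prob = c(0.3, 0.4, 0.3)))
        smp <- synth_minute(pm, tpl_m, movement = mov[m])
        minutes[[k]] <- if (is.null(transform)) smp else transform(smp)
      }
      rows[[s]] <- tibble::tibble(
        subject_id = sid,
        minute_index = seq_len(minutes_per_subject),
        posture = posture_by_min,
        movement = mov
      )
    }
    structure(list(minutes = minutes, manifest = dplyr::bind_rows(rows)),
              class = "mat_cohort")
  })
}

#' Write a simulated dataset to disk
#'
#' Generates a cohort with [simulate_cohort()] and writes it as a dataset
#' directory: `manifest.csv` (columns `subject_id`, `minute_index`, `posture`,
#' `movement`, `file`) plus one matrix file per minute holding the 32 x 6000
#' voltage matrix, either as a packed binary container (`format = "bin"`) or
#' delimited text (`format = "tsv"`).
#'
#' @inheritParams simulate_cohort
#' @param dir Output directory (created if missing).
#' @param format Matrix container format, `"bin"` (default) or `"tsv"`.
#' @return The manifest tibble, invisibly.
#' @export
synth_dataset <- function(dir, n_subjects, minutes_per_subject,
                          master_seed = 1, movement_rate = 0.12,
                          format = c("bin", "tsv")) {
  format <- match.arg(format)
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, 2) != 0)
    stop("cannot write to output directory: ", dir, call. = FALSE)
  cohort <- simulate_cohort(n_subjects, minutes_per_subject, master_seed,
                            movement_rate)
  ext <- if (format == "bin") "bin" else "tsv"
  man <- cohort$manifest
  man$file <- sprintf("%s_min%04d.%s", man$subject_id, man$minute_index, ext)
  for (i in seq_along(cohort$minutes)) {
    path <- file.path(dir, man$file[i])
    if (format == "bin") write_matrix_bin(cohort$minutes[[i]]$voltages, path)
    else write_matrix_tsv(cohort$minutes[[i]]$voltages, path)
  }
  write_manifest(man, file.path(dir, "manifest.csv"))
  invisible(man)
}
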