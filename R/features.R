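#' Extract all posture features of one uninterfered minute
#'
#' Convenience wrapper running both feature paths on a decomposed minute:
#' the temporal amplitude/interval matrices ([extract_temporal()]) and the
#' spatial activity-intensity maps ([spatial_features()]).
#'
#' @param d A `decomposed_sample`.
#' @param params A [piezo_params()].
#' @return A `posture_features` object: list with `M1` (2 x 90), `M2`
#'   (2 x 180), `maps` (an `intensity_map_pair`) and `rates` (estimated
#'   `fres`, `fhea`, `mbcg`).
#' @export
extract_features <- function(d, params = piezo_params()) {
  tf <- extract_temporal(d)
  maps <- spatial_features(d, params)
  structure(list(M1 = tf$M1, M2 = tf$M2, maps = maps,
                 rates = attr(maps, "rates")),
            class = "posture_features")
}

#' Build the labelled feature set of a simulated cohort
#'
#' Runs the full preprocessing chain over an in-memory cohort: band-pass
#' decomposition of every minute, artifact screening (either with a trained
#' channel classifier and the >= `threshold` channel rule, or using the
#' generator's ground-truth movement flags when `artifact_model = NULL`),
#' then feature extraction for the retained uninterfered minutes. Minutes
#' whose feature extraction is rejected (no credible peaks) are dropped and
#' counted.
#'
#' @param cohort A `mat_cohort` from [simulate_cohort()].
#' @param artifact_model Optional `artifact_mlp`; `NULL` uses ground truth.
#' @param threshold Channel-count threshold for the minute-level flag.
#' @param params A [piezo_params()].
#' @return A `feature_set`: list with `samples` (list of `posture_features`),
#'   `manifest` (tibble of retained minutes: `subject_id`, `posture`,
#'   `movement`, `predicted_movement`), and exclusion counts.
#' @export
build_feature_set <- function(cohort, artifact_model = NULL, threshold = 7,
                              params = piezo_params()) {
  stopifnot(inherits(cohort, "mat_cohort"))
  n <- length(cohort$minutes)
  keep <- logical(n)
  pred <- logical(n)
  samples <- vector("list", n)
  n_rejected <- 0L
  for (i in seq_len(n)) {
    d <- decompose_minute(cohort$minutes[[i]])
    if (is.null(artifact_model)) {
      pred[i] <- isTRUE(d$movement)
    } else {
      p <- predict(artifact_model, minute_feature_matrix(d))
      pred[i] <- flag_sample(p > 0.5, threshold)$sample_flag
    }
    if (pred[i]) next
    ft <- tryCatch(extract_features(d, params),
                   sleepmat_rejected_fit = function(e) NULL,
                   sleepmat_unusable_minute = function(e) NULL)
    if (is.null(ft)) { n_rejected <- n_rejected + 1L; next }
    samples[[i]] <- ft
    keep[i] <- TRUE
  }
  man <- cohort$manifest
  man$predicted_movement <- pred
  structure(list(samples = samples[keep],
                 manifest = man[keep, , drop = FALSE],
                 screening = man,
                 n_flagged = sum(pred), n_rejected = n_rejected),
            class = "feature_set")
}

#' Simulate a cohort and extract its features in one streaming pass
#'
#' Equivalent to [simulate_cohort()] followed by [build_feature_set()], but
#' each minute is decomposed, screened and reduced to its features as soon
#' as it is generated, so the raw 32 x 6000 voltage matrices are never all
#' held in memory — full-night multi-subject studies fit comfortably.
#'
#' @inheritParams simulate_cohort
#' @inheritParams build_feature_set
#' @return A `feature_set`; its `screening` tibble holds one row per
#'   generated minute (kept or not) with the `predicted_movement` flag.
#' @export
simulate_feature_set <- function(n_subjects, minutes_per_subject,
                                 master_seed = 1, movement_rate = 0.12,
                                 artifact_model = NULL, threshold = 7,
                                 params = piezo_params(),
                                 fixed_profile = NULL) {
  process <- function(smp) {
    d <- decompose_minute(smp)
    flagged <- if (is.null(artifact_model)) {
      isTRUE(d$movement)
    } else {
      p <- predict(artifact_model, minute_feature_matrix(d))
      flag_sample(p > 0.5, threshold)$sample_flag
    }
    if (flagged) return(list(flagged = TRUE, features = NULL))
    ft <- tryCatch(extract_features(d, params),
                   sleepmat_rejected_fit = function(e) NULL,
                   sleepmat_unusable_minute = function(e) NULL)
    list(flagged = FALSE, features = ft)
  }
  coh <- simulate_cohort(n_subjects, minutes_per_subject, master_seed,
                         movement_rate, fixed_profile, transform = process)
  pred <- vapply(coh$minutes, function(x) x$flagged, TRUE)
  samples <- lapply(coh$minutes, function(x) x$features)
  keep <- !pred & !vapply(samples, is.null, TRUE)
  man <- coh$manifest
  man$predicted_movement <- pred
  structure(list(samples = samples[keep],
                 manifest = man[keep, , drop = FALSE],
                 screening = man,
                 n_flagged = sum(pred),
                 n_rejected = sum(!pred & !keep)),
            class = "feature_set")
}

# z-score each temporal feature row (M1/M2 amplitude and interval) against
# the subject's own night, so the network sees deviations from the wearer's
# baseline rather than absolute, subject-confounded values
normalize_by_subject <- function(batch, subject_ids) {
  for (nm in intersect(c("M1", "M2"), names(batch))) {
    X <- batch[[nm]]
    rows <- rep(1:2, length.out = nrow(X))
    for (sid in unique(subject_ids)) {
      cols <- which(subject_ids == sid)
      for (r in 1:2) {
        v <- X[rows == r, cols, drop = FALSE]
        s <- sd(v)
        X[rows == r, cols] <- (v - mean(v)) / (if (is.finite(s) && s > 0) s else 1)
      }
    }
    batch[[nm]] <- X
  }
  batch
}

#' Stack per-minute features into network input matrices
#'
#' Converts a list of `posture_features` into the four input matrices of the
#' posture network (one column per sample): `M1` (180 rows), `M2` (360),
#' `N1`, `N2` (512 each). Activity maps are divided by their own maximum and
#' fed with the long (32-cell) axis first.
#'
#' @param samples List of `posture_features` (e.g. a `feature_set$samples`).
#' @return Named list of numeric matrices.
#' @export
assemble_batch <- function(samples) {
  mapvec <- function(m) {
    mx <- max(m)
    if (mx > 0) m <- m / mx
    as.vector(t(m))  # 16 x 32 -> 32 x 16, column-major flatten
  }
  list(
    M1 = vapply(samples, function(s) as.vector(s$M1), numeric(180)),
    M2 = vapply(samples, function(s) as.vector(s$M2), numeric(360)),
    N1 = vapply(samples, function(s) mapvec(s$maps$upsampled_resp), numeric(512)),
    N2 = vapply(samples, function(s) mapvec(s$maps$upsampled_bcg), numeric(512))
  )
}
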