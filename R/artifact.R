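#' Train the channel-level artifact classifier
#'
#' Fits a single-hidden-layer perceptron (12 logistic hidden units, sigmoid
#' output) mapping the six entropy features of a channel-minute to the
#' probability that the channel is interfered by motion. Features are
#' z-scored with training-set statistics stored in the model; the decision
#' rule is `probability > 0.5`.
#'
#' @param features Numeric matrix (or data frame) with six columns, one row
#'   per channel-minute, in the order produced by [channel_features()].
#' @param labels Logical (or 0/1) vector: `TRUE` = interfered. Both classes
#'   must be present.
#' @param seed Integer seed for weight initialization and fitting.
#' @param maxit Maximum training iterations (default 500).
#' @return An `artifact_mlp` object.
#' @export
train_artifact_mlp <- function(features, labels, seed = 1, maxit = 500) {
  features <- as.matrix(features)
  labels <- as.logical(labels)
  if (ncol(features) != 6) abort_bad_arg("`features` must have 6 columns")
  if (length(unique(labels)) < 2)
    abort_bad_arg("both classes must be present in `labels`")
  mu <- colMeans(features)
  sdv <- apply(features, 2, sd)
  sdv[sdv == 0] <- 1
  xs <- scale(features, mu, sdv)
  fit <- with_seed(seed,
    nnet::nnet(xs, as.numeric(labels), size = 12, entropy = TRUE,
               maxit = maxit, trace = FALSE))
  structure(list(fit = fit, center = mu, scale = sdv), class = "artifact_mlp")
}

#' @describeIn train_artifact_mlp Predict interference probabilities for new
#'   channel-minutes.
#' @param object An `artifact_mlp`.
#' @param newdata Feature matrix with six columns.
#' @param ... Unused.
#' @export
predict.artifact_mlp <- function(object, newdata, ...) {
  xs <- scale(as.matrix(newdata), object$center, object$scale)
  as.vector(predict(object$fit, xs))
}

#' Minute-level artifact decision from channel flags
#'
#' A minute is an "interfered sample" when at least `threshold` of its 32
#' channels are individually flagged.
#'
#' @param channel_flags Logical vector of exactly 32 channel decisions.
#' @param threshold Channel-count threshold (default 7).
#' @return An `artifact_decision`: list with `channel_flags`,
#'   `interfered_count` and `sample_flag`.
#' @examples
#' flag_sample(c(rep(TRUE, 7), rep(FALSE, 25)))$sample_flag
#' @export
flag_sample <- function(channel_flags, threshold = 7) {
  channel_flags <- as.logical(channel_flags)
  if (length(channel_flags) != 32 || anyNA(channel_flags))
    abort_bad_arg("`channel_flags` must be exactly 32 non-missing logicals")
  cnt <- sum(channel_flags)
  structure(list(channel_flags = channel_flags, interfered_count = cnt,
                 sample_flag = cnt >= threshold),
            class = "artifact_decision")
}

#' Detect motion-artifact minutes in a set of decomposed samples
#'
#' Computes the 32 x 6 entropy feature matrix of every minute, scores each
#' channel with the trained perceptron, and applies the >= `threshold`
#' channel rule.
#'
#' @param decomposed List of `decomposed_sample` objects.
#' @param model An `artifact_mlp` from [train_artifact_mlp()].
#' @param threshold Channel-count threshold (default 7).
#' @return A tibble with one row per minute: `interfered_count`,
#'   `predicted_movement`.
#' @export
detect_artifacts <- function(decomposed, model, threshold = 7) {
  stopifnot(inherits(model, "artifact_mlp"))
  rows <- lapply(decomposed, function(d) {
    p <- predict(model, minute_feature_matrix(d))
    dec <- flag_sample(p > 0.5, threshold)
    tibble::tibble(interfered_count = dec$interfered_count,
                   predicted_movement = dec$sample_flag)
  })
  dplyr::bind_rows(rows)
}

# assemble pooled channel-level training data (features + generator ground
# truth) from a list of decomposed samples
artifact_training_data <- function(decomposed) {
  feats <- do.call(rbind, lapply(decomposed, minute_feature_matrix))
  labels <- unlist(lapply(decomposed, function(d) {
    if (is.null(d$per_channel_movement)) rep(FALSE, nrow(d$resp))
    else d$per_channel_movement
  }))
  list(features = feats, labels = labels)
}
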