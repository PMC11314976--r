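#' Subject-grouped k-fold assignment
#'
#' Partitions subjects into `k` folds of near-equal size (sizes differ by at
#' most one; with 22 subjects and `k = 10` every fold holds 2-3 subjects).
#' All minutes of a subject share that subject's fold, so no subject ever
#' appears in both the training and test side of a split.
#'
#' @param subject_ids Character vector of subject identifiers (duplicates
#'   allowed; the unique set is partitioned).
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the shuffle.
#' @return A `fold_plan` tibble: `subject_id`, `fold` (1..k).
#' @export
grouped_kfold <- function(subject_ids, k = 10, seed = 1) {
  subjects <- unique(as.character(subject_ids))
  if (length(subjects) < k)
    abort_bad_arg("fewer subjects than folds")
  with_seed(seed, {
    shuffled <- sample(subjects)
    tibble::tibble(subject_id = shuffled,
                   fold = rep_len(seq_len(k), length(shuffled)))
  })
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy, macro-averaged recall, precision and F1, and (when class
#' probability scores are supplied) one-vs-rest ROC areas per class plus
#' their macro average. The confusion matrix is oriented rows = true class,
#' columns = predicted class. A class absent from the truth has undefined
#' recall, reported as 0 with a warning.
#'
#' @param confusion Square numeric matrix (3 x 3 for the posture task).
#' @param scores Optional samples x classes probability matrix.
#' @param truth Optional factor of true labels matching `scores` rows.
#' @return A tibble with columns `metric`, `value`; per-class values are
#'   attached as attribute `"per_class"`.
#' @export
compute_metrics <- function(confusion, scores = NULL, truth = NULL) {
  stopifnot(is.matrix(confusion), nrow(confusion) == ncol(confusion))
  classes <- rownames(confusion)
  if (is.null(classes)) classes <- paste0("class", seq_len(nrow(confusion)))
  total <- sum(confusion)
  acc <- sum(diag(confusion)) / total
  rs <- rowSums(confusion)
  cs <- colSums(confusion)
  if (any(rs == 0))
    warning("class(es) absent from the truth: recall reported as 0",
            call. = FALSE)
  recall <- unname(ifelse(rs > 0, diag(confusion) / rs, 0))
  precision <- unname(ifelse(cs > 0, diag(confusion) / cs, 0))
  f1 <- ifelse(recall + precision > 0,
               2 * recall * precision / (recall + precision), 0)
  per_class <- tibble::tibble(class = classes, recall = recall,
                              precision = precision, f1 = f1)
  auc <- rep(NA_real_, length(classes))
  if (!is.null(scores) && !is.null(truth)) {
    truth <- factor(as.character(truth), levels = classes)
    for (i in seq_along(classes)) {
      resp <- truth == classes[i]
      if (length(unique(resp)) == 2) {
        auc[i] <- as.numeric(pROC::auc(
          pROC::roc(response = resp, predictor = scores[, i], quiet = TRUE,
                    direction = "<", levels = c(FALSE, TRUE))))
      }
    }
    per_class$auc <- auc
  }
  out <- tibble::tibble(
    metric = c("accuracy", "recall_macro", "precision_macro", "f1_macro",
               "auc_macro"),
    value = c(acc, mean(recall), mean(precision), mean(f1),
              if (all(is.na(auc))) NA_real_ else mean(auc, na.rm = TRUE)))
  attr(out, "per_class") <- per_class
  out
}

fit_fold_classifier <- function(classifier, train_batch, train_labels,
                                config, seed) {
  switch(classifier,
    s3cnn = {
      model <- build_s3cnn(config, seed = seed)
      train_s3cnn(model, train_batch, train_labels, config, seed = seed)
    },
    oracle = structure(list(), class = "oracle_stub"),
    majority = structure(
      list(class = names(which.max(table(as.character(train_labels))))),
      class = "majority_stub"))
}

predict_fold <- function(fit, test_batch, test_labels) {
  n <- ncol(test_batch[[1]])
  lev <- posture_levels()
  if (inherits(fit, "oracle_stub")) {
    prob <- matrix(0, n, 3, dimnames = list(NULL, lev))
    prob[cbind(seq_len(n), as.integer(factor(test_labels, lev)))] <- 1
    list(prob = prob, class = factor(as.character(test_labels), lev))
  } else if (inherits(fit, "majority_stub")) {
    prob <- matrix(1 / 3, n, 3, dimnames = list(NULL, lev))
    list(prob = prob, class = factor(rep(fit$class, n), lev))
  } else {
    predict(fit, test_batch)
  }
}

#' Subject-grouped cross-validation of the posture classifier
#'
#' Runs `rounds` rounds of `k`-fold subject-grouped cross-validation on a
#' feature set (uninterfered minutes only): per round, each fold's subjects
#' are held out, the classifier is trained on the remainder, and the ten
#' per-fold confusion matrices are summed before computing metrics, so every
#' retained sample contributes exactly once per round. If a split's training
#' side lacks a posture class, the round's fold plan is reshuffled (logged).
#'
#' @param features A `feature_set` from [build_feature_set()].
#' @param config An [s3cnn_config()]; its `branches` field selects the
#'   ablation variant.
#' @param k Number of folds (default 10).
#' @param rounds Number of cross-validation rounds (default 3).
#' @param seed Integer master seed; round `r` uses `seed + r - 1`.
#' @param classifier `"s3cnn"` (default), or the stubs `"oracle"` /
#'   `"majority"` used to validate the harness.
#' @param subject_norm Z-score each subject's temporal feature rows against
#'   that subject's own night (default `TRUE`). Baseline amplitudes and
#'   rates vary between sleepers far more than between postures, so the
#'   network sees deviations from the wearer's night baseline — an
#'   unsupervised calibration that needs no posture labels.
#' @return A `cv_report`: list with `rounds` (per-round list of `confusion`,
#'   `metrics`, `n`), `summary` (tibble of mean and SD per metric across
#'   rounds) and `n_samples`.
#' @export
run_cv <- function(features, config = s3cnn_config(), k = 10, rounds = 3,
                   seed = 1, classifier = c("s3cnn", "oracle", "majority"),
                   subject_norm = TRUE) {
  classifier <- match.arg(classifier)
  stopifnot(inherits(features, "feature_set"))
  man <- features$manifest
  if (length(unique(man$subject_id)) < k)
    abort_bad_arg("need at least as many subjects as folds")
  full_batch <- assemble_batch(features$samples)
  if (subject_norm)
    full_batch <- normalize_by_subject(full_batch, man$subject_id)
  labels <- factor(man$posture, levels = posture_levels())
  lev <- posture_levels()
  round_res <- vector("list", rounds)
  for (r in seq_len(rounds)) {
    rseed <- seed + r - 1
    for (attempt in 1:10) {
      plan <- grouped_kfold(man$subject_id, k, seed = rseed + 1000L * (attempt - 1L))
      fold_of <- plan$fold[match(man$subject_id, plan$subject_id)]
      ok <- all(vapply(seq_len(k), function(f)
        nlevels(droplevels(labels[fold_of != f])) == 3L, TRUE))
      if (ok) break
      message("fold plan reshuffled (round ", r,
              "): a training split lacked a posture class")
    }
    confusion <- matrix(0, 3, 3, dimnames = list(lev, lev))
    scores <- matrix(NA_real_, nrow(man), 3, dimnames = list(NULL, lev))
    for (f in seq_len(k)) {
      tr <- which(fold_of != f)
      te <- which(fold_of == f)
      if (!length(te)) next
      tr_batch <- lapply(full_batch, function(X) X[, tr, drop = FALSE])
      te_batch <- lapply(full_batch, function(X) X[, te, drop = FALSE])
      fit <- fit_fold_classifier(classifier, tr_batch, labels[tr], config,
                                 seed = rseed * 100 + f)
      pr <- predict_fold(fit, te_batch, labels[te])
      scores[te, ] <- pr$prob
      confusion <- confusion + table(factor(labels[te], lev),
                                     factor(pr$class, lev))
    }
    metrics <- compute_metrics(confusion, scores, labels)
    round_res[[r]] <- list(confusion = confusion, metrics = metrics,
                           n = sum(confusion))
  }
  wide <- dplyr::bind_rows(lapply(seq_len(rounds), function(r)
    dplyr::mutate(round_res[[r]]$metrics, round = r)))
  summary <- dplyr::summarise(
    dplyr::group_by(wide, .data$metric),
    mean = mean(.data$value), sd = if (rounds > 1) sd(.data$value) else 0,
    .groups = "drop")
  structure(list(rounds = round_res, summary = summary,
                 n_samples = nrow(man), classifier = classifier,
                 branches = config$branches),
            class = "cv_report")
}

#' Ablation study: temporal-only, spatial-only and combined variants
#'
#' Repeats the cross-validation with the two 1-D branches only (temporal),
#' the two 2-D branches only (spatial) and all four branches (combined),
#' under identical fold plans and seeds.
#'
#' @inheritParams run_cv
#' @return A tibble: `variant`, `metric`, `mean`, `sd`.
#' @export
run_ablation <- function(features, config = s3cnn_config(), k = 10,
                         rounds = 1, seed = 1) {
  variants <- list(temporal = c("M1", "M2"), spatial = c("N1", "N2"),
                   combined = c("M1", "M2", "N1", "N2"))
  out <- lapply(names(variants), function(v) {
    cfg <- config
    cfg$branches <- variants[[v]]
    rep <- run_cv(features, cfg, k = k, rounds = rounds, seed = seed)
    dplyr::mutate(rep$summary, variant = v)
  })
  dplyr::bind_rows(out)[, c("variant", "metric", "mean", "sd")]
}

#' @export
tidy.cv_report <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$rounds), function(r)
    dplyr::mutate(x$rounds[[r]]$metrics, round = r)))
}

#' @export
glance.cv_report <- function(x, ...) {
  s <- x$summary
  out <- tibble::as_tibble(setNames(as.list(s$mean), s$metric))
  out$n_samples <- x$n_samples
  out
}

#' @export
autoplot.cv_report <- function(object, round = 1, ...) {
  cm <- object$rounds[[round]]$confusion
  df <- tibble::tibble(truth = rep(rownames(cm), ncol(cm)),
                       predicted = rep(colnames(cm), each = nrow(cm)),
                       n = as.vector(cm))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(title = sprintf("Summed confusion matrix (round %d)", round),
                  x = "predicted posture", y = "true posture") +
    ggplot2::theme_minimal()
}

#' @export
print.cv_report <- function(x, ...) {
  cat("Subject-grouped cross-validation (", x$classifier, ", branches: ",
      paste(x$branches, collapse = "+"), ")\n", sep = "")
  cat(x$n_samples, "samples,", length(x$rounds), "round(s)\n\n")
  print(x$summary)
  invisible(x)
}
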