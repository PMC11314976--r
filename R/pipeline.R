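# ---- matrix and manifest containers ----------------------------------------

#' Read and write numeric matrices (packed binary or delimited text)
#'
#' The binary container is a minimal packed format: an 8-byte magic string,
#' two integers (rows, columns) and the matrix as little-endian doubles in
#' column-major order; round-trips are bit-identical. The text container is
#' plain tab-separated values.
#'
#' @param m Numeric matrix.
#' @param path File path.
#' @return `write_*` return `path` invisibly; `read_*` return the matrix.
#' @export
write_matrix_bin <- function(m, path) {
  stopifnot(is.matrix(m), is.numeric(m))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("SMATBIN1", con, nchars = 8, eos = NULL)
  writeBin(c(nrow(m), ncol(m)), con, size = 4, endian = "little")
  writeBin(as.vector(m), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_matrix_bin
#' @export
read_matrix_bin <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 8, useBytes = TRUE)
  if (!identical(magic, "SMATBIN1"))
    stop("not a sleepmat binary matrix file: ", path, call. = FALSE)
  dims <- readBin(con, "integer", 2, size = 4, endian = "little")
  vals <- readBin(con, "double", prod(dims), size = 8, endian = "little")
  matrix(vals, dims[1], dims[2])
}

#' @rdname write_matrix_bin
#' @export
write_matrix_tsv <- function(m, path) {
  utils::write.table(m, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_bin
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
}

read_matrix_any <- function(path) {
  if (grepl("\\.bin$", path)) read_matrix_bin(path) else read_matrix_tsv(path)
}

#' Read and write dataset manifests
#'
#' A manifest is a CSV with one row per minute-sample and at least the
#' columns `subject_id`, `minute_index`, `posture`, `movement`; a `file`
#' column references the per-minute matrix file. [validate_manifest()]
#' checks the schema and that every referenced file exists, reporting the
#' offending row.
#'
#' @param manifest A data frame/tibble.
#' @param path CSV path.
#' @param dir Directory holding the referenced matrix files.
#' @return `write_manifest` returns `path` invisibly; `read_manifest` a
#'   tibble; `validate_manifest` the manifest invisibly (or an error).
#' @export
write_manifest <- function(manifest, path) {
  write.csv(as.data.frame(manifest), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname write_manifest
#' @export
validate_manifest <- function(manifest, dir) {
  need <- c("subject_id", "minute_index", "posture", "movement")
  missing_cols <- setdiff(need, names(manifest))
  if (length(missing_cols))
    stop("manifest lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if ("file" %in% names(manifest)) {
    ok <- file.exists(file.path(dir, manifest$file))
    if (!all(ok))
      stop("manifest row ", which(!ok)[1], ": referenced file not found: ",
           manifest$file[which(!ok)[1]], call. = FALSE)
  }
  invisible(manifest)
}

# ---- pipeline orchestration ------------------------------------------------

#' Pipeline run configuration
#'
#' One object resolving every stage's parameters: simulation size and seed,
#' filter band edges, artifact threshold, network/training settings and the
#' cross-validation plan. A stable hash of the configuration is recorded in
#' the outputs.
#'
#' @param out_dir Output directory for all stages.
#' @param n_subjects,minutes_per_subject,movement_rate Simulation size.
#' @param seed Global seed; all stage randomness derives from it.
#' @param artifact_threshold Channel-count threshold for minute flags.
#' @param k,rounds,epochs Cross-validation folds, rounds and training epochs.
#' @param format Matrix container format (`"bin"` or `"tsv"`).
#' @return A `run_config` object.
#' @export
run_config <- function(out_dir, n_subjects = 4, minutes_per_subject = 30,
                       movement_rate = 0.12, seed = 1,
                       artifact_threshold = 7, k = 4, rounds = 1,
                       epochs = 10, format = "bin") {
  cfg <- list(out_dir = out_dir, n_subjects = n_subjects,
              minutes_per_subject = minutes_per_subject,
              movement_rate = movement_rate, seed = seed,
              artifact_threshold = artifact_threshold, k = k,
              rounds = rounds, epochs = epochs, format = format)
  cfg$hash <- rlang::hash(cfg[setdiff(names(cfg), "out_dir")])
  structure(cfg, class = "run_config")
}

#' Run the full pipeline: simulate, decompose, screen, extract, evaluate
#'
#' Executes every stage against the configured output directory. Stages are
#' idempotent and resumable: each per-minute output file is regenerated only
#' if absent, so re-running a completed pipeline performs no recomputation
#' and deleting a single intermediate file regenerates exactly that file.
#' Stage failures abort with the stage name; completed outputs are retained.
#'
#' @param config A [run_config()].
#' @param quiet Suppress stage progress messages.
#' @return A `cv_report` (invisibly also written as CSV under
#'   `<out_dir>/report/`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message("[sleepmat] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  raw_dir <- file.path(config$out_dir, "raw")
  comp_dir <- file.path(config$out_dir, "components")
  feat_dir <- file.path(config$out_dir, "features")
  rep_dir <- file.path(config$out_dir, "report")
  for (d in c(raw_dir, comp_dir, feat_dir, rep_dir))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)

  # 1: simulate
  man_path <- file.path(raw_dir, "manifest.csv")
  stage("simulate", {
    if (!file.exists(man_path)) {
      say("simulate: ", config$n_subjects, " x ", config$minutes_per_subject,
          " minutes")
      synth_dataset(raw_dir, config$n_subjects, config$minutes_per_subject,
                    master_seed = config$seed,
                    movement_rate = config$movement_rate,
                    format = config$format)
    } else say("simulate: manifest present, skipping")
  })
  man <- validate_manifest(read_manifest(man_path), raw_dir)

  # 2: decompose (respiratory + BCG components per minute)
  stage("decompose", {
    for (i in seq_len(nrow(man))) {
      out <- file.path(comp_dir, sub("\\.(bin|tsv)$", "_comp.bin", man$file[i]))
      if (file.exists(out)) next
      x <- read_matrix_any(file.path(raw_dir, man$file[i]))
      d <- decompose_minute(x)
      write_matrix_bin(rbind(d$resp, d$bcg), out)
    }
    say("decompose: components ready")
  })

  # 3: artifact model + minute screening
  flag_path <- file.path(config$out_dir, "manifest_flags.csv")
  mlp_path <- file.path(config$out_dir, "artifact_mlp.rds")
  stage("detect-artifacts", {
    if (!file.exists(mlp_path)) {
      say("detect-artifacts: training channel classifier on calibration data")
      calib <- simulate_cohort(4, 40, master_seed = config$seed + 7919,
                               movement_rate = 0.5)
      dec <- lapply(calib$minutes, decompose_minute)
      td <- artifact_training_data(dec)
      mlp <- train_artifact_mlp(td$features, td$labels, seed = config$seed)
      saveRDS(mlp, mlp_path)
    }
    mlp <- readRDS(mlp_path)
    if (!file.exists(flag_path)) {
      flags <- logical(nrow(man))
      for (i in seq_len(nrow(man))) {
        x <- read_matrix_any(file.path(raw_dir, man$file[i]))
        d <- decompose_minute(x)
        p <- predict(mlp, minute_feature_matrix(d))
        flags[i] <- flag_sample(p > 0.5, config$artifact_threshold)$sample_flag
      }
      man$predicted_movement <- flags
      write_manifest(man, flag_path)
    }
    say("detect-artifacts: flags ready")
  })
  man <- read_manifest(flag_path)

  # 4: features for retained minutes
  stage("extract-features", {
    kept <- which(!man$predicted_movement)
    for (i in kept) {
      out <- file.path(feat_dir, sub("\\.(bin|tsv)$", "_feat.tsv", man$file[i]))
      if (file.exists(out)) next
      x <- read_matrix_any(file.path(raw_dir, man$file[i]))
      d <- decompose_minute(x)
      ft <- tryCatch(extract_features(d),
                     sleepmat_rejected_fit = function(e) NULL,
                     sleepmat_unusable_minute = function(e) NULL)
      if (is.null(ft)) {
        say("extract-features: minute ", man$file[i], " unusable, skipped")
        next
      }
      write_feature_file(ft, out)
    }
    say("extract-features: done")
  })

  # 5: evaluate
  stage("evaluate", {
    kept <- which(!man$predicted_movement)
    paths <- file.path(feat_dir, sub("\\.(bin|tsv)$", "_feat.tsv",
                                     man$file[kept]))
    have <- file.exists(paths)
    samples <- lapply(paths[have], read_feature_file)
    fs <- structure(list(samples = samples,
                         manifest = man[kept[have], , drop = FALSE],
                         n_flagged = sum(man$predicted_movement),
                         n_rejected = sum(!have)),
                    class = "feature_set")
    cfg <- s3cnn_config(epochs = config$epochs)
    report <- run_cv(fs, cfg, k = config$k, rounds = config$rounds,
                     seed = config$seed)
    utils::write.csv(cbind(as.data.frame(report$summary),
                           config_hash = config$hash),
                     file.path(rep_dir, "metrics.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(report$rounds[[1]]$confusion),
                     file.path(rep_dir, "confusion_round1.csv"))
    say("evaluate: report written")
    invisible(report)
  })
}

# per-minute feature file: long-format TSV (block, row, col, value)
write_feature_file <- function(ft, path) {
  blk <- function(m, name) {
    tibble::tibble(block = name, row = as.vector(row(m)),
                   col = as.vector(col(m)), value = as.vector(m))
  }
  df <- dplyr::bind_rows(
    blk(ft$M1, "M1"), blk(ft$M2, "M2"),
    blk(ft$maps$upsampled_resp, "map_resp"),
    blk(ft$maps$upsampled_bcg, "map_bcg"))
  utils::write.table(df, path, sep = "\t", row.names = FALSE)
  invisible(path)
}

read_feature_file <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  get <- function(name) {
    b <- df[df$block == name, ]
    m <- matrix(0, max(b$row), max(b$col))
    m[cbind(b$row, b$col)] <- b$value
    m
  }
  structure(list(M1 = get("M1"), M2 = get("M2"),
                 maps = structure(list(upsampled_resp = get("map_resp"),
                                       upsampled_bcg = get("map_bcg")),
                                  class = "intensity_map_pair")),
            class = "posture_features")
}
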