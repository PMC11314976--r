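# Shared fixtures, built lazily and cached for the whole test run.
fixture_env <- new.env()

fixture <- function(name, builder) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- builder()
  fixture_env[[name]]
}

default_profile <- function(...) subject_profile(...)

# one clean default minute (seed 42) and its decomposition
fx_minute <- function() fixture("minute", function()
  synth_minute(default_profile(), spatial_template("supine"), rng_seed = 42))
fx_decomp <- function() fixture("decomp", function()
  decompose_minute(fx_minute()))

# 50 clean default minutes, generated as one seeded stream (shared by the
# energy-fraction and fit-quality checks)
fx_clean50 <- function() fixture("clean50", function() {
  set.seed(42)
  prof <- default_profile()
  tpl <- spatial_template("supine")
  lapply(1:50, function(i) synth_minute(prof, tpl))
})
fx_clean50_decomp <- function() fixture("clean50_decomp", function()
  lapply(fx_clean50(), decompose_minute))

# naive reference ApEn (double loop over template vectors)
apen_reference <- function(x, m, r) {
  n <- length(x)
  phi <- function(mm) {
    nm <- n - mm + 1
    emb <- sapply(seq_len(mm), function(k) x[k:(k + nm - 1)])
    if (nm == 1) emb <- matrix(emb, nrow = 1)
    C <- numeric(nm)
    for (i in seq_len(nm)) {
      d <- apply(abs(sweep(emb, 2, emb[i, ], "-")), 1, max)
      C[i] <- mean(d <= r)
    }
    mean(log(C))
  }
  phi(m) - phi(m + 1)
}

# independent arithmetic for the voltage-to-force inversion
voltage_to_force_oracle <- function(U, p) U * p$CM / (p$beta * p$d33)

# a movement-contaminated default minute
fx_movement_minute <- function(seed = 7) {
  synth_minute(default_profile(), spatial_template("supine"),
               movement = TRUE, rng_seed = seed)
}

# small cohort + features for exercising the cross-validation harness
fx_cv_cohort <- function() fixture("cv_cohort", function()
  simulate_cohort(4, 40, master_seed = 11, movement_rate = 0.05))
fx_cv_features <- function() fixture("cv_features", function()
  build_feature_set(fx_cv_cohort()))

# small labelled artifact training set + trained channel classifier
fx_artifact_model <- function() fixture("artifact_model", function() {
  coh <- simulate_cohort(6, 40, master_seed = 314, movement_rate = 0.5)
  dec <- lapply(coh$minutes, decompose_minute)
  td <- sleepmat:::artifact_training_data(dec)
  list(model = train_artifact_mlp(td$features, td$labels, seed = 1),
       training = td)
})
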