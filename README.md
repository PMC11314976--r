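# sleepmat

Sleep posture detection from a sparse piezoelectric pressure mat.

Sleep posture is clinically consequential — supine sleep worsens
obstructive sleep apnea, and bed-bound patients need regular repositioning
to prevent pressure ulcers — yet the gold standard (polysomnography) is too
costly for continuous home monitoring. A sparse mat of 32 piezoelectric
sensors (a 4 × 8 grid, 100 Hz, placed under the chest) records the
micro-vibrations of breathing and the heartbeat. `sleepmat` implements the
full analysis chain that turns those raw voltages into posture labels:

1. **Simulation** — a calibrated generator of labelled mat recordings
   (`simulate_cohort()`, `synth_dataset()`): sinusoidal respiration
   `A sin(2π f_res t)`, an amplitude-modulated ballistocardiogram (BCG)
   `U_Am (1 + M cos 2π f_hea t) cos(2π · 5 f_hea · t)` (five IJKL waves per
   heartbeat), posture-specific 4 × 8 coupling templates, and saturating
   broadband movement bursts on ≥ 7 channels in ~12% of minutes.
2. **Decomposition** (`decompose_minute()`) — 1000-tap linear-phase FIR
   band-pass filters (Dolph-Chebyshev window) split each minute into the
   respiratory (0.1–0.8 Hz), BCG (0.8–15 Hz) and deviation components; on
   undisturbed minutes these carry ≈ 90%, 5–8% and < 3% of the energy.
3. **Artifact screening** (`channel_features()`, `train_artifact_mlp()`,
   `flag_sample()`) — per-channel energy entropy and approximate entropy
   feed a 12-unit perceptron; a minute is discarded when ≥ 7 of its 32
   channels are flagged.
4. **Feature extraction** — per-channel cardiorespiratory activity
   intensities from the summed-instantaneous-variation identity
   `Σ|ΔU| ≈ 4 A f T`, upsampled bicubically into 16 × 32 activity maps
   (`spatial_features()`); beat-by-beat amplitude/interval sequences
   resampled to 2 × 90 (respiration) and 2 × 180 (heartbeat)
   (`extract_temporal()`).
5. **Classification** (`build_s3cnn()`, `train_s3cnn()`) — a four-branch
   spatiotemporal CNN (two 1-D temporal branches, two 2-D map branches,
   each ending in a 32-vector, stacked 32 × 4, dense 64 → 96 → softmax over
   supine / right-lateral / left-lateral), trained with Adam, batch 48,
   L1 + weight-decay regularization; ~55k parameters, fully deterministic
   given a seed.
6. **Evaluation** (`run_cv()`, `run_ablation()`) — subject-grouped 10-fold
   cross-validation with summed confusion matrices, macro metrics and
   one-vs-rest AUC, plus the temporal-only / spatial-only / combined
   ablation.

The methods vignette (`vignettes/sleepmat-methods.Rmd`) documents the
signal model, every numerical convention, and the design decisions.

## Worked example

```r
library(sleepmat)

# one minute of a default subject lying supine
m <- synth_minute(subject_profile(), spatial_template("supine"), rng_seed = 42)
d <- decompose_minute(m)
energy_fractions(d)
#> # A tibble: 1 × 3
#>   resp_frac bcg_frac dev_frac
#>       <dbl>    <dbl>    <dbl>
#> 1     0.917   0.0740  0.00861

agg <- fit_respiration(d$resp[which.max(d$resp_energy), ])
tidy(agg)
#> # A tibble: 2 × 2
#>   term  estimate
#>   <chr>    <dbl>
#> 1 Ares     1.000
#> 2 fres     0.250
glance(agg)$r.squared
#> [1] 0.979683
```

92% of this minute's energy sits in the respiratory band, and a single
sinusoid at the true breathing frequency (0.25 Hz) explains 98.0% of the
band-passed variance of the best-coupled channel — the regime in which the
model-based intensity and interval features are meaningful.

A small end-to-end study (4 subjects × 30 minutes, 4-fold subject-grouped
cross-validation) runs in about two minutes:

```r
fs  <- simulate_feature_set(4, 30, master_seed = 1)   # ground-truth screening
rep <- run_cv(fs, s3cnn_config(epochs = 10), k = 4, rounds = 1, seed = 1)
rep$summary
```

The resumable disk pipeline and its command-line wrapper do the same
against a dataset directory:

```sh
inst/cli/sleepmat run-all --out run1 --subjects 4 --minutes 30 --seed 1
```

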