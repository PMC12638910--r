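# eegstages

Analysis pipeline for 14-channel consumer-grade EEG (Emotiv EPOC+-style
montage, 128 Hz) recorded while learners work through a multi-session course
with three task types (lecture videos, virtual labs, quizzes) grouped into
three learning stages (sessions 1–3, 4–6, 7–11). The package is aimed at
educational-neuroscience work that needs a reproducible, tested route from
raw multi-channel recordings to stage/task statistics and learning-stage
classification.

It implements, end to end:

- **Quality control** — zero-phase 1 Hz high-pass + 50 Hz notch, 30 s setup
  discard, non-overlapping 10 s segments with linear detrending, the
  outlier rule |y − mean| > 3·SD with half-lead discard,
  nearest-neighbour correction, and the ±150 µV amplitude rejection.
- **Spectral features** — Welch PSD (2 s Hamming windows, 50 % overlap) and
  relative band power in six bands (δ, θ, α, low-β, high-β, γ) over
  1–45 Hz; per-channel average amplitude; 84-feature vectors
  (14 channels × 6 bands).
- **Connectivity** — phase-lag index PLI(i,j) = |⟨sign sin(φᵢ − φⱼ)⟩|,
  strongest long-range links, weighted Latora–Marchiori global/local
  efficiency, and a symmetric information-transfer matrix
  MI(q,s) = H(q) + H(s) − H(q,s) (bits) over delay-embedded,
  histogram-discretized states.
- **Components** — group task-related component analysis (gTRCA): spatial
  filters solving S w = λ Q w, maximizing inter-trial reproducibility, with
  forward-model scalp patterns.
- **Statistics** — Wilcoxon rank-sum stage/task contrasts (exact null for
  small tie-free groups, tie/continuity-corrected normal otherwise) with
  Cohen's d, rank-biserial correlation and noncentral-t post-hoc power.
- **Classification** — MRMR feature ranking and a five-model suite
  (SVM, KNN, decision tree, regularized QDA, neural network) under a
  stratified 80/20 test split plus 10-fold cross-validation.
- **Synthetic sessions** — a seeded generator (band-limited oscillations +
  1/f noise, stage/task effect profiles, channel-pair phase coupling,
  artifact injection with a ground-truth ledger) so the full pipeline is
  testable without participant data.

## Worked example

```r
library(eegstages)

# one synthetic quiz session from learning stage 3, with artifacts
cfg <- synth_config(duration = 230, seed = 11, session = 8L, task = "quiz",
                    band_profiles = default_band_profiles(3, "quiz"),
                    artifact_spec = artifact_spec(spike_rate = 0.15,
                                                  excursion_rate = 0.1,
                                                  half_lead_rate = 0.1))
rec <- generate_session(cfg)
pp  <- preprocess_recording(rec)
pp$report
#> # A tibble: 4 x 2
#>   status                  n
#>   <chr>               <int>
#> 1 kept                    0
#> 2 kept_corrected         13
#> 3 discarded_outliers      4
#> 4 discarded_amplitude     3

feats <- extract_features(pp$kept)        # 13 rows x (labels + 84 + 14) cols
fv <- feature_vector(pp$kept[[1]])
length(fv)                                # 84 relative-power features
#> [1] 84
round(fv[c("O1_alpha", "AF3_theta")], 3)
#>  O1_alpha AF3_theta
#>     0.291     0.264

P <- pli_matrix(pp$kept[[1]])             # 14 x 14, full band 1-45 Hz
efficiency(P)
#> $global_efficiency
#> [1] 0.1851684
#> $local_efficiency
#> [1] 0.1844268
```

The per-segment QC statuses come straight from the artifact ledger the
generator wrote (`attr(rec, "artifacts")`): excursion-injected segments are
discarded by the 150 µV rule, half-lead-corrupted segments by the outlier
rule, isolated spikes are corrected and kept. The relative-power entries are
fractions of 1–45 Hz power (posterior alpha is the largest single share on
O1, as configured), and the efficiency values are graph summaries of the
weighted PLI network in [0, 1].

A full study-shaped run — stage-labelled dataset, rank-sum contrasts and
classifier suite — is one call per step:

```r
cfg <- pipeline_config(synth = list(n_subjects = 2, effect_size = 1.5),
                       seed = 1)
for (step in c("simulate", "preprocess", "features", "connectivity",
               "stats", "classify", "report"))
  run_pipeline(step, cfg, "eeg_run")
```

Each step writes plain-text artifacts (CSV/TSV/JSON, BrainNet-style
`.node`/`.edge` files) into the run directory under a config-hash manifest.

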