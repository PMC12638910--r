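---
title: "Methods: multi-task, multi-stage learning EEG analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-task, multi-stage learning EEG analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

`eegstages` analyses 14-channel consumer-grade EEG (Emotiv EPOC+-style
montage, 128 Hz) recorded while learners repeatedly perform three task types
(lecture videos, virtual labs, quizzes) across an 11-session curriculum whose
sessions are grouped into three learning stages (1–3, 4–6, 7–11). The
pipeline covers: segment-level quality control, Welch relative band power,
per-channel average amplitude, group task-related component analysis (gTRCA),
phase-lag-index (PLI) connectivity with weighted graph efficiencies, a
histogram mutual-information transfer matrix over delay-embedded states,
Wilcoxon rank-sum stage/task contrasts with post-hoc effect size and power,
and MRMR-ranked machine-learning discrimination of the three stages from
84-dimensional relative-power feature vectors.

Because no participant data are distributable, the package ships a synthetic
session generator that emulates the recording setup; every downstream stage
is developed and tested against it.

## The synthetic generator

Each channel is a sum of six band-limited oscillations (sinusoids at fixed
representative frequencies: 2.5, 6, 10, 14, 20, 35 Hz) plus 1/f-shaped
Gaussian noise (default SD 10 µV). Amplitudes come from a channels × bands
profile; defaults place stronger alpha posteriorly and stronger delta/theta
frontally, with plausible magnitudes (1.5–10 µV per rhythm). Oscillation
amplitudes are jittered multiplicatively per 10 s block (SD 0.15),
independently across blocks, channels and bands. Blocks are aligned with the
QC slicing grid, so non-overlapping 10 s segments are statistically
independent by construction — a property the type-I-error calibration of the
statistics module relies on, and a deliberate idealization: real EEG has
slow state drifts that correlate neighbouring segments, so calibration on
synthetic data does not by itself guarantee nominal error rates on real
pooled segments (the grouped, subject-session-wise splitting mode exists for
that reason).

Stage and task effects are qualitative directions scaled by a single
`effect_size` knob: alpha power declining across lab stages, high-beta
elevated in late lab/quiz stages, frontal theta elevated in early lectures,
and overall amplitude rising across lecture stages while falling for labs
and quizzes (8–20 % per unit `effect_size`). No quantitative per-band effect
sizes are available to copy, so these magnitudes were fixed once at values a
practitioner would call realistic; `effect_size = 0` makes all stages
identically distributed (the null generator), and `effect_size = 2` gives
band-power shifts of at least twice the jitter SD (the "strong effect"
regime used when a clearly separable dataset is required).

Channel-pair coupling mixes a shared oscillator into both channels with a
fixed phase offset, which yields analytic PLI targets (strength 1, lag π/2 →
PLI exactly 1; lag 0 → PLI exactly 0). Injected artifacts are designed so
their QC outcome is predictable and recorded in a ledger: isolated 1-sample
spikes (corrected by the outlier rule → `kept_corrected`), slow triangular
drift (removed by filtering/detrending → kept), a 2 s ±220 µV multi-channel
burst (dominates the segment variance, so it survives the outlier rule and
trips the 150 µV check → `discarded_amplitude`), and dense ±220 µV spikes on
58 % of one lead (→ `discarded_outliers`). The generator does not attempt
biophysical realism (no head-model mixing, no blink/EMG waveform shapes);
what passing tests demonstrate is that the *pipeline computes its quantities
correctly*, not that it would reach any particular accuracy on human data.

## Quality control

Preprocessing is a zero-phase 4th-order Butterworth 1 Hz high-pass plus a
50 Hz biquad notch (Q = 30; the two sections are multiplied into one cascade
and applied forward–backward). The first 30 s of each recording are
discarded, the remainder cut into non-overlapping 10 s segments (trailing
remainder dropped; a recording shorter than 40 s yields zero segments with a
warning), and each segment is linearly detrended per channel.

Outliers are samples with |y − mean| > 3 · SD. The reference statistics are
computed over **all channels of the segment jointly** (configurable to
per-channel). This choice is forced by arithmetic: relative to a channel's
own mean and SD, Chebyshev's inequality caps the fraction of samples beyond
3 SD at 1/9, so a "more than half the lead is outliers → discard" rule could
never fire under per-channel statistics. With segment-wide statistics a
single corrupted lead is judged against the montage-wide scale and the
half-lead discard behaves as intended. The QC order is fixed: (a) half-lead
discard, (b) nearest-neighbour interpolation of outliers (ties to the
earlier sample), (c) the ±150 µV amplitude check on the corrected signal.
Running the amplitude check *after* correction means an isolated 200 µV
spike that interpolation repairs does not cost the segment; a sustained
excursion does. ICA-based artifact removal is exposed only as a pass-through
hook: no component-selection criterion is defined here, so the default
pipeline omits it.

## Spectral features

Welch PSD uses 2 s Hamming windows with 50 % overlap (9 windows per segment,
0.5 Hz resolution) with per-window mean removal; the estimator satisfies
Parseval within a few percent. Band edges — delta [1,4), theta [4,8), alpha
[8,12), low-beta [12,16), high-beta [16,25), gamma [25,45) Hz — are
package assumptions (common consumer-EEG conventions) and fully
configurable; the six bands tile the 1–45 Hz analysis range, so the six
relative powers of a channel sum to 1 (and are therefore exactly collinear —
see the QDA note below). Relative power is band power divided by total power
over 1–45 Hz, making features invariant to amplitude scaling. "Average
amplitude" is defined as mean absolute voltage (the raw mean is ~0 after
high-pass filtering); RMS is available as an option. Feature vectors are
channel-major (`AF3_delta`, `AF3_theta`, …, `AF4_gamma`), 84 entries.

## gTRCA

Spatial filters maximize inter-trial reproducibility via the generalized
eigenproblem S w = λ Q w, with Q the pooled within-trial covariance and S
the summed cross-trial covariances, pooled within subject blocks and summed
over subjects (the full Bayesian multi-subject extension of the original
method is out of scope). Q always receives a relative ridge of 1e-6 × tr(Q)/C;
filters are unit length and sign-fixed (largest-magnitude pattern entry
positive); the forward pattern is Q w, normalized. Unequal trial lengths are
truncated to the common minimum. With K identical trials the leading
objective attains its maximum K − 1, which the tests use as an exact anchor.

## Connectivity

PLI follows the sign-of-phase-difference definition: band-pass (zero-phase
Butterworth), analytic-signal phase, then |mean sign(sin Δφ)| with 5 % of
samples trimmed at each end. sign(0) contributes 0, so identical (zero-lag)
channels give PLI 0 — the volume-conduction robustness that motivates the
index. Full-band PLI is computed on 1–45 Hz; any sub-band is available.
The long-range rule for link extraction is a package decision: electrode
pairs whose schematic 10–20 distance exceeds the median pairwise distance
(an inter-hemispheric-only mode is provided). Ties in link strength break by
channel index. Efficiencies are Latora–Marchiori on the weighted,
unthresholded graph with edge distance 1/weight; local efficiency averages
the global efficiency of each node's neighbour-induced subgraph, with
isolated/degree-1 nodes contributing 0. Disconnected pairs contribute 0 via
infinite distances.

The information-transfer matrix uses MI(q,s) = H(q) + H(s) − H(q,s) in bits.
States are formed by delay-embedding each channel (m = 3, τ = 4 samples ≈
31 ms at 128 Hz) and histogramming the leading embedding coordinate into 16
equal-width bins; the joint distribution is the 16 × 16 histogram of paired
coordinates. Embedding parameters, bin count and the estimator are flagged
assumptions — the quantity is symmetric by construction, so no directional
(source → receiver) claim is made, and the default estimator is the plug-in
(so MI(X,X) = H(X) holds exactly and a deterministic 4-state copy gives
exactly 2 bits); a Miller–Madow bias correction (clamped at zero) is
available and is what should be used when near-zero MI between independent
channels matters.

## Statistics

`ranksum()` uses the exact Mann-Whitney null distribution when both groups
have ≤ 10 tie-free observations, otherwise the normal approximation with tie
and continuity corrections. The exact mode agrees with a brute-force
permutation oracle on every fixture with n1 + n2 ≤ 12. The normal
approximation deviates from the exact p by up to ~0.13 in the extreme tails
at these sizes (a property of the approximation itself, measured exactly
from the null distribution), which is precisely why the exact path exists
and is preferred at small n. Effect size is Cohen's d with pooled SD plus
the rank-biserial correlation; post-hoc power is the two-sided two-sample
t-test power at the observed d via the noncentral t distribution (the
convention of common power software). Stars are uncorrected (*, **, *** at
0.05/0.01/0.001), matching the reporting convention the pipeline mirrors; a
Benjamini–Hochberg option exists but is off by default. Whole-brain, left
({AF3, F7, F3, FC5, T7, P7, O1}) and right ({AF4, F8, F4, FC6, T8, P8, O2})
regions are supported; segments are pooled across subjects by default (a
subject-grouped alternative exists in the classifier's splitting mode).

Type-I calibration is verified on the null generator with 20 kept segments
per group: at that size the tie-corrected normal path's exact null rejection
probability at α = 0.05 is 0.0491 (computed from the discrete U
distribution), so a ~1000-contrast simulation should land near 5 %.

## Stage classification

Samples are the 84-feature segments pooled across sessions; assembly is
deterministic (subject, session, segment order) and rejects duplicates and
missing classes. The protocol is a stratified 80/20 pool/test split followed
by stratified 10-fold cross-validation on the pool (9:1), validation
accuracy being the mean fold accuracy; the final model is refit on the whole
pool and scored once on the held-out test set, with test/fold disjointness
asserted programmatically. Splitting is segment-level by default (mirroring
a pooled-segments design and its optimistic bias on correlated real data);
`grouped = TRUE` splits by subject-session instead.

Models: RBF SVM (standardized features), KNN with k = 10, an unpruned
(cp = 0, depth ≤ 20) Gini decision tree, regularized QDA and a single-hidden-
layer neural network (30 logistic units, weight decay 1e-3, ≤ 200
iterations). QDA is implemented in-package with per-class covariance
ridging (λ = 1e-4 × mean diagonal): the six relative powers of each channel
sum to exactly 1, so the 84-feature covariance is rank-deficient by
construction and unregularized QDA is undefined. The NN differs from a
100-ReLU-unit design on purpose: the available backend offers logistic
units, and 30 suffice at these input dimensions; all hyperparameters are
exposed in the model config.

MRMR uses equal-frequency 4-bin discretization, plug-in MI, the MID
(relevance − mean redundancy) criterion and low-index tie-breaking, making
rankings deterministic.

## Numerical and scale choices

Fixed QC constants follow the procedure the pipeline mirrors (k = 3, 150 µV,
30 s discard, 10 s segments, top-10 links in the [0.5, 0.7] PLI window,
α = 0.05). Degenerate inputs are defined, not accidental: zero-SD channels
have zero outliers (strict inequality), zero total power raises an explicit
error, constant channels carry zero entropy, and fully tied rank-sum data
give p = 1.

Test and demonstration problem sizes are chosen for laptop-scale runs: the
classifier checks use ~3.8 k synthetic segments (test set ≈ 750), recovery
checks use 20–50 seeded replicates, and the null calibration uses ~1000
contrasts of 20 segments per group. The acceptance script scales the same
computations to a few minutes of CPU; all sizes are parameters, and nothing
in the methods depends on them.

## Known limitations

- The generator's spectral and artifact realism is deliberately minimal;
  accuracies obtained on it say nothing quantitative about human data.
- Segment-level pooling ignores within-session correlation; use the grouped
  split and subject-level summaries for inference on real recordings.
- The MI matrix is symmetric: it quantifies shared information, not
  directed transfer.
- Band edges, embedding parameters, histogram bins, the long-range rule and
  the 80/20 test protocol are documented assumptions where the mirrored
  procedure leaves gaps.
- EDF and HDF5 I/O are not provided; session I/O is Emotiv-style CSV with a
  JSON sidecar, matrices are TSV, networks are BrainNet-style text files.
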