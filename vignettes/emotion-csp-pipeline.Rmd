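---
title: "Methods: CSP/LDA emotion classification and band-power statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CSP/LDA emotion classification and band-power statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emocsp)
```

## The analysis model

`emocsp` treats emotion recognition from EEG as a spatial-spectral pattern
problem. The working assumption is that an emotional state modulates the
power of band-limited cortical sources with a stable spatial signature:
each source projects to the electrodes through a fixed mixing vector, so
states differ in the *spatial covariance* of the band-passed signal rather
than in its mean. That assumption motivates the whole chain:

* **Common spatial patterns** estimate, for a target state against the
  rest, the linear channel combinations whose variance is maximally
  state-dependent. Per epoch `X` (channels × samples) we use the
  trace-normalized covariance `C = XXᵀ / tr(XXᵀ)`; class covariances are
  arithmetic means of epoch covariances, which weights every epoch equally
  regardless of its absolute power. The projection `W` simultaneously
  diagonalizes both class covariances (`W C₁ Wᵀ = λ₁`, `W C₂ Wᵀ = λ₂`,
  `λ₁ + λ₂ = I`), computed by whitening the composite covariance and
  rotating into the eigenbasis of the whitened class-1 covariance.
* **Log-variance features** `f_q = log(var Y_q / Σ var Yᵢ)` over the first
  and last `m` filters summarize each epoch. The within-epoch
  normalization makes features invariant to global amplitude, and the log
  brings the variance ratios close enough to Gaussian for a linear
  discriminant.
* **Shared-covariance LDA** with weights `w = C⁻¹(μ₊ − μ₋)` and a midpoint
  bias is the matching classifier under the equal-covariance Gaussian
  model. Multiclass assignment is one-vs-rest: three binary CSP+LDA
  stacks, each epoch assigned the state with the largest signed distance
  `(wᵀx − b)/‖w‖`. Exact ties (measure-zero in practice) resolve to the
  lowest state index in the fixed order fear < joy < neutral, so results
  are deterministic.

Statistical claims about *where* and *in which band* power changes are
made separately from classification: percent band-power change relative to
the pre-stimulus reference, aggregated channel → region, and a
repeated-measures ANOVA over state × band × region.

## Trial structure and segmentation

Four stimulation paradigms are supported, with defaults mirroring the
study design the package targets:

| paradigm | trials/state | trial length | analysis window | epochs/state |
|----------|-------------:|-------------:|-----------------|-------------:|
| EI, VI   | 10           | 60 s         | last 55 s       | 550          |
| PI       | 45           | 7 s          | last 5 s        | 225          |
| SI       | 45           | 6–10 s       | last 5 s        | 225          |

Every trial carries a 5 s pre-stimulus baseline. Analysis windows are cut
into non-overlapping 1 s epochs (256 samples at 256 Hz on the 14-channel
montage). SI trial duration is fixed at 7 s — the midpoint of the nominal
6–10 s range — so the 5 s window always fits; it is configurable. Trials
shorter than their window are dropped with a warning rather than padded.

The pipeline order is fixed: segment → epoch → max–min rejection →
baseline correction → filter bank. Filtering inside 1 s epochs rather than
on the continuous record introduces edge transients (mitigated by
odd-reflection padding and steady-state initial conditions), and epoching
and filtering only commute approximately; the order above is therefore a
definition of the method, not an interchangeable choice, and the tests
assert this fixed order.

## Tunable parameters

* `threshold` (µV, default 150): max–min rejection. Applied per channel;
  an epoch fails if *any* channel's peak-to-peak range exceeds it — the
  strictest reading of the rule.
* `interval_ms` (default 200): baseline-correction window, the final
  200 ms before onset. The *power* reference in band-power statistics uses
  the full 5 s baseline instead: 200 ms holds less than one delta-band
  cycle and would make the low-band reference meaningless.
* Filter bank: delta 1–3, theta 4–7, alpha 8–13, beta 14–30, low gamma
  31–50, high gamma 51–70 Hz; order 5. "Order 5" is interpreted as the
  band-pass prototype order; with the zero-phase forward–backward pass the
  effective magnitude response is the square of the order-5 design. The
  zero-phase choice suits variance-based features, which are insensitive
  to latency but not to phase distortion across channels.
* `m` (default 3): CSP filters kept per tail. The classical guidance is a
  small number relative to the channel count; with 14 channels, `2m = 6`
  features keep LDA well-conditioned at the smallest per-fold training
  sizes. Tests exercise `m ∈ {1, 2, 3}`.
* `gamma` (default 0): optional ridge shrinkage of class covariances
  toward scaled identity, for rank-deficient data; plain CSP is the
  default method.
* CV scheme: 10 folds × 10 repetitions, trial-wise.

## Why trial-wise cross-validation

One-second epochs from the same trial share slow background activity, so
epoch-wise partitioning puts near-duplicates on both sides of a split and
inflates accuracy. `run_cv` therefore partitions *trials*, stratified by
state, and refits CSP and LDA per fold on training trials only; the
held-out fold contributes epoch-level accuracy. An epoch-wise mode
(`by_epoch = TRUE`) exists for comparison with analyses that partition
epochs directly. With 30 trials and 10 folds each fold holds 3 trials and
training uses 27 — the test suite asserts this bookkeeping, along with a
direct no-leakage check that per-fold parameters are identical when the
test trials are physically deleted from the input.

## The synthetic generator

`generate_recording()` emulates the *structure* that the downstream stages
rely on, with known ground truth:

* trials in alternating state order (fear, neutral, joy, …), per-paradigm
  counts and durations as above, 5 s baselines;
* background: 1/f-amplitude Gaussian noise, spatially mixed through a
  random full-rank matrix. The non-diagonal noise covariance matters: CSP
  whitening is trivial under white noise, and only correlated backgrounds
  exercise it;
* per state, a unit-norm mixing pattern (pairwise |cos| < 0.9 enforced)
  carrying a band-limited source (white noise filtered to
  `band_of_effect`, default alpha) during activity windows only;
* `snr` is total source power over total background power across channels;
* amplitude convention: background at 2 µV RMS per channel, so a source at
  `snr = 10` stays below the 150 µV rejection threshold while injected
  artifacts (one-sided 200 µV half-sine deflections) are guaranteed above
  it. The one-sided shape makes every injected epoch's max–min range at
  least the artifact amplitude, so recovery by the rejection rule is exact
  rather than probabilistic;
* determinism: a single integer seed drives everything; per-trial
  sub-streams mean a trial's source does not depend on how many trials
  precede it.

What the generator does **not** emulate: ERP morphology and evoked phase
locking, realistic ocular/EMG artifact waveforms, volume-conduction
geometry, non-stationary state dynamics within a trial, and inter-subject
anatomical variability (exposed only as `pattern_jitter`, Gaussian jitter
on the mixing patterns, with no claimed realistic scale). Consequently,
passing tests demonstrate that the *pipeline* is correct and calibrated —
recovery of planted structure, chance-level behavior under nulls — not
that any particular accuracy is attainable on human recordings.

## Numerical choices

* **Filters as second-order sections.** An order-5 band-pass expanded into
  a degree-10 polynomial is numerically unstable for the delta band at
  256 Hz (a pole lands outside the unit circle in double precision). The
  design is therefore carried in zero-pole-gain form through the low-pass →
  band-pass transform and bilinear transform, and applied as cascaded
  biquads; the forward–backward pass uses odd-reflection padding with
  steady-state initial conditions, so constant inputs map to exactly zero.
* **CSP conventions.** Filters are ordered by λ₁ descending; each filter
  is scaled so its largest-magnitude coefficient is positive, making
  output deterministic up to floating-point rounding. Patterns are the
  matrix inverse of the projection. Rank-deficient composite covariances
  raise an error pointing at `gamma`.
* **"Rest" covariance** in one-vs-rest CSP is the mean normalized
  covariance over all non-target epochs, keeping the binary framing of
  target-versus-everything-else.
* **LDA shrinkage** toward scaled identity engages only when the pooled
  covariance is numerically singular, with the smallest power of ten that
  restores invertibility, and is recorded on the model.
* **ANOVA.** Effects are tested against their subject-by-effect strata
  (`aov` with an `Error(subject/…)` term). Effects whose sums of squares
  are zero to machine precision are reported as F = 0, p = 1 instead of a
  0/0 ratio. No sphericity correction is applied by default; subjects with
  incomplete cells are removed listwise with a message. Follow-up
  fear-vs-joy contrasts are paired t-tests per (band, region) cell with a
  Benjamini–Hochberg column alongside raw p-values.
* **Zero-variance epochs** are flagged invalid at the feature stage and
  excluded downstream rather than producing `-Inf` features.

## Calibration and problem sizes in the test suite

The suite validates statistical behavior at sizes chosen to make the
checks sharp but fast: CSP/eigenproblem equivalence on 100 random 3–10
channel problems; pattern recovery on 100 generator runs at `snr = 10`
(absolute cosine > 0.9 required in ≥95); classification on 15 trials/state
picture-paradigm data (≥95 % three-class accuracy at `snr = 10`); and two
chance-level nulls — permuted labels and `snr = 0` — whose accuracies are
averaged over several independent permutations/datasets because a single
dataset of n trials has a binomial sampling error of a few percentage
points around the 33.3 % chance level. ANOVA calibration uses a
table-level null simulator (`simulate_bandpower_table`): 200 replicates of
a no-effect design, whose state-effect p-values must pass a
Kolmogorov–Smirnov uniformity test; the planted-effect localization check
uses a shift of three residual standard deviations, i.e. a clearly
separated effect, and requires the smallest contrast p-value to land in
the planted (band, region) cell in ≥90 % of runs. Running the full
generator at these replicate counts would add nothing to what the
table-level null measures, so the ANOVA calibration deliberately operates
at the table level.

## Known limitations

* ICA-based artifact removal is not implemented; the max–min rule is the
  only automatic rejection. The preprocessing chain accepts externally
  cleaned data, so an ICA step can be applied upstream.
* European Data Format I/O is not included; recordings interchange as
  delimited text (samples + events + montage), which round-trips
  bit-identically.
* The repeated-measures ANOVA assumes a balanced complete within-subject
  design after listwise removal and offers no Greenhouse–Geisser
  correction; with the 2 × 5 × 5 grids it targets, sphericity violations
  inflate only the multi-df band/region effects, not the two-level state
  effect that the follow-up contrasts probe.
* The montage's region map (AF3, AF4, F3, F4, F7, F8 → frontal; FC5, FC6 →
  central; T7, T8 → temporal; P7, P8 → parietal; O1, O2 → occipital)
  follows standard 10–20 prefixes; other conventions can be supplied via
  montage files.
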