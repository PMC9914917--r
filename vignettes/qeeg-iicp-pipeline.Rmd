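---
title: "Predicting increased intracranial pressure from single-channel qEEG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting increased intracranial pressure from single-channel qEEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Intracranial pressure (ICP) monitoring after traumatic brain injury is
invasive: it requires a burr hole and an intraparenchymal or subdural
pressure catheter. A non-invasive surrogate with usable discrimination for
*increased* ICP (IICP, operationally ICP ≥ 25 mmHg) would let clinicians
triage earlier. The electrical activity of the cortex shifts as ICP rises —
in particular the share of faster (≥ 13 Hz) rhythms grows under
intracranial hypertension — so quantitative indices of a single-channel
EEG carry information about the ICP state.

This package implements the full analysis chain for that question in a
stepwise balloon-inflation injury protocol: a cohort of anaesthetized
subjects undergoes a 5-min baseline (ICP ≈ 12.4 mmHg) followed by four
6-min injury steps targeting 20, 30, 40 and 50 mmHg, while single-channel
EEG (250 Hz) and ICP/MAP/HR are recorded continuously. Epochs of EEG are
labelled IICP-positive when their mean ICP is ≥ 25 mmHg, a feature bank is
computed per epoch, the most discriminative features are selected on a
derivation group of subjects, and four classifiers are evaluated on
held-out validation subjects.

Because data of this kind are restricted, the cohort itself is synthetic:
the `protocol_sim` functions generate records whose spectral statistics
move with ICP the way the real recordings are reported to. Everything
downstream is agnostic to the data's origin and reads the same EDF + CSV
formats it writes.

## The synthetic cohort

`generate_cohort()` produces `subject_record`s from two ingredients:

* **Protocol** (`protocol_config()`): phase layout, ICP targets, sampling
  rates. Each injury step starts with a 30-s linear ramp and then
  fluctuates around its target with additive Gaussian jitter (SD
  1.5 mmHg). Hemodynamic traces are generated at 10 Hz rather than the
  kilohertz rates of an acquisition platform: the analysis only ever uses
  epoch means, for which 10 Hz is ample resolution.
* **Spectral profile** (`spectral_profile()`): for each of the five ICP
  bins (< 20, 20–30, 30–40, 40–50, ≥ 50 mmHg), the relative power weights
  of the five conventional EEG bands and a target RMS amplitude, plus a
  pink-noise fraction.

The EEG model is

$$x(t) = A(t)\Big(\sqrt{p}\,\eta_{1/f}(t) +
  \sqrt{1-p}\sum_{b=1}^{5}\sqrt{w_b(t)}\,\xi_b(t)\Big),$$

where $\xi_b$ are unit-variance band-limited Gaussian oscillators (FFT
brick-wall masks over δ 0.5–4, θ 4–8, α 8–13, β 13–30, γ 30–47 Hz),
$\eta_{1/f}$ is band-limited pink noise, $p$ is the pink fraction
(default 0.3), and $A(t)$, $w_b(t)$ are looked up from the profile by the
concurrent ICP bin. The spectral state follows the *noise-free protocol
ICP level*, not the jittered measured trace: the cortex responds to the
underlying intracranial state, and driving the weights from measurement
jitter would make the generator flip bins spuriously whenever a plateau
sits at a bin boundary (every plateau does).

The default profile moves monotonically with the bin — the theta share
falls (0.145 → 0.08), beta and gamma shares rise (0.22 → 0.38 and
0.02 → 0.08), and the RMS amplitude grows from 32.5 to 41.5 µV. The
anchor values are the reported per-bin feature means where available
(gamma share 0.02 at baseline to 0.07–0.08 at ≥ 50 mmHg; EEG magnitudes
of roughly 32–42 µV; MAP 90 → 120 mmHg; HR 96 → 135 /min), filled in with
conventional anaesthetized-EEG band compositions where no anchor exists.
These are *directional calibration anchors*, not fitted targets: the
generator is judged by whether the downstream bin means move the right
way, not by reproducing any printed number.

Per-subject random effects make subjects exchangeable but not identical:
a log-normal amplitude factor (SD 0.15 on the log scale) and Gaussian
jitter on each band weight (SD 0.02, rows renormalized). Both matter for
honesty of the subject-split evaluation — validation subjects have
amplitudes and band compositions the models never saw.

What the generator deliberately does **not** emulate: artefacts (the
analysis assumes artefact-free EEG), burst suppression, non-stationarity
within a plateau, ECG/EMG contamination, and any biomechanics of the
balloon–ICP relationship. Passing the end-to-end checks on this cohort
therefore shows that the pipeline recovers a planted, physiologically
plausible spectral signal under subject heterogeneity — not that the
real-data effect sizes are reproduced. A `include_recovery` flag can
append a recovery phase with flattened (amplitude-suppressed) EEG for
robustness experiments; it is off by default because recovery EEG is not
analyzable in this model and the analysis protocol excludes it.

One protocol arithmetic note: the full protocol yields 25 min of retained
epochs per subject (5 baseline + 4 × 5 after exclusions), i.e. 750
subject-minutes for 30 subjects. Reported totals for the real experiment
are slightly lower (~612 min), implying unstated per-animal truncation;
the generator produces the full protocol and we document rather than
imitate the discrepancy.

## Preprocessing

* **Filtering**: 4th-order Butterworth band-pass 0.5–47 Hz, applied
  forward and backward (zero phase). The filter runs on the whole record
  *before* epoching, so epochs share no edge transients. The
  implementation initializes each pass at the filter's steady-state
  response to the first sample value and pads by odd reflection, so a
  constant input produces (exactly) its zero steady-state output.
* **Epochs**: 2 s long, 1.5 s overlap (0.5 s stride), half-open windows
  $[s, s+2)$ anchored at the record start; no partial trailing epoch.
* **Synchronization**: the epoch's ICP/MAP/HR is the mean of the 10-Hz
  trace samples whose (centred) time falls in the window. For a linear
  ramp this reproduces the trapezoid mean exactly.
* **Label**: IICP = 1 iff mean ICP ≥ 25 mmHg — inclusive, per the
  threshold's definition ("equal to or greater").
* **Phase rule**: an epoch takes the phase of its start time.
* **Exclusion**: every epoch whose window intersects the first 60 s of an
  injury step is dropped (hemodynamic stabilization), including epochs
  that lean in from the preceding phase. Baseline is otherwise retained in
  full, leaving exactly 25 min of epochs per subject under the default
  protocol.

## The feature bank

Per epoch, 20 candidate features in three domains. The spectral estimate
is a Welch periodogram (1-s Hann segments, 50% overlap — three segments
per epoch), chosen over a raw periodogram for variance; the raw
periodogram can be selected by setting `seg_seconds` to the epoch length.

The ten *panel* features mirror the indices conventionally reported per
ICP bin:

| feature | definition |
|---|---|
| `magnitude` | RMS amplitude of the epoch (µV) |
| `deltar` | $\log_{10}\!\big(P_\delta / (P_\theta+P_\alpha+P_\beta+P_\gamma)\big)$ |
| `dtabr` | $\log_{10}\!\big((P_\delta+P_\theta)/(P_\alpha+P_\beta)\big)$ |
| `thetapr`, `gammapr` | $P_\theta/P_{tot}$, $P_\gamma/P_{tot}$ |
| `log_energy_entropy` | $\sum_i \ln(x_i^2 + 10^{-12})$ |
| `sd_theta` … `sd_gamma` | SD of the epoch after zero-phase band-limiting |

The log-ratio forms for `deltar`/`dtabr` are a declared design choice:
the two indices are reported with near-mirror negative/positive values of
similar magnitude, which is the signature of $\log_{10}$ ratios of
complementary band groups. They are validated only directionally, and the
formulas are isolated in `ratio_features()` so alternates can be swapped.
Band powers are floored at $10^{-12} P_{tot}$ before logs; entropy uses
the natural log, ratios $\log_{10}$.

The remaining candidates (`rel_delta`, `rel_alpha`, `rel_beta`,
`sd_delta`, spectral entropy, 95% spectral edge frequency, line length,
zero-crossing rate, Hjorth mobility/complexity) are a documented
surrogate for the unenumerated wider index bank the ranking stage is
meant to sift; they give the selection stage 20 candidates of mixed
usefulness.

Band SDs use FFT brick-wall masks rather than IIR filters: on a fixed
500-sample window this is exactly zero-phase, respects the band edges
exactly, and vectorizes across all epochs of a subject in a handful of
FFTs.

## Feature selection

Selection is fitted on the derivation subjects only; normalization
parameters and the selected set are frozen before any validation epoch is
touched, and every fitted object carries the subject ids it saw so the
evaluator can enforce this provenance.

1. **Min-max normalization**: derivation minimum → 0, maximum → 1;
   validation values extrapolate without clipping; constant columns map
   to 0 with a warning.
2. **NCA ranking**: diagonal (feature-weighting) neighborhood component
   analysis, implemented from its objective — maximize the leave-one-out
   soft accuracy $\sum_i p_i - \lambda \sum_r w_r^2$ with
   $p_{ij} \propto \exp(-\sum_r w_r^2 |x_{ir}-x_{jr}|/\sigma)$ — by
   gradient ascent with a backtracking step, so the objective trajectory
   is non-decreasing by construction. The weighted-L1 kernel distance and
   the per-feature weight vector follow the feature-selection NCA
   convention (this is the ranking variant, not the linear-transform
   metric learner). Defaults: $\sigma = 1$ on normalized features,
   $\lambda = 1/n$, 100 iterations, tolerance $10^{-6}$. Because the
   objective is $O(n^2)$, the fit runs on a label-and-subject-stratified
   subsample (default 2000 epochs), seed-controlled; with 0.5-s stride
   the epochs are 75%-overlapping and highly redundant, so the subsample
   loses little information.
3. **t-test filter**: classical pooled-variance two-sided t-test per
   feature, no multiple-testing correction (the selection rule is a raw
   p < 0.05 joint with the ranking — kept as such deliberately).
4. **Top-10**: survivors ranked by descending weight, ties broken by
   registry order; fewer than 10 survivors is allowed with a warning.

## Classifiers

All four models consume the same frozen 10-feature schema:

* **LR** — binomial GLM with logit link (`stats::glm`).
* **NB** — naive Bayes with Gaussian-kernel-smoothed class-conditional
  densities per feature; bandwidth by the normal-reference rule
  (`bw.nrd`), densities floored at $10^{-12}$ and clamped to their grid
  endpoints outside it.
* **SVM** — Gaussian kernel with kernel scale 1.7 and box constraint 1,
  i.e. `gamma = 1/1.7^2`, `cost = 1` (via e1071/libsvm); Platt-scaled
  probabilities, seed-fixed.
* **RF** — a random-subspace ensemble of 30 learners: each tree is grown
  on a random subset of $\lceil\sqrt{d}\rceil$ features using all
  training rows, and scores are averaged class-1 probabilities. This is
  the attribute-bagging reading of "ensemble aggregation with a random
  subspace, 30 learning cycles"; the trees are rpart CART trees
  (cp 0.001, minsplit 40, depth ≤ 10).

Models train on a stratified subsample of derivation epochs (default
6000, by label and subject). The rationale is the same redundancy
argument as for NCA; the subsample size is a `run_config()` knob.
Cross-validation (`cross_validate()`) partitions *subjects* into the k
folds, so no subject's epochs straddle a fold boundary; an epoch-level
mode exists behind `grouped = FALSE` for comparison, because the original
description does not state its grouping. No class rebalancing is applied
(prevalence is near-balanced by design of the protocol).

## Evaluation

`evaluate_holdout()` reports, per model: confusion counts, accuracy,
sensitivity, specificity, precision, F1, MCC and AUC with 95% CIs, and
ROC points. Choices:

* **AUC** by the midrank Mann–Whitney formula (ties get half credit);
  ROC from continuous scores, never from thresholded labels.
* **CIs** by cluster bootstrap: subjects are resampled with replacement
  (1000 draws, percentile interval). Epochs within a subject are strongly
  dependent, so epoch-level binomial intervals would be far too narrow;
  with 9 validation clusters the subject bootstrap is the defensible
  default. Draws on which a metric is undefined are dropped from that
  metric's interval (the generic `bootstrap_ci()` instead redraws, with a
  capped retry budget).
* **Degenerate ratios** (zero denominators, e.g. an all-negative
  predictor) are reported as 0 and flagged, the standard MCC convention.
* **Leakage guard**: the evaluator refuses to score any model whose
  recorded training subjects, or whose normalization's fitting subjects,
  intersect the validation group.

How 5-fold CV on the derivation group relates to the holdout table is
left open by the original description; here the holdout evaluation of the
frozen models is the headline result and CV is reported alongside when
`run_cv = TRUE`.

## Reproducibility and problem sizes

A single master seed drives everything: per-subject seeds, the NCA and
training subsamples, stochastic fits and the bootstrap are all derived
from it, and two runs with the same configuration write byte-identical
feature tables, selection JSON and evaluation reports. Every artifact
embeds the configuration's MD5 hash and the package version.

The test suite exercises the full default cohort (30 subjects, 89,550
retained epochs) once for the end-to-end planted-signal and trend checks,
plus a signal-free negative control of the same size; unit tests run on
small purpose-built fixtures (4-subject short-protocol cohorts,
200-sample planted selection problems, 20 × 4 finite-difference
instances). These sizes are the package's chosen test conditions: large
enough that bin means and holdout AUCs are stable, small enough to keep
the suite pleasant to run.

## Known limitations

* The generative model is stationary within an ICP bin; real EEG drifts,
  and real effect sizes need not match the planted ones. End-to-end
  numbers on synthetic cohorts characterize the *pipeline*, not porcine
  physiology.
* The exact formulas behind the reported `DELTAR`/`DTABR`/"magnitude"
  indices are not public; ours are declared, directionally validated
  choices.
* Single channel only; no artefact rejection beyond the band-pass.
* The NCA subsample bounds the fit at $O(\text{subsample}^2)$; with very
  many features the `KM` precompute (n² × d doubles) dominates memory.
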