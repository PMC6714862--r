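---
title: "Cross-subject EEG emotion recognition with stsbssvm: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-subject EEG emotion recognition with stsbssvm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stsbssvm)
```

## The problem

Classifying positive versus negative emotional valence from scalp EEG is
substantially harder when the classifier must generalize to *subjects it has
never seen*: inter-individual differences in skull geometry, electrode
impedance and idiosyncratic cortical dynamics shift every feature's
distribution from one person to the next. `stsbssvm` implements a
filter-plus-wrapper approach to this cross-subject setting: a large bank of
per-channel descriptors is screened by a two-sample significance test, the
survivors are pruned by SVM-wrapped sequential backward selection, and
everything is evaluated under leave-one-subject-out (LOSO)
cross-validation, where each fold holds out *all* trials of one subject.

## The feature bank

For every trial and channel, ten descriptors are computed, giving a
`trials x (channels x 10)` matrix:

* **Hjorth activity** — the population variance of the signal,
  `m0 = mean((x - mean(x))^2)`.
* **Hjorth mobility** — `sqrt(var(diff(x)) / var(x))`, a normalized measure
  of mean frequency.
* **Hjorth complexity** — the mobility of the first difference divided by
  the mobility of the signal; 1 for a pure sinusoid, above 1 for broadband
  activity.
* **Standard deviation** — population convention (denominator `n`),
  configurable to `n - 1`.
* **Band power in theta (3–7 Hz), alpha (8–13 Hz), beta (14–29 Hz) and
  gamma (30–47 Hz)** — each measured on the correspondingly band-pass
  filtered signal (4th-order Butterworth applied forward–backward, so zero
  phase), as the mean of a Welch power-spectral-density estimate over that
  band's bins.
* **Sample entropy** — `-ln(A/B)` with `B` the number of template pairs of
  length `m = 2` within Chebyshev tolerance `r = 0.2 * sd(x)` and `A` the
  same count at length `m + 1`, self-matches excluded.
* **Wavelet entropy** — the Shannon entropy `-sum(p_j * ln(p_j))` of the
  relative energies `p_j` of a 4-level `db4` discrete wavelet decomposition
  (five components: the deepest approximation plus four detail levels).

Band powers are the only features computed on band-filtered signals; the
remaining six descriptors use the broadband signal as supplied (the
assumption is that inputs are already artifact-cleaned; no EOG/EMG removal
or re-referencing is attempted here). This broadband choice is
configurable through the `config` argument of `assemble_feature_matrix()`.

### Numerical choices

* **Filtering:** 4th-order Butterworth + `filtfilt`. Zero phase matters
  because band power is measured on the filtered samples directly.
* **Welch estimator:** 2-s Hann segments at 50% overlap, mean-detrended,
  one-sided density scaling. The 0.5 Hz resolution resolves the narrow
  theta band comfortably on 60-s trials; segments are configurable.
* **Sample entropy caps:** a constant channel returns 0; if no
  length-`m+1` pair matches (`A = 0`), the infinite value is capped at
  `log(B) + log(n)` so feature matrices stay finite. The counting kernel
  is exact `O(n^2)` template enumeration in C++ and is tested against an
  independent brute-force enumerator in R.
* **Wavelet boundary handling:** periodized decomposition (circular
  convolution), which keeps the energy partition clean and the transform
  orthogonal; odd-length intermediate vectors are extended by repeating
  the final sample. The filter bank matches the standard Daubechies
  coefficients; `db1`, `db2` and `db4` are built in.
* **Degenerate inputs:** an all-zero signal has no energy distribution, so
  wavelet entropy raises by default; inside matrix assembly the uniform
  distribution (maximum entropy) is substituted instead, which is the
  sensible "no structure" value and keeps the no-NaN invariant.

## The selection and classification stages

**Significance-test (ST) filter.** Each feature column is split into its
positive-label and negative-label halves. One test is chosen for *all*
columns by a majority normality vote: every column-half is checked with
Shapiro–Wilk (deterministically thinned to at most 500 values, which keeps
the test inside its valid sample range), and if more than half of all
halves are compatible with normality, a pooled-variance two-sample t-test
is used; otherwise — including an exact tie — the two-sample
Kolmogorov–Smirnov test. Columns with `p < alpha` (default 0.05) survive.
No multiple-testing correction is applied by default — the stage is a
deliberately permissive screen in front of a wrapper, not an inferential
procedure — but `p_adjust` accepts any `stats::p.adjust` method.

**Sequential backward selection (SBS).** From the surviving set, the
single feature whose removal maximizes an evaluator accuracy is dropped,
repeatedly, down to one feature; the best-scoring visited subset wins.
Ties are resolved deterministically: among equal removals the
largest-index column is dropped, and among equally accurate subset sizes
the larger subset is kept (retaining more information). The evaluator
inside a fit is grouped cross-validation *by subject* over the training
subjects (5 folds, round-robin over the sorted subject list — again
deterministic), with an RBF-kernel SVM. Greedy SBS on `p` columns costs at
most `p(p+1)/2 - 1` candidate evaluations, the property that makes it
tractable where exhaustive search is not; the filter stage in front is
what makes `p` small enough for the wrapper to be affordable at all.

**Classifier.** `e1071::svm` (libsvm) with the radial basis kernel,
`C = 1`, and `gamma = 1/(n_features * var(x))`. Inputs are z-scored per
column with statistics learned from training rows only; zero-variance
columns are centered and left unscaled. KNN (`k = 5`), random forest
(100 trees) and PCA variants (components up to 95% cumulative variance)
are provided as baselines under the identical LOSO folds.

**Leakage policy.** By default every stage — normalization, ST filter,
SBS, classifier — is fitted inside each LOSO training fold, so the
held-out subject cannot influence any of them; the test suite asserts
this by garbling a held-out subject's rows and checking the fold's model
is unchanged. The original formulation applies the significance filter
once to the full matrix before cross-validation; that global-filter
variant is available as `paper_faithful = TRUE` and is kept strictly for
reproduction, since it lets test-subject data into the screening step.

## The synthetic generator

Licensed EEG corpora cannot ship with a package, so `generate_trialset()`
emulates the two benchmark layouts — 32 subjects x 40 trials x 32 channels
at 128 Hz with continuous 1–9 valence ratings, and 15 subjects x 3
sessions x 15 trials x 62 channels at 200 Hz with
positive/neutral/negative labels (5 each per session) — with a transparent
ground truth:

* each channel is `1/f^beta` background noise (default `beta = 1`,
  unit standard deviation) plus one unit-amplitude oscillator per rhythm
  at a random frequency inside the band;
* positive-class trials multiply the chosen band's amplitude by
  `effect_size` on the discriminative channels;
* each subject carries a persistent multiplicative gain
  `1 + N(0, subject_sd)`, the cross-subject nuisance the method exists to
  survive;
* continuous ratings are drawn from Uniform(6, 9) for positive and
  Uniform(1, 4) for negative trials, deliberately avoiding the boundary
  score of 5.

What this emulates is the *statistical* shape of the problem — planted
band-specific class effects, subject-level amplitude nuisance, power-law
background. What it does not emulate: volume conduction and channel
correlation, non-stationarity within a trial, artifacts, or realistic
rating noise (real ratings sit on both sides of 5 for the same stimulus).
Passing tests on this generator therefore demonstrates that the pipeline
recovers planted structure through subject-level nuisance — not that any
particular accuracy is attainable on real recordings.

`generate_feature_table()` bypasses the signal level entirely (Gaussian
features, mean-shifted informative columns, per-subject intercepts) and is
used where only the selection/classification machinery is under test.

## Label handling

Continuous ratings above 5 are positive (1), below 5 negative (0). A
rating exactly at 5 belongs to neither stated class; such trials are
dropped by default (`equal = "drop"`), with `equal = "negative"` available
for pipelines that must keep every trial. Categorical recordings keep only
positive and negative trials; with the 15 x 3 x 15 layout that leaves
`15 x 3 x 10 = 450` trials. For categorical layouts a 60-s window centered
in each trial (`floor` start, half-open in 0-based sample coordinates) is
taken first, matching the one-minute trials of the continuous-valence
layout.

## Problem sizes in tests and the acceptance script

Feature-matrix shapes are duration-independent (ten features per channel
regardless of trial length), so the shape checks run the full trial
*counts* at reduced trial durations — 4-s trials for the 1280 x 320
layout, 8-s trials windowed to 4 s for the 450 x 620 layout — which keeps
a complete end-to-end run at roughly 10<sup>4</sup> channel-trials, a few
minutes on one core. Statistical checks use layouts between 4 and 10
subjects with 10–20 trials each; the null-retention check uses 2000 null
columns, giving a 99% binomial band of about [75, 125] retained at
`alpha = 0.05`. These sizes are the package's own desk-scale choices and
are stated here so results are interpreted at the scale that produced
them.

## A worked example

```{r example, eval = FALSE}
desc <- new_descriptor(n_subjects = 6, trials_per_subject_session = 12,
                       n_sessions = 1, n_channels = 4, fs_hz = 128,
                       trial_duration_s = 6,
                       rating_kind = "continuous_valence")
eff <- effect_spec(discriminative_channels = 1:2, band = "alpha",
                   effect_size = 3, subject_sd = 0.1, seed = 11)
gen <- generate_trialset(desc, eff)
fm  <- assemble_feature_matrix(gen$trialset)
fit <- st_sbssvm(fm)
summary(fit)
loso_evaluate(fm, "st_sbssvm")
```

## Known limitations

* The significance filter's retained counts on the real benchmark
  recordings (68 and 227 columns) depend on those licensed datasets and on
  unstated test conventions; they are documented, not reproduced.
* SBS cost grows quadratically in the retained column count; with a weak
  filter stage (large `alpha`, strong effects everywhere) the wrapper can
  dominate runtime, which is precisely the regime the filter exists to
  avoid.
* The pooled-variance t-test is the default because the method names the
  Student form; the Welch variant (`var_equal = FALSE`) is usually the
  safer choice when class variances differ.
* `read_edf()` is a minimal parser for uncompressed EDF with a common
  sampling rate across channels; EDF+ annotations and variable-rate
  signals are out of scope.
* HDF5 is not among the package's I/O backends; the trial container is a
  CSV directory with a JSON sidecar, which round-trips bit-exactly and
  stays human-inspectable.
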