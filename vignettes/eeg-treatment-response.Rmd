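---
title: "Predicting SSRI treatment response from resting-state EEG: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting SSRI treatment response from resting-state EEG: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegresp)
```

## The problem

About half of patients with major depressive disorder (MDD) do not respond
to the first selective serotonin reuptake inhibitor (SSRI) they are
prescribed, and each failed trial costs weeks. A long-standing idea in
clinical neurophysiology is that the *pre-treatment* resting EEG already
carries a signature of who will respond. This package implements, as a
fully tested analysis pipeline, one concrete version of that idea:

1. record 19-channel 10–20 resting EEG (eyes closed and eyes open) before
   treatment;
2. decompose each channel with the discrete wavelet transform (Daubechies
   db4) and keep the delta- and theta-band coefficient blocks as features
   (with short-time Fourier and empirical-mode-decomposition features as
   comparators);
3. z-score every feature against a healthy-control reference;
4. rank features by the area between their empirical ROC curve and the
   chance diagonal, prune correlated survivors, and keep a small top-k
   subset;
5. classify responders (R) versus non-responders (NR) — defined by a ≥50%
   improvement in pre- vs post-treatment BDI-II score — with logistic
   regression under 100 repetitions of stratified 10-fold
   cross-validation;
6. localize the group differences with per-channel Wilcoxon rank-sum
   topographies and visualize the reduced feature space with PCA.

No patient EEG is distributed with studies of this kind, so the package
ships a synthetic-cohort generator with a *known planted* group structure.
Every stage of the pipeline is validated against that ground truth, against
closed-form oracles, and against a fully worked ranking example.

## The synthetic cohort generator

`cohort_spec()` / `generate_cohort()` simulate a study of 34 patients
(16 R / 18 NR, sexes balanced within group) and 30 controls: per subject
one eyes-closed and one eyes-open recording, 19 channels at 256 samples/s,
five minutes per condition by default.

Each channel is a sum of band-limited components (delta 0.5–4, theta
4–8.5, alpha 8.5–17.5, beta 17.5–35, gamma 35–70 Hz — the dyadic band
edges the wavelet analysis lands on), a 1/f broadband background, and
optional eye-blink and 50 Hz artifacts (off by default: the generator
emulates artifact-corrected data). Band components are synthesized in the
frequency domain (brick-wall band-limited Gaussian noise), so per-band
power is analytically exact and checkable with Welch's method. Eyes-closed
recordings double the alpha amplitude relative to eyes-open, reproducing
the classical alpha blocking contrast. Simulated pre/post questionnaire
scores are drawn from group-conditional normals matching the clinical
summary being emulated, with rejection sampling so the 50% rule
(`label_response()`) reproduces the planted label exactly.

### How the group contrast is planted — and why

The responder/non-responder contrast is a standardized difference
(`effect_size`, Cohen's *d*, default 1.5) in delta/theta **log band
power** at three frontal/temporal channels (F7, F8, T4 by default),
against a between-subject log-power SD of 0.8 natural-log units — a
realistic magnitude of inter-individual EEG power variability.

One design point deserves honesty. The classifier's features are *raw
wavelet coefficients*, and the ROC/Mann–Whitney ranking detects
**location** differences between groups. A band-power difference realized
purely as random-phase oscillation is a *scale* difference at the
coefficient level — zero-mean in both groups — and is mathematically
invisible to a rank test (AUC = ½ exactly). For the planted structure to
be recoverable by the method under study, a fraction of each band's power
(`signature_fraction`, default 0.7) is carried by a fixed-phase
band-limited "signature" waveform shared across subjects and scaled by
each subject's amplitude; the group amplitude difference then shifts
coefficient locations. Both parameters were fixed once, from an a-priori
coefficient-level sizing analysis, before any end-to-end run.

By default patients and controls are drawn from the same spectral
population (`patient_shift = 0`): the responder contrast lives *within*
the patient group, and the diagnosis task (MDD vs controls) has nothing
to find. Setting `patient_shift` plants an additional delta/theta
log-power offset of all patients relative to controls at the effect
channels, making the diagnosis classification meaningful when a study
design calls for it.

Consequently the recovery and classification tests validate the
*machinery* — ranking, pruning, train/test isolation, fold bookkeeping,
statistics — under a structure the method can in principle detect. They do
**not** show that real resting EEG contains phase-locked signatures, nor
do they reproduce the clinical accuracy figures of any real cohort; those
depend on data that is not deposited. The generator also makes no attempt
at volume conduction or realistic depressive electrophysiology beyond the
planted contrasts (a declared non-goal).

## Preprocessing

`filter_recording()` applies a zero-phase (forward–backward) chain: 2nd
order Butterworth high-pass at 0.1 Hz cascaded with a 2nd order low-pass
at 70 Hz (a numerically safer realization of a 4th-order band-pass when
the low edge sits three decades below Nyquist) plus an RBJ biquad notch at
50 Hz (Q = 30). Channel means are removed first: the 0.1 Hz high-pass has
a multi-second time constant and forward–backward filtering alone leaves
visible DC leakage at the record edges.

Re-referencing uses the common average (`rereference_average()`). A
model-based infinity reference needs a head model the pipeline does not
have; the literature treats the two as comparably efficient for this use,
and the original linked-ear reference can be kept with
`reference = "as-recorded"`.

`extract_epoch()` uses 0-based half-open `[start, end)` windows; the
default analysis epoch is the first 120 s of the cleaned record (which
2-minute window the original design used is unstated; the first window is
the deterministic choice).

`resample_recording()` resamples in the Fourier domain — exact for
signals already band-limited below the target Nyquist, which 0.1–70 Hz
filtered EEG at a 140 Hz target is. The target 140 Hz is chosen so the
dyadic wavelet bands land exactly on the band table's printed edges:
140/2⁵ = 4.375 ≈ "4" Hz, 140/2⁴ = 8.75 ≈ "8.5" Hz, then 17.5, 35, 70.

## Feature families

**Wavelet (primary).** `dwt_decompose()` implements the db4 filter bank
with symmetric (half-point) boundary extension; block lengths follow
`len_k = floor((len_{k-1} − 1)/2) + 4`, the convention of the standard
`wavedec` tooling, and single-level coefficients are frozen in the tests
against an independent reference implementation. Depth 4 at 140 Hz yields
the five canonical blocks A4 (delta), D4 (theta), D3, D2, D1; the
band map is frequency-driven, so 70 Hz at depth 3 produces the identical
delta/theta edges (used by the reduced Monte-Carlo studies). Features are
the raw delta- and theta-block coefficients per channel
(alpha/beta/gamma blocks are discarded); the inverse transform
reconstructs inputs to < 1e−8 relative RMS.

**STFT.** `stft_features()`: Hamming window, 2 s length, 0.5 s hop, 4096
FFT points at the native 256 samples/s, reduced to log band power per
frame in delta and theta. The source material states both "0.5 s hop" and
"50% overlap"; the hop value is the more specific statement and is
adopted (overlap is configurable). A 120 s signal yields
`floor((120−2)/0.5)+1 = 237` frames.

**EMD.** `emd_sift()` is classical envelope sifting: strict local
extrema, cubic-spline upper/lower envelopes with mirrored-extrema end
conditions, envelope-mean subtraction, acceptance when the two IMF
conditions hold (extrema/zero-crossing counts within one; envelope mean
near zero) and the normalized squared-difference criterion falls below
0.2, with a 40 dB residual-energy stop for the outer loop — without the
energy stop, negligible spurious trailing modes appear. IMFs plus residue
reconstruct the input to < 1e−6 relative RMS by construction.
`emd_features()` selects IMFs whose Welch-dominant frequency falls in
delta/theta. Because the IMF count varies across recordings, the
cohort-level EMD feature vector is defined as the per-channel *sum* of
the selected IMFs (the delta/theta reconstruction), which has fixed
length — the package's resolution of an open point in the source
description.

**Spectra and connectivity.** `welch_psd()` is the Hamming-windowed, 50%
overlap averaged periodogram scaled so the density integrates to the
variance; `coherence()` forms the magnitude-squared coherence
`|S_xy|²/(S_x S_y)` on a 1 Hz grid over 2–30 Hz, bounded in [0, 1], with
at least two averaging segments required (one segment gives the
identically-1 artifact and is an error). `p300_extract()` averages
baseline-corrected Target-locked epochs and reads the P300 as the
positive maximum in 300–700 ms.

## Standardization and feature selection

`fit_reference()` computes per-feature means and SDs (n−1) over the
healthy-control instances; `standardize()` replaces every patient value
by `z = (x − μ)/σ`. Zero-variance reference features are dropped with a
warning.

`auc_rank()` is the core ranking statistic: sort instances by descending
feature value (stable, ties by original index), accumulate cumulative
true/false-positive rates, and take the trapezoid area minus the chance
area ½. Runs of tied values are collapsed to a single ROC step, making
the result *exactly* the Mann–Whitney AUC − ½ with half credit for ties —
an equivalence the tests verify against exhaustive pair counting on a
thousand random instances, and which also gives invariance to monotone
transforms and antisymmetry under negation. The ranking key is |auc|
(range [0, 0.5], the per-feature "z-value"); the signed value and the
full worked-example trace (tp, fp, Y, X vectors) are preserved. A
vectorized single-radix-sort implementation handles the tens of
thousands of columns inside cross-validation folds and is asserted equal
to the reference route.

`prune_correlated()` walks the ranking top-down and keeps a feature only
if |Pearson r| < 0.9 with everything already kept (the threshold is not
stated in the source; 0.9 is the package default, configurable, and the
greedy top-down order makes pruning deterministic). `mrmr_select()`
provides the comparator selector: 3 equal-frequency bins, plug-in mutual
information, greedy maximum-relevance-minus-mean-redundancy (MID).

## Classification and validation

`fit_logistic()` fits `F(z) = 1/(1+e^{−z})`, `z = α + Σ β_k X_k` by IRLS
with a tiny ridge (λ = 1e−6, never on the intercept) purely as a guard
against divergence under linear separability — common with 60-odd
instances and strongly selected features; on well-conditioned data it
agrees with `glm()` to four decimals (tested). Predicted label is
positive iff `F(z)` strictly exceeds 0.5.

`cross_validate()` runs the whole experiment: per repeat a fresh
stratified fold assignment (by default at the *subject* level, so a
subject's EC and EO instances can never straddle the train/test split —
row-level assignment is available for fidelity to the original
68-instance scheme); per fold, standardization, ranking, pruning and
subset choice are computed from the training instances only and reused
unchanged on the test fold (a property the tests enforce by corrupting
test rows and checking the selection is unmoved). Confusion counts are
pooled per repeat; sensitivity, specificity, accuracy and F-measure are
reported as mean ± SD over 100 repeats. Whether standardization inside
CV should be per-fold or use a fixed external control reference is
ambiguous in the source; per-training-fold is the default and both are
available (`scope=`). `subset_sweep()` repeats the experiment over the
canonical subset sizes 1, 2, 3, 4, 5, 10, 15, 20, 25, 30, 35, 50, and
`combine_features()` concatenates the per-method top-15 lists
(15 + 15 + 15 = 45 columns).

## Topographies and PCA

`ks_normality()` gates the statistics: a one-sample Kolmogorov–Smirnov
test of the (already standardized) features against N(0, 1) at 5% — its
rejections motivate the non-parametric test. `wilcoxon_channel_map()`
pools each channel's selected delta/theta features per instance (mean of
standardized values; per-feature best-p is available), runs a two-sided
rank-sum test R vs NR, and records H ∈ {0, 1} at the 5% level with no
multiple-testing correction across the 19 channels — matching
per-location 5% maps (a Benjamini–Hochberg option exists, off by
default). Channels absent from the top-15 subset are covered by
extending the ranking to the top 100. Maps are computed pooled and
stratified by sex, per condition. `interpolate_topomap()` renders the
binary map by two-nearest-electrode inverse-distance interpolation on a
schematic head disc (exact at electrode positions). `pca_scatter()` is
linear PCA of the reduced top-15 matrix — the source's own
implementation note names a plain principal-components routine, so no
kernelization is reproduced — returning the first two score columns and
variance-explained fractions.

## Numerical choices and degenerate inputs

* Filter instability (band edge at/above Nyquist) is a configuration
  error, not a warning.
* Constant features: dropped (reference fitting, with warning), pass-through
  as zeros (in-fold standardization), trivially rejected (KS gate).
* Empty confusion denominators yield `NA` ("undefined"), never 0.
* Tied feature values: stable sort by original index in the trace;
  half-credit in the statistic.
* `F(z) = 0.5` classifies negative (strict threshold inequality).
* All randomness flows from explicit seeds; a fixed seed makes cohorts
  and whole pipeline runs byte-identical.

## Problem sizes used by the validation suites

The Monte-Carlo suites run on size-reduced versions of the study: 10 s
recordings at 72 samples/s with the delta–beta band set, analyzed at the
70 Hz dyadic rate (depth 3 — the same delta/theta edges as 140 Hz at
depth 4). Per-coefficient discriminability does not depend on recording
length or rate, so the planted-contrast conditions (d = 1.5 at F7/F8/T4,
34 patients, 16/18 split, 100 replicate cohorts, 100×10-fold CV) are
preserved exactly while each replicate stays near two seconds of
compute. The `analysis/` scripts use fuller sizes (60 s at 256 samples/s
with the complete band set) to exercise the full-rate path end to end.

## Known limitations

* The planted signature waveform is a validation device, not
  electrophysiology; see above.
* Average reference instead of a model-based infinity reference; no ICA
  or regression-based ocular correction (a simple amplitude-threshold
  epoch rejector is provided, off by default).
* The EMD feature definition at cohort level is one defensible reading of
  an under-specified step.
* Clinical accuracy figures from real cohorts are out of reach by
  construction and are not asserted anywhere in this package.
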