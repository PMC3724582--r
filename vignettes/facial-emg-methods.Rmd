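---
title: "Methods: facial-EMG gesture recognition with elliptic basis function networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: facial-EMG gesture recognition with elliptic basis function networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facialemg)
```

## The problem

Surface electromyograms (sEMG) recorded over facial muscles can serve as a
control channel for human–machine interfaces: a user holds one of ten facial
gestures (mouth opening, jaw clenching, brow raising, eye closures, frowning,
three smile variants), and the system must recognize which gesture is active
from three bipolar recording channels (left temporalis, frontalis, right
temporalis). Facial EMG spectra are too similar across gestures for
frequency-domain analysis to discriminate them, so the pipeline works
entirely with time-domain amplitude statistics, and the classifier is chosen
for speed: an elliptic basis function network that learns in a single pass
over the training data.

The package implements the complete pipeline — synthetic signal generation,
band-pass filtering, windowing, feature extraction, mutual-information-based
and accuracy-based feature ranking, one-epoch classification, and evaluation
reporting — as testable, seeded components.

## Synthetic signal model

No public facial-EMG corpus matches this acquisition protocol, so the
package ships a generator that emulates it: 10 gestures × 5 trials × 2 s of
active signal per trial, 3 channels, 1000 Hz. Each channel of a trial is

* white Gaussian noise, band-pass filtered to 30–450 Hz,
* rescaled to unit RMS and multiplied by `amplitude[channel] × envelope(t)`,
* plus independent Gaussian sensor noise (`noise_floor`, default 0.05 a.u.).

This is the standard engineering model of a non-fatiguing sEMG contraction:
an amplitude-modulated band-limited Gaussian process. Gesture identity is
carried *entirely* by the 3-channel amplitude signature, because the
discriminative time-domain features (MPV, MAV, RMS, IEMG, SSI) are amplitude
statistics. The default signatures place higher amplitude on the muscles
anatomically involved in each gesture and keep absolute units arbitrary (no
calibration exists for facial muscles; only ratios matter after min-max
normalization).

Two deliberate structural choices:

* **Envelope.** The default envelope is constant: the protocol analyses only
  the *active* portion of each trial, i.e. a sustained contraction. A
  trapezoid envelope (10% onset/offset ramps) is available for sensitivity
  checks.
* **Confusable pair.** Mouth opening (G1) and bilateral smiling (G8) share a
  signalling source, so their signatures are deliberately similar. The
  `class_separation` parameter scales every gesture's contrast around the
  per-channel grand mean, but the G1–G8 contrast is shrunk back by
  `1/class_separation`, so increasing separation spreads all other pairs
  while G1/G8 remain the closest pair — the confusion structure concentrates
  there, as it should.

What the generator does *not* emulate: motor-unit action potentials and
recruitment, fatigue, electrode lift and motion artifacts, inter-trial
electrode migration, cross-talk between channels. Consequences for
interpretation are discussed under *Limitations*.

Determinism: every sample is a pure function of
`(seed, subject, gesture, trial, channel)` via a small integer stream-hash,
so datasets are bit-reproducible and independent of evaluation order. The
generator saves and restores the caller's RNG state.

## Preprocessing

* **Band-pass 30–450 Hz**, 4th-order Butterworth applied forward–backward
  (`signal::filtfilt`). The band is the standard sEMG envelope; the filter
  realization is our choice — zero phase matters because all features are
  amplitude statistics, and the forward–backward pass squares the magnitude
  response (≈ 8th-order roll-off), putting >95% of the filtered noise power
  inside the band. Filtering runs **per trial**, before trials are
  concatenated, so no splicing discontinuity passes through the filter.
* **Windowing.** The five filtered 2-s actives of a gesture are concatenated
  per channel (10 s = 10,000 samples) and cut into non-overlapping 256-ms
  windows; the incomplete tail is discarded, giving
  `floor(10000/256) = 39` windows per gesture per channel. Window length in
  samples is `round(window_ms × fs / 1000)`.

## Time-domain features

Nine per-window statistics (MAV, RMS, VAR, WL, IEMG, SSC, MV, SSI, MPV) are
evaluated exactly as printed in the sEMG literature — see the table in
`?feature_value`. Three conventions deserve a note:

* **VAR** uses the population form (1/N), not 1/(N−1).
* **SSC** counts *thresholded local maxima only*: interior samples with
  `x[i] > x[i-1]`, `x[i] > x[i+1]` and `x[i] − x[i+1] ≥ ε` (ε = 0.02 EMG
  units by default). The conventional two-sided rule (minima as well) is
  available via `feature_config(ssc_both_extrema = TRUE)` but is off by
  default, matching the one-sided definition this pipeline standardizes on.
* **MAVS** is the first difference of MAV across adjacent windows; 39 MAVs
  give only 38 differences, so the final element is padded (default zero,
  optionally replicate) to preserve the 39-per-gesture count. The padding
  policy is our construction; it affects one row in 39.

A per-subject single-feature set is a 390 × 3 matrix (10 gestures × 39
windows, one column per channel). A k-feature combination concatenates the
first k ranked single-feature sets channel-major, giving 3k columns — e.g.
`[mpv_ch1, mpv_ch2, mpv_ch3, mav_ch1, mav_ch2, mav_ch3]` for k = 2.

## Mutual information and feature ranking

MI is estimated with an equal-width histogram (default 10 bins per variable,
exposed in the configuration), the simplest reproducible estimator:

* The **displayed MI matrix** uses *normalized* MI, `MI/sqrt(H(A)H(B))`, so
  a feature has MI 1 with itself and strongly redundant pairs approach 1.
* **Inside mRMR** *raw* MI (bits) is used — the canonical Peng formulation.
* Class relevance treats the gesture label as categorical (no binning).
* Channels are concatenated (not averaged) into one vector per feature
  before MI; a per-channel average would hide channel-specific dependence.

Caveat on the estimator: equal-width binning is not invariant under
nonlinear monotone transforms, so normalized MI of a feature with a
nonlinearly rescaled copy of itself is high but below 1 (affine rescalings
give exactly 1). The histogram estimator's positive bias on independent data
is about `(bins−1)²/(2N ln 4)` bits, well below 0.01 at the n ≈ 10⁴ sizes
used here.

**mRMR ranking** is the greedy incremental procedure: the first feature
maximizes relevance `MI(f;C)`; each next feature maximizes
`MI(f;C) − mean(MI(f;s), s ∈ selected)`. The set-level maximization of
relevance-minus-redundancy is combinatorial; the greedy chain is the
canonical published surrogate, and every step is re-checked against
brute-force maximization in the tests. Per prefix the set-level relevance
`D`, redundancy `R` (diagonal included) and `D − R` are reported. Ties break
alphabetically, making the ranking deterministic. **RA ranking** simply
sorts features by their individual mean test accuracy, ties alphabetical.

## The VEBF classifier

A hidden unit is a hyperellipsoid `Ω = (C, S, N, A, d)`: center `C`,
covariance `S` of the samples it absorbed, count `N`, per-axis widths `A`,
class `d`. Its axes are the eigenvectors of `S` (descending eigenvalues,
each vector's sign fixed so its largest component is positive), so the unit
*rotates* to cover nearby data without moving or growing. The activation

$$\psi(x) = \sum_i \frac{((x - C)^\top u_i)^2}{a_i^2} - 1$$

is ≤ 0 iff `x` lies inside the ellipsoid.

**One-epoch training.** Samples stream through once, in order:

1. Widths start as a sphere, `A₀ = (0.5, …, 0.5)` — meaningful because the
   pipeline min-max normalizes every dimension to `[0, 1]` on training-set
   extrema (test values are *not* clipped). The scaling step is our
   addition; a fixed 0.5 radius presumes a bounded input scale.
2. If no neuron of the sample's class exists, a new one is created at the
   sample (`C = x`, `S = 0`, `N = 1`, `A = A₀`).
3. Otherwise the nearest same-class neuron (Euclidean center distance, ties
   to the earliest-created) is *tentatively* updated: recursive mean
   `μ_new = n μ_old/(n+1) + x/(n+1)` and the matching recursive covariance
   update, which reproduce the batch mean and population covariance of all
   absorbed samples exactly (to machine precision; verified against batch
   oracles). The eigenbasis is refreshed from the updated covariance.
4. If the updated neuron covers the sample (ψ ≤ 0) the update is committed;
   otherwise it is discarded and a fresh neuron is created at the sample.
5. After each insertion, same-class neurons whose center distance is at most
   `merge_gamma × (mean(A_i) + mean(A_j))` are merged by pooling their
   sufficient statistics (count-weighted mean; pooled population
   covariance), widths reset to `A₀`, basis recomputed; merging repeats
   until no pair qualifies. The merge gate and pooled-moment formulas are
   our concretization — the procedure is the natural one given that each
   neuron carries exact batch moments.

Widths stay at `A₀` throughout: coverage adapts through rotation only. With
the default spherical `A₀` the rotation is inert at *prediction* time (a
sphere is rotation-invariant), but the covariance still drives the coverage
decision history and the serialized model, and non-uniform widths activate
the rotation fully.

**Prediction** assigns the class of the neuron minimizing ψ(x) (ties:
earliest-created). ψ is the network's only scoring quantity, making min-ψ
the natural decision rule; a nearest-center rule is available via
`predict(..., rule = "nearest_center")` for sensitivity checks. Training is
deterministic — no random initialization exists — and each sample is
consumed exactly once (an `on_consume` hook lets tests assert this).

## Splits, evaluation and reports

Each 390-row feature set is shuffled with a derived seed and split 300/90.
The split is **stratified** by default (30 train / 9 test per gesture):
plain shuffling can leave a class without training rows, which a per-class
neuron model cannot tolerate; `stratified = FALSE` reproduces the plain
shuffle. Stratification uses largest-remainder allocation, ties by class
order, so it is deterministic given the seed.

Reports carry train and test accuracy (%), per-gesture accuracy, a
row-stochastic confusion matrix (each true-class row sums to 100), training
time (informational only — hardware dependent, excluded from determinism
contracts), and a mean absolute error defined as `100 − test accuracy`
(inferred definition; it is the arithmetic complement of mean accuracy, not
a per-sample regression error). Subject-averaged reports average accuracies
and confusion matrices; on balanced test sets the gesture-averaged accuracy
equals the overall accuracy up to rounding.

`run_experiment()` wires everything together: per subject — generate,
filter, extract all features; per feature — split, normalize, train,
evaluate; then RA and mRMR rankings, then the C2…C10 combinations prescribed
by each ranking. The bundle is a pure function of the configuration apart
from timing fields, and `report_json()` serializes it with timing stripped,
so identical configurations give byte-identical reports.

## Numerical choices

* Covariance symmetry is enforced (`(S + Sᵀ)/2`) before eigendecomposition;
  asymmetry beyond 1e−8 is an error. A zero covariance returns the standard
  basis with zero eigenvalues (for rank-deficient but nonzero matrices,
  LAPACK's symmetric solver already returns a complete orthonormal basis).
* Eigenvector sign is fixed (largest-magnitude component positive) so
  serialized models are reproducible.
* Equal-width binning maps each value by
  `floor((v − min)/range × bins) + 1`, top edge clamped into the last bin; a
  constant vector occupies a single bin, and normalized MI with a constant
  (zero-entropy) vector returns 1 for a self-pair and 0 otherwise, with a
  warning.
* Constant training columns min-max-normalize to 0 everywhere, with a
  warning.
* All tie-breaks (nearest neuron, min-ψ, mRMR, RA, stratified remainders)
  are deterministic and documented above.

## Problem sizes in the test and acceptance suites

The suites run the full study geometry where it is cheap (one synthetic
subject = 390 × 3 features in a few seconds) and scale the rest to keep the
whole run fast: oracle equivalence uses 100 random streams (n ≤ 50, d = 3)
and 1000 random windows; the separability checks use ten 3-D Gaussian blobs
(30 train / 10 test per class, ≥ 6σ apart) and a 10-subject synthetic
experiment with `class_separation = 3` — well-separated signatures apart
from the exempted G1/G8 pair, which is where residual confusion shows up.

## Limitations

* Synthetic gestures differ *only* in amplitude signature. Features that
  measure amplitude (MPV, MAV, RMS, IEMG, SSI, VAR and — through its
  amplitude dependence at fixed spectrum — WL) separate them; features that
  measure waveform dynamics (MAVS under a constant envelope, SSC, MV after
  band-pass filtering) are uninformative *by construction* here, even where
  real facial EMG gives them discriminative power. Passing recovery tests
  therefore validates the pipeline mechanics and the classifier, not
  feature effectiveness rankings on real recordings.
* The histogram MI estimator is biased and bin-sensitive; rankings on small
  samples should be read qualitatively.
* The merge rule is one reasonable concretization; alternatives (e.g.
  eigenvalue-adaptive widths) exist and are deliberately out of scope.
* No artifact rejection, notch filtering, or rest-period handling: inputs
  are assumed to be clean active-signal segments.
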