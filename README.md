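# facialemg

Facial-gesture recognition from surface electromyograms (sEMG), built as a
fully seeded, testable R pipeline. The package is aimed at biomedical
signal-processing researchers and HMI (human–machine interface) developers
who want a reproducible reference implementation of the classic
time-domain-feature / fast-classifier recipe for facial EMG: three bipolar
channels (left temporalis, frontalis, right temporalis), ten gesture
classes, and a classifier fast enough for online use.

## What it implements

* **Synthetic facial EMG.** Each channel of a 2-s active trial is an
  amplitude-modulated, band-limited (30–450 Hz) Gaussian process plus sensor
  noise; gesture identity lives in a per-channel amplitude signature.
  10 gestures × 5 trials × 3 channels at 1000 Hz per subject,
  bit-reproducible from `(seed, subject, gesture, trial, channel)`.
* **Preprocessing.** Zero-phase 4th-order Butterworth band-pass (30–450 Hz)
  per trial; non-overlapping 256-ms windows on the concatenated 10-s active
  signal — `floor(10000/256) = 39` windows per gesture per channel.
* **Ten time-domain features** per window: MAV, MAVS, RMS, VAR, WL, IEMG,
  SSC, MV, SSI, MPV (exact printed formulas; population-form VAR;
  thresholded-peak SSC with ε = 0.02), giving a 390 × 3 per-subject set per
  feature and 3k-column combinations for k = 2…10.
* **Feature ranking.** Histogram mutual information (normalized for the MI
  matrix, raw inside mRMR), greedy minimum-redundancy-maximum-relevance

  ```
  D(A,C) = mean MI(f;C),  R(A) = mean MI(f;g) over f,g in A,  max (D − R)
  ```

  and recognition-accuracy (RA) ranking by individual test accuracy.
* **VEBF network.** One-epoch classifier whose hidden units are
  hyperellipsoids `Ω = (C, S, N, A, d)` with activation

  ```
  ψ(x) = Σ_i ((x − C)ᵀ u_i)² / a_i²  −  1        (ψ ≤ 0 ⇔ covered)
  ```

  where `{u_i}` is the eigenbasis of the neuron's covariance. Training
  streams each sample once: recursive mean/covariance update of the nearest
  same-class neuron, commit iff the updated neuron covers the sample,
  otherwise spawn a neuron at the sample; close same-class neurons merge by
  pooling sufficient statistics. Prediction takes the class of the
  ψ-minimizing neuron.
* **Evaluation.** Stratified seeded 300/90 splits, train-set min-max
  normalization, accuracy, per-gesture accuracy, row-stochastic confusion
  matrices, MAE (= 100 − test accuracy), training-time reporting, and a
  full experiment driver (`run_experiment()`) with deterministic JSON
  reports.

## Worked example

```r
library(facialemg)

cfg <- experiment_config(n_subjects = 3, features = c("MPV", "RMS", "MV"),
                         k_range = 2,
                         sim = emg_sim_config(class_separation = 3),
                         seed = 42)
bundle <- run_experiment(cfg)
bundle
#> <emg_report_bundle> 3 subjects, 3 single features, 2 combination set(s)
#>   MPV   test  95.9 +-  3.6 %  (MAE   4.1 %)
#>   RMS   test 100.0 +-  0.0 %  (MAE   0.0 %)
#>   MV    test  12.2 +-  1.1 %  (MAE  87.8 %)

bundle$rankings$RA
#> <emg_ranking> RA: RMS > MPV > MV
round(bundle$singles$MPV$averaged$confusion[c("G1", "G8"), c("G1", "G8")], 1)
#>      G1   G8
#> G1 96.3  3.7
#> G8 18.5 81.5
```

Reading the output: the amplitude features MPV and RMS recognize the ten
gestures almost perfectly on well-separated synthetic signatures, while MV
(the window mean, ~0 after band-pass filtering) is uninformative — its 12%
accuracy is near the 10% chance level. The confusion excerpt shows the
deliberately confusable pair: mouth opening (G1) and bilateral smiling (G8)
share a signalling source in the generator, and essentially all residual
error concentrates between them. The two-feature RA combination
(RMS + MPV) reaches 99.6% here.

Synthetic data can also be written/read as per-subject CSV
(`write_emg_dataset()` / `read_emg_dataset()`), and thin command-line
wrappers live in `inst/cli/` (`simulate.R`, `experiment.R`). The methods
vignette (`vignettes/facial-emg-methods.Rmd`) documents the signal model,
estimator choices and limitations.

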