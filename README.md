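# emgphasor

Gait phase recognition from multichannel surface electromyography (EMG) for
lower-limb myoelectric control: an R implementation of a **phasor
spatial-synergy feature extraction scheme** together with feature-space
quality metrics and a leave-one-trial-out evaluation harness, fully testable
end-to-end on a built-in synthetic gait EMG generator.

## Who this is for

Researchers and engineers working on myoelectric interfaces (prostheses,
exoskeletons, rehabilitation devices) who want shallow, embeddable
classifiers (LDA / SVM) to benefit from *spatial* muscle-synergy information
without training a synergy map by matrix factorization, and who need a
reproducible benchmark harness for comparing EMG feature sets.

## The method

Given `N` EMG channels (electrodes conceptually placed radially), channel
`k` (0-based) is assigned the complex-plane position `e^{j k 2π/N}`. For a
per-window, per-channel base feature `f_k` — here waveform length
`WL = Σ |x_{i+1} − x_i|` or root mean square `RMS = sqrt(mean x_i²)` — the
embedded vector is `f_k e^{j k 2π/N}`, and the spatial-synergy feature
vector **Df** collects the moduli of all pairwise differences:

    Df[(k,l)] = | f_k e^{j k 2π/N} − f_l e^{j l 2π/N} |
              = sqrt(f_k² + f_l² − 2 f_k f_l cos((k−l) 2π/N)),   k < l

giving `N(N−1)/2` values (36 for N = 9). Computing the same construction on
the first-differenced signals gives `∇Df`, and the **f-PHASOR** set is

    f-PHASOR = [ log(Df), log(Df / ∇Df) ]        (72 columns for N = 9)

with WL-PHASOR and RMS-PHASOR concatenated into the combined **PHASOR** set
(144 columns). Feature-space quality is assessed by the **separability
index** (SI: mean half-Mahalanobis distance between each class centroid and
its most conflicting class, under their averaged covariance — higher is
better) and the **mean semi-principal axis** (MSA: mean geometric mean of
each class's hyper-ellipsoid semi-axes from SVD — lower is better).
Classification is evaluated intra-subject by **five-fold leave-one-trial-out
(LOTO)** with diagonal-covariance LDA and RBF-kernel SVM, reporting accuracy
(ACC) and the multiclass Matthews correlation coefficient (MCC), which is
robust to the natural unbalance of gait-phase durations.

Comparators included: Hudgins time-domain (HTD), time-domain power spectral
descriptors (TDPSD), time-domain + AR (TDAR), Du, and minimal Rocket /
Mini-Rocket style random-convolutional-kernel transforms at 84 kernels.

## Worked example

Synthesize one subject's gait EMG (9 channels, 5 phases — heel strike, flat
foot, mid-stance, heel-off, toe-off — at 1920 Hz, 10 trials of 5 cycles,
strong synergy contrast), preprocess (zero-lag 4th-order Butterworth
10–400 Hz; 150/25 ms windows), extract features, and evaluate:

```r
library(emgphasor)
cfg  <- synth_config(synergy_gains = synergy_gain_matrix(contrast = 2),
                     n_cycles = 5, seed = 1)
recs <- generate_dataset(cfg, n_subjects = 1)
win  <- preprocess_trials(recs)
win
#> <window_set> S01: 1950 windows x 9 channels x 288 samples (150/25 ms)

fm <- phasor_combined_set(win)
quality_report(fm)
#> <quality_report> S01 [phasor]: SI = 6.529, MSA = 0.011 (K = 5, D = 144)
quality_report(htd_set(win))
#> <quality_report> S01 [htd]: SI = 3.793, MSA = 1.109 (K = 5, D = 36)

run_subject_eval(fm, eval_config("svm_rbf"))
#> <eval_result> S01 [phasor, svm_rbf]: ACC = 0.972 +/- 0.005, MCC = 0.964 +/- 0.006 (5 folds)
```

The PHASOR space separates the five phases much more strongly than HTD
(SI 6.5 vs 3.8) while being far more compact (MSA 0.011 vs 1.11), and the
held-out SVM recovers the phase labels almost perfectly on this
high-contrast synthetic subject. The pooled confusion matrix
(`res$confusion`, row-normalized) is dominated by its diagonal:

```
     pred
truth    0    1    2    3    4
    0 0.97 0.02 0.00 0.00 0.02
    1 0.02 0.96 0.02 0.00 0.00
    2 0.00 0.01 0.98 0.01 0.00
    3 0.00 0.00 0.02 0.97 0.01
    4 0.02 0.00 0.00 0.01 0.97
```

A command-line interface covers the same pipeline
(`simulate`, `extract`, `quality`, `train-eval`, `benchmark`); see
`?emgphasor_cli` or `inst/cli/emgphasor`.

## Layout

- `R/` — synthesis, filtering/windowing, classic feature sets, phasor sets,
  quality metrics, kernel baselines, evaluation, CLI
- `tests/testthat/` — unit, property and acceptance tests with independent
  oracles
- `vignettes/phasor-gait-features.Rmd` — methods, assumptions, parameter
  choices and limitations
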