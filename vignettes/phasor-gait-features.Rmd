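---
title: "Phasor spatial-synergy features for gait phase recognition: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasor spatial-synergy features for gait phase recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgphasor)
```

## The problem and the model

Surface EMG from the lower limb is a highly stochastic, band-limited
(roughly 10–400 Hz) signal whose short-time amplitude statistics are gated
by which gait phase the leg is in. Shallow classifiers (LDA, SVM) fed with
per-channel window features ignore *where* activity sits across the
electrode array — the spatial synergy pattern. The phasor scheme injects
that information without learning anything: channel `k` of `N` is pinned to
the complex position `e^{j k 2π/N}`, a per-channel base feature `f_k`
(waveform length or RMS here) becomes the phasor `f_k e^{j k 2π/N}`, and
the feature vector `Df` collects the `N(N−1)/2` pairwise difference moduli

$$ Df_{(k,l)} = \sqrt{f_k^2 + f_l^2 - 2 f_k f_l \cos\!\big((k-l)\tfrac{2\pi}{N}\big)}, \qquad k < l. $$

Each entry couples two channels' magnitudes with their angular separation,
so ratios of activity across the array — the synergy signature of a gait
phase — move the vector even when overall amplitude does not. The
generalized set for base feature `f` is

$$ f\text{-PHASOR} = \big[\, \log Df,\; \log (Df / \nabla Df) \,\big], $$

where `∇Df` repeats the construction on the first-differenced signals. The
log-ratio block is invariant to uniform amplitude scaling of the signal
(both `Df` and `∇Df` scale linearly), which is why it adds robustness to
electrode-gain drift; the `log Df` block keeps the absolute-level
information. WL-PHASOR and RMS-PHASOR each have `N(N−1)` columns (72 at
`N = 9`); their concatenation is the combined PHASOR set (144).

Assumptions worth stating: the channel→angle map is the file column order —
physical electrode geometry is the caller's responsibility, and the
construction is most meaningful for radially arranged electrodes; the
window is short enough (150 ms) that the phase is locally constant; and the
base features are non-negative, so `Df` is a genuine spatial contrast.

## Preprocessing

Recordings are filtered with a zero-lag Butterworth band-pass, realized as
forward–backward application of a designed 4th-order filter (so the
effective magnitude response is 8th order with exactly zero phase). The
source description "zero-lag ... fourth order" does not say whether the
order counts per pass or combined; we fix *4th order per pass* and note
that the choice only affects roll-off steepness, not the pass band.
Initial filter states are set to the step steady state and the signal is
odd-reflection padded, so constant offsets are rejected to machine
precision and edge transients do not leak into the analysis windows (the
implementation matches `scipy.signal.filtfilt` to ~1e-10 on identical
inputs, and is validated in the tests against analytic magnitude-response
oracles and an independently designed coefficient set).

Windows are `round(ms·fs/1000)` samples (exact at 1920 Hz: 150 ms → 288,
25 ms → 48), advanced by the increment, never crossing trial boundaries;
the count obeys `floor((T−L)/S)+1`. A window takes the *plurality* label of
its samples; ties break toward the phase occurring later in the window,
which encodes the causal direction of gait progression and handles the
toe-off → heel-strike wrap-around without a special case.

## Tunable parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| band edges | 10–400 | Hz | standard surface-EMG band |
| window / increment | 150 / 25 | ms | decision-rate vs estimate-variance trade-off common in myocontrol |
| `eps` log guard | 1e-12 | – | bounds `log(Df)` on silent channels; configurable |
| AR order (TDAR) | 4 | – | the source does not print it; 4 is the field default |
| Du WAMP threshold | 0.05·RMS | – | amplitude-relative deadband |
| SVM `gamma` rule | `inverse_scale` | – | see below |
| SVM cost `C` | 1 | – | standard soft-margin default |
| covariance ridge (SI) | 1e-9·tr/D | – | PHASOR/TDPSD columns can be collinear |

**The SVM gamma rule.** The reproduced configuration describes the RBF
width as "the product between the number of the features and the variance
of the features". Taken literally after z-scoring (variance ≈ 1) this gives
`γ ≈ D`, an extremely peaked kernel. We implement both: `paper_product`
(`γ = D·Var`, the literal reading) and `inverse_scale` (`γ = 1/(D·Var)`,
the common "scale" heuristic the phrase most plausibly paraphrases), with
`inverse_scale` as default; the rule used is recorded in every result.
Variance is computed over the flattened training matrix (configurable
convention, documented in `?svm_gamma`).

**Diagonal LDA.** The "principal diagonal covariance model" is realized as
a Gaussian classifier with class means, class priors and one pooled
per-feature variance vector — equivalent to LDA with the pooled covariance
constrained to its diagonal.

**MSA scaling.** The semi-axes are singular values of the centered class
data divided by `sqrt(n_i − 1)`, so they estimate per-axis standard
deviations and the metric is sample-size independent (the σ-recovery test
asserts exactly this); raw singular values are available via
`scaled = FALSE`. With the raw convention the metric grows like `sqrt(n)`,
which would make cross-subject comparisons depend on trial counts.

## The synthetic generator: what it emulates, what it does not

`generate_trial()` produces `N`-channel recordings in which band-limited
Gaussian noise (20–350 Hz carrier, filtered by the same Butterworth code
path used in preprocessing) is amplitude-gated per channel by the active
phase through a channel×phase **synergy gain matrix**, with 10 ms
raised-cosine crossfades at transitions (so waveform length sees no
discontinuity artifacts), unbalanced phase durations
(100/150/250/200/300 ms — gait phases are naturally unbalanced, which is
what makes MCC informative next to ACC), ±10% per-cycle duration jitter,
and additive white sensor noise (default sd 0.05, ~5–10% of a
baseline-gain channel's RMS). Subjects differ by a per-channel log-normal
gain perturbation (σ = 0.1), emulating electrode placement/impedance
variability. The perturbation is deliberately *per channel*, not per
channel×phase: a per-entry perturbation would re-introduce
phase-discriminative structure even when the synergy contrast is zero,
destroying the generator's own null contract (a zero-contrast dataset must
be unclassifiable).

What a green end-to-end test establishes: the pipeline recovers spatial
synergy structure that is genuinely present, and reports chance-level MCC
when it is absent. What it does not establish: performance on real EMG —
the generator has no motor-unit physiology, no crosstalk between channels,
no fatigue or electrode-shift nonstationarity, no movement artifacts, and
its amplitude envelopes are piecewise-constant rather than
kinematics-driven.

Two regimes discovered while validating, both documented in the tests:

* **SI saturation in contrast.** Raising the synergy contrast raises the
  RMS-space separability index strictly only while sensor noise dominates
  (contrast ≲ 0.5 at the default noise). Beyond that, windows spanning
  phase transitions contribute within-class spread that scales with the
  gains exactly as the between-class separation does, and the Mahalanobis
  ratio saturates. The monotonicity invariant is therefore tested at
  contrasts {0.02, 0.1, 0.5}.
* **Null stability needs windows.** With one gait cycle per trial (~350
  heavily overlapping windows) held-out MCC under zero contrast fluctuates
  beyond ±0.1 across seeds; the null acceptance check runs at 6 cycles per
  trial (~2300 windows), in line with the ≥2000-window guidance the
  permutation-null contract itself states.

## Numerical choices

* `Df` uses the trigonometric closed form with a `pmax(., 0)` clamp before
  the square root (the argument can go ~−1e-16 at equal features); the
  tests verify equality with the complex-arithmetic form to <1e-10 over
  10⁴ random vectors, N ∈ 2…12.
* Pair ordering is lexicographic `(k, l), k < l`, fixing column identity
  across runs; logarithms are natural (a monotone transform — base is
  irrelevant to the classifiers and to SI, which is affine invariant).
* Numerical differentiation is the in-window first difference (length
  `L−1`, no `Δt` scaling): the sampling interval would contribute a
  constant factor that the log-ratio turns into an additive constant.
  Differentiating per window differs from windowing a trial-level
  difference only at one boundary sample (asserted in the tests).
* Degenerate inputs: silent channels (ε in both log arguments), constant
  windows (AR coefficients set to 0; TDPSD ε-guarded), zero-variance
  feature columns (z-score maps them to 0; SI ridge; MSA ε floor with a
  warning), training folds missing a class (fold skipped, recorded).
* The SVM dual is solved exactly per class pair with `quadprog` (ridge
  1e-8 on the kernel diagonal for strict positive definiteness);
  one-vs-one voting with summed-margin tie-breaks keeps predictions
  deterministic.

## Design decisions that were genuinely open

* **Window labels**: plurality vote with later-phase tie-break (the
  upstream description never says how transition windows are labeled).
* **Comparator set internals** (HTD/TDPSD/TDAR/Du are named but not
  defined upstream): fixed to their canonical forms — HTD = {MAV, ZC, SSC,
  WL} with a configurable deadband (default 0); TDPSD = six
  moment-derived descriptors computed via time-domain derivatives with the
  0.1-power normalization; TDAR = HTD + Burg AR(4); Du = {IEMG, VAR,
  WAMP, ZC, SSC, WL}.
* **Kernel baselines**: 84 kernels; Mini-Rocket mode uses the complete
  C(9,3) = 84 set of length-9 {−1, 2} patterns (three 2s), which is
  exactly where the canonical 84 figure comes from. Default pooling is PPV
  *and* max for both modes, following the comparison being reproduced;
  `canonical = TRUE` restores PPV-only Mini-Rocket. Pooled features go
  through the same LDA/SVM harness as every other set (no ridge readout).
* **Fold grouping**: deterministic by trial order (10 trials → 5 folds of
  2), with an optional seeded shuffle; per-subject aggregation is
  folds-then-subjects.
* **Quality metrics on unnormalized features**, before the z-scoring used
  for classification.
* **Timing**: `run_subject_eval` times the classification of held-out
  windows per fold; the CLI `benchmark` path, which owns extraction, also
  reports per-trial extraction time. Timings are reported, never asserted.

## Known limitations

* SI and MSA need class sample counts comfortably above the feature
  dimension; with the combined 144-column PHASOR set and few gait cycles,
  the shortest phase (heel strike) can go rank-deficient — MSA then floors
  the missing axes at ε and warns. Use more cycles or a single-base
  f-PHASOR set for quality analysis on small data.
* The RBF SVM solves a dense QP per class pair: fine into the low
  thousands of windows per fold, not meant for full-scale datasets.
* The synthetic world is a stated model, not a biophysical simulation;
  published headline numbers on real 40-subject recordings are outside
  what desk-scale synthetic data can or should reproduce.
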