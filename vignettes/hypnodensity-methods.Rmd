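---
title: "Quantifying sleep intrusions and instability from hypnodensities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sleep intrusions and instability from hypnodensities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Standard polysomnography (PSG) reduces each 30-second epoch of sleep to a
single expert-assigned stage (W, N1, N2, N3, REM). That discretization hides
two phenomena that matter for sleep quality and for insomnia in particular:
*intrusions* — the presence of another state's electrophysiological
signature inside an epoch — and *instability* — abrupt changes in the
composition of sleep from one epoch to the next. Both are invisible in a
hypnogram, and both are candidate mechanisms for the common mismatch between
how people say they slept and what their PSG shows
(subjective–objective sleep discrepancy, SOSD).

`hypnodens` implements a continuous alternative. Each epoch is mapped to a
*hypnodensity*: a probability distribution $P = (p_W, p_{N1}, p_{N2},
p_{N3}, p_{REM})$ over the five stages, produced by a personalized,
calibrated classifier trained on that subject's own recording and expert
staging. Two information-theoretic functionals then summarize sleep
dynamics, in bits:

* intrusion level of an epoch:
  $H(P) = -\sum_{i \in \Omega} p_i \log_2 p_i$, where
  $\Omega = \{W, N1, N2, N3, REM\}$. $H$ is 0 for a pure (Dirac) epoch and
  $\log_2 5 \approx 2.32$ for a maximally mixed one.
* instability between temporally adjacent epochs that carry the *same*
  expert stage:
  $D_{KL}(P_t \| P_{t+1}) = \sum_i p_{t,i} \log_2 (p_{t,i} / p_{t+1,i})$,
  which is 0 iff the two hypnodensities coincide and grows with the size of
  the epoch-to-epoch shift. Pairs that span a stage change or an invalid
  epoch never qualify.

Per subject, the mean and SD of both metrics over epochs of W, N2, N3 and
REM give a 16-feature summary (`ave_H_W`, `sd_dKL_REM`, ...). N1 is kept in
the probability support — it contributes to every $H$ and $D_{KL}$ — but is
not summarized as a stage, because N1 staging is unreliable even between
human experts.

## The estimation pipeline

1. **Preprocessing** (`preprocess()`): EEG channels are re-referenced to the
   contralateral mastoid when mastoid channels are present (recordings
   without them pass through, with a message), then band-pass filtered
   0.5–40 Hz with a linear-phase Hamming-window FIR applied forward and
   backward, so the net phase response is exactly zero. The filter order
   follows the Hamming design rule for a 0.5 Hz transition band
   (order $\approx 3.3 f_s / 0.5$). The forward–backward pass is realized
   in the frequency domain — multiplying the zero-padded spectrum by
   $|B(\omega)|^2$ — which is exact linear convolution and $O(n \log n)$.
2. **Epoching** (`make_epochs()`): non-overlapping 30-s windows from sample
   one; a trailing partial window is discarded; epochs without a valid
   stage are dropped (no further artifact rejection is applied — scored
   epochs are taken as-is).
3. **Features** (`extract_features()`): the 22 canonical time-series
   features, computed per channel per epoch (so $22 \times k$ columns for
   $k$ EEG+EOG channels). The feature set is reimplemented in the package's
   C++ from the published definitions; non-finite values from degenerate
   series are set to 0, the set's convention, which keeps tree models
   total.
4. **Hypnodensity** (`fit_hypnodensity()`): a gradient-boosted tree
   stager (learning rate 0.1, depth 6, 80% row and 80% column subsampling,
   gamma 0.1) trained intra-subject under cross-validation. The default
   scheme is 10-fold (stratified by stage); leave-one-out is available and
   is implemented as $k = n$, so the equivalence of the two schemes at
   $k = n$ is exact and is asserted in the tests. Per training fold, an
   inner stratified 80/20 split provides held-out margins on which
   per-class sigmoid (Platt) calibrations are fitted; fitting them on
   training scores directly would push probabilities toward 0/1. Calibrated
   class probabilities are renormalized to the simplex. Argmax ties break
   toward the lower stage index (W first) — a deterministic convention.
   Boosting runs for 60 rounds per fold model (100 rounds for the
   cohort-level models below); these counts are the package's own
   defaults, small enough that the shrinkage (0.1) dominates model
   capacity.
5. **QC** (`qc_exclude()`): a subject whose staging balanced accuracy is
   *strictly below* 0.4 is excluded; exactly 0.4 is kept.
6. **Cohort models** (`mrmr_rank()`, `sequential_cv_classify()`,
   `sequential_cv_regress()`, `subject_accuracy()`, `matched_subsample()`,
   `group_stats()`): minimum-redundancy-maximum-relevance feature ranking
   (relevance = out-of-bag permutation importance of a random forest;
   redundancy = mean absolute Pearson correlation with already-selected
   features), sequential-inclusion repeated stratified 5-fold
   cross-validation (60 repeats for classification, 120 for regression,
   1000 iterations for per-subject accuracy), size balancing through a
   pool of 30 pre-drawn smallest-class-size subsamples cycled across
   repeats, sex-exact subsampling gated by Kolmogorov–Smirnov tests on age
   and BMI at p > 0.1 (500 accepted draws in batch mode), and
   Kruskal–Wallis plus pairwise rank-sum group tests with Bonferroni
   correction over the whole family of tests in the call. Binary
   classifiers use depth 3 rather than 6. Missing summary values (absent
   stages) are routed by the trees' native missing-value handling rather
   than imputed.
7. **Interpretation** (`epoch_psd()`, `correlate_entropy_power()`,
   `correlate_instability_deltapsd()`, `self_transition()`): a multitaper
   PSD per epoch and channel, projected on the common 0.5–40 Hz grid at
   0.5 Hz steps and normalized to total power, summed into six canonical
   bands (delta 0.5–4, theta 4–8, alpha 8–12, sigma 12–16, beta 16–30,
   gamma 30–40 Hz; half-open `[low, high)` bin assignment with gamma closed
   at 40 so the bands tile the grid exactly once). Epoch-level band
   fractions are correlated with entropy (per stage) and their
   consecutive-epoch differences with $D_{KL}$; hypnogram self-transition
   probabilities are correlated with mean wake instability across
   subjects. Pearson correlation is the default, Spearman is available.

### Numerical choices

* Probability floor: $D_{KL}$ is undefined where $q_i = 0$, and calibrated
  probabilities can underflow; both arguments are floored at
  $\varepsilon = 10^{-6}$ and renormalized. Entropy needs no floor
  ($0 \log 0 \equiv 0$).
* SDs use the $n-1$ denominator; a stage with a single epoch (or a single
  qualifying pair) yields an explicit `NA`, never a silent zero.
* Multitaper: sine tapers (7 tapers, uniform weights). Sine tapers are an
  established multitaper family whose band concentration at this resolution
  is equivalent to the classical prolate tapers for the purpose of 0.5-Hz
  band fractions, and they require no per-length eigendecomposition.
* Heterogeneous sampling rates are never resampled; harmonization happens
  at the PSD-grid and feature levels, which is why the common 0.5-Hz grid
  exists.
* Seeding: every stochastic stage derives its seed deterministically from
  the global seed and the subject/fold/repeat index, so cohort runs are
  bit-reproducible and individual subjects can be regenerated in
  isolation.

## The synthetic cohort generator

The clinical recordings this methodology targets cannot be redistributed,
so the package ships a generator (`simulate_cohort()`) whose parameters
plant exactly the structure the pipeline is supposed to detect. It is
first-class, tested code, not a fixture.

* **Hypnograms** are Markov chains over the five stages (row-stochastic
  5×5 per-group transition matrices, 240 epochs per subject by default,
  starting in W).
* **Signals** are sums of six band-limited Gaussian noise components whose
  expected band-power proportions follow each stage's spectral profile
  (wake alpha/beta-weighted, N1 theta, N2 sigma/theta, N3 delta-dominant,
  REM theta/beta — textbook AASM signatures). 128 Hz, two EEG plus one EOG
  channel by default; channels are independent realizations of the same
  epoch-level spectral target. Synthesis is direct in the frequency domain,
  which makes band-fraction targets analytically controllable.
* **Intrusions** are convex mixtures: a wake epoch with mixing weight
  $\lambda$ draws $(1-\lambda)$ of its band power from the wake profile and
  $\lambda$ from the mean sleep profile; sleep epochs mix toward the wake
  profile. $\lambda$ is constant within an epoch (the metrics are
  epoch-level). Across wake epochs $\lambda$ follows a bounded random walk
  (step SD = `wake_instability_sd`, clipped to [0, 1]); across sleep epochs
  it jitters i.i.d. around the group's `sleep_wake_intrusion`
  (`sleep_instability_sd`).
* **Within-stage spectral variability**: every epoch's mixed band weights
  receive log-normal jitter (SD 0.4 on the log scale). Real sleep EEG shows
  large epoch-to-epoch variability of within-stage band power; without it
  the synthetic stage clouds are so separable that a personalized stager's
  calibrated probabilities saturate at 0 and 1, and the *mean* intrusion
  level of a group becomes invisible to entropy (only its variance would
  show). The value 0.4 is a realism choice fixed once, not a tuning knob.
* **Groups**: the default three-group cohort plants the contrasts of
  interest. GS-like: wake mixing 0.05, stable wake (walk SD 0.02), no wake
  intrusion into sleep. SOSDminus-like ("objectively disrupted"): wake
  mixing 0.15 *plus* wake-into-sleep mixing 0.15 (jitter SD 0.05), more
  fragmented sleep. SOSDplus-like ("misperception"): wake mixing 0.30 with
  three-fold wake instability (walk SD 0.06) and fragmented wakefulness
  (wake self-transition 0.78 vs 0.92 in GS-like), but objectively normal
  sleep (no wake-into-sleep mixing). Demographics (sex ratio, age, BMI per
  group) follow the published clinical-cohort summaries. Sleep metrics
  (TST, SOL, WASO, SE) are *derived from the hypnogram* rather than drawn
  independently, with SOL defined as time to the first non-wake epoch —
  clinical SOL conventions vary, and internal consistency is worth more
  here than any one convention.
* The generator does **not** attempt transient morphology (spindles,
  K-complexes, slow-wave shapes), artifacts, arousals, or non-EEG
  channels; realism is spectral-envelope-level only. Consequently, passing
  recovery tests show that the *pipeline* detects planted spectral mixing
  and instability — they do not certify performance on clinical
  recordings, where transients carry staging information that these
  band-power profiles cannot emulate, and where the printed clinical
  effect sizes (group entropies, AUCs) live. No quantitative intrusion
  effect size in physical units exists to copy; the mixing defaults are
  calibration choices.

## Problem sizes and what the checks compute

The default verification cohort is 3 groups × 30 subjects × 240 epochs at
128 Hz with the 10-fold staging scheme — large enough for one-sided
rank-sum tests at $\alpha = 0.01$ on group contrasts, small enough to run
on a laptop core. On it, the package's checks recover: the wake-entropy
ordering GS-like < SOSDminus-like < SOSDplus-like; higher wake probability
within sleep for SOSDminus-like than SOSDplus-like; highest wake
instability in SOSDplus-like; 3-class balanced accuracy well above a
label-permuted null; a positive median correlation between wake-epoch delta
fraction and wake entropy together with a negative one in N3 (intrusion
displaces delta there); and a negative correlation between mean wake
$D_{KL}$ and wake self-transition. Unit suites check the structural
contracts (22 × channels feature columns, 5-simplex rows, 16 summary
features, 6 band fractions, 76-subject matched subsamples), verify entropy
and divergence against an independent brute-force oracle at $10^{-10}$, and
exercise regression recovery and the corrected type-I error of the group
statistics on null cohorts.

## Known limitations

* The catch-all imputation (non-finite feature → 0) is coarse; it only
  ever fires on degenerate series (flat epochs).
* Platt scaling is fitted per class on one 80/20 inner split per fold; with
  very few epochs of a class the sigmoid can be steep, and a class absent
  from the split falls back to the raw softmax output for that class.
* The EDF layer writes/reads continuous equal-rate 16-bit EDF only (no
  EDF+ annotations, no per-signal rates).
* Group transition matrices, spectral profiles and mixing weights are
  stylized; none of the numeric results on synthetic cohorts should be
  read as clinical estimates.
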