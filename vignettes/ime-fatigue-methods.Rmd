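---
title: "Methods: simulating and analysing isotonic muscular endurance tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing isotonic muscular endurance tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imefatigue)
```

## The measurement problem

An isotonic muscular endurance (IME) test loads a joint with a constant
resistance — here 50% of the isometric peak torque (IPT) — and asks the
subject to perform paced concentric/eccentric cycles (45–60 cycles/min) until
they voluntarily stop. Because the load is constant and the velocity free,
the mechanical output of interest is **power**, torque × angular velocity
(rad/s), and fatigue is operationalized as the decline of the
per-repetition *peak* power. A dynamometer flags the conventional fatigue
point when cycle power stays below 75% of the output of the first five
seconds for two consecutive cycles, but under a psychophysiological protocol
subjects are encouraged to continue to their own limit — which is why
end-of-trial power falls well below the 75% line (the first-five vs
last-five repetition ratio the simulator is calibrated to is ≈ 0.617, not
0.75).

Surface EMG (sEMG) recorded over the working muscles changes systematically
with fatigue: the power spectrum compresses toward lower frequencies while
the amplitude tends to grow. The package quantifies these changes with nine
per-contraction parameters and asks how well their percent changes *map* the
percent change in peak power — first linearly (univariate and
forward-stepwise multiple regression), then non-linearly (a multilayer
perceptron trained with Levenberg–Marquardt), with the mapping quality
scored by a signal-to-noise ratio.

No public recordings accompany this problem, so the package's first-class
citizen is a trial simulator with fully known ground truth; every
downstream stage is tested against it.

## The simulated world

`sim_config()` fixes one subject's stated world. The defaults are the
protocol's values, not free dials:

* **Kinematics.** The joint angle follows a raised-cosine bell over each
  cycle of duration `60/pace_cpm` s (default 60 cpm), so the angular
  velocity has one positive (concentric) and one negative (eccentric) lobe;
  the concentric-lobe velocity integral equals the range of motion exactly.
  Group ROMs: 80–130° (plantar flexors), 80–170° (knee extensors), 90–180°
  (hip extensors). Sampling is 1.5 kHz throughout.
* **Load and power.** Torque is nominally `resistance_frac` (0.5) of the
  group-mean IPT (154.90, 166.45, 198.56 N·m). With the protocol pacing this
  kinematic chain cannot reach the observed peak-power magnitudes
  (~630 W for plantar flexors), so the simulator rescales the torque trace
  of each cycle to hit the imposed peak-power schedule — the analysis
  consumes power, and this keeps its magnitude and decay faithful at the
  cost of literal torque realism.
* **Power decay.** A latent fatigue state `s_k` rises from 0 to 1 over the
  trial (with shared multiplicative noise `noise_cv`, default 0.03); peak
  power decays linearly (or exponentially) in `s_k` by `decay_frac`. The
  default `decay_frac` ≈ 0.408 is the closed-form calibration
  (`calibrate_decay_frac()`) that makes mean(last 5)/mean(first 5) equal
  388.73/629.62 at the group-mean repetition count.
* **Trial length.** The trial runs to the voluntary stop `n_reps` (group
  means 52/31/48 repetitions, between-subject SDs 13.3/9.5/16.5 in
  `cohort_configs()`), capped at `n_max`. The 75% rule is evaluated and
  recorded (`rule_trigger_rep`) but does not stop the trial, mirroring the
  psychophysiological protocol.
* **sEMG.** Each concentric segment is white Gaussian noise shaped by a
  4th-order Butterworth band-pass whose edges scale together so that the
  power-spectrum centroid follows the imposed trajectory
  (`emg_mnf_start_hz` 110 → `emg_mnf_end_hz` 80 over the trial, driven by
  the same latent state as power); segment RMS follows the amplitude
  schedule (base 100 µV growing by `emg_amp_growth_frac` = 0.2). Rest
  intervals carry baseline noise at 5% of the first repetition's RMS so
  segmentation is exercised against a non-silent floor. The myoelectric
  burst is amplitude-modulated by the effort bell within each contraction.

Three further choices shape the *statistical* texture of the sEMG, selected
once so that the pooled correlation structure of a simulated cohort mirrors
what dynamic contractions show (amplitude weakest, median-based frequency
estimators strongest, instantaneous median best) and then frozen:

* the **amplitude trajectory** carries autocorrelated wander
  (`emg_amp_noise_sd` = 1 latent-state unit, AR(1) with coefficient 0.7):
  sEMG amplitude reflects recruitment and compensation and is only loosely
  coupled to power loss;
* a **high-frequency spectral shoulder** (flat 150–250 Hz, ~11% of segment
  power on average) does not track the fatigue state, and its level
  fluctuates across repetitions (lognormal, CV = 1). Mean-frequency
  estimators integrate the tail and are dragged by these fluctuations;
  median-frequency estimators follow the compressing main lobe;
* `noise_cv = 0` switches off *all* trial-level randomness, giving the
  exactly reproducible degenerate cases the tests rely on.

What the generator does **not** emulate: motor-unit recruitment or
conduction-velocity physiology (the spectra are phenomenological),
eccentric-phase sEMG, powerline or ECG artifacts, electrode lift-off, or
non-stationarity within a single contraction. A green test therefore
establishes that the pipeline recovers imposed fatigue structure from
signals with realistic spectral statistics — not that it would survive
every artifact of a real laboratory recording.

## Preprocessing

* **Band-pass 20–250 Hz.** The acquisition protocol prescribes a 5th-order
  high-pass and a 10th-order low-pass; the filter family is Butterworth (a
  documented choice — only the orders and band are prescribed) applied at
  *exactly zero phase* by multiplying the FFT of the full
  record by the corresponding magnitude responses. This is the same
  magnitude behaviour a forward–backward IIR pass approximates, without
  start-up transients; the trade-off is the implicit circular boundary,
  which is negligible for zero-mean EMG. The record is filtered once, in
  full, before segmentation — filtering per segment would bias boundaries.
  The 750 Hz anti-alias analog filter is assumed applied by hardware and is
  not re-applied.
* **Adjacent averaging.** Mechanical traces are smoothed by a centered
  moving average with shrinking edge windows; the window (11 samples,
  ~7.3 ms) is a documented default — no window is stated in the protocol.
* **Segmentation.** Concentric phases are the contiguous runs where the
  smoothed angular velocity exceeds a floor (5% of the trial's
  95th-percentile velocity) for ≥ 0.2 s. Indices are 0-based and half-open
  everywhere, including persisted files.
* **Termination rule.** The baseline is the mean power of the cycles
  completed within the first 5 s; the rule returns the first cycle `k` with
  cycles `k-1` and `k` both below 75% of it. Peak power per repetition
  feeds the feature tables; the rule itself is order-exact (cycles after
  the trigger cannot change the index).

## The nine parameters

For each concentric segment: MAV and RMS (amplitude); MNF and MDF from a
single rectangular-window periodogram restricted to 20–250 Hz (the segments
are short, ~0.5 s, so one periodogram is used rather than averaged
subwindows; MDF is linearly interpolated between the two bins straddling
half the cumulative power to remove bin quantization); ZC, SSC and WL
(the Hudgins time-domain set, with an optional amplitude deadband `eps`,
default 0 — real recordings typically need ~10 µV); and IMNF/IMDF.

The instantaneous pair is computed on a differently filtered copy of the
record: a six-level db1 (Haar) wavelet decomposition retaining the detail
bands D2–D6, i.e. a nominal band from `fs/2^7` = 11.71875 Hz (the printed
11.7188 Hz) to `fs/4`. Two documented resolutions:

* the literal reading "the approximation was retained" contradicts the
  printed 11.72–350 Hz band (keeping A6 would retain 0–11.7 Hz); the
  printed band wins, and `keep_approx = TRUE` restores the other reading;
* the printed upper edge 350 Hz matches no dyadic edge at 1.5 kHz (D2's
  edge is 375 Hz); the dyadic structure is followed and the 350 Hz figure
  left unexplained.

The denoiser is implemented as the *shift-invariant* (stationary) Haar
multiresolution analysis applied through its exact zero-phase frequency
response `S1(f) − S6(f)`, `Sj(f) = ∏_{i≤j} cos²(2^{i−1}πf/fs)`. The
decimated orthogonal transform is not shift-invariant and leaves a
substantially larger out-of-band residual; the zero-phase stationary form
suppresses a 5 Hz tone below 15% RMS while preserving over 85% at 100 Hz
(both bounds are asserted by the test suite).

IMNF and IMDF are the squared-envelope-weighted mean and median of the
instantaneous frequency `f(t) = (1/2π)·dφ/dt` of the analytic signal
(FFT Hilbert transform; central differences of the unwrapped phase, clipped
to `[0, fs/2]`). The aggregation weighting is not defined in the source
description — squared-envelope weighting is this package's documented
choice; it reduces to the plain mean/median for constant envelope, and
whole contractions (not sliding windows) are the analysis unit.

Percent changes normalize every per-repetition series to the mean of its
first two repetitions (= 100%); the normalization is scale-invariant, and
the frequency parameters themselves are amplitude-invariant.

## Mapping power loss

The six percent predictors are RMS%, MAV%, MNF%, MDF%, IMNF%, IMDF%
(pooled across subjects with subject-tagged rows; the grouping is exposed
rather than asserted to be the original study's). Three mappings:

* `univariate_map()` — OLS of power% on one predictor, reporting the signed
  Pearson r, R², slope/intercept and SNR;
* `stepwise_mlr()` — forward selection with backward checks at
  `p_enter = 0.05`, `p_remove = 0.10` (conventional thresholds; none are
  stated in the source), reporting the regression equation in the
  `Power% = a × IMNF% + b` form. Aliased duplicates cannot enter; if
  nothing enters, an intercept-only model is returned with a warning. Note
  that uncorrected forward selection over six candidates admits at least
  one noise predictor in ~26% of null datasets — this is a property of the
  conventional procedure, reproduced faithfully;
* `train_mlp()`/`compare_linear_nonlinear()` — an `n → 10 (tanh) → 1`
  perceptron trained by full-batch Levenberg–Marquardt: damping λ starts at
  1e-3, ×10 on a rejected step, ÷10 on an accepted one, so training MSE
  never increases; stopping at 100 epochs, at a training-MSE goal of 4e-5
  (on z-scored targets), or after 18 consecutive validation failures, with
  the best-validation weights returned. Weights start uniform in
  [−0.5, 0.5] from a seed; inputs and targets are z-scored on the training
  folds only. The configured "learning rate 0.1" has no role in LM and is
  retained as the gradient-descent fallback step (`use_lm = FALSE`).
  Cross-validation uses five *contiguous* blocks in repetition order (the
  protocol's "four training segments and one validation segment"); a
  shuffled mode exists behind a flag. Out-of-fold estimates are pooled so
  each point is predicted exactly once.

**SNR.** The score is `10·log₁₀(Σ(aᵢ−ā)² / Σ(aᵢ−eᵢ)²)` dB — actual-series
variability over estimation residual — capped at +100 dB for numerically
zero residuals. No formula is printed in the source (it cites references),
so values are comparable in spirit, not numerically, to the study's tables.
An estimate fixed at the actual mean scores exactly 0 dB.

`simulate_feature_cohort()` generates percent tables directly at the
feature level with a known feature→power map (affine, or affine plus a
centered quadratic and an interaction term) for evaluating the mappers
without resynthesizing raw EMG; its trajectory ranges (frequencies falling
18–30 points, amplitudes rising 15–18 points, power noise 3 points) sit in
the range the trial simulator produces.

## Statistics

`cv_percent()` (screening the three IPT repetitions at < 10%), `paired_t()`
(with exact guards for zero-variance differences), `pearson_cor()`,
`rm_anova()` (one-way repeated measures across muscle groups — the
repeated-measures flavour is this package's documented choice, with a
one-way independent option — plus Bonferroni-corrected pairwise paired t
post-hocs flagged at 0.05/0.01), and `compare_regression_lines()` (slope
equality by the extra-sum-of-squares F between separate-slopes and
common-slope models; intercept equality under the common slope). All
p-values are two-tailed. The test suite checks the empirical size of each
test against its nominal 0.05 level by Monte-Carlo.

## Numerical details worth knowing

* FFT-domain filtering assumes circular continuation; records are long and
  zero-mean, segments are interior, and the tests bound any edge effect.
* MDF/IMDF use linear interpolation of the cumulative power/weight, so they
  are not quantized to bin edges or sample values.
* `snr()` caps at +100 dB; the cap triggers when the residual sum of
  squares falls below 1e-12 of the signal sum of squares.
* LM falls back to damping escalation on singular systems and stops
  training (reason `"lm_stalled"`) if no acceptable step exists within 30
  retries at λ ≤ 1e10.
* All randomness flows through per-purpose streams derived from
  `(master seed, stream id)` with the caller's RNG state restored, so
  pipelines re-run bit-identically and never perturb the user's session.

## Limitations

The simulator's fatigue structure is phenomenological; its defaults encode
one protocol (lower-limb muscle groups, 45–60 cpm, 50% IPT). The mapping
comparison inherits the study design's ambiguity about pooling across
subjects, and SNR values are not numerically portable across SNR
definitions. Stepwise selection retains the known liberal behaviour of
p-threshold entry. None of the statistics here address within-subject
autocorrelation of repetitions; the study design treats repetitions as
observations, and the package follows it.
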