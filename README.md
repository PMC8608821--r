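# imefatigue

Analysis of **isotonic muscular endurance (IME) tests**: repetitive
concentric contractions of the lower-limb muscles against a constant load
(50% of isometric peak torque) performed to voluntary exhaustion, with
dynamometer mechanics and surface EMG (sEMG) recorded at 1.5 kHz. The
package is written for researchers in neuromuscular fatigue, sports science
and rehabilitation who need a tested, fully reproducible pipeline from raw
traces to fatigue mapping — and, because endurance recordings of this kind
are rarely deposited, it ships a trial simulator with known ground truth as
a first-class component.

## What it computes

Fatigue is operationalized as the decline of per-repetition peak power
*P = τ · ω* (torque × angular velocity in rad/s, W). Each concentric phase
is located from the positive bell of the angular velocity, and nine sEMG
parameters are extracted per contraction:

* amplitude: MAV, RMS (on the 20–250 Hz band-passed signal);
* spectral: MNF = Σf·P(f)/ΣP(f) and MDF (half-cumulative-power frequency)
  from the periodogram;
* instantaneous: IMNF, IMDF — envelope²-weighted mean/median of
  f(t) = (1/2π)·dφ/dt from the Hilbert analytic signal of the signal
  denoised by a 6-level db1 (Haar) wavelet decomposition retaining D2–D6
  (band 11.7188–375 Hz at 1.5 kHz);
* Hudgins time-domain: ZC, SSC, WL.

Percent changes (relative to the first two repetitions) of the six
amplitude/frequency parameters then map percent power loss by:

* univariate and forward-stepwise multiple linear regression
  (`Power% = a × IMNF% + b × MNF% + c` style equations), and
* a multilayer perceptron *n* → 10 (tanh) → 1 trained with
  Levenberg–Marquardt (100 epochs max, MSE goal 4e-5, 18 validation
  failures, 5 contiguous cross-validation segments),

scored by the signal-to-noise ratio
`SNR = 10·log₁₀(Σ(aᵢ−ā)²/Σ(aᵢ−eᵢ)²)` dB and by the slope/intercept F tests
between the two actual-vs-estimated regression lines. Supporting statistics:
CV screening, paired t, repeated-measures ANOVA with Bonferroni post-hoc,
Pearson correlations.

## Worked example

Simulate one plantar-flexor trial, segment it, and extract the feature
table:

```r
library(imefatigue)

tr <- simulate_trial(sim_config(muscle_group = "plantar_flexors",
                                n_reps = 20, seed = 3))
tr
#> <ime_trial> plantar_flexors, 20 reps (75% rule at rep 16), peak power 624.2 -> 375.3 W

vel  <- smooth_mechanical(tr$mech$velocity_deg_s, 11)
pow  <- smooth_mechanical(tr$mech$power_W, 11)
mech <- mech_recording(tr$mech$time_s, tr$mech$torque_Nm, tr$mech$angle_deg,
                       vel, power_w = pow)
segs <- segment_concentric(mech)
ft   <- feature_table(tr$emg, segs, power_w = mech$power_W)
round(head(ft, 3), 2)
#>   rep peak_power_W    MAV    RMS    MNF    MDF   IMNF   IMDF  ZC SSC       WL
#> 1   1       624.10  80.95 111.55 118.96 104.60 115.72 114.34 136 162 32541.35
#> 2   2       609.55  80.71 102.09 172.02 174.42 168.55 171.73 181 190 43261.92
#> 3   3       598.66 100.62 125.40 176.91 182.85 174.04 173.28 180 194 55288.67
```

The trial ran to its voluntary stop at 20 repetitions while the 75%
dynamometer rule triggered at repetition 16, and peak power fell from 624 W
to 375 W (the imposed ~0.62 endurance ratio). Each row holds one
contraction's peak power and its nine sEMG parameters.

The full pipeline (simulate → preprocess → features → map → stats) over a
small cohort:

```r
cfg <- pipeline_config(out_dir = tempfile("ime"), n_subjects = 4,
                       sim = list(n_reps = 25), seed = 1)
res <- run_pipeline(cfg)
cat(render_report(res), sep = "\n")
#> Per-feature linear mapping of percent power loss
#> feature         r       R2     SNR_dB
#> RMS        -0.351    0.123      0.570
#> MAV        -0.336    0.113      0.520
#> MNF         0.362    0.131      0.610
#> MDF         0.323    0.104      0.479
#> IMNF        0.374    0.140      0.656
#> IMDF        0.363    0.132      0.615
#>
#> Linear versus non-linear mapping
#> method                r     SNR_dB
#> stepwise_mlr      0.637      2.260
#> mlp_cv            0.633      1.923
#> equation: Power% = 10.083 × IMNF% − 0.130 × MAV% − 7.678 × MNF% − 0.580 × MDF% − 1.213 × IMDF% + 39.334
#> slope F = 2.102 (p = 0.1487), intercept F = 0.823 (p = 0.3653)
```

Power loss correlates negatively with the amplitude percents and positively
with the frequency percents (spectral compression travels with fatigue);
the stepwise equation and both mappings' r/SNR mirror the reporting format
of endurance studies. Every stage writes delimited-text intermediates with
`#`-prefixed provenance headers (config hash, seed) under `out_dir`, and
reruns are byte-identical.

## Acceptance script

`scripts/acceptance.R` re-runs the package's full computation from scratch —
simulating a cohort, preprocessing it, extracting features, and fitting the
linear and MLP mappings — printing the report above and writing its JSON
result file:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Learn more

The methods vignette (`vignettes/ime-fatigue-methods.Rmd`) documents the
simulator's stated world and what it does and does not emulate, every
tunable parameter with units and defaults, the numerical choices
(zero-phase frequency-domain Butterworth filtering, stationary Haar MRA,
interpolated medians, LM damping schedule), and known limitations.
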