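# Synthetic isotonic-muscular-endurance (IME) trial generator: paced
# concentric/eccentric cycles against a constant load, per-repetition peak
# power decay, sEMG with imposed spectral compression and amplitude growth,
# and the 75% termination rule. Ground truth is returned alongside every
# trial so downstream stages can be tested without recorded data.

.group_defaults <- list(
  plantar_flexors = list(rom_deg = c(80, 130), peak_torque_nm = 154.90,
                         baseline_peak_power_w = 629.62, n_reps = 52,
                         n_reps_sd = 13.30),
  knee_extensors  = list(rom_deg = c(80, 170), peak_torque_nm = 166.45,
                         baseline_peak_power_w = 606.21, n_reps = 31,
                         n_reps_sd = 9.52),
  hip_extensors   = list(rom_deg = c(90, 180), peak_torque_nm = 198.56,
                         baseline_peak_power_w = 2036.58, n_reps = 48,
                         n_reps_sd = 16.51)
)

# First-5 vs last-5 peak-power ratio the default decay is calibrated to
# (plantar flexors, 388.73 W / 629.62 W).
.default_endurance_ratio <- 388.73 / 629.62

#' Calibrate the total power-decay fraction from an endurance ratio
#'
#' For a linear per-repetition decay schedule, returns the total fractional
#' loss `decay_frac` such that the mean of the last `k` repetitions divided by
#' the mean of the first `k` equals `ratio` (closed form).
#'
#' @param ratio Target mean(last k)/mean(first k) peak-power ratio in (0, 1).
#' @param n_reps Number of repetitions in the trial.
#' @param k Repetitions in each averaging window (default 5).
#' @return The decay fraction in (0, 1).
#' @examples
#' d <- calibrate_decay_frac(388.73 / 629.62, n_reps = 52)
#' p <- 629.62 * (1 - d * (0:51) / 51)
#' mean(p[48:52]) / mean(p[1:5])   # = 388.73 / 629.62
#' @export
calibrate_decay_frac <- function(ratio, n_reps, k = 5) {
  if (!is.numeric(ratio) || ratio <= 0 || ratio >= 1) {
    stopf("'ratio' must lie in (0, 1)")
  }
  if (!is_count(n_reps) || n_reps <= k) stopf("'n_reps' must exceed 'k'")
  a <- mean(seq(n_reps - k, n_reps - 1)) / (n_reps - 1)  # last-k mean of f
  b <- mean(seq(0, k - 1)) / (n_reps - 1)                # first-k mean of f
  d <- (1 - ratio) / (a - ratio * b)
  if (d <= 0 || d >= 1) stopf("calibration produced decay_frac outside (0, 1)")
  d
}

#' Configuration of a simulated IME trial
#'
#' Defines the stated world of one simulated subject: pacing and range of
#' motion of the chosen muscle group, resistance as a fraction of isometric
#' peak torque, the imposed per-repetition peak-power decay, the imposed sEMG
#' spectral-centroid drift and amplitude growth, and the noise level.
#'
#' Group defaults follow the protocol: ROM 80-130 deg (plantar flexors),
#' 80-170 deg (knee extensors), 90-180 deg (hip extensors); resistance 50% of
#' the group-mean isometric peak torque (154.90, 166.45, 198.56 N·m); first
#' repetition peak power and mean repetition counts at the group means; sEMG
#' sampled at 1.5 kHz. The default `decay_frac` is calibrated so the linear
#' schedule reproduces the plantar-flexor first-5/last-5 power ratio
#' 388.73/629.62 at the group-mean repetition count.
#'
#' @param muscle_group One of `"plantar_flexors"`, `"knee_extensors"`,
#'   `"hip_extensors"`.
#' @param rom_deg Start/end joint angle (degrees); defaults to the group range.
#' @param pace_cpm Cycles per minute, in `[45, 60]`.
#' @param resistance_frac Fraction of peak torque loaded (default 0.5).
#' @param peak_torque_nm Isometric peak torque used to set the nominal load;
#'   defaults to the group mean.
#' @param baseline_peak_power_w First-repetition peak power (W).
#' @param n_reps Repetitions performed (the voluntary stop); group default.
#' @param n_max Hard cap on repetitions.
#' @param decay_frac Total fractional peak-power loss across the trial; the
#'   default is calibrated (see above).
#' @param decay_shape `"linear"` or `"exponential"` decay of expected power.
#' @param emg_mnf_start_hz,emg_mnf_end_hz Imposed sEMG spectral-centroid drift
#'   (Hz) from first to last repetition; end must not exceed start.
#' @param emg_amp_growth_frac Fractional sEMG RMS growth over the trial.
#' @param emg_base_rms_uv First-repetition sEMG RMS scale (uV).
#' @param fs_hz Sampling rate (Hz), default 1500.
#' @param noise_cv Per-repetition multiplicative noise coefficient shared by
#'   the latent fatigue state (0 disables all trial-level randomness).
#' @param emg_disturbance_frac Mean RMS of the high-frequency spectral
#'   shoulder (flat 150-250 Hz band) added to each contraction, as a
#'   fraction of the contraction RMS (default 0.35, i.e. ~11% of segment
#'   power). Unlike the main lobe it does not track the fatigue state, and
#'   its level fluctuates across repetitions (lognormal, CV
#'   `emg_disturbance_cv`): mean-frequency estimators are dragged by these
#'   tail fluctuations while median-frequency estimators follow the
#'   compressing main lobe, reproducing the robustness ordering seen in
#'   dynamic contractions. Set to 0 for a pure rigidly-scaling spectrum.
#' @param emg_disturbance_cv Repetition-to-repetition coefficient of
#'   variation of the shoulder level (default 0.8).
#' @param emg_amp_noise_sd Independent autocorrelated per-repetition noise on
#'   the amplitude-growth trajectory, in latent-state units (default 1):
#'   sEMG amplitude reflects recruitment/compensation and is far more
#'   loosely coupled to power loss than spectral compression is. Applied
#'   only when `noise_cv > 0`, so `noise_cv = 0` still yields a fully
#'   deterministic trial.
#' @param seed RNG seed for the trial.
#' @param subject_id Integer label used in cohort file names.
#' @return An object of class `sim_config`.
#' @seealso [simulate_trial()], [simulate_cohort()]
#' @export
sim_config <- function(muscle_group = c("plantar_flexors", "knee_extensors",
                                        "hip_extensors"),
                       rom_deg = NULL, pace_cpm = 60, resistance_frac = 0.5,
                       peak_torque_nm = NULL, baseline_peak_power_w = NULL,
                       n_reps = NULL, n_max = 80, decay_frac = NULL,
                       decay_shape = c("linear", "exponential"),
                       emg_mnf_start_hz = 110, emg_mnf_end_hz = 80,
                       emg_amp_growth_frac = 0.2, emg_base_rms_uv = 100,
                       fs_hz = 1500, noise_cv = 0.03,
                       emg_disturbance_frac = 0.35, emg_disturbance_cv = 1,
                       emg_amp_noise_sd = 1, seed = 1, subject_id = 1L) {
  muscle_group <- match.arg(muscle_group)
  decay_shape <- match.arg(decay_shape)
  gd <- .group_defaults[[muscle_group]]
  if (is.null(rom_deg)) rom_deg <- gd$rom_deg
  if (is.null(peak_torque_nm)) peak_torque_nm <- gd$peak_torque_nm
  if (is.null(baseline_peak_power_w)) {
    baseline_peak_power_w <- gd$baseline_peak_power_w
  }
  if (is.null(n_reps)) n_reps <- gd$n_reps
  if (is.null(decay_frac)) {
    decay_frac <- calibrate_decay_frac(.default_endurance_ratio, gd$n_reps)
  }

  if (length(rom_deg) != 2 || rom_deg[2] <= rom_deg[1]) {
    stopf("'rom_deg' must be c(start, end) with end > start")
  }
  if (rom_deg[1] < gd$rom_deg[1] - 1e-9 || rom_deg[2] > gd$rom_deg[2] + 1e-9) {
    stopf("'rom_deg' must lie within the %s protocol range [%g, %g] deg",
          muscle_group, gd$rom_deg[1], gd$rom_deg[2])
  }
  if (!is.numeric(pace_cpm) || pace_cpm < 45 || pace_cpm > 60) {
    stopf("'pace_cpm' must lie in [45, 60]")
  }
  if (resistance_frac <= 0 || resistance_frac > 1) {
    stopf("'resistance_frac' must lie in (0, 1]")
  }
  if (decay_frac < 0 || decay_frac >= 1) {
    stopf("'decay_frac' must lie in [0, 1)")
  }
  if (fs_hz <= 2 * 250) stopf("'fs_hz' must exceed 500 Hz (2 x 250 Hz band)")
  if (emg_mnf_end_hz > emg_mnf_start_hz || emg_mnf_start_hz > fs_hz / 2) {
    stopf("need emg_mnf_end_hz <= emg_mnf_start_hz <= fs_hz/2")
  }
  if (emg_mnf_end_hz <= 0) stopf("'emg_mnf_end_hz' must be positive")
  if (!is_count(n_reps) || !is_count(n_max)) {
    stopf("'n_reps' and 'n_max' must be positive integers")
  }
  if (noise_cv < 0) stopf("'noise_cv' must be non-negative")
  if (emg_amp_growth_frac < 0) stopf("'emg_amp_growth_frac' must be >= 0")
  if (emg_disturbance_frac < 0 || emg_disturbance_cv < 0 ||
      emg_amp_noise_sd < 0) {
    stopf("disturbance/amplitude noise parameters must be non-negative")
  }

  structure(list(
    muscle_group = muscle_group, rom_deg = as.numeric(rom_deg),
    pace_cpm = pace_cpm, resistance_frac = resistance_frac,
    peak_torque_nm = peak_torque_nm,
    baseline_peak_power_w = baseline_peak_power_w,
    n_reps = as.integer(n_reps), n_max = as.integer(n_max),
    decay_frac = decay_frac, decay_shape = decay_shape,
    emg_mnf_start_hz = emg_mnf_start_hz, emg_mnf_end_hz = emg_mnf_end_hz,
    emg_amp_growth_frac = emg_amp_growth_frac,
    emg_base_rms_uv = emg_base_rms_uv, fs_hz = fs_hz, noise_cv = noise_cv,
    emg_disturbance_frac = emg_disturbance_frac,
    emg_disturbance_cv = emg_disturbance_cv,
    emg_amp_noise_sd = emg_amp_noise_sd,
    seed = as.integer(seed), subject_id = as.integer(subject_id)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    paste0("<sim_config> %s: ROM %g-%g deg, %g cpm, %d reps, ",
           "decay %.3f (%s), MNF %g->%g Hz, RMS growth %g, seed %d\n"),
    x$muscle_group, x$rom_deg[1], x$rom_deg[2], x$pace_cpm, x$n_reps,
    x$decay_frac, x$decay_shape, x$emg_mnf_start_hz, x$emg_mnf_end_hz,
    x$emg_amp_growth_frac, x$seed))
  invisible(x)
}

# Latent-state draw shared by power, spectral-centroid and amplitude ground
# truth. A common fatigue state s_k drives power and the sEMG centroid
# (shared noise), while the amplitude schedule carries independent noise;
# this couples power loss to spectral compression more tightly than to
# amplitude growth, as the analysis design assumes.
simulate_truth <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- min(cfg$n_reps, cfg$n_max)
  f <- if (n == 1) 0 else (seq_len(n) - 1) / (n - 1)
  with_seed(cfg$seed, {
    eps <- stats::rnorm(n)   # shared state noise
    eta <- stats::rnorm(n)   # independent power noise
    zeta <- stats::rnorm(n)  # independent amplitude noise
    s <- pmin(pmax(f + cfg$noise_cv * eps, 0), 1.2)
    decay_mult <- switch(cfg$decay_shape,
      linear = 1 - cfg$decay_frac * s,
      exponential = (1 - cfg$decay_frac)^s)
    power <- cfg$baseline_peak_power_w * decay_mult *
      (1 + cfg$noise_cv / 2 * eta)
    mnf <- cfg$emg_mnf_start_hz +
      (cfg$emg_mnf_end_hz - cfg$emg_mnf_start_hz) * pmin(s, 1)
    amp_sd <- if (cfg$noise_cv > 0) cfg$emg_amp_noise_sd else 0
    # smooth (AR) amplitude wander, stationary sd = amp_sd
    zeta_ar <- as.numeric(stats::filter(zeta, 0.7, method = "recursive")) *
      sqrt(1 - 0.7^2)
    rms_scale <- pmax(1 + cfg$emg_amp_growth_frac * (f + amp_sd * zeta_ar),
                      0.5)
    list(peak_power_w = power, mnf_hz = mnf, rms_scale = rms_scale,
         termination_rep = n)
  })
}

#' Simulate the per-repetition true peak-power series
#'
#' Draws the ground-truth peak power of every repetition: a monotone-decreasing
#' expected schedule from `baseline_peak_power_w` losing `decay_frac` of the
#' baseline over the trial (linear or exponential in the latent fatigue
#' state), with multiplicative per-repetition noise of coefficient `noise_cv`.
#'
#' @param cfg A [sim_config()].
#' @return Numeric vector of peak power (W), one value per repetition.
#' @examples
#' cfg <- sim_config(noise_cv = 0)
#' p <- simulate_power_decay(cfg)
#' mean(tail(p, 5)) / mean(head(p, 5))   # calibrated endurance ratio
#' @export
simulate_power_decay <- function(cfg) {
  simulate_truth(cfg)$peak_power_w
}

#' Simulate the kinematics of one IME cycle
#'
#' One complete cycle of duration `60 / pace_cpm` s: the joint angle follows a
#' raised-cosine bell from the start angle to the end angle and back, so the
#' angular velocity has one positive (concentric) and one negative
#' (eccentric) lobe. Torque is the constant isotonic load
#' `resistance_frac * peak_torque_nm`; when `peak_power_w` is given the torque
#' trace is rescaled so the cycle's peak power matches it (this is how the
#' imposed fatigue schedule enters the mechanics).
#'
#' @param cfg A [sim_config()].
#' @param rep_index Repetition number (>= 1); fixes the cycle's time offset.
#' @param peak_power_w Optional target peak power (W) for this cycle.
#' @return A [mech_recording()] spanning one cycle.
#' @examples
#' cyc <- simulate_kinematics(sim_config(), rep_index = 1)
#' range(cyc$angle_deg)
#' @export
simulate_kinematics <- function(cfg, rep_index, peak_power_w = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is_count(rep_index)) stopf("'rep_index' must be a positive integer")
  T_cyc <- 60 / cfg$pace_cpm
  npc <- round(T_cyc * cfg$fs_hz)
  if (npc < 8) stopf("degenerate cycle: too few samples per cycle")
  t_local <- (seq_len(npc) - 1) / cfg$fs_hz
  span <- diff(cfg$rom_deg)
  angle <- cfg$rom_deg[1] + span * (1 - cos(2 * pi * t_local / T_cyc)) / 2
  vel <- span * (pi / T_cyc) * sin(2 * pi * t_local / T_cyc)
  torque <- rep(cfg$resistance_frac * cfg$peak_torque_nm, npc)
  if (!is.null(peak_power_w)) {
    nominal_peak <- max(compute_power(torque, vel))
    torque <- torque * (peak_power_w / nominal_peak)
  }
  t_abs <- (rep_index - 1) * T_cyc + t_local
  mech_recording(t_abs, torque, angle, vel)
}

#' Apply the 75% power termination rule
#'
#' The trial's fatigue point is indicated at the first cycle `k` such that
#' cycles `k - 1` and `k` are both below `threshold_frac` times the mean power
#' of the cycles completed within the first `baseline_window_s` seconds. If
#' the rule never triggers the series length is returned.
#'
#' @param power_per_cycle Power output per cycle (W).
#' @param cycle_times Completion time of each cycle (s).
#' @param threshold_frac Fraction of the baseline power (default 0.75).
#' @param baseline_window_s Baseline window from trial start (default 5 s).
#' @return Integer index of the triggering cycle, or `length(power_per_cycle)`.
#' @examples
#' apply_termination_rule(c(100, 100, 80, 74, 74, 74), 1:6)   # 5
#' @export
apply_termination_rule <- function(power_per_cycle, cycle_times,
                                   threshold_frac = 0.75,
                                   baseline_window_s = 5) {
  n <- length(power_per_cycle)
  if (n == 0) stopf("'power_per_cycle' must be non-empty")
  if (length(cycle_times) != n) {
    stopf("'cycle_times' must match 'power_per_cycle' in length")
  }
  if (n < 2) return(n)
  base_idx <- which(cycle_times <= baseline_window_s)
  if (length(base_idx) == 0) base_idx <- 1L
  baseline <- mean(power_per_cycle[base_idx])
  below <- power_per_cycle < threshold_frac * baseline
  hit <- which(below[-1] & below[-n])
  if (length(hit) == 0) n else hit[1] + 1L
}

# Random-phase spectral synthesis of band-shaped noise whose power-spectrum
# centroid equals `centroid_hz` exactly (up to binning). The shape is a
# 4th-order Butterworth band-pass whose edges scale together with the target
# centroid, giving single-parameter spectral compression.
.shaped_noise <- function(n, fs_hz, centroid_hz) {
  # template edges in centroid units; template centroid computed numerically
  fl0 <- 0.55
  fh0 <- 1.45
  gsq <- function(u) butter_hp_gain(u, fl0, 4)^2 * butter_lp_gain(u, fh0, 4)^2
  u <- seq(0.001, 12, by = 0.002)
  c0 <- sum(u * gsq(u)) / sum(gsq(u))
  s <- centroid_hz / c0
  if (fh0 * s >= 0.95 * fs_hz / 2) {
    stopf("imposed centroid %.1f Hz pushes the shaping band beyond Nyquist",
          centroid_hz)
  }
  gain <- function(f) {
    butter_hp_gain(f, fl0 * s, 4) * butter_lp_gain(f, fh0 * s, 4)
  }
  x <- fft_filter(stats::rnorm(n), fs_hz, gain)
  x <- x - mean(x)
  x / sqrt(mean(x^2))
}

# Unit-RMS flat-band Gaussian noise, used for the high-frequency spectral
# shoulder that does not track the fatigue state.
.flat_noise <- function(n, fs_hz, band = c(150, 250)) {
  x <- fft_filter(stats::rnorm(n), fs_hz, function(f) {
    as.numeric(f >= band[1] & f <= band[2])
  })
  x <- x - mean(x)
  x / sqrt(mean(x^2))
}

#' Simulate multichannel-style sEMG for a trial
#'
#' Fills each concentric segment with zero-mean noise whose power-spectrum
#' centroid follows the imposed per-repetition centroid trajectory and whose
#' RMS follows the imposed amplitude schedule; inter-segment rest carries
#' low-level baseline noise at 5% of the first repetition's RMS. Deterministic
#' under a fixed config seed.
#'
#' @param cfg A [sim_config()].
#' @param segments Data frame of concentric segments with 0-based half-open
#'   `start_idx`/`end_idx` columns (see [segment_concentric()]).
#' @param truth Ground-truth list from [simulate_truth()]-style generation:
#'   fields `mnf_hz` and `rms_scale`, one value per segment.
#' @param n_samples Total recording length; defaults to the last segment end.
#' @return An [emg_recording()].
#' @export
simulate_semg <- function(cfg, segments, truth, n_samples = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  ns <- nrow(segments)
  if (ns == 0) stopf("'segments' must be non-empty")
  if (is.unsorted(segments$start_idx) ||
      any(segments$start_idx[-1] < segments$end_idx[-ns])) {
    stopf("'segments' must be sorted and non-overlapping")
  }
  if (length(truth$mnf_hz) < ns || length(truth$rms_scale) < ns) {
    stopf("'truth' must provide mnf_hz and rms_scale for every segment")
  }
  if (is.null(n_samples)) n_samples <- max(segments$end_idx)
  with_seed(derive_seed(cfg$seed, 7L), {
    base_rms <- cfg$emg_base_rms_uv * truth$rms_scale[1]
    x <- stats::rnorm(n_samples, sd = 0.05 * base_rms)
    for (i in seq_len(ns)) {
      idx <- (segments$start_idx[i] + 1L):segments$end_idx[i]
      target_rms <- cfg$emg_base_rms_uv * truth$rms_scale[i]
      m <- length(idx)
      # myoelectric burst: amplitude-modulated by the effort bell of the
      # concentric phase; the spectral shoulder is not modulated
      bell <- 0.25 + 0.75 * sin(pi * (seq_len(m) - 1) / (m - 1))^2
      seg <- .shaped_noise(m, cfg$fs_hz, truth$mnf_hz[i]) * bell
      seg <- seg / sqrt(mean(seg^2))
      if (cfg$emg_disturbance_frac > 0) {
        cv <- cfg$emg_disturbance_cv
        level <- cfg$emg_disturbance_frac *
          stats::rlnorm(1, meanlog = -cv^2 / 2, sdlog = cv)
        seg <- seg + level * .flat_noise(m, cfg$fs_hz)
        seg <- seg / sqrt(mean(seg^2))
      }
      x[idx] <- seg * target_rms
    }
    emg_recording(x, cfg$fs_hz, channel = cfg$muscle_group)
  })
}

#' Simulate one complete IME trial
#'
#' Assembles the repetition cycles (kinematics scaled to the ground-truth
#' peak-power schedule), the true concentric segment boundaries, the sEMG
#' recording, and the termination bookkeeping. The trial runs to the
#' voluntary stop (`n_reps`, capped at `n_max`); the cycle at which the 75%
#' dynamometer rule first indicates fatigue is recorded separately as
#' `rule_trigger_rep` — subjects in this protocol continue past the
#' indication, which is what makes end-of-trial power fall below 75% of
#' baseline.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `ime_trial` with elements `mech`
#'   ([mech_recording()]), `emg` ([emg_recording()]), `truth` (per-repetition
#'   `peak_power_w`, `mnf_hz`, `rms_scale`, plus `termination_rep` and
#'   `rule_trigger_rep`), `segments` (true concentric boundaries, 0-based
#'   half-open), and `cfg`.
#' @examples
#' tr <- simulate_trial(sim_config(n_reps = 8, seed = 2))
#' tr$truth$termination_rep
#' @export
simulate_trial <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  truth <- simulate_truth(cfg)
  n <- truth$termination_rep
  T_cyc <- 60 / cfg$pace_cpm
  npc <- round(T_cyc * cfg$fs_hz)
  half <- npc %/% 2

  cycles <- lapply(seq_len(n), function(k) {
    simulate_kinematics(cfg, k, peak_power_w = truth$peak_power_w[k])
  })
  mech <- mech_recording(
    time_s = unlist(lapply(cycles, `[[`, "time_s")),
    torque_nm = unlist(lapply(cycles, `[[`, "torque_Nm")),
    angle_deg = unlist(lapply(cycles, `[[`, "angle_deg")),
    velocity_deg_s = unlist(lapply(cycles, `[[`, "velocity_deg_s")))

  segments <- data.frame(
    rep = seq_len(n),
    start_idx = (seq_len(n) - 1L) * npc,
    end_idx = (seq_len(n) - 1L) * npc + half)
  emg <- simulate_semg(cfg, segments, truth, n_samples = n * npc)

  truth$rule_trigger_rep <- apply_termination_rule(
    truth$peak_power_w, cycle_times = seq_len(n) * T_cyc)

  structure(list(mech = mech, emg = emg, truth = truth, segments = segments,
                 cfg = cfg),
            class = "ime_trial")
}

#' @export
print.ime_trial <- function(x, ...) {
  cat(sprintf(
    "<ime_trial> %s, %d reps (75%% rule at rep %d), peak power %.1f -> %.1f W\n",
    x$cfg$muscle_group, x$truth$termination_rep, x$truth$rule_trigger_rep,
    x$truth$peak_power_w[1],
    x$truth$peak_power_w[length(x$truth$peak_power_w)]))
  invisible(x)
}

#' Build per-subject configurations for a simulated cohort
#'
#' Draws between-subject variability around the group means (repetition counts
#' with the group SD, baseline power with a 10% CV) and derives one RNG stream
#' per subject from the master seed.
#'
#' @param n_subjects Number of subjects.
#' @param muscle_group Muscle group label (see [sim_config()]).
#' @param master_seed Master seed; per-subject seeds are derived from it.
#' @param ... Further arguments forwarded to every subject's [sim_config()].
#' @return List of [sim_config()] objects.
#' @export
cohort_configs <- function(n_subjects, muscle_group = "plantar_flexors",
                           master_seed = 1, ...) {
  if (!is_count(n_subjects)) stopf("'n_subjects' must be a positive integer")
  gd <- .group_defaults[[match.arg(muscle_group, names(.group_defaults))]]
  dots <- list(...)
  with_seed(derive_seed(master_seed, 1L), {
    n_reps <- pmin(pmax(round(stats::rnorm(n_subjects, gd$n_reps,
                                           gd$n_reps_sd)), 10L), 80L)
    p0 <- gd$baseline_peak_power_w *
      (1 + 0.10 * stats::rnorm(n_subjects))
    lapply(seq_len(n_subjects), function(i) {
      args <- c(list(muscle_group = muscle_group,
                     seed = derive_seed(master_seed, 100L + i),
                     subject_id = i), dots)
      if (is.null(dots$n_reps)) args$n_reps <- n_reps[i]
      if (is.null(dots$baseline_peak_power_w)) {
        args$baseline_peak_power_w <- p0[i]
      }
      do.call(sim_config, args)
    })
  })
}

#' Simulate a cohort and persist it as delimited text
#'
#' Writes, per subject, a mechanics file
#' (`time_s,torque_Nm,angle_deg,velocity_deg_s`), an sEMG file
#' (`time_s,<muscle>`), and a ground-truth file
#' (`rep,true_peak_power_W,true_mnf_Hz,true_rms_scale`). Re-running with the
#' same configs reproduces identical numeric content.
#'
#' @param cfgs List of [sim_config()] objects (distinct seeds per subject).
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a data frame listing the written files per subject.
#' @export
simulate_cohort <- function(cfgs, out_dir) {
  if (!length(cfgs)) stopf("'cfgs' must be a non-empty list")
  seeds <- vapply(cfgs, function(cfg) cfg$seed, integer(1))
  if (anyDuplicated(seeds)) stopf("subject seeds must be distinct")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stopf("cannot create output directory '%s'", out_dir)
  }
  files <- lapply(cfgs, function(cfg) {
    tr <- simulate_trial(cfg)
    id <- sprintf("subject_%02d", cfg$subject_id)
    mech_file <- file.path(out_dir, paste0(id, "_mech.csv"))
    emg_file <- file.path(out_dir, paste0(id, "_emg.csv"))
    truth_file <- file.path(out_dir, paste0(id, "_truth.csv"))
    mech_df <- as.data.frame(tr$mech)[c("time_s", "torque_Nm", "angle_deg",
                                        "velocity_deg_s")]
    utils::write.csv(mech_df, mech_file, row.names = FALSE)
    emg_df <- data.frame(time_s = tr$mech$time_s, x = tr$emg$samples)
    names(emg_df)[2] <- tr$emg$channel
    utils::write.csv(emg_df, emg_file, row.names = FALSE)
    truth_df <- data.frame(rep = seq_along(tr$truth$peak_power_w),
                           true_peak_power_W = tr$truth$peak_power_w,
                           true_mnf_Hz = tr$truth$mnf_hz,
                           true_rms_scale = tr$truth$rms_scale)
    utils::write.csv(truth_df, truth_file, row.names = FALSE)
    data.frame(subject = cfg$subject_id, mech = mech_file, emg = emg_file,
               truth = truth_file, stringsAsFactors = FALSE)
  })
  invisible(do.call(rbind, files))
}
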