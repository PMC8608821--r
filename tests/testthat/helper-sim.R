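# Shared fixtures: all synthetic, generated in code at test time.

# Smooth the mechanical traces and segment the concentric lobes the way the
# pipeline does.
preprocess_trial <- function(tr, window = 11) {
  vel_s <- smooth_mechanical(tr$mech$velocity_deg_s, window)
  pow_s <- smooth_mechanical(tr$mech$power_W, window)
  ms <- mech_recording(tr$mech$time_s, tr$mech$torque_Nm, tr$mech$angle_deg,
                       vel_s, power_w = pow_s)
  list(mech = ms, segments = segment_concentric(ms))
}

# One subject's pooled percent table (simulate -> preprocess -> features).
trial_percent_table <- function(cfg) {
  tr <- simulate_trial(cfg)
  pp <- preprocess_trial(tr)
  ft <- feature_table(tr$emg, pp$segments, power_w = pp$mech$power_W)
  percent_table(ft)
}

# A pure sinusoid as an emg_recording.
tone_recording <- function(freq_hz, fs_hz = 1500, dur_s = 1, amp = 1) {
  t <- seq(0, dur_s - 1 / fs_hz, by = 1 / fs_hz)
  emg_recording(amp * sin(2 * pi * freq_hz * t), fs_hz)
}

rms <- function(x) sqrt(mean(x^2))
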