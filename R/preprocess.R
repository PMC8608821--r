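# Preprocessing: sEMG band-pass filtering, adjacent-averaging smoothing of
# mechanical traces, concentric-phase identification from the positive
# angular-velocity lobe, and per-repetition peak power.
#
# Pipeline order is fixed: the full sEMG record is filtered first, segments
# are cut afterwards. The 750 Hz anti-alias analog low-pass is assumed
# already applied by the acquisition hardware and is not reapplied here.

#' Band-pass filter an sEMG recording (20-250 Hz)
#'
#' Zero-phase filtering with the Butterworth magnitude response of a 5th-order
#' high-pass at `low_hz` and a 10th-order low-pass at `high_hz`, applied in
#' the frequency domain. Output length equals input length.
#'
#' @param rec An [emg_recording()]; `fs_hz` must be at least `2 * high_hz`.
#' @param low_hz,high_hz Passband edges in Hz (defaults 20 and 250).
#' @param hp_order,lp_order Butterworth orders (defaults 5 and 10).
#' @return A filtered [emg_recording()].
#' @examples
#' fs <- 1500; t <- seq(0, 1, by = 1 / fs)
#' rec <- emg_recording(sin(2 * pi * 100 * t), fs)
#' filt <- bandpass_emg(rec)
#' sqrt(mean(filt$samples^2)) / sqrt(mean(rec$samples^2))  # ~1 in passband
#' @export
bandpass_emg <- function(rec, low_hz = 20, high_hz = 250, hp_order = 5,
                         lp_order = 10) {
  stopifnot(inherits(rec, "emg_recording"))
  if (rec$fs_hz < 2 * high_hz) {
    stopf("sampling rate %g Hz is below 2 x %g Hz", rec$fs_hz, high_hz)
  }
  if (length(rec$samples) < 16) {
    stopf("input too short to filter (need >= 16 samples)")
  }
  y <- fft_filter(rec$samples, rec$fs_hz, function(f) {
    butter_hp_gain(f, low_hz, hp_order) * butter_lp_gain(f, high_hz, lp_order)
  })
  emg_recording(y, rec$fs_hz, rec$channel)
}

#' Adjacent-averaging smoothing
#'
#' Centered moving average with an odd window; the edges use shrinking
#' windows so the output length equals the input length. A window of 1 is the
#' identity.
#'
#' @param series Numeric vector.
#' @param window_samples Odd window width in samples (default 11, about
#'   7.3 ms at 1.5 kHz).
#' @return Smoothed numeric vector of the same length.
#' @examples
#' smooth_mechanical(c(1, 2, 3, 4, 5), 3)   # 1.5 2 3 4 4.5
#' @export
smooth_mechanical <- function(series, window_samples = 11) {
  if (!is_count(window_samples) || window_samples %% 2 == 0) {
    stopf("'window_samples' must be a positive odd integer")
  }
  if (window_samples == 1) return(as.numeric(series))
  moving_average(as.numeric(series), as.integer(window_samples))
}

#' Instantaneous power from torque and angular velocity
#'
#' `power = torque * velocity * pi / 180` (velocity converted from deg/s to
#' rad/s); the sign follows the velocity sign, so eccentric phases are
#' negative.
#'
#' @param torque_nm Torque (N·m).
#' @param velocity_deg_s Angular velocity (deg/s).
#' @return Power in watts, same length as the inputs.
#' @examples
#' compute_power(100, 90)   # 157.0796 W
#' @export
compute_power <- function(torque_nm, velocity_deg_s) {
  if (length(torque_nm) != length(velocity_deg_s)) {
    stopf("'torque_nm' and 'velocity_deg_s' must have equal length")
  }
  torque_nm * velocity_deg_s * pi / 180
}

#' Identify concentric contraction segments
#'
#' One segment per contiguous run where the (smoothed) angular velocity
#' exceeds `velocity_floor` for at least `min_duration_s` — the positive
#' bell-shaped lobe of each cycle. Repetition indices are assigned in
#' temporal order. Indices are 0-based, half-open `[start_idx, end_idx)`.
#'
#' @param mech A [mech_recording()] whose velocity has been smoothed (see
#'   [smooth_mechanical()]).
#' @param min_duration_s Minimum lobe duration in seconds (default 0.2).
#' @param velocity_floor Velocity threshold in deg/s; default 5% of the
#'   trial's 95th-percentile velocity.
#' @return Data frame with columns `rep`, `start_idx`, `end_idx` (possibly
#'   zero rows).
#' @export
segment_concentric <- function(mech, min_duration_s = 0.2,
                               velocity_floor = NULL) {
  stopifnot(inherits(mech, "mech_recording"))
  vel <- mech$velocity_deg_s
  if (is.null(velocity_floor)) {
    velocity_floor <- 0.05 * stats::quantile(vel, 0.95, names = FALSE)
    if (velocity_floor <= 0) velocity_floor <- .Machine$double.eps
  }
  dt <- stats::median(diff(mech$time_s))
  min_len <- max(1L, ceiling(min_duration_s / dt))
  above <- vel > velocity_floor
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  if (!any(keep)) {
    return(data.frame(rep = integer(0), start_idx = integer(0),
                      end_idx = integer(0)))
  }
  data.frame(rep = seq_len(sum(keep)),
             start_idx = starts[keep] - 1L,       # 0-based
             end_idx = ends[keep])                # half-open
}

#' Per-repetition peak power
#'
#' Maximum of the power trace within each concentric segment, ordered by
#' repetition index.
#'
#' @param power_w Power trace (W).
#' @param segments Segment table from [segment_concentric()].
#' @return Numeric vector of peak power, one value per segment.
#' @export
peak_power_per_rep <- function(power_w, segments) {
  if (nrow(segments) == 0) return(numeric(0))
  if (any(segments$start_idx < 0) ||
      any(segments$end_idx > length(power_w)) ||
      any(segments$start_idx >= segments$end_idx)) {
    stopf("segments out of range for the power trace")
  }
  vapply(seq_len(nrow(segments)), function(i) {
    max(power_w[(segments$start_idx[i] + 1L):segments$end_idx[i]])
  }, numeric(1))
}

#' Read a mechanics file written by [simulate_cohort()]
#'
#' Delimited text with header `time_s,torque_Nm,angle_deg,velocity_deg_s`;
#' lines starting with `#` are treated as metadata and skipped. Power is
#' derived on read.
#'
#' @param path File path.
#' @return A [mech_recording()].
#' @export
read_mech_file <- function(path) {
  if (!file.exists(path)) stopf("mechanics file '%s' does not exist", path)
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("time_s", "torque_Nm", "angle_deg", "velocity_deg_s")
  if (!all(need %in% names(df))) {
    stopf("mechanics file must have columns %s", paste(need, collapse = ","))
  }
  mech_recording(df$time_s, df$torque_Nm, df$angle_deg, df$velocity_deg_s)
}

#' Read an sEMG file written by [simulate_cohort()]
#'
#' Delimited text with header `time_s,<muscle>`; the sampling rate is
#' recovered from the time stamps. Only the first channel column is read.
#'
#' @param path File path.
#' @return An [emg_recording()].
#' @export
read_emg_file <- function(path) {
  if (!file.exists(path)) stopf("sEMG file '%s' does not exist", path)
  df <- utils::read.csv(path, comment.char = "#")
  if (ncol(df) < 2 || names(df)[1] != "time_s") {
    stopf("sEMG file must have columns time_s,<muscle>")
  }
  fs <- 1 / stats::median(diff(df$time_s))
  emg_recording(df[[2]], fs, channel = names(df)[2])
}
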