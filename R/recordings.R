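#' Surface EMG recording
#'
#' Container for one muscle channel's samples with its sampling rate. Raw and
#' filtered recordings share this class; amplitudes are in microvolts.
#'
#' @param samples Numeric vector of amplitudes (uV); must be finite.
#' @param fs_hz Sampling rate in Hz (positive scalar).
#' @param channel Muscle label, e.g. `"medial_gastrocnemius"`.
#' @return An object of class `emg_recording` with fields `samples`, `fs_hz`,
#'   `channel`.
#' @examples
#' rec <- emg_recording(rnorm(1500), fs_hz = 1500, channel = "vastus_lateralis")
#' rec
#' @export
emg_recording <- function(samples, fs_hz, channel = "emg") {
  samples <- as.numeric(samples)
  if (!is.numeric(fs_hz) || length(fs_hz) != 1 || !is.finite(fs_hz) ||
      fs_hz <= 0) {
    stopf("'fs_hz' must be a positive scalar")
  }
  if (length(samples) == 0 || !all(is.finite(samples))) {
    stopf("'samples' must be a non-empty finite numeric vector")
  }
  structure(list(samples = samples, fs_hz = fs_hz,
                 channel = as.character(channel)[1]),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> channel '%s': %d samples @ %g Hz (%.2f s)\n",
              x$channel, length(x$samples), x$fs_hz,
              length(x$samples) / x$fs_hz))
  invisible(x)
}

#' Synchronized mechanical recording of a dynamometer trial
#'
#' Time, torque, joint angle and angular velocity traces sampled together;
#' power (W) is derived as torque times angular velocity in rad/s unless
#' supplied.
#'
#' @param time_s Strictly increasing time stamps (s).
#' @param torque_nm Torque (N·m).
#' @param angle_deg Joint angle (degrees).
#' @param velocity_deg_s Angular velocity (deg/s).
#' @param power_w Optional power trace (W); computed with [compute_power()]
#'   when `NULL`.
#' @return An object of class `mech_recording` with fields `time_s`,
#'   `torque_Nm`, `angle_deg`, `velocity_deg_s`, `power_W`.
#' @seealso [compute_power()], [segment_concentric()]
#' @export
mech_recording <- function(time_s, torque_nm, angle_deg, velocity_deg_s,
                           power_w = NULL) {
  n <- length(time_s)
  lens <- c(length(torque_nm), length(angle_deg), length(velocity_deg_s))
  if (any(lens != n)) stopf("all mechanical traces must have equal length")
  if (n < 2 || any(diff(time_s) <= 0)) {
    stopf("'time_s' must be strictly increasing with at least 2 samples")
  }
  if (!all(is.finite(c(time_s, torque_nm, angle_deg, velocity_deg_s)))) {
    stopf("mechanical traces must be finite")
  }
  if (is.null(power_w)) {
    power_w <- compute_power(torque_nm, velocity_deg_s)
  } else if (length(power_w) != n) {
    stopf("'power_w' length must match the other traces")
  }
  structure(list(time_s = as.numeric(time_s),
                 torque_Nm = as.numeric(torque_nm),
                 angle_deg = as.numeric(angle_deg),
                 velocity_deg_s = as.numeric(velocity_deg_s),
                 power_W = as.numeric(power_w)),
            class = "mech_recording")
}

#' @export
print.mech_recording <- function(x, ...) {
  cat(sprintf(
    "<mech_recording> %d samples, %.2f-%.2f s, angle %.1f-%.1f deg, peak power %.1f W\n",
    length(x$time_s), x$time_s[1], x$time_s[length(x$time_s)],
    min(x$angle_deg), max(x$angle_deg), max(x$power_W)))
  invisible(x)
}

#' @export
as.data.frame.mech_recording <- function(x, ...) {
  data.frame(time_s = x$time_s, torque_Nm = x$torque_Nm,
             angle_deg = x$angle_deg, velocity_deg_s = x$velocity_deg_s,
             power_W = x$power_W)
}
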