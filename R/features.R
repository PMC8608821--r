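# Per-contraction sEMG parameters: amplitude (MAV, RMS), spectral (MNF, MDF
# from the periodogram), instantaneous frequency (IMNF, IMDF from the
# analytic signal of the wavelet-denoised record), the Hudgins time-domain
# set (MAV, ZC, SSC, WL), and percent-change normalization to the first two
# repetitions.

#' Amplitude parameters of an sEMG segment
#'
#' Mean absolute value and root mean square; `MAV <= RMS` always
#' (Cauchy-Schwarz).
#'
#' @param samples Numeric vector (>= 2 samples).
#' @return Named numeric vector `c(MAV = ..., RMS = ...)`.
#' @examples
#' amplitude_features(c(1, -1, 2, -2))   # MAV 1.5, RMS 1.581
#' @export
amplitude_features <- function(samples) {
  if (length(samples) < 2) stopf("'samples' must have at least 2 values")
  c(MAV = mean(abs(samples)), RMS = sqrt(mean(samples^2)))
}

#' Spectral parameters of an sEMG segment
#'
#' Mean (power-weighted mean frequency) and median (frequency halving the
#' cumulative power, linearly interpolated between bins) of the single
#' rectangular-window periodogram, restricted to the analysis band.
#'
#' @param samples Numeric vector (>= 64 samples).
#' @param fs_hz Sampling rate in Hz.
#' @param band Analysis band in Hz (default `c(20, 250)`).
#' @return Named numeric vector `c(MNF = ..., MDF = ...)` in Hz.
#' @examples
#' fs <- 1500; t <- (0:1499) / fs
#' spectral_features(sin(2 * pi * 100 * t), fs)   # both ~100 Hz
#' @export
spectral_features <- function(samples, fs_hz, band = c(20, 250)) {
  n <- length(samples)
  if (n < 64) stopf("'samples' must have at least 64 values")
  if (all(samples == 0)) stopf("spectrum undefined for an all-zero segment")
  half <- floor(n / 2)
  P <- Mod(stats::fft(samples))^2
  f <- (seq_len(half)) / n * fs_hz        # skip the DC bin
  P <- P[2:(half + 1)]
  keep <- f >= band[1] & f <= band[2]
  f <- f[keep]
  P <- P[keep]
  if (length(f) < 2 || sum(P) <= 0) {
    stopf("no spectral power inside the analysis band")
  }
  mnf <- sum(f * P) / sum(P)
  cum <- cumsum(P)
  target <- cum[length(cum)] / 2
  i <- which(cum >= target)[1]
  mdf <- if (i == 1) f[1] else {
    f[i - 1] + (target - cum[i - 1]) / P[i] * (f[i] - f[i - 1])
  }
  c(MNF = mnf, MDF = mdf)
}

#' Nominal retained band of the dyadic wavelet denoiser
#'
#' With a 6-level dyadic (db1/Haar) decomposition the retained detail
#' subbands D2-D6 nominally span `fs / 2^(levels + 1)` to `fs / 4` Hz; at
#' 1.5 kHz the lower edge is 11.71875 Hz.
#'
#' @param fs_hz Sampling rate in Hz.
#' @param levels Decomposition depth (default 6).
#' @return Named numeric vector `c(lower = ..., upper = ...)` in Hz.
#' @examples
#' wavelet_retained_band(1500)   # lower edge 11.71875 Hz
#' @export
wavelet_retained_band <- function(fs_hz, levels = 6) {
  if (!is_count(levels)) stopf("'levels' must be a positive integer")
  c(lower = fs_hz / 2^(levels + 1), upper = fs_hz / 4)
}

# Zero-phase gain of the level-j Haar smooth (analysis + synthesis) of the
# shift-invariant multiresolution analysis: prod_{i<=j} cos^2(2^(i-1) pi f/fs).
.haar_smooth_gain <- function(f, fs_hz, level) {
  w <- pi * f / fs_hz
  g <- rep(1, length(f))
  for (j in seq_len(level)) g <- g * cos(2^(j - 1) * w)^2
  g
}

#' Haar (db1) wavelet denoising for instantaneous-frequency analysis
#'
#' Six-level db1 multiresolution analysis in its shift-invariant (stationary)
#' form, applied as its exact zero-phase frequency response: the first detail
#' level (D1) and the final approximation (A6) are discarded and the signal is
#' reconstructed from D2-D6, giving a nominal retained band whose lower edge
#' is `fs / 2^(levels + 1)` (11.71875 Hz at 1.5 kHz). Set
#' `keep_approx = TRUE` to retain A6 as well (drop only D1). Length is
#' preserved.
#'
#' @param samples Numeric vector, length at least `2^levels`.
#' @param fs_hz Sampling rate in Hz.
#' @param levels Decomposition depth (default 6).
#' @param keep_approx Retain the final approximation band (default `FALSE`).
#' @return Denoised numeric vector of the same length.
#' @seealso [wavelet_retained_band()], [instantaneous_features()]
#' @export
wavelet_denoise <- function(samples, fs_hz, levels = 6, keep_approx = FALSE) {
  n <- length(samples)
  if (!is_count(levels)) stopf("'levels' must be a positive integer")
  if (n < 2^levels) {
    stopf("input too short: need at least 2^%d = %d samples", levels,
          2^levels)
  }
  fft_filter(samples, fs_hz, function(f) {
    s1 <- .haar_smooth_gain(f, fs_hz, 1)
    if (keep_approx) s1 else s1 - .haar_smooth_gain(f, fs_hz, levels)
  })
}

#' Instantaneous frequency parameters via the Hilbert transform
#'
#' The instantaneous frequency `f(t) = (1/2pi) dphi/dt` of the analytic
#' signal (central differences of the unwrapped phase), clipped to
#' `[0, fs/2]`; IMNF is its squared-envelope-weighted mean and IMDF its
#' squared-envelope-weighted median (interpolated). Intended for
#' wavelet-denoised segments.
#'
#' @param samples Numeric vector (>= 128 samples), typically the output of
#'   [wavelet_denoise()] restricted to one contraction.
#' @param fs_hz Sampling rate in Hz.
#' @return Named numeric vector `c(IMNF = ..., IMDF = ...)` in Hz.
#' @examples
#' fs <- 1500; t <- (0:1499) / fs
#' instantaneous_features(sin(2 * pi * 100 * t), fs)   # both ~100 Hz
#' @export
instantaneous_features <- function(samples, fs_hz) {
  n <- length(samples)
  if (n < 128) stopf("'samples' must have at least 128 values")
  z <- analytic_signal(samples)
  env <- Mod(z)
  if (max(env) <= 0 || all(env < 1e-12 * max(abs(samples), 1))) {
    stopf("analytic envelope is numerically zero throughout")
  }
  ph <- Arg(z)
  dph <- diff(ph)
  dph <- (dph + pi) %% (2 * pi) - pi          # unwrap increments
  phu <- cumsum(c(ph[1], dph))
  inst <- (phu[3:n] - phu[1:(n - 2)]) / 2 * fs_hz / (2 * pi)
  inst <- pmin(pmax(inst, 0), fs_hz / 2)
  w <- env[2:(n - 1)]^2
  if (sum(w) <= 0) stopf("zero envelope weights")
  imnf <- sum(w * inst) / sum(w)
  o <- order(inst)
  cw <- cumsum(w[o])
  target <- cw[length(cw)] / 2
  i <- which(cw >= target)[1]
  fo <- inst[o]
  imdf <- if (i == 1) fo[1] else {
    fo[i - 1] + (target - cw[i - 1]) / w[o][i] * (fo[i] - fo[i - 1])
  }
  c(IMNF = imnf, IMDF = imdf)
}

#' Hudgins time-domain parameters
#'
#' Mean absolute value, zero crossings (sign changes between consecutive
#' samples with amplitude step exceeding the deadband `eps`), slope sign
#' changes (sign changes of consecutive first differences with at least one
#' difference exceeding `eps`), and waveform length (total variation).
#'
#' @param samples Numeric vector (>= 3 samples).
#' @param eps Amplitude deadband (default 0; real recordings typically need
#'   ~10 uV).
#' @return Named numeric vector `c(MAV = , ZC = , SSC = , WL = )`.
#' @examples
#' hudgins_features(c(1, 3, 2, 4, 1))   # SSC 3, WL 8
#' @export
hudgins_features <- function(samples, eps = 0) {
  n <- length(samples)
  if (n < 3) stopf("'samples' must have at least 3 values")
  if (eps < 0) stopf("'eps' must be non-negative")
  x1 <- samples[-n]
  x2 <- samples[-1]
  zc <- sum(((x1 > 0 & x2 < 0) | (x1 < 0 & x2 > 0)) & abs(x2 - x1) > eps)
  d <- diff(samples)
  d1 <- d[-(n - 1)]
  d2 <- d[-1]
  ssc <- sum(d1 * d2 < 0 & pmax(abs(d1), abs(d2)) > eps)
  c(MAV = mean(abs(samples)), ZC = zc, SSC = ssc, WL = sum(abs(d)))
}

#' Percent change relative to the first repetitions
#'
#' `100 * value / mean(value[1:baseline_reps])`, so the mean of the first
#' `baseline_reps` values maps to 100. Scale-invariant.
#'
#' @param series Per-repetition values.
#' @param baseline_reps Number of initial repetitions in the baseline
#'   (default 2).
#' @return Numeric vector of percentages.
#' @examples
#' percent_change(c(10, 10, 5))   # 100 100 50
#' @export
percent_change <- function(series, baseline_reps = 2) {
  if (length(series) < baseline_reps) {
    stopf("'series' must have at least %d values", baseline_reps)
  }
  base <- mean(series[seq_len(baseline_reps)])
  if (!is.finite(base) || base == 0) {
    stopf("baseline mean must be non-zero")
  }
  100 * series / base
}

#' Per-repetition feature table
#'
#' Computes all nine sEMG parameters for every concentric segment: MAV, RMS,
#' MNF, MDF, ZC, SSC and WL on the 20-250 Hz band-passed signal, IMNF and
#' IMDF on the Haar-wavelet-denoised signal. The raw recording is filtered
#' internally along both paths. Deterministic.
#'
#' @param emg Raw [emg_recording()].
#' @param segments Segment table from [segment_concentric()].
#' @param power_w Optional power trace aligned with the sEMG samples; adds a
#'   `peak_power_W` column.
#' @param eps Deadband for [hudgins_features()].
#' @param band Analysis band for [spectral_features()].
#' @param keep_approx Passed to [wavelet_denoise()].
#' @return Data frame with one row per segment and columns `rep`,
#'   (`peak_power_W`,) `MAV`, `RMS`, `MNF`, `MDF`, `IMNF`, `IMDF`, `ZC`,
#'   `SSC`, `WL`.
#' @export
feature_table <- function(emg, segments, power_w = NULL, eps = 0,
                          band = c(20, 250), keep_approx = FALSE) {
  stopifnot(inherits(emg, "emg_recording"))
  ns <- nrow(segments)
  if (ns == 0) {
    return(data.frame(rep = integer(0)))
  }
  if (any(segments$end_idx > length(emg$samples)) ||
      any(segments$start_idx < 0)) {
    stopf("segments out of range for the sEMG record")
  }
  bp <- bandpass_emg(emg, low_hz = band[1], high_hz = band[2])
  dn <- wavelet_denoise(emg$samples, emg$fs_hz, keep_approx = keep_approx)
  rows <- lapply(seq_len(ns), function(i) {
    idx <- (segments$start_idx[i] + 1L):segments$end_idx[i]
    tryCatch({
      xs <- bp$samples[idx]
      xd <- dn[idx]
      amp <- amplitude_features(xs)
      sp <- spectral_features(xs, emg$fs_hz, band = band)
      inst <- instantaneous_features(xd, emg$fs_hz)
      hud <- hudgins_features(xs, eps = eps)
      row <- data.frame(rep = segments$rep[i], MAV = amp[["MAV"]],
                        RMS = amp[["RMS"]], MNF = sp[["MNF"]],
                        MDF = sp[["MDF"]], IMNF = inst[["IMNF"]],
                        IMDF = inst[["IMDF"]], ZC = hud[["ZC"]],
                        SSC = hud[["SSC"]], WL = hud[["WL"]])
      if (!is.null(power_w)) {
        row$peak_power_W <- max(power_w[idx])
      }
      row
    }, error = function(e) {
      stopf("segment %d: %s", segments$rep[i], conditionMessage(e))
    })
  })
  out <- do.call(rbind, rows)
  first <- intersect(c("rep", "peak_power_W"), names(out))
  out[c(first, setdiff(names(out), first))]
}

#' Percent-change table of features and power
#'
#' Normalizes every numeric column of a [feature_table()] to the mean of its
#' first `baseline_reps` repetitions (appending `_pct`); `peak_power_W`
#' becomes `power_pct`.
#'
#' @param features Data frame from [feature_table()].
#' @param baseline_reps Baseline repetitions (default 2).
#' @return Data frame with `rep` plus `*_pct` columns.
#' @export
percent_table <- function(features, baseline_reps = 2) {
  if (nrow(features) < baseline_reps) {
    stopf("need at least %d repetitions", baseline_reps)
  }
  out <- data.frame(rep = features$rep)
  for (nm in setdiff(names(features), "rep")) {
    pct_name <- if (nm == "peak_power_W") "power_pct" else paste0(nm, "_pct")
    out[[pct_name]] <- percent_change(features[[nm]], baseline_reps)
  }
  out
}
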