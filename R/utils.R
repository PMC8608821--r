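# Internal helpers shared across modules.

# Evaluate `code` with a temporary RNG state; the caller's .Random.seed is
# restored afterwards so library calls never perturb user-level streams.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Deterministic child seed from (master seed, stream id); kept below 2^31 - 1.
derive_seed <- function(master, id) {
  as.integer((as.double(master) %% 1e6L * 1009 + as.double(id) * 9973) %%
               2147483629 + 1)
}

# Small order-sensitive string hash (FNV-flavoured) for config provenance lines
# in persisted files; no cryptographic intent.
config_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# Centered moving average with shrinking windows at the edges
# (adjacent-averaging); window must be odd.
moving_average <- function(x, window) {
  n <- length(x)
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(0L, i - half - 1L)
  hi <- pmin(n, i + half)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

# Butterworth magnitude responses (gain, not transfer function); used for
# zero-phase frequency-domain filtering.
butter_lp_gain <- function(f, fc, order) {
  1 / sqrt(1 + (f / fc)^(2 * order))
}

butter_hp_gain <- function(f, fc, order) {
  g <- numeric(length(f))
  pos <- f > 0
  g[pos] <- 1 / sqrt(1 + (fc / f[pos])^(2 * order))
  g
}

# Apply a real, even frequency-domain gain to a signal (exact zero phase).
# gain_fun receives a vector of non-negative frequencies in Hz.
fft_filter <- function(x, fs_hz, gain_fun) {
  n <- length(x)
  f <- (seq_len(n) - 1) / n * fs_hz
  f <- pmin(f, fs_hz - f)           # fold to [0, fs/2]
  g <- gain_fun(f)
  Re(stats::fft(stats::fft(x) * g, inverse = TRUE)) / n
}

# Analytic signal via the FFT (one-sided spectrum doubling).
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x > 0 && x == round(x)
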