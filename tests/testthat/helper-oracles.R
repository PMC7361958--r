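# Brute-force re-implementations of the five sub-band statistics, written as
# literal loops over the printed formulas so they stay independent of the
# vectorized implementations they check.

oracle_variance <- function(s) {
  n <- length(s)
  mu <- 0
  for (v in s) mu <- mu + v
  mu <- mu / n
  acc <- 0
  for (v in s) acc <- acc + (v - mu)^2
  acc / n
}

oracle_sd <- function(s) sqrt(oracle_variance(s))

oracle_kurtosis <- function(s) {
  n <- length(s)
  mu <- sum(s) / n
  sig2 <- oracle_variance(s)
  acc <- 0
  for (v in s) acc <- acc + ((v - mu)^2 / sig2)^2
  acc / n
}

oracle_entropy <- function(s) {
  acc <- 0
  for (v in s) if (v != 0) acc <- acc + v^2 * log(v^2)
  acc
}

oracle_lbp <- function(s) {
  acc <- 0
  for (v in s) acc <- acc + v^2
  log(acc / length(s))
}

rms <- function(x) sqrt(mean(x^2))

# pure-tone segment helper
tone_segment <- function(freq, fs = 256, duration_s = 10, amp = 1) {
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  eeg_segment(amp * sin(2 * pi * freq * t), fs = fs, duration_s = duration_s)
}

# relative band power from a periodogram over named (low, high] windows
periodogram_band_powers <- function(x, fs, bands) {
  n <- length(x)
  p <- Mod(fft(x))^2
  f <- (seq_len(n) - 1) * fs / n
  keep <- f > 0 & f <= fs / 2
  vapply(bands, function(b) sum(p[keep & f > b[1] & f <= b[2]]), numeric(1))
}
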