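# Shared fixtures, all built in code.

# Pure tone sampled at fs for `dur` seconds.
tone <- function(freq, fs = 2000, dur = 4, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq * (0:(fs * dur - 1)) / fs + phase)
}

# White noise brick-wall band-limited to [0, cutoff] Hz via FFT masking;
# independent of the package's filters.
brickwall_noise <- function(fs = 2000, dur = 10, cutoff = 500, seed = 1) {
  set.seed(seed)
  w <- rnorm(fs * dur)
  W <- fft(w)
  fr <- (seq_along(w) - 1) * fs / length(w)
  W[fr > cutoff & fr < fs - cutoff] <- 0
  Re(fft(W, inverse = TRUE)) / length(W)
}

# Independent periodogram-based spectral oracles (plain FFT, no windowing,
# no shared code with the package's Welch estimator).
oracle_psd <- function(x, fs) {
  n <- length(x)
  sp <- abs(fft(x - mean(x)))^2 / (n * fs)
  nf <- n %/% 2 + 1
  list(freq = (seq_len(nf) - 1) * fs / n, psd = 2 * sp[seq_len(nf)])
}

oracle_band_power <- function(x, fs, lo, hi) {
  p <- oracle_psd(x, fs)
  df <- p$freq[2] - p$freq[1]
  sum(p$psd[p$freq >= lo & p$freq <= hi]) * df
}

oracle_mpf <- function(x, fs) {
  p <- oracle_psd(x, fs)
  sum(p$freq * p$psd) / sum(p$psd)
}

# Three well-separated Gaussian blobs in 11-feature space, labeled -1/0/1.
feature_blobs <- function(n_per_class = 20, sep = 4, sd = 1, seed = 1) {
  set.seed(seed)
  centers <- rbind(rep(-sep, 11), rep(0, 11), rep(sep, 11))
  X <- do.call(rbind, lapply(1:3, function(i)
    matrix(rnorm(n_per_class * 11, centers[i, ], sd), n_per_class, 11,
           byrow = TRUE)))
  colnames(X) <- feature_names()
  list(X = X, y = rep(c(-1, 0, 1), each = n_per_class))
}

# Synthetic ECG built directly in the test (independent of generate_ecg):
# a narrow Gaussian R spike at each requested beat time.
spike_ecg <- function(beat_times, fs = 2000, dur = NULL) {
  dur <- if (is.null(dur)) max(beat_times) + 0.5 else dur
  t <- (0:(fs * dur - 1)) / fs
  x <- numeric(length(t))
  for (b in beat_times) x <- x + exp(-(t - b)^2 / (2 * 0.008^2))
  x
}
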