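#' Welch power spectral density estimate
#'
#' Averaged modified periodogram with a Hann window and 50% segment overlap.
#' All spectral features in the package (MPF, MF, HRV band powers) are computed
#' from this one estimator so they are mutually consistent.
#'
#' @param x numeric vector of samples.
#' @param fs sampling rate in Hz.
#' @param nperseg segment length in samples; shortened to `length(x)` when the
#'   signal is shorter. Default 1024.
#' @param overlap fractional overlap between segments in `[0, 1)`. Default 0.5.
#' @param demean subtract the mean of each segment before windowing. Default
#'   `TRUE`.
#' @return A list with `freq` (Hz, one-sided) and `psd` (power density, units
#'   of `x^2` per Hz) such that `sum(psd) * df` approximates the signal power.
#' @export
#' @examples
#' p <- welch_psd(sin(2 * pi * 50 * seq(0, 1, by = 1 / 1000)), fs = 1000)
#' p$freq[which.max(p$psd)]
welch_psd <- function(x, fs, nperseg = 1024L, overlap = 0.5, demean = TRUE) {
  if (!is.numeric(x) || length(x) < 8L)
    ff_stop_invalid("`x` must be a numeric vector with at least 8 samples")
  check_scalar(fs, "fs", positive = TRUE)
  if (overlap < 0 || overlap >= 1)
    ff_stop_invalid("`overlap` must be in [0, 1)")
  n <- length(x)
  nseg <- min(as.integer(nperseg), n)
  step <- max(1L, as.integer(floor(nseg * (1 - overlap))))
  starts <- seq(1L, n - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))  # Hann
  wpow <- sum(w^2)
  nfreq <- nseg %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    if (demean) seg <- seg - mean(seg)
    spec <- abs(fft(seg * w))^2
    acc <- acc + spec[seq_len(nfreq)]
  }
  psd <- acc / (length(starts) * fs * wpow)
  # one-sided: double everything except DC (and Nyquist when nseg is even)
  mult <- rep(2, nfreq)
  mult[1L] <- 1
  if (nseg %% 2L == 0L) mult[nfreq] <- 1
  list(freq = (seq_len(nfreq) - 1L) * fs / nseg, psd = psd * mult)
}

# Integrated power in [f_lo, f_hi] from a welch_psd() result (rectangle rule).
band_power <- function(psd, f_lo, f_hi) {
  df <- psd$freq[2L] - psd$freq[1L]
  sel <- psd$freq >= f_lo & psd$freq <= f_hi
  sum(psd$psd[sel]) * df
}

# Spectral centroid sum(f * P) / sum(P) of a welch_psd() result.
spectral_centroid <- function(psd) {
  tot <- sum(psd$psd)
  if (tot <= 0) ff_stop_quality("zero total spectral power; centroid undefined")
  sum(psd$freq * psd$psd) / tot
}

# Frequency splitting the cumulative spectral power in half, with linear
# interpolation between bins.
spectral_median <- function(psd) {
  tot <- sum(psd$psd)
  if (tot <= 0) ff_stop_quality("zero total spectral power; median undefined")
  cs <- cumsum(psd$psd)
  half <- tot / 2
  df <- psd$freq[2L] - psd$freq[1L]
  i <- which(cs >= half)[1L]
  prev <- if (i == 1L) 0 else cs[i - 1L]
  frac <- (half - prev) / psd$psd[i]
  # each bin is treated as covering [f - df/2, f + df/2]
  max(0, psd$freq[i] - df / 2) + frac * df
}
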