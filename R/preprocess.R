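#' Zero-phase low-pass filter
#'
#' Butterworth low-pass applied forward and backward (zero phase, so R-peak
#' timing is not distorted). The ECG channel is conventionally filtered at
#' 100 Hz and the sEMG channels at 500 Hz.
#'
#' @param x numeric vector of samples.
#' @param fs sampling rate in Hz.
#' @param cutoff cutoff frequency in Hz, must be below `fs/2`.
#' @param order Butterworth order (default 4; applied twice, so the effective
#'   roll-off is 8th order).
#' @return Filtered samples, same length as `x`.
#' @export
lowpass <- function(x, fs, cutoff, order = 4L) {
  check_scalar(fs, "fs", positive = TRUE)
  check_scalar(cutoff, "cutoff", positive = TRUE)
  if (cutoff >= fs / 2)
    ff_stop_invalid("`cutoff` must be below the Nyquist frequency fs/2")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  filtfilt_sym(bf$b, bf$a, x)
}

# Zero-phase filtering with symmetric signal extension to suppress edge
# transients (signal::filtfilt pads with zeros, which distorts the ends).
# The extension length is sized from the slowest filter pole so the startup
# transient decays below 1e-9 inside the pad.
filtfilt_sym <- function(b, a, x) {
  n <- length(x)
  pad <- 3L * max(length(a), length(b)) * 10L
  if (length(a) > 1L) {
    r <- suppressWarnings(max(Mod(polyroot(rev(a)))))
    if (is.finite(r) && r < 1)
      pad <- max(pad, ceiling(log(1e-9) / log(r)))
  }
  pad <- min(n - 1L, as.integer(pad))
  # even mirror extension: value-continuous and free of the endpoint-offset
  # artifact that an odd extension injects into the passband
  ext <- c(x[(pad + 1L):2L], x, x[(n - 1L):(n - pad)])
  y <- signal::filter(b, a, ext)
  y <- rev(as.numeric(signal::filter(b, a, rev(as.numeric(y)))))
  y[(pad + 1L):(pad + n)]
}

#' Adaptive 50 Hz notch filter
#'
#' Suppresses powerline interference and its harmonics. The default method is
#' a reference-free adaptive noise canceler: for each target frequency an
#' internally generated quadrature pair (cos/sin) is scaled by LMS-adapted
#' weights and subtracted, which tracks slow amplitude/phase drift of the
#' interference. The canceler is run twice (the converged weights of the
#' first pass seed the second) so the adaptation transient does not leak
#' interference into the output. A fixed zero-phase biquad IIR notch is
#' available as a fallback (`method = "iir"`).
#'
#' @param x numeric vector of samples.
#' @param fs sampling rate in Hz.
#' @param f0 fundamental powerline frequency in Hz (default 50).
#' @param harmonics how many multiples of `f0` to cancel (default 3, i.e.
#'   50/100/150 Hz); harmonics at or above `fs/2` are skipped.
#' @param mu LMS step size (default 0.01); larger values adapt faster but
#'   widen the notch.
#' @param method `"lms"` (default) or `"iir"`.
#' @param bandwidth -3 dB notch width in Hz for the IIR fallback (default 1).
#' @return Filtered samples, same length as `x`.
#' @export
adaptive_notch <- function(x, fs, f0 = 50, harmonics = 3L, mu = 0.01,
                           method = c("lms", "iir"), bandwidth = 1) {
  check_scalar(fs, "fs", positive = TRUE)
  check_scalar(f0, "f0", positive = TRUE)
  if (f0 >= fs / 2) ff_stop_invalid("`f0` must be inside (0, fs/2)")
  method <- match.arg(method)
  freqs <- f0 * seq_len(harmonics)
  freqs <- freqs[freqs < fs / 2]
  y <- as.numeric(x)
  for (f in freqs) {
    if (method == "lms") y <- lms_cancel(y, fs, f, mu)
    else y <- iir_notch(y, fs, f, bandwidth)
  }
  y
}

# Single-frequency LMS canceler with quadrature reference; two passes so the
# output carries converged weights from sample one.
lms_cancel <- function(x, fs, f, mu) {
  n <- length(x)
  t <- (seq_len(n) - 1L) / fs
  rc <- cos(2 * pi * f * t)
  rs <- sin(2 * pi * f * t)
  run <- function(w) lms_cancel_core(x, rc, rs, mu, w)
  first <- run(c(0, 0))
  run(first$w)$e
}

# Plain-R LMS loop (small and fast enough at the window sizes used here).
lms_cancel_core <- function(x, rc, rs, mu, w) {
  res <- smo_lms(x, rc, rs, mu, w)  # compiled inner loop
  list(e = res$e, w = res$w)
}

# Zero-phase biquad notch at frequency f with the given -3 dB bandwidth.
iir_notch <- function(x, fs, f, bandwidth) {
  w0 <- 2 * pi * f / fs
  r <- 1 - pi * bandwidth / fs
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1, -2 * r * cos(w0), r^2)
  # normalize passband gain at DC
  g <- sum(a) / sum(b)
  filtfilt_sym(b * g, a, x)
}

#' EMD + wavelet denoising of the initial IMFs
#'
#' Decomposes the signal by empirical mode decomposition, wavelet-thresholds
#' the first `n_initial_imfs` intrinsic mode functions (the components that
#' carry most of the wideband noise at high sampling rates) rather than
#' discarding them, and reconstructs as thresholded-initial-IMFs + remaining
#' IMFs + residue. Output length equals input length.
#'
#' @param x numeric vector of samples.
#' @param n_initial_imfs how many leading IMFs to threshold (default 3).
#' @param wavelet wavelet name for the thresholding step (default `"db4"`).
#' @param level DWT decomposition depth (default 4).
#' @param threshold `"universal"` (default) uses `sigma * sqrt(2 log n)` with
#'   a robust MAD noise estimate; or a numeric threshold value.
#' @param max_imfs maximum number of IMFs to extract (default 10).
#' @return Denoised samples, same length as `x`.
#' @seealso [emd_decompose()], [dwt_denoise()]
#' @export
emd_dwt_denoise <- function(x, n_initial_imfs = 3L, wavelet = "db4",
                            level = 4L, threshold = "universal",
                            max_imfs = 10L) {
  if (length(x) < 2^level)
    ff_stop_invalid("signal shorter than the wavelet decomposition depth allows")
  if (all(x == 0)) return(x)
  dec <- emd_decompose(x, max_imfs = max_imfs)
  k <- min(n_initial_imfs, ncol(dec$imfs))
  out <- dec$residue
  if (ncol(dec$imfs) > 0) {
    for (j in seq_len(ncol(dec$imfs))) {
      imf <- dec$imfs[, j]
      if (j <= k) imf <- dwt_denoise(imf, wavelet = wavelet, level = level,
                                     threshold = threshold)
      out <- out + imf
    }
  }
  out
}

#' Standard preprocessing chain for a signal window
#'
#' Applies the fixed order low-pass -> adaptive notch -> EMD+DWT denoising to
#' every channel of a [signal_record()]: 100 Hz low-pass for the ECG channel,
#' 500 Hz for sEMG channels, then 50 Hz notch (with harmonics) and optional
#' EMD-domain wavelet denoising.
#'
#' @param record a [signal_record()].
#' @param ecg_cutoff,semg_cutoff low-pass cutoffs in Hz (defaults 100 / 500).
#' @param notch_f0 powerline frequency (default 50 Hz).
#' @param harmonics notch harmonics (default 3).
#' @param emd_denoise apply the EMD+DWT stage (default `TRUE`; the stage
#'   dominates preprocessing cost and can be disabled for quick runs).
#' @param n_initial_imfs leading IMFs to threshold (default 3).
#' @return A [signal_record()] with filtered channels; label and ground truth
#'   are carried through.
#' @export
preprocess_record <- function(record, ecg_cutoff = 100, semg_cutoff = 500,
                              notch_f0 = 50, harmonics = 3L,
                              emd_denoise = TRUE, n_initial_imfs = 3L) {
  stopifnot(inherits(record, "signal_record"))
  out <- record
  for (ch in record$channels) {
    cutoff <- if (grepl("ecg", ch, ignore.case = TRUE)) ecg_cutoff else semg_cutoff
    x <- record$samples[[ch]]
    if (cutoff < record$fs / 2) x <- lowpass(x, record$fs, cutoff)
    x <- adaptive_notch(x, record$fs, f0 = notch_f0, harmonics = harmonics)
    if (emd_denoise) x <- emd_dwt_denoise(x, n_initial_imfs = n_initial_imfs)
    out$samples[[ch]] <- x
  }
  out
}
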