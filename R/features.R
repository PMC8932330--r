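#' Canonical feature order
#'
#' The 11 fatigue features in their fixed order: an ECG block (3 HRV
#' features) followed by an sEMG block (4 features per channel, right then
#' left).
#'
#' @return Character vector of the 11 feature column names.
#' @export
feature_names <- function() {
  c("ECG_mean", "ECG_LF", "ECG_LFHF",
    "sEMG_R_IEMG", "sEMG_R_RMS", "sEMG_R_MPF", "sEMG_R_MF",
    "sEMG_L_IEMG", "sEMG_L_RMS", "sEMG_L_MPF", "sEMG_L_MF")
}

#' @rdname feature_names
#' @export
ecg_feature_names <- function() feature_names()[1:3]

#' @rdname feature_names
#' @export
semg_feature_names <- function() feature_names()[4:11]

#' R-peak detection
#'
#' Derivative-energy QRS detector in the Pan-Tompkins tradition: band-pass
#' 5-15 Hz to isolate the QRS complex, differentiate, square, integrate over
#' a 150 ms moving window, threshold adaptively, then refine each detection
#' to the local maximum of the band-passed signal. A 200 ms refractory period
#' is enforced between peaks.
#'
#' @param x preprocessed ECG samples.
#' @param fs sampling rate in Hz.
#' @return Strictly increasing R-peak times in seconds.
#' @export
detect_r_peaks <- function(x, fs) {
  check_scalar(fs, "fs", positive = TRUE)
  if (length(x) < 2 * fs)
    ff_stop_invalid("need at least 2 s of ECG for R-peak detection")
  if (sd(x) < 1e-9)
    ff_stop_quality("flat ECG signal: no detectable R peaks")
  bf <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  xb <- filtfilt_sym(bf$b, bf$a, x)
  der <- c(0, diff(xb)) * fs
  sq <- der^2
  wlen <- max(3L, round(0.150 * fs))
  integ <- as.numeric(stats::filter(sq, rep(1 / wlen, wlen), sides = 2))
  integ[is.na(integ)] <- 0
  thr <- 0.25 * quantile(integ, 0.98)
  if (thr <= 0) ff_stop_quality("no QRS energy above threshold")
  refr <- round(0.200 * fs)
  n <- length(x)
  above <- integ > thr
  # rising edges of the thresholded integrator output mark QRS candidates
  starts <- which(above & !c(FALSE, above[-n]))
  peaks <- integer(0)
  half <- round(0.080 * fs)
  for (s in starts) {
    lo <- s
    hi <- min(n, s + round(0.150 * fs))
    ctr <- lo + which.max(integ[lo:hi]) - 1L
    a <- max(1L, ctr - half)
    b <- min(n, ctr + half)
    pk <- a + which.max(xb[a:b]) - 1L
    if (length(peaks) == 0L || pk - peaks[length(peaks)] >= refr)
      peaks <- c(peaks, pk)
  }
  if (length(peaks) == 0L) ff_stop_quality("no R peaks detected")
  (peaks - 1L) / fs
}

#' RR interval series
#'
#' @param beat_times strictly increasing R-peak times in seconds.
#' @return A list of class `rr_series` with `rr` (interval durations, s),
#'   `M` (interval count) and `beat_times`.
#' @export
rr_series <- function(beat_times) {
  if (length(beat_times) < 2L)
    ff_stop_invalid("need at least 2 beat times to form RR intervals")
  if (any(diff(beat_times) <= 0))
    ff_stop_invalid("beat times must be strictly increasing")
  structure(list(rr = diff(beat_times), M = length(beat_times) - 1L,
                 beat_times = beat_times),
            class = "rr_series")
}

#' Mean RR interval
#'
#' Arithmetic mean of the RR interval durations, `sum(RR_i) / M`.
#'
#' @param rr an [rr_series()] or a numeric vector of RR durations.
#' @return Mean RR interval in seconds.
#' @export
ecg_mean <- function(rr) {
  v <- if (inherits(rr, "rr_series")) rr$rr else as.numeric(rr)
  if (length(v) == 0L) ff_stop_invalid("empty RR series")
  mean(v)
}

#' HRV band powers from the RR tachogram
#'
#' The RR tachogram is interpolated with a cubic spline onto a uniform grid
#' (default 4 Hz), mean-centered and its spectrum estimated with
#' [welch_psd()]. LF is the integrated power in 0.04-0.15 Hz, HF in
#' 0.15-0.40 Hz (the conventional HRV bands).
#'
#' @param rr an [rr_series()].
#' @param resample_fs uniform resampling rate for the tachogram (default 4 Hz).
#' @param lf_band,hf_band band edges in Hz.
#' @param min_intervals minimum RR count required (default 16).
#' @return List with `lf`, `hf` (power, s^2) and `lf_hf` (ratio).
#' @export
hrv_band_powers <- function(rr, resample_fs = 4, lf_band = c(0.04, 0.15),
                            hf_band = c(0.15, 0.40), min_intervals = 16L) {
  stopifnot(inherits(rr, "rr_series"))
  if (rr$M < min_intervals)
    ff_stop_quality(sprintf("too few RR intervals for spectral analysis (%d < %d)",
                            rr$M, min_intervals))
  # tachogram sample i: interval rr[i] attributed to the time of its closing beat
  tt <- rr$beat_times[-1L]
  grid <- seq(tt[1L], tt[length(tt)], by = 1 / resample_fs)
  if (length(grid) < 32L)
    ff_stop_quality("tachogram too short for spectral analysis")
  tach <- spline(tt, rr$rr, xout = grid)$y
  psd <- welch_psd(tach, resample_fs, nperseg = 256L)
  lf <- band_power(psd, lf_band[1L], lf_band[2L])
  hf <- band_power(psd, hf_band[1L], hf_band[2L])
  tot <- band_power(psd, 0, resample_fs / 2)
  if (hf <= 0 || hf < 1e-12 * max(tot, 1e-300))
    ff_stop_quality("HF power is zero: LF/HF ratio undefined")
  list(lf = lf, hf = hf, lf_hf = lf / hf)
}

#' Integrated EMG
#'
#' Time integral of the rectified signal, `sum(|x(k)|) / fs`.
#'
#' @param x sEMG samples (mV).
#' @param fs sampling rate in Hz.
#' @return IEMG in mV*s.
#' @export
iemg <- function(x, fs) {
  check_scalar(fs, "fs", positive = TRUE)
  if (length(x) == 0L) ff_stop_invalid("empty signal")
  sum(abs(x)) / fs
}

#' Root mean square amplitude
#'
#' @param x samples (mV).
#' @return `sqrt(mean(x^2))` in mV.
#' @export
rms <- function(x) {
  if (length(x) == 0L) ff_stop_invalid("empty signal")
  rms_value(x)
}

#' Mean power frequency
#'
#' Power-weighted spectral centroid `sum(f * P(f)) / sum(P(f))` over the full
#' band, with `P` the Welch power spectral density.
#'
#' @param x samples.
#' @param fs sampling rate in Hz.
#' @param nperseg Welch segment length (default 1024).
#' @return MPF in Hz.
#' @export
mpf <- function(x, fs, nperseg = 1024L) {
  if (length(x) < 256L) ff_stop_invalid("need >= 256 samples for MPF")
  spectral_centroid(welch_psd(x, fs, nperseg = nperseg))
}

#' Median frequency
#'
#' The frequency below which half of the total spectral power lies, with
#' linear interpolation between spectral bins.
#'
#' @inheritParams mpf
#' @return MF in Hz.
#' @export
mf <- function(x, fs, nperseg = 1024L) {
  if (length(x) < 256L) ff_stop_invalid("need >= 256 samples for MF")
  spectral_median(welch_psd(x, fs, nperseg = nperseg))
}

#' Extract the 11-feature fatigue vector from a window
#'
#' Computes, in the fixed order of [feature_names()]: mean RR interval, LF
#' band power and LF/HF ratio from the ECG channel, then IEMG, RMS, MPF and
#' MF for each sEMG channel (right, then left). The window label is carried
#' through.
#'
#' @param record a preprocessed three-channel [signal_record()] with channels
#'   `ecg`, `semg_r`, `semg_l`.
#' @param min_intervals minimum RR count for the HRV features (default 16).
#' @return Named numeric vector of length 11 with attributes `label`.
#' @export
extract_features <- function(record, min_intervals = 16L) {
  stopifnot(inherits(record, "signal_record"))
  need <- c("ecg", "semg_r", "semg_l")
  if (!all(need %in% record$channels))
    ff_stop_invalid(sprintf("record must contain channels %s",
                            paste(need, collapse = ", ")))
  fs <- record$fs
  beats <- tryCatch(detect_r_peaks(record$samples$ecg, fs),
                    fatiguefuse_quality_error = function(e)
                      ff_stop_quality(paste0("ECG channel: ", conditionMessage(e))))
  rr <- rr_series(beats)
  hrv <- tryCatch(hrv_band_powers(rr, min_intervals = min_intervals),
                  fatiguefuse_quality_error = function(e)
                    ff_stop_quality(paste0("ECG channel: ", conditionMessage(e))))
  semg_block <- function(ch) {
    x <- record$samples[[ch]]
    tryCatch(c(iemg(x, fs), rms(x), mpf(x, fs), mf(x, fs)),
             fatiguefuse_error = function(e)
               ff_stop_quality(paste0(ch, " channel: ", conditionMessage(e))))
  }
  out <- c(ecg_mean(rr), hrv$lf, hrv$lf_hf, semg_block("semg_r"),
           semg_block("semg_l"))
  names(out) <- feature_names()
  attr(out, "label") <- record$label
  out
}

#' Build a feature table from a list of windows
#'
#' @param records list of [signal_record()] windows.
#' @param ... passed to [extract_features()].
#' @return A data.frame with the 11 feature columns of [feature_names()],
#'   plus `label` and `window_id`.
#' @export
extract_feature_table <- function(records, ...) {
  rows <- lapply(seq_along(records), function(i) {
    fv <- extract_features(records[[i]], ...)
    df <- as.data.frame(as.list(fv))
    df$label <- attr(fv, "label")
    df$window_id <- i
    df
  })
  do.call(rbind, rows)
}
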