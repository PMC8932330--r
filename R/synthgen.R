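#' Multichannel signal window
#'
#' Container for one labeled window of synchronously sampled signals. All
#' channels share a sampling rate and length.
#'
#' @param samples named list of equal-length numeric vectors (mV); canonical
#'   channel names are `ecg`, `semg_r` (semitendinosus, right leg) and
#'   `semg_l` (tibialis anterior, left leg).
#' @param fs sampling rate in Hz.
#' @param label fatigue state: -1 (relaxed), 0 (transition), 1 (tired), or
#'   `NA` when unlabeled.
#' @param ground_truth optional list recording the generating parameters and,
#'   for ECG, the true R-peak times (`beat_times`) and the noise-free signal
#'   (`clean`).
#' @return An object of class `signal_record`.
#' @export
signal_record <- function(samples, fs, label = NA, ground_truth = NULL) {
  if (!is.list(samples) || length(samples) < 1L || is.null(names(samples)))
    ff_stop_invalid("`samples` must be a named list of numeric vectors")
  lens <- vapply(samples, length, integer(1))
  if (length(unique(lens)) != 1L)
    ff_stop_invalid("all channels must have the same length")
  check_scalar(fs, "fs", positive = TRUE)
  if (!is.na(label) && !label %in% c(-1, 0, 1))
    ff_stop_invalid("`label` must be -1, 0, 1 or NA")
  structure(
    list(samples = lapply(samples, as.numeric), fs = fs,
         channels = names(samples), label = label, ground_truth = ground_truth),
    class = "signal_record"
  )
}

#' @export
print.signal_record <- function(x, ...) {
  n <- length(x$samples[[1L]])
  cat(sprintf("<signal_record> %d channel(s) [%s], %d samples @ %g Hz (%.1f s), label: %s\n",
              length(x$channels), paste(x$channels, collapse = ", "),
              n, x$fs, n / x$fs, ifelse(is.na(x$label), "none", x$label)))
  invisible(x)
}

#' Per-state synthesis parameters
#'
#' Bundles everything needed to synthesize one window of ECG and sEMG for a
#' given fatigue state. Defaults come from [state_template()] for the chosen
#' state; any field can be overridden.
#'
#' The state templates encode the qualitative physiology of progressive
#' fatigue: the RR interval shortens (heart rate rises), the sympathetic
#' low-frequency RR modulation grows while vagal high-frequency modulation
#' shrinks (LF/HF increases), sEMG amplitude grows (motor-unit recruitment)
#' and the sEMG spectrum compresses towards low frequencies (conduction
#' velocity drop), so that IEMG/RMS increase and MPF/MF decrease with fatigue.
#'
#' @param state fatigue state in `{-1, 0, 1}`.
#' @param duration_s window length in seconds (> 0).
#' @param fs sampling rate in Hz (default 2000).
#' @param rr_mean_s mean RR interval (s).
#' @param lf_amp,hf_amp RR modulation amplitudes (s) at `lf_freq` / `hf_freq`.
#' @param lf_freq,hf_freq RR modulation frequencies (Hz); defaults 0.1 / 0.25,
#'   i.e. the centers of the conventional HRV LF and HF bands.
#' @param semg_gain RMS amplitude (mV) of the clean sEMG component.
#' @param semg_spectral_center center (Hz) of the sEMG band shaping, which
#'   sets the window's MPF/MF.
#' @param powerline_amp 50 Hz interference amplitude (mV).
#' @param baseline_amp baseline-wander amplitude (mV).
#' @param ecg_bleed_gain gain of ECG bleed-through into the sEMG channels.
#' @param noise_sd wideband Gaussian noise SD (mV).
#' @param seed integer seed; generation is bit-reproducible for a fixed seed.
#' @return A list of class `synth_params`.
#' @export
synth_params <- function(state, duration_s = 30, fs = 2000,
                         rr_mean_s = NULL, lf_amp = NULL, hf_amp = NULL,
                         lf_freq = 0.1, hf_freq = 0.25,
                         semg_gain = NULL, semg_spectral_center = NULL,
                         powerline_amp = 0.05, baseline_amp = 0.10,
                         ecg_bleed_gain = 0.05, noise_sd = 0.02,
                         seed = NULL) {
  if (!state %in% c(-1, 0, 1))
    ff_stop_invalid("`state` must be -1 (relaxed), 0 (transition) or 1 (tired)")
  check_scalar(duration_s, "duration_s", positive = TRUE)
  check_scalar(fs, "fs", positive = TRUE)
  tmpl <- state_template(state)
  p <- list(
    state = state, duration_s = duration_s, fs = fs,
    rr_mean_s = rr_mean_s %||% tmpl$rr_mean_s,
    lf_amp = lf_amp %||% tmpl$lf_amp, hf_amp = hf_amp %||% tmpl$hf_amp,
    lf_freq = lf_freq, hf_freq = hf_freq,
    semg_gain = semg_gain %||% tmpl$semg_gain,
    semg_spectral_center = semg_spectral_center %||% tmpl$semg_spectral_center,
    powerline_amp = powerline_amp, baseline_amp = baseline_amp,
    ecg_bleed_gain = ecg_bleed_gain, noise_sd = noise_sd, seed = seed
  )
  check_scalar(p$rr_mean_s, "rr_mean_s", positive = TRUE)
  check_scalar(p$semg_gain, "semg_gain", positive = TRUE)
  if (p$semg_spectral_center >= fs / 2)
    ff_stop_invalid("`semg_spectral_center` must be below the Nyquist frequency fs/2")
  n <- duration_s * fs
  if (abs(n - round(n)) > 1e-9)
    ff_stop_invalid("`duration_s * fs` must be an integer sample count")
  structure(p, class = "synth_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' State templates for the synthetic generator
#'
#' Default per-state parameter values used by [synth_params()] and
#' [generate_dataset()]. The two modalities are deliberately complementary:
#' the ECG block separates the relaxed state sharply from the other two
#' (large RR-mean gap) but barely separates transition from tired, while the
#' sEMG block separates the tired state sharply (amplitude jump plus spectral
#' compression) but barely separates relaxed from transition — so neither
#' modality alone resolves all three states, and their fusion does.
#'
#' @param state fatigue state in `{-1, 0, 1}`.
#' @return A named list of template values for that state.
#' @export
state_template <- function(state) {
  i <- match(state, c(-1, 0, 1))
  if (is.na(i)) ff_stop_invalid("`state` must be -1, 0 or 1")
  list(
    rr_mean_s            = c(0.95, 0.76, 0.72)[i],
    lf_amp               = c(0.020, 0.030, 0.035)[i],
    hf_amp               = c(0.030, 0.014, 0.012)[i],
    semg_gain            = c(0.50, 0.62, 0.90)[i],
    semg_spectral_center = c(120, 108, 85)[i]
  )
}

#' Per-window jitter used by [generate_dataset()]
#'
#' Standard deviations of the per-window Gaussian perturbations applied to the
#' state templates, producing the partial between-state overlap (especially
#' for the transition state) seen in real fatigue data.
#'
#' @return Named list of jitter magnitudes: `rr_mean_s` (additive, s),
#'   `semg_spectral_center` (additive, Hz), `lf_amp`, `hf_amp`, `semg_gain`
#'   (multiplicative, log-scale SD).
#' @export
jitter_profile <- function() {
  list(rr_mean_s = 0.05, lf_amp = 0.25, hf_amp = 0.25,
       semg_gain = 0.20, semg_spectral_center = 10)
}

# Fixed PQRST template: Gaussian bumps at offsets (s) relative to the R peak.
ecg_beat_components <- function() {
  data.frame(
    offset = c(-0.20, -0.025, 0.0, 0.025, 0.25),
    amp    = c(0.12, -0.12, 1.0, -0.18, 0.30),
    width  = c(0.025, 0.008, 0.008, 0.010, 0.050)
  )
}

#' Generate a synthetic ECG window
#'
#' Places a fixed sum-of-Gaussians PQRST template at beat times whose RR
#' series is `rr_mean_s + lf_amp * sin(2*pi*lf_freq*t) + hf_amp *
#' sin(2*pi*hf_freq*t)`, then adds powerline, baseline-wander and wideband
#' noise contaminants. The deterministic sinusoidal RR modulation makes the
#' LF/HF ground truth analytic.
#'
#' @param params a [synth_params()] object.
#' @return A single-channel [signal_record()] whose `ground_truth` holds the
#'   true R-peak times (`beat_times`), the true RR series (`rr`), the
#'   noise-free waveform (`clean`) and the generating parameters.
#' @export
generate_ecg <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  with_seed(params$seed, {
    n <- round(params$duration_s * params$fs)
    t <- (seq_len(n) - 1L) / params$fs
    # beat placement: next beat follows at the RR interval evaluated at the
    # current beat time
    beats <- numeric(0)
    bt <- 0.3
    while (bt < params$duration_s - 0.05) {
      beats <- c(beats, bt)
      rr <- params$rr_mean_s +
        params$lf_amp * sin(2 * pi * params$lf_freq * bt) +
        params$hf_amp * sin(2 * pi * params$hf_freq * bt)
      if (rr <= 0.25) rr <- 0.25  # physiological floor
      bt <- bt + rr
    }
    if (length(beats) < 2L)
      ff_stop_invalid("window too short for the requested RR interval")
    comp <- ecg_beat_components()
    clean <- numeric(n)
    half <- ceiling(0.45 * params$fs)
    for (b in beats) {
      ctr <- round(b * params$fs) + 1L
      idx <- max(1L, ctr - half):min(n, ctr + half)
      tt <- t[idx] - b
      for (k in seq_len(nrow(comp)))
        clean[idx] <- clean[idx] +
          comp$amp[k] * exp(-(tt - comp$offset[k])^2 / (2 * comp$width[k]^2))
    }
    x <- clean +
      params$powerline_amp * sin(2 * pi * 50 * t + runif(1, 0, 2 * pi)) +
      params$baseline_amp * sin(2 * pi * 0.3 * t + runif(1, 0, 2 * pi)) +
      rnorm(n, sd = params$noise_sd)
    signal_record(
      list(ecg = x), params$fs, label = params$state,
      ground_truth = list(beat_times = beats, rr = diff(beats),
                          clean = clean, params = params)
    )
  })
}

#' Generate a synthetic sEMG window
#'
#' The clean component is Gaussian noise band-shaped by a 4th-order
#' Butterworth bandpass centered at `semg_spectral_center` (edges at 0.5x and
#' 1.5x the center) and scaled to RMS `semg_gain`; contaminants are optional
#' ECG bleed-through, 50 Hz powerline, low-frequency baseline wander and
#' wideband noise. Lowering the spectral center compresses MPF/MF, the
#' classical spectral signature of muscle fatigue.
#'
#' @param params a [synth_params()] object.
#' @param ecg_bleed optional ECG [signal_record()] whose waveform leaks into
#'   the sEMG channel with gain `params$ecg_bleed_gain`.
#' @param channel name for the generated channel (default `"semg"`).
#' @return A single-channel [signal_record()]; `ground_truth$clean` holds the
#'   contaminant-free component.
#' @export
generate_semg <- function(params, ecg_bleed = NULL, channel = "semg") {
  stopifnot(inherits(params, "synth_params"))
  fc <- params$semg_spectral_center
  if (fc >= params$fs / 2)
    ff_stop_invalid("`semg_spectral_center` must be below fs/2")
  with_seed(params$seed, {
    n <- round(params$duration_s * params$fs)
    t <- (seq_len(n) - 1L) / params$fs
    edges <- c(0.5 * fc, min(1.5 * fc, 0.95 * params$fs / 2)) / (params$fs / 2)
    bp <- signal::butter(4, edges, type = "pass")
    clean <- as.numeric(signal::filter(bp, rnorm(n)))
    clean <- clean * (params$semg_gain / rms_value(clean))
    x <- clean +
      params$powerline_amp * sin(2 * pi * 50 * t + runif(1, 0, 2 * pi)) +
      params$baseline_amp * sin(2 * pi * 0.25 * t + runif(1, 0, 2 * pi)) +
      rnorm(n, sd = params$noise_sd)
    if (!is.null(ecg_bleed)) {
      stopifnot(inherits(ecg_bleed, "signal_record"))
      x <- x + params$ecg_bleed_gain * ecg_bleed$samples[[1L]]
    }
    out <- list(x)
    names(out) <- channel
    signal_record(out, params$fs, label = params$state,
                  ground_truth = list(clean = clean, params = params))
  })
}

# Apply per-window Gaussian jitter to a state's template parameters.
jitter_params <- function(params, jitter) {
  p <- unclass(params)
  p$rr_mean_s <- max(0.4, p$rr_mean_s + rnorm(1, sd = jitter$rr_mean_s))
  p$lf_amp <- p$lf_amp * exp(rnorm(1, sd = jitter$lf_amp))
  p$hf_amp <- p$hf_amp * exp(rnorm(1, sd = jitter$hf_amp))
  p$semg_gain <- p$semg_gain * exp(rnorm(1, sd = jitter$semg_gain))
  p$semg_spectral_center <- min(max(40, p$semg_spectral_center +
                                      rnorm(1, sd = jitter$semg_spectral_center)),
                                0.45 * p$fs)
  class(p) <- "synth_params"
  p
}

#' Generate a three-channel labeled window
#'
#' Combines [generate_ecg()] and two independent [generate_semg()] channels
#' (right semitendinosus, left tibialis anterior) with ECG bleed-through into
#' both sEMG channels.
#'
#' @param params a [synth_params()] object (its `seed` drives all channels).
#' @return A three-channel [signal_record()] with channels
#'   `ecg`, `semg_r`, `semg_l`.
#' @export
generate_window <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  seeds <- derive_seeds(params$seed %||% 0, 3)
  pe <- params; pe$seed <- seeds[1L]
  ecg <- generate_ecg(pe)
  pr <- params; pr$seed <- seeds[2L]
  semg_r <- generate_semg(pr, ecg_bleed = ecg, channel = "semg_r")
  pl <- params; pl$seed <- seeds[3L]
  semg_l <- generate_semg(pl, ecg_bleed = ecg, channel = "semg_l")
  signal_record(
    list(ecg = ecg$samples$ecg, semg_r = semg_r$samples$semg_r,
         semg_l = semg_l$samples$semg_l),
    params$fs, label = params$state,
    ground_truth = list(beat_times = ecg$ground_truth$beat_times,
                        rr = ecg$ground_truth$rr,
                        clean = list(ecg = ecg$ground_truth$clean,
                                     semg_r = semg_r$ground_truth$clean,
                                     semg_l = semg_l$ground_truth$clean),
                        params = params)
  )
}

#' Generate a balanced labeled dataset of windows
#'
#' Produces `n_per_state` windows for each of the three fatigue states, with
#' per-window parameters jittered around the state templates so the
#' transition state partially overlaps its neighbours. Fully reproducible for
#' a fixed seed.
#'
#' @param n_per_state windows per state (>= 1); the study-scale default is
#'   400 per state (1200 windows total).
#' @param window_s window length in seconds (default 30, the labeling
#'   cadence).
#' @param fs sampling rate in Hz (default 2000).
#' @param jitter jitter magnitudes, see [jitter_profile()].
#' @param seed integer seed.
#' @param ... further arguments passed to [synth_params()] (contaminant
#'   levels etc.).
#' @return A list of three-channel [signal_record()] objects, labels in block
#'   order (-1, then 0, then 1).
#' @export
generate_dataset <- function(n_per_state = 400, window_s = 30, fs = 2000,
                             jitter = jitter_profile(), seed = NULL, ...) {
  if (n_per_state < 1) ff_stop_invalid("`n_per_state` must be >= 1")
  labels <- rep(c(-1, 0, 1), each = n_per_state)
  seeds <- derive_seeds(seed %||% 0, length(labels))
  with_seed(seed, {
    lapply(seq_along(labels), function(i) {
      base <- synth_params(labels[i], duration_s = window_s, fs = fs, ...)
      p <- jitter_params(base, jitter)
      p$seed <- seeds[i]
      generate_window(p)
    })
  })
}
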