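fs <- 2000

test_that("IEMG matches its closed form", {
  expect_equal(iemg(rep(2, 2000), 2000), 2.0)
  expect_equal(iemg(numeric(100), 2000), 0)
  expect_equal(iemg(3, 2000), 0.0015)
  expect_error(iemg(numeric(0), 2000), class = "fatiguefuse_invalid_parameter")
})

test_that("RMS matches its closed form and a brute-force oracle", {
  s <- tone(50, fs, dur = 1, amp = 2)  # whole periods
  expect_equal(rms(s), 2 / sqrt(2), tolerance = 1e-3)
  expect_equal(rms(rep(-3, 10)), 3)
  set.seed(1)
  x <- rnorm(10)
  expect_equal(rms(x), sqrt(mean(x^2)), tolerance = 1e-12)
  expect_error(rms(numeric(0)), class = "fatiguefuse_invalid_parameter")
})

test_that("MPF matches line-spectrum and flat-spectrum oracles", {
  expect_equal(mpf(tone(80, fs), fs), 80, tolerance = 1 / 80)
  expect_equal(mpf(tone(40, fs) + tone(120, fs), fs), 80, tolerance = 1 / 80)
  wb <- brickwall_noise(fs, 10, 500, seed = 2)
  expect_equal(mpf(wb, fs), 250, tolerance = 0.05)
  expect_error(mpf(numeric(300), fs), class = "fatiguefuse_quality_error")
})

test_that("MF matches line-spectrum, flat-spectrum and cumulative-sum oracles", {
  expect_equal(mf(tone(80, fs), fs), 80, tolerance = 1 / 80)
  wb <- brickwall_noise(fs, 10, 500, seed = 3)
  expect_equal(mf(wb, fs), 250, tolerance = 0.05)
  # equal lines at 40 and 120 Hz: the median is degenerate (half the power
  # lies at each line), so any crossing inside [40, 120] is correct
  v <- mf(tone(40, fs) + tone(120, fs), fs)
  expect_gte(v, 40)
  expect_lte(v, 120)
  # non-degenerate two-line case: 2/3 of the power below 50 Hz pins the
  # median to the 40 Hz line; cross-check against the periodogram oracle
  x2 <- tone(40, fs, amp = sqrt(2)) + tone(120, fs)
  p <- oracle_psd(x2, fs)
  cs <- cumsum(p$psd) / sum(p$psd)
  oracle_mf <- p$freq[which(cs >= 0.5)[1]]
  expect_equal(mf(x2, fs), oracle_mf, tolerance = 0.05)
})

test_that("mean RR interval is the arithmetic mean", {
  expect_identical(ecg_mean(c(0.8, 1.0, 1.2)), 1.0)
  expect_identical(ecg_mean(0.75), 0.75)
  expect_error(ecg_mean(numeric(0)), class = "fatiguefuse_invalid_parameter")
})

test_that("HRV band powers recover an analytic tachogram", {
  # beats placed so the RR series is 1.0 + 0.05 sin(2 pi 0.1 t), > 300 s
  bt <- 0
  while (bt[length(bt)] < 320) {
    t_now <- bt[length(bt)]
    bt <- c(bt, t_now + 1.0 + 0.05 * sin(2 * pi * 0.1 * t_now))
  }
  h <- hrv_band_powers(rr_series(bt))
  expect_equal(h$lf, 0.05^2 / 2, tolerance = 0.10)
  expect_gt(h$lf_hf, 10)
  # modulation at 0.3 Hz only -> HF dominated
  bt2 <- 0
  while (bt2[length(bt2)] < 320) {
    t_now <- bt2[length(bt2)]
    bt2 <- c(bt2, t_now + 1.0 + 0.05 * sin(2 * pi * 0.3 * t_now))
  }
  expect_lt(hrv_band_powers(rr_series(bt2))$lf_hf, 0.1)
  # constant tachogram has no band power at all
  expect_error(hrv_band_powers(rr_series(seq(0, 300, by = 1))),
               class = "fatiguefuse_quality_error")
  expect_error(hrv_band_powers(rr_series(c(0, 1, 2))),
               class = "fatiguefuse_quality_error")
})

test_that("R-peak detection recovers known beat patterns", {
  # constant RR 1.0 s over 60 s, built independently of the generator
  bt <- seq(0.5, 59.5, by = 1.0)
  det <- detect_r_peaks(spike_ecg(bt, fs, dur = 60), fs)
  expect_equal(length(det), length(bt))
  expect_lt(max(abs(det - bt)), 0.020)
  # alternating RR 0.8 / 1.2 s
  bt2 <- 0.5 + cumsum(c(0, rep(c(0.8, 1.2), 25)))
  det2 <- detect_r_peaks(spike_ecg(bt2, fs), fs)
  expect_equal(length(det2), length(bt2))
  rr_det <- diff(det2)
  expect_lt(max(abs(rr_det - rep(c(0.8, 1.2), 25))), 0.020)
  expect_error(detect_r_peaks(numeric(10 * fs), fs),
               class = "fatiguefuse_quality_error")
  # refractory constraint
  expect_true(all(diff(det2) >= 0.2))
})

test_that("the 11-feature vector has the frozen order and sane values", {
  w <- generate_window(synth_params(-1, duration_s = 30, seed = 31))
  fv <- extract_features(w)
  expect_identical(names(fv), c(
    "ECG_mean", "ECG_LF", "ECG_LFHF",
    "sEMG_R_IEMG", "sEMG_R_RMS", "sEMG_R_MPF", "sEMG_R_MF",
    "sEMG_L_IEMG", "sEMG_L_RMS", "sEMG_L_MPF", "sEMG_L_MF"))
  expect_true(all(is.finite(fv)))
  expect_identical(attr(fv, "label"), -1)
  expect_true(all(fv[c("sEMG_R_MPF", "sEMG_R_MF", "sEMG_L_MPF", "sEMG_L_MF")] > 0))
  expect_true(all(fv[c("sEMG_R_MPF", "sEMG_R_MF")] < w$fs / 2))
})

test_that("flat ECG in a window raises a quality error naming the channel", {
  w <- generate_window(synth_params(0, duration_s = 30, seed = 32))
  w$samples$ecg <- numeric(length(w$samples$ecg))
  expect_error(extract_features(w), regexp = "ECG",
               class = "fatiguefuse_quality_error")
})

test_that("amplitude scaling moves IEMG/RMS linearly but not MPF/MF", {
  w <- generate_window(synth_params(1, duration_s = 30, seed = 33))
  fv1 <- extract_features(w)
  w2 <- w
  w2$samples$semg_r <- 3 * w2$samples$semg_r
  fv2 <- extract_features(w2)
  expect_equal(fv2[["sEMG_R_IEMG"]], 3 * fv1[["sEMG_R_IEMG"]], tolerance = 1e-10)
  expect_equal(fv2[["sEMG_R_RMS"]], 3 * fv1[["sEMG_R_RMS"]], tolerance = 1e-10)
  expect_lt(abs(fv2[["sEMG_R_MPF"]] - fv1[["sEMG_R_MPF"]]), 0.5)
  expect_lt(abs(fv2[["sEMG_R_MF"]] - fv1[["sEMG_R_MF"]]), 0.5)
  # untouched channel identical
  expect_identical(fv2[["sEMG_L_MPF"]], fv1[["sEMG_L_MPF"]])
})

test_that("spectral features are stable under circular time shifts", {
  p <- synth_params(0, duration_s = 10, seed = 34)
  x <- generate_semg(p)$samples$semg
  shift <- 4321
  xs <- c(x[(shift + 1):length(x)], x[1:shift])
  for (f in list(mpf, mf)) {
    expect_equal(f(xs, fs), f(x, fs), tolerance = 0.01)
  }
})
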