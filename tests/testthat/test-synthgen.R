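test_that("constant-RR ECG places the expected beats with exact RR", {
  p <- synth_params(-1, duration_s = 60, rr_mean_s = 1.0, lf_amp = 0,
                    hf_amp = 0, powerline_amp = 0, baseline_amp = 0,
                    noise_sd = 0, seed = 1)
  e <- generate_ecg(p)
  bt <- e$ground_truth$beat_times
  expect_true(abs(length(bt) - 60) <= 1)
  expect_true(all(abs(diff(bt) - 1.0) < 1e-9))
  expect_length(e$samples$ecg, 60 * 2000)
})

test_that("LF-only RR modulation yields LF-dominated tachogram power", {
  p <- synth_params(0, duration_s = 300, rr_mean_s = 1.0, lf_amp = 0.05,
                    hf_amp = 0, noise_sd = 0, seed = 2)
  e <- generate_ecg(p)
  bt <- e$ground_truth$beat_times
  # independent oracle: linear-interpolate the true RR series to 4 Hz and
  # integrate the raw periodogram over the HRV bands
  tt <- bt[-1]
  grid <- seq(tt[1], tt[length(tt)], by = 0.25)
  tach <- approx(tt, diff(bt), xout = grid)$y
  lf <- oracle_band_power(tach, 4, 0.04, 0.15)
  hf <- oracle_band_power(tach, 4, 0.15, 0.40)
  expect_gt(lf, 20 * hf)
  expect_equal(lf, 0.05^2 / 2, tolerance = 0.15)
})

test_that("generators are bit-identical under a fixed seed", {
  p <- synth_params(1, duration_s = 5, seed = 99)
  expect_identical(generate_ecg(p)$samples, generate_ecg(p)$samples)
  expect_identical(generate_semg(p)$samples, generate_semg(p)$samples)
  w1 <- generate_window(p)
  w2 <- generate_window(p)
  expect_identical(w1$samples, w2$samples)
})

test_that("invalid synthesis parameters are rejected", {
  expect_error(synth_params(-1, duration_s = -3), class = "fatiguefuse_invalid_parameter")
  expect_error(synth_params(2), class = "fatiguefuse_invalid_parameter")
  expect_error(synth_params(0, semg_spectral_center = 1500, fs = 2000),
               class = "fatiguefuse_invalid_parameter")
  expect_error(synth_params(0, duration_s = 1.00017, fs = 2000),
               class = "fatiguefuse_invalid_parameter")
})

test_that("sEMG gain scales the clean component linearly", {
  p1 <- synth_params(0, duration_s = 5, semg_gain = 0.5, seed = 7)
  p2 <- synth_params(0, duration_s = 5, semg_gain = 1.0, seed = 7)
  s1 <- generate_semg(p1)$ground_truth$clean
  s2 <- generate_semg(p2)$ground_truth$clean
  expect_equal(sqrt(mean(s2^2)) / sqrt(mean(s1^2)), 2, tolerance = 1e-10)
})

test_that("lower sEMG spectral center lowers the oracle MPF", {
  p_hi <- synth_params(0, duration_s = 5, semg_spectral_center = 120, seed = 8)
  p_lo <- synth_params(0, duration_s = 5, semg_spectral_center = 80, seed = 8)
  mpf_hi <- oracle_mpf(generate_semg(p_hi)$ground_truth$clean, 2000)
  mpf_lo <- oracle_mpf(generate_semg(p_lo)$ground_truth$clean, 2000)
  expect_lt(mpf_lo, mpf_hi - 20)
})

test_that("contaminant-free sEMG has negligible out-of-band power", {
  p <- synth_params(0, duration_s = 5, semg_spectral_center = 100,
                    powerline_amp = 0, baseline_amp = 0, noise_sd = 0, seed = 9)
  x <- generate_semg(p)$samples$semg
  total <- oracle_band_power(x, 2000, 0, 1000)
  outside <- oracle_band_power(x, 2000, 320, 1000)  # > 2x the upper band edge
  expect_lt(outside / total, 0.01)
})

test_that("datasets are balanced, labeled and reproducible", {
  d1 <- generate_dataset(1, window_s = 2, seed = 5)
  expect_length(d1, 3)
  expect_equal(vapply(d1, `[[`, numeric(1), "label"), c(-1, 0, 1))
  d2 <- generate_dataset(2, window_s = 2, seed = 6)
  d3 <- generate_dataset(2, window_s = 2, seed = 6)
  expect_identical(lapply(d2, `[[`, "samples"), lapply(d3, `[[`, "samples"))
  expect_equal(vapply(d2, `[[`, numeric(1), "label"), rep(c(-1, 0, 1), each = 2))
})

test_that("state templates impose the fatigue trends on generated batches", {
  recs <- generate_dataset(30, window_s = 4, seed = 42)
  labels <- vapply(recs, `[[`, numeric(1), "label")
  clean_rms <- vapply(recs, function(r) sqrt(mean(r$ground_truth$clean$semg_r^2)),
                      numeric(1))
  clean_mpf <- vapply(recs, function(r) oracle_mpf(r$ground_truth$clean$semg_r, 2000),
                      numeric(1))
  rr_mean <- vapply(recs, function(r) mean(r$ground_truth$rr), numeric(1))
  m <- function(v, l) mean(v[labels == l])
  # relaxed -> tired: amplitude grows, spectrum compresses, RR shortens
  expect_true(m(clean_rms, -1) < m(clean_rms, 0) && m(clean_rms, 0) < m(clean_rms, 1))
  expect_true(m(clean_mpf, -1) > m(clean_mpf, 0) && m(clean_mpf, 0) > m(clean_mpf, 1))
  expect_true(m(rr_mean, -1) > m(rr_mean, 0) && m(rr_mean, 0) > m(rr_mean, 1))
})

test_that("stored R-peak times match peaks of the clean ECG within 1 sample", {
  p <- synth_params(0, duration_s = 20, seed = 13)
  e <- generate_ecg(p)
  clean <- e$ground_truth$clean
  fs <- 2000
  for (b in e$ground_truth$beat_times) {
    ctr <- round(b * fs) + 1
    win <- max(1, ctr - 100):min(length(clean), ctr + 100)
    peak_idx <- win[which.max(clean[win])]
    expect_lte(abs(peak_idx - 1 - b * fs), 1)
  }
})
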