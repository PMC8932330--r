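# Orthogonal (periodized) discrete wavelet transform and wavelet-threshold
# denoising. Implemented with the standard pyramid algorithm; the scatter
# form of the synthesis step is the exact transpose of the analysis step, so
# the transform is perfectly invertible.

# Scaling (low-pass) filter coefficients for the supported wavelets.
wavelet_filter <- function(name) {
  switch(name,
    haar = c(1, 1) / sqrt(2),
    db2 = c(0.48296291314469025, 0.836516303737469,
            0.22414386804185735, -0.12940952255092145),
    db4 = c(0.23037781330885523, 0.7148465705525415, 0.6308807679295904,
            -0.02798376941698385, -0.18703481171888114, 0.030841381835986965,
            0.032883011666982945, -0.010597401784997278),
    ff_stop_invalid(sprintf("unknown wavelet '%s' (supported: haar, db2, db4)", name))
  )
}

# One analysis level: length-N vector -> approximation + detail of length N/2.
dwt_step <- function(a, h) {
  N <- length(a)
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1L)
  k <- seq_len(N %/% 2L)
  ap <- numeric(N %/% 2L)
  dt <- numeric(N %/% 2L)
  for (m in seq_len(L)) {
    idx <- (2L * (k - 1L) + (m - 1L)) %% N + 1L
    ap <- ap + h[m] * a[idx]
    dt <- dt + g[m] * a[idx]
  }
  list(a = ap, d = dt)
}

# One synthesis level (transpose of dwt_step).
idwt_step <- function(ap, dt, h) {
  N <- 2L * length(ap)
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1L)
  k <- seq_len(length(ap))
  y <- numeric(N)
  for (m in seq_len(L)) {
    idx <- (2L * (k - 1L) + (m - 1L)) %% N + 1L
    contrib <- h[m] * ap + g[m] * dt
    # scatter-add; idx values repeat across k only when N < L, avoided by
    # limiting the decomposition depth
    y[idx] <- y[idx] + contrib
  }
  y
}

#' Discrete wavelet transform (periodized, orthogonal)
#'
#' @param x numeric vector; its length must be divisible by `2^level`.
#' @param wavelet `"haar"`, `"db2"` or `"db4"`.
#' @param level decomposition depth.
#' @return List with `approx` (coarsest approximation) and `details` (list of
#'   detail coefficient vectors, finest first).
#' @export
dwt_forward <- function(x, wavelet = "db4", level = 4L) {
  h <- wavelet_filter(wavelet)
  if (length(x) %% 2^level != 0)
    ff_stop_invalid("length(x) must be divisible by 2^level")
  if (length(x) / 2^level < length(h))
    ff_stop_invalid("decomposition depth too large for this signal length")
  a <- as.numeric(x)
  details <- vector("list", level)
  for (j in seq_len(level)) {
    st <- dwt_step(a, h)
    a <- st$a
    details[[j]] <- st$d
  }
  list(approx = a, details = details, wavelet = wavelet, level = level)
}

#' Inverse discrete wavelet transform
#'
#' @param dec a decomposition from [dwt_forward()].
#' @return The reconstructed signal.
#' @export
dwt_inverse <- function(dec) {
  h <- wavelet_filter(dec$wavelet)
  a <- dec$approx
  for (j in rev(seq_len(dec$level)))
    a <- idwt_step(a, dec$details[[j]], h)
  a
}

#' Wavelet-threshold denoising
#'
#' Soft (or hard) thresholding of all detail coefficients. The default
#' threshold is the universal threshold `sigma * sqrt(2 * log(n))` with the
#' noise scale `sigma` estimated robustly from the finest detail level as
#' `median(|d1|) / 0.6745`. The signal is symmetrically padded to a multiple
#' of `2^level` and truncated after reconstruction, so any length is
#' accepted.
#'
#' @param x numeric vector of samples.
#' @param wavelet wavelet name (default `"db4"`).
#' @param level decomposition depth (default 4).
#' @param threshold `"universal"` or a numeric threshold.
#' @param rule `"soft"` (default) or `"hard"`.
#' @return Denoised samples, same length as `x`.
#' @export
dwt_denoise <- function(x, wavelet = "db4", level = 4L,
                        threshold = "universal", rule = c("soft", "hard")) {
  rule <- match.arg(rule)
  n <- length(x)
  if (n < 2^level) ff_stop_invalid("signal shorter than 2^level samples")
  block <- 2^level
  target <- ceiling(n / block) * block
  # keep enough coarse-level samples for the filter length
  h_len <- length(wavelet_filter(wavelet))
  while (target / block < h_len) target <- target + block
  pad <- target - n
  xp <- if (pad > 0) c(x, rep(c(rev(x), x), length.out = pad)) else x
  dec <- dwt_forward(xp, wavelet, level)
  thr <- if (identical(threshold, "universal")) {
    sigma <- median(abs(dec$details[[1L]])) / 0.6745
    sigma * sqrt(2 * log(length(xp)))
  } else {
    check_scalar(threshold, "threshold")
    threshold
  }
  dec$details <- lapply(dec$details, function(d) {
    if (rule == "soft") sign(d) * pmax(abs(d) - thr, 0)
    else d * (abs(d) > thr)
  })
  dwt_inverse(dec)[seq_len(n)]
}
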