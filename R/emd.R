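#' Empirical mode decomposition
#'
#' Adaptive decomposition of a signal into intrinsic mode functions (IMFs) by
#' the classical sifting procedure: cubic-spline envelopes through the local
#' extrema (mirrored at the boundaries) define a local mean that is
#' subtracted until the component satisfies a Cauchy-type stopping criterion.
#' The IMFs plus the final residue reproduce the input exactly by
#' construction.
#'
#' @param x numeric vector of samples.
#' @param max_imfs maximum number of IMFs to extract (default 10).
#' @param stop_sd sifting stops when the normalized squared change between
#'   consecutive sifts falls below this value (default 0.2, the conventional
#'   range being 0.2-0.3).
#' @param max_sift maximum sifting iterations per IMF (default 12).
#' @return A list with `imfs` (matrix, one column per IMF; zero columns when
#'   the input has too few extrema) and `residue` (vector) such that
#'   `rowSums(imfs) + residue == x` to machine precision.
#' @export
emd_decompose <- function(x, max_imfs = 10L, stop_sd = 0.2, max_sift = 12L) {
  n <- length(x)
  if (n < 8L) ff_stop_invalid("signal too short for EMD (need >= 8 samples)")
  x <- as.numeric(x)
  residue <- x
  imfs <- list()
  while (length(imfs) < max_imfs) {
    ex <- local_extrema(residue)
    if (length(ex$max) < 2L || length(ex$min) < 2L) break
    h <- residue
    for (s in seq_len(max_sift)) {
      ex <- local_extrema(h)
      if (length(ex$max) < 2L || length(ex$min) < 2L) break
      upper <- envelope_spline(ex$max, h[ex$max], n)
      lower <- envelope_spline(ex$min, h[ex$min], n)
      m <- (upper + lower) / 2
      h_new <- h - m
      sd_crit <- sum((h - h_new)^2) / (sum(h^2) + .Machine$double.eps)
      h <- h_new
      if (sd_crit < stop_sd) break
    }
    imfs[[length(imfs) + 1L]] <- h
    residue <- residue - h
  }
  imf_mat <- if (length(imfs)) do.call(cbind, imfs) else matrix(numeric(0), n, 0)
  list(imfs = imf_mat, residue = residue)
}

# Indices of strict local maxima and minima.
local_extrema <- function(x) {
  n <- length(x)
  d <- diff(x)
  # collapse flat runs by looking at sign changes of the first difference
  s <- sign(d)
  nz <- which(s != 0)
  if (length(nz) < 2L) return(list(max = integer(0), min = integer(0)))
  idx <- integer(0); kind <- integer(0)
  prev <- nz[1L]
  for (k in nz[-1L]) {
    if (s[k] != s[prev]) {
      # extremum between prev and k: place at midpoint of the flat run
      pos <- as.integer(ceiling((prev + 1L + k) / 2))
      idx <- c(idx, pos)
      kind <- c(kind, s[prev])
      prev <- k
    } else prev <- k
  }
  list(max = idx[kind > 0], min = idx[kind < 0])
}

# Cubic spline through extrema, mirrored about the signal ends to tame
# boundary swings, evaluated on 1..n.
envelope_spline <- function(px, py, n) {
  k <- length(px)
  m <- min(2L, k)
  left_x <- 2 * 1 - px[m:1]
  left_y <- py[m:1]
  right_x <- 2 * n - px[k:(k - m + 1L)]
  right_y <- py[k:(k - m + 1L)]
  xs <- c(left_x, px, right_x)
  ys <- c(left_y, py, right_y)
  keep <- !duplicated(xs)
  spline(xs[keep], ys[keep], xout = seq_len(n))$y
}
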