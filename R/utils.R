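#' @useDynLib fatiguefuse, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx spline fft sd quantile median rnorm runif predict
#' @importFrom utils read.csv write.csv modifyList
NULL

# Condition constructors: every user-facing failure carries a package class so
# callers can distinguish bad parameters from bad data quality.
ff_stop <- function(msg, class = "fatiguefuse_error", call. = FALSE) {
  stop(structure(
    class = c(class, "fatiguefuse_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

ff_stop_invalid <- function(msg) ff_stop(msg, "fatiguefuse_invalid_parameter")
ff_stop_quality <- function(msg) ff_stop(msg, "fatiguefuse_quality_error")
ff_stop_format  <- function(msg) ff_stop(msg, "fatiguefuse_format_error")

check_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    ff_stop_invalid(sprintf("`%s` must be a finite numeric scalar", name))
  if (positive && x <= 0)
    ff_stop_invalid(sprintf("`%s` must be > 0 (got %g)", name, x))
  invisible(x)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  check_scalar(seed, "seed")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministically derive a stream of child seeds from one parent seed, so a
# single pipeline seed controls every stage (kept < 2^31).
derive_seeds <- function(seed, n, salt = 0L) {
  (as.numeric(seed) * 48271 + salt * 16807 + seq_len(n) * 69621) %% 2147483629 + 1
}

rms_value <- function(x) sqrt(mean(x^2))
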