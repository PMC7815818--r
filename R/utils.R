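#' @keywords internal
"_PACKAGE"

# Internal validation helpers. Errors are classed so callers/tests can
# distinguish argument problems from degenerate data.

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("envtrack_invalid_argument", "error")))
}

stop_degenerate <- function(...) {
  stop(errorCondition(paste0(...), class = c("envtrack_degenerate_input", "error")))
}

stop_dimension <- function(...) {
  stop(errorCondition(paste0(...), class = c("envtrack_dimension_error", "error")))
}

stop_insufficient <- function(...) {
  stop(errorCondition(paste0(...), class = c("envtrack_insufficient_data", "error")))
}

assert_scalar_num <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
    stop_invalid("`", name, "` must be a single finite number")
  if (positive && x <= 0)
    stop_invalid("`", name, "` must be > 0, got ", x)
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x))
    stop_invalid("`", name, "` must be an integer >= ", min)
  invisible(as.integer(x))
}

# Evaluate `expr` with the global RNG stream temporarily seeded, restoring
# the caller's stream afterwards so seeded package functions do not disturb
# user-level reproducibility.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Gaussian noise with power spectral density proportional to f^(-exponent),
# generated by spectral shaping of white noise (DC component zeroed).
powerlaw_noise <- function(n, exponent, fs) {
  n <- as.integer(n)
  white <- stats::rnorm(n)
  X <- stats::fft(white)
  f <- seq(0, fs, length.out = n + 1L)[seq_len(n)]
  # fold to two-sided frequency magnitudes
  f[f > fs / 2] <- fs - f[f > fs / 2]
  shape <- c(0, f[-1L]^(-exponent / 2))
  x <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

rms <- function(x) sqrt(mean(x^2))

# Pearson correlation of each column of `pred` with the matching column of
# `obs`; plain cor() per column but vectorised.
colwise_pearson <- function(pred, obs) {
  pc <- sweep(pred, 2L, colMeans(pred))
  oc <- sweep(obs, 2L, colMeans(obs))
  num <- colSums(pc * oc)
  den <- sqrt(colSums(pc^2) * colSums(oc^2))
  r <- num / den
  r[den == 0] <- NA_real_
  r
}
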