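# Minimal IIR/FFT signal-processing kernel used throughout the package:
# Butterworth designs realised as second-order sections (numerically safe at
# the low relative cutoffs EEG work needs), zero-phase filtering, an FFT
# Hilbert transform, and FFT-based resampling with an anti-alias taper.

# Butterworth design, digital, returned as an SOS matrix (n_sections x 6:
# b0 b1 b2 a0 a1 a2) plus overall gain applied to the first section.
#
# n:    analog prototype order (per edge for band-pass).
# w:    normalized cutoff(s) in (0, 1), as a fraction of the Nyquist rate.
# type: "low", "high" or "pass".
butter_sos <- function(n, w, type = c("low", "high", "pass")) {
  type <- match.arg(type)
  if (any(w <= 0) || any(w >= 1)) stop_invalid("cutoffs must lie in (0, 1) of Nyquist")
  if (type == "pass" && (length(w) != 2L || w[1] >= w[2]))
    stop_invalid("band-pass needs two increasing cutoffs")
  # analog low-pass prototype poles (unit cutoff, left half-plane)
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  z <- complex(0)
  gain <- 1
  # prewarp (bilinear with fs = 2)
  warped <- 4 * tan(pi * w / 2)
  if (type == "low") {
    wo <- warped
    p <- p * wo
    gain <- gain * wo^n
  } else if (type == "high") {
    wo <- warped
    gain <- gain * Re(prod(-p))  # 1/prod(-p) * prod(-z); z empty
    gain <- 1 / gain
    p <- wo / p
    z <- rep(0 + 0i, n)
  } else {
    bw <- warped[2] - warped[1]
    wo <- sqrt(warped[1] * warped[2])
    gain <- gain * bw^n
    p <- p * bw / 2
    p <- c(p + sqrt(p^2 - wo^2), p - sqrt(p^2 - wo^2))
    z <- rep(0 + 0i, n)
  }
  # bilinear transform (fs = 2)
  fs2 <- 4
  zd <- (fs2 + p) / (fs2 - p)
  znum <- if (length(z)) (fs2 + z) / (fs2 - z) else complex(0)
  gain <- gain * Re(prod(fs2 - z) / prod(fs2 - p))
  # pad zeros at z = -1 to match pole count
  znum <- c(znum, rep(-1 + 0i, length(zd) - length(znum)))
  zpk_to_sos(znum, zd, gain)
}

# Pair conjugate poles/zeros into biquads. Assumes poles come in conjugate
# pairs (true for the real-coefficient designs above with even pole count).
zpk_to_sos <- function(z, p, k) {
  pair_up <- function(v) {
    used <- rep(FALSE, length(v))
    pairs <- list()
    for (i in seq_along(v)) {
      if (used[i]) next
      used[i] <- TRUE
      if (abs(Im(v[i])) < 1e-12) {
        j <- which(!used & abs(Im(v)) < 1e-12)[1]
        if (is.na(j)) { pairs[[length(pairs) + 1L]] <- v[i]; next }
      } else {
        j <- which(!used & abs(v - Conj(v[i])) < 1e-8)[1]
        if (is.na(j)) j <- which(!used)[1]
      }
      used[j] <- TRUE
      pairs[[length(pairs) + 1L]] <- c(v[i], v[j])
    }
    pairs
  }
  zp <- pair_up(z)
  pp <- pair_up(p)
  ns <- max(length(zp), length(pp))
  sos <- matrix(0, ns, 6L)
  for (s in seq_len(ns)) {
    zz <- if (s <= length(zp)) zp[[s]] else complex(0)
    ppp <- if (s <= length(pp)) pp[[s]] else complex(0)
    b <- Re(poly_from_roots(zz))
    a <- Re(poly_from_roots(ppp))
    b <- c(b, rep(0, 3 - length(b)))
    a <- c(a, rep(0, 3 - length(a)))
    sos[s, ] <- c(b, a)
  }
  sos[1, 1:3] <- sos[1, 1:3] * k
  sos
}

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

# Biquad cascade with zero initial conditions; the MA part by vectorized
# shifts, the AR part via the C-level recursive filter.
sosfilt <- function(sos, x) {
  n <- length(x)
  for (s in seq_len(nrow(sos))) {
    b <- sos[s, 1:3]; a <- sos[s, 4:6]
    b <- b / a[1]; a <- a / a[1]
    y <- b[1] * x
    if (n > 1) y[-1] <- y[-1] + b[2] * x[-n]
    if (n > 2) y[-(1:2)] <- y[-(1:2)] + b[3] * x[-c(n - 1, n)]
    if (any(a[2:3] != 0)) {
      y <- as.numeric(stats::filter(y, -a[2:3], method = "recursive"))
    }
    x <- y
  }
  x
}

# Zero-phase filtering: odd-symmetric edge padding, forward and reverse pass.
filtfilt_sos <- function(sos, x) {
  n <- length(x)
  pad <- min(n - 1L, 3L * 10L * nrow(sos))
  if (pad > 0) {
    pre <- 2 * x[1] - x[seq(pad + 1, 2)]
    post <- 2 * x[n] - x[seq(n - 1, n - pad)]
    xp <- c(pre, x, post)
  } else xp <- x
  y <- sosfilt(sos, xp)
  y <- rev(sosfilt(sos, rev(y)))
  if (pad > 0) y <- y[(pad + 1):(pad + n)]
  y
}

# Frequency response of an SOS cascade at frequencies f (Hz) for rate fs.
sos_freq_response <- function(sos, f, fs) {
  w <- 2 * pi * f / fs
  z1 <- exp(-1i * w)
  h <- rep(1 + 0i, length(w))
  for (s in seq_len(nrow(sos))) {
    b <- sos[s, 1:3]; a <- sos[s, 4:6]
    h <- h * (b[1] + b[2] * z1 + b[3] * z1^2) / (a[1] + a[2] * z1 + a[3] * z1^2)
  }
  h
}

# Analytic-signal magnitude via the FFT method, with reflection padding to
# suppress edge artifacts on short inputs.
hilbert_env <- function(x, pad = 0L) {
  n0 <- length(x)
  pad <- min(as.integer(pad), n0 - 1L)
  if (pad > 0) x <- c(x[seq(pad + 1, 2)], x, x[seq(n0 - 1, n0 - pad)])
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  a <- stats::fft(X * h, inverse = TRUE) / n
  env <- Mod(a)
  if (pad > 0) env <- env[(pad + 1):(pad + n0)]
  env
}

# FFT resampling from fs_in to fs_out with a raised-cosine anti-alias taper
# opening at `taper_lo` of the output rate and closing at output Nyquist.
resample_fft <- function(x, fs_in, fs_out, taper_lo = 0.4) {
  if (fs_out > fs_in) stop_invalid("upsampling not supported (fs_out > fs_in)")
  n <- length(x)
  if (fs_out == fs_in) return(x)
  n_out <- as.integer(round(n * fs_out / fs_in))
  X <- stats::fft(x)
  f <- seq(0, fs_in, length.out = n + 1L)[seq_len(n)]
  f[f > fs_in / 2] <- fs_in - f[f > fs_in / 2]
  f_lo <- taper_lo * fs_out
  f_hi <- fs_out / 2
  g <- rep(1, n)
  trans <- f > f_lo & f < f_hi
  g[trans] <- 0.5 * (1 + cos(pi * (f[trans] - f_lo) / (f_hi - f_lo)))
  g[f >= f_hi] <- 0
  X <- X * g
  # spectrum truncation to n_out bins
  Y <- complex(n_out)
  half <- floor((n_out - 1) / 2)
  Y[1] <- X[1]
  if (half >= 1) {
    Y[2:(half + 1)] <- X[2:(half + 1)]
    Y[n_out - (1:half) + 1] <- X[n - (1:half) + 1]
  }
  if (n_out %% 2 == 0) Y[n_out / 2 + 1] <- 0
  Re(stats::fft(Y, inverse = TRUE)) / n * 1  # scale: (1/n) * n_out/n_out
}
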