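# Multiband envelope-edge stimulus model: gammatone filterbank on an ERB
# scale, Hilbert envelopes, power-law compression, resampling to the EEG
# clock, and the first temporal derivative ("acoustic edges").

#' Gammatone filterbank specification
#'
#' @param n_bands Number of filters (default 16).
#' @param f_low,f_high Lowest/highest center frequency in Hz (defaults 250 and
#'   8000).
#' @param order Gammatone order (the all-pole cascade implements order 4).
#' @return An object of class `filterbank_spec`.
#' @export
filterbank_spec <- function(n_bands = 16L, f_low = 250, f_high = 8000,
                            order = 4L) {
  n_bands <- assert_count(n_bands, "n_bands", min = 2L)
  assert_scalar_num(f_low, "f_low", positive = TRUE)
  assert_scalar_num(f_high, "f_high", positive = TRUE)
  if (f_low >= f_high) stop_invalid("f_low must be < f_high")
  if (order != 4L) stop_invalid("only 4th-order gammatone filters are implemented")
  structure(list(n_bands = n_bands, f_low = f_low, f_high = f_high,
                 spacing = "erb", order = 4L),
            class = "filterbank_spec")
}

#' ERB-rate scale (Glasberg-Moore)
#'
#' `erb_rate()` maps frequency in Hz to the ERB-rate scale
#' \eqn{21.4 \log_{10}(0.00437 f + 1)}; `erb_rate_inv()` is its inverse, and
#' `erb_bandwidth()` gives the equivalent rectangular bandwidth
#' \eqn{24.7 (4.37 f / 1000 + 1)} in Hz.
#'
#' @param f Frequency in Hz.
#' @param r ERB-rate value.
#' @return Numeric vector.
#' @export
erb_rate <- function(f) 21.4 * log10(0.00437 * f + 1)

#' @rdname erb_rate
#' @export
erb_rate_inv <- function(r) (10^(r / 21.4) - 1) / 0.00437

#' @rdname erb_rate
#' @export
erb_bandwidth <- function(f) 24.7 * (4.37 * f / 1000 + 1)

#' Center frequencies uniformly spaced on the ERB-rate scale
#'
#' Returns `n_bands` frequencies whose ERB-rate values are uniformly spaced
#' between `erb_rate(f_low)` and `erb_rate(f_high)`, inclusive of both
#' endpoints.
#'
#' @param spec A [filterbank_spec()].
#' @return Increasing numeric vector of center frequencies in Hz.
#' @export
erb_center_frequencies <- function(spec) {
  stopifnot(inherits(spec, "filterbank_spec"))
  r <- seq(erb_rate(spec$f_low), erb_rate(spec$f_high),
           length.out = spec$n_bands)
  erb_rate_inv(r)
}

# Slaney's all-pole gammatone coefficients for one center frequency:
# four cascaded biquads sharing the denominator, plus an overall gain.
gammatone_coefs <- function(cf, fs) {
  T <- 1 / fs
  B <- 1.019 * 2 * pi * erb_bandwidth(cf)
  arg <- 2 * cf * pi * T
  vec <- exp(2i * arg)
  k0 <- 2 * T * cos(arg) / exp(B * T)
  kp <- 2 * sqrt(3 + 2^1.5) * T * sin(arg) / exp(B * T)
  km <- 2 * sqrt(3 - 2^1.5) * T * sin(arg) / exp(B * T)
  A11 <- -(k0 + kp) / 2; A12 <- -(k0 - kp) / 2
  A13 <- -(k0 + km) / 2; A14 <- -(k0 - km) / 2
  B0 <- 1
  B1 <- -2 * cos(arg) / exp(B * T)
  B2 <- exp(-2 * B * T)
  g1 <- -2 * vec * T + 2 * exp(-B * T + 1i * arg) * T *
    (cos(arg) - sqrt(3 - 2^1.5) * sin(arg))
  g2 <- -2 * vec * T + 2 * exp(-B * T + 1i * arg) * T *
    (cos(arg) + sqrt(3 - 2^1.5) * sin(arg))
  g3 <- -2 * vec * T + 2 * exp(-B * T + 1i * arg) * T *
    (cos(arg) - sqrt(3 + 2^1.5) * sin(arg))
  g4 <- -2 * vec * T + 2 * exp(-B * T + 1i * arg) * T *
    (cos(arg) + sqrt(3 + 2^1.5) * sin(arg))
  gain <- abs(g1 * g2 * g3 * g4 /
                (-2 / exp(2 * B * T) - 2 * vec + 2 * (1 + vec) / exp(B * T))^4)
  list(A0 = T, A11 = A11, A12 = A12, A13 = A13, A14 = A14,
       B = c(B0, B1, B2), gain = gain)
}

# Apply one gammatone filter (4 cascaded biquads) to a signal.
gammatone_apply <- function(x, co) {
  a <- co$B
  ma <- function(x, b) {
    n <- length(x)
    y <- b[1] * x
    if (n > 1) y[-1] <- y[-1] + b[2] * x[-n]
    y
  }
  ar <- function(y) as.numeric(stats::filter(y, -a[2:3], method = "recursive"))
  y <- ar(ma(x, c(co$A0 / co$gain, co$A11 / co$gain)))
  y <- ar(ma(y, c(co$A0, co$A12)))
  y <- ar(ma(y, c(co$A0, co$A13)))
  y <- ar(ma(y, c(co$A0, co$A14)))
  y
}

#' Gammatone filterbank analysis
#'
#' Filters the audio through a bank of 4th-order gammatone filters (Slaney's
#' all-pole cascade) at ERB-spaced center frequencies.
#'
#' @param audio An [audio_track()].
#' @param spec A [filterbank_spec()].
#' @return A band x time numeric matrix; rows ordered by increasing center
#'   frequency (attribute `band_centers`).
#' @export
gammatone_filterbank <- function(audio, spec = filterbank_spec()) {
  stopifnot(inherits(audio, "audio_track"))
  if (audio$fs < 2 * spec$f_high)
    stop_invalid("sampling rate ", audio$fs, " Hz cannot represent the top band at ",
                 spec$f_high, " Hz (Nyquist)")
  cfs <- erb_center_frequencies(spec)
  out <- matrix(0, spec$n_bands, length(audio$samples))
  for (b in seq_len(spec$n_bands)) {
    out[b, ] <- gammatone_apply(audio$samples, gammatone_coefs(cfs[b], audio$fs))
  }
  attr(out, "band_centers") <- cfs
  attr(out, "fs") <- audio$fs
  out
}

#' Multiband envelope container
#'
#' @param features Band x time matrix of envelope-edge features.
#' @param fs Sampling rate of the feature time axis (the EEG clock), Hz.
#' @param band_centers Center frequencies of the filterbank bands, Hz.
#' @param compression_exponent Power-law exponent used (for provenance).
#' @param track_id Track label.
#' @return An object of class `multiband_envelope`.
#' @export
multiband_envelope <- function(features, fs, band_centers,
                               compression_exponent = 0.6,
                               track_id = "track") {
  if (!is.matrix(features) || !all(is.finite(features)))
    stop_invalid("`features` must be a finite band x time matrix")
  if (length(band_centers) != nrow(features))
    stop_dimension("band_centers length != number of feature rows")
  if (is.unsorted(band_centers, strictly = TRUE))
    stop_invalid("band_centers must be strictly increasing")
  structure(list(features = features, fs = fs,
                 band_centers = as.numeric(band_centers),
                 compression_exponent = compression_exponent,
                 track_id = as.character(track_id)),
            class = "multiband_envelope")
}

#' @export
print.multiband_envelope <- function(x, ...) {
  cat(sprintf("<multiband_envelope '%s'> %d bands x %d samples @ %g Hz\n",
              x$track_id, nrow(x$features), ncol(x$features), x$fs))
  invisible(x)
}

#' Compressed envelope edges on the EEG clock
#'
#' Per band: (1) magnitude of the analytic signal (Hilbert transform with 1 s
#' reflection padding); (2) power-law compression with `exponent`;
#' (3) anti-alias low-pass (raised-cosine taper from `0.4 * fs_out`) and FFT
#' resampling to `fs_out`; (4) first temporal difference scaled by `fs_out`.
#' The derivative is signed by default (onsets positive, offsets negative);
#' `rectify = TRUE` keeps only positive deflections. The first derivative
#' sample is defined as 0.
#'
#' @param band_signals Band x time matrix (e.g. from
#'   [gammatone_filterbank()]).
#' @param fs_in Input sampling rate, Hz.
#' @param fs_out Output (EEG) sampling rate, Hz; must not exceed `fs_in`.
#' @param exponent Compression exponent (> 0, default 0.6).
#' @param band_centers Center frequencies; taken from the input's attribute
#'   when present.
#' @param rectify Half-wave rectify the derivative (default `FALSE`).
#' @param track_id Track label.
#' @return A [multiband_envelope()] at `fs_out`.
#' @export
envelope_edges <- function(band_signals, fs_in, fs_out, exponent = 0.6,
                           band_centers = attr(band_signals, "band_centers"),
                           rectify = FALSE, track_id = "track") {
  if (exponent <= 0) stop_invalid("`exponent` must be > 0")
  if (fs_out > fs_in) stop_invalid("fs_out must be <= fs_in")
  nb <- nrow(band_signals)
  if (is.null(band_centers)) band_centers <- seq_len(nb)
  n_out <- as.integer(round(ncol(band_signals) * fs_out / fs_in))
  feats <- matrix(0, nb, n_out)
  cenv <- matrix(0, nb, n_out)
  pad <- as.integer(round(fs_in))  # 1 s reflection padding
  for (b in seq_len(nb)) {
    env <- hilbert_env(band_signals[b, ], pad = pad)
    env <- env^exponent
    env <- resample_fft(env, fs_in, fs_out)
    cenv[b, ] <- env
    d <- c(0, diff(env) * fs_out)
    if (rectify) d <- pmax(d, 0)
    feats[b, ] <- d
  }
  out <- multiband_envelope(feats, fs_out, band_centers,
                            compression_exponent = exponent,
                            track_id = track_id)
  attr(out, "compressed_envelope") <- cenv
  out
}

#' Full stimulus-model front end for one track
#'
#' Convenience wrapper: gammatone filterbank, then [envelope_edges()].
#'
#' @inheritParams gammatone_filterbank
#' @inheritParams envelope_edges
#' @return A [multiband_envelope()].
#' @export
compute_envelope <- function(audio, spec = filterbank_spec(), fs_out = 128,
                             exponent = 0.6, rectify = FALSE) {
  bands <- gammatone_filterbank(audio, spec)
  envelope_edges(bands, audio$fs, fs_out, exponent = exponent,
                 rectify = rectify, track_id = audio$track_id)
}
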