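# EEG conditioning: zero-phase band-pass filtering into analysis bands,
# epoching of continuous recordings, common-average referencing, and
# subject-level z-scoring pooled over channels.

#' Analysis band specification
#'
#' Built-in bands: full 1-8 Hz, delta 1-4 Hz, theta 4-8 Hz, plus the 1-15 Hz
#' acquisition band (`"raw15"`).
#'
#' @param name Band label.
#' @param f_lo,f_hi Band edges in Hz.
#' @return An object of class `band_spec`.
#' @export
band_spec <- function(name, f_lo, f_hi) {
  assert_scalar_num(f_lo, "f_lo", positive = TRUE)
  assert_scalar_num(f_hi, "f_hi", positive = TRUE)
  if (f_lo >= f_hi) stop_invalid("f_lo must be < f_hi")
  structure(list(name = as.character(name), f_lo = f_lo, f_hi = f_hi),
            class = "band_spec")
}

#' @rdname band_spec
#' @param band Band name, one of `"full"`, `"delta"`, `"theta"`.
#' @export
default_bands <- function(band = c("full", "delta", "theta")) {
  band <- match.arg(band)
  switch(band,
         full = band_spec("full", 1, 8),
         delta = band_spec("delta", 1, 4),
         theta = band_spec("theta", 4, 8))
}

#' Zero-phase band-pass filter
#'
#' Two-pass (forward-backward) 4th-order Butterworth band-pass applied per
#' channel and track, giving zero group delay. The output is tagged with the
#' band name when it matches a canonical band.
#'
#' @param epochs An [eeg_epochs()] with band `"raw"` or `"full"`.
#' @param band A [band_spec()] or a canonical band name.
#' @return Filtered [eeg_epochs()].
#' @export
bandpass <- function(epochs, band) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (is.character(band)) band <- default_bands(band)
  if (!epochs$band %in% c("raw", "full"))
    stop_invalid("band-limited epochs (", epochs$band,
                 ") cannot be re-filtered; start from raw or full band")
  nyq <- epochs$fs / 2
  if (band$f_hi >= nyq)
    stop_invalid("band upper edge ", band$f_hi, " Hz >= Nyquist ", nyq, " Hz")
  sos <- butter_sos(4L, c(band$f_lo, band$f_hi) / nyq, "pass")
  out <- epochs$data
  for (k in seq_len(n_tracks(epochs))) {
    for (c in seq_len(n_channels(epochs))) {
      out[c, , k] <- filtfilt_sos(sos, epochs$data[c, , k])
    }
  }
  res <- epochs
  res$data <- out
  res$band <- if (band$name %in% c("full", "delta", "theta")) band$name
              else epochs$band
  res
}

#' Frequency-response report for the analysis filters
#'
#' Returns the two-pass magnitude response of the band's filter on a
#' frequency grid, for inclusion alongside results.
#'
#' @param band A [band_spec()] or canonical band name.
#' @param fs Sampling rate, Hz.
#' @param f Frequency grid, Hz.
#' @return data.frame with `frequency_hz` and `magnitude` (two-pass).
#' @export
filter_response_report <- function(band, fs = 128,
                                   f = seq(0.1, fs / 2 - 0.1, by = 0.1)) {
  if (is.character(band)) band <- default_bands(band)
  sos <- butter_sos(4L, c(band$f_lo, band$f_hi) / (fs / 2), "pass")
  h <- abs(sos_freq_response(sos, f, fs))^2  # two passes
  data.frame(frequency_hz = f, magnitude = h)
}

#' Common-average reference
#'
#' Subtracts the instantaneous mean across channels from every channel,
#' separately per time sample and track.
#'
#' @param epochs An [eeg_epochs()] with at least 2 channels.
#' @return Referenced [eeg_epochs()].
#' @export
common_average_reference <- function(epochs) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (n_channels(epochs) < 2L)
    stop_invalid("common-average reference needs >= 2 channels")
  out <- epochs$data
  d <- dim(out)
  for (k in seq_len(d[3L])) {
    m <- matrix(out[, , k], d[1L], d[2L])
    out[, , k] <- sweep(m, 2L, colMeans(m))
  }
  epochs$data <- out
  epochs
}

#' Subject-level z-scoring
#'
#' `mode = "pooled"` (default) centers and scales with a single grand
#' mean/SD pooled over all channels, samples and tracks, preserving relative
#' channel amplitudes; `mode = "per_channel"` standardizes each channel
#' separately.
#'
#' @param epochs An [eeg_epochs()].
#' @param mode `"pooled"` or `"per_channel"`.
#' @return Standardized [eeg_epochs()].
#' @export
zscore_subject <- function(epochs, mode = c("pooled", "per_channel")) {
  mode <- match.arg(mode)
  x <- epochs$data
  if (mode == "pooled") {
    s <- stats::sd(x)
    if (s == 0) stop_degenerate("constant EEG: zero variance, cannot z-score")
    epochs$data <- (x - mean(x)) / s
  } else {
    for (c in seq_len(n_channels(epochs))) {
      xc <- x[c, , ]
      s <- stats::sd(xc)
      if (s == 0) stop_degenerate("channel ", c, " has zero variance")
      x[c, , ] <- (xc - mean(xc)) / s
    }
    epochs$data <- x
  }
  epochs
}

#' Epoch a continuous recording around stimulus onsets
#'
#' @param continuous Channel x time matrix.
#' @param fs Sampling rate, Hz.
#' @param onsets_s Stimulus onsets in seconds from recording start.
#' @param window_s Length-2 epoch window in seconds relative to onset
#'   (default `c(-5, 70)`).
#' @param ... Passed to [eeg_epochs()] (labels, subject, group).
#' @return An [eeg_epochs()] with one track per onset.
#' @export
epoch_tracks <- function(continuous, fs, onsets_s, window_s = c(-5, 70), ...) {
  if (!is.matrix(continuous)) stop_invalid("`continuous` must be a matrix")
  nlen <- as.integer(round((window_s[2] - window_s[1]) * fs))
  nch <- nrow(continuous)
  out <- array(0, c(nch, nlen, length(onsets_s)))
  for (k in seq_along(onsets_s)) {
    i0 <- as.integer(round((onsets_s[k] + window_s[1]) * fs)) + 1L
    i1 <- i0 + nlen - 1L
    if (i0 < 1L || i1 > ncol(continuous))
      stop_invalid("track ", k, ": epoch window [", window_s[1], ", ",
                   window_s[2], "] s around onset ", onsets_s[k],
                   " s exceeds the recording bounds")
    out[, , k] <- continuous[, i0:i1]
  }
  eeg_epochs(out, fs = fs, epoch_window_s = as.numeric(window_s),
             onset_sample = as.integer(round(-window_s[1] * fs)) + 1L, ...)
}

#' Standard preprocessing chain
#'
#' Band-pass, common-average reference, then pooled z-scoring — the order
#' used throughout the pipeline for already-epoched data.
#'
#' @inheritParams bandpass
#' @param zscore_mode Passed to [zscore_subject()].
#' @return Analysis-ready [eeg_epochs()].
#' @export
preprocess_epochs <- function(epochs, band, zscore_mode = "pooled") {
  zscore_subject(common_average_reference(bandpass(epochs, band)),
                 mode = zscore_mode)
}
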