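# Core data containers. Lightweight S3 lists, validated on construction.

#' Audio track container
#'
#' One narrative segment's waveform with sampling metadata.
#'
#' @param samples Numeric vector of amplitudes (dimensionless, |x| of order 1).
#' @param fs Sampling rate in Hz.
#' @param track_id Label for the track.
#' @return An object of class `audio_track`.
#' @export
audio_track <- function(samples, fs, track_id = "track") {
  assert_scalar_num(fs, "fs", positive = TRUE)
  if (!is.numeric(samples) || length(samples) < 1L)
    stop_invalid("`samples` must be a non-empty numeric vector")
  if (!all(is.finite(samples))) stop_invalid("`samples` contains non-finite values")
  structure(list(samples = as.numeric(samples), fs = fs,
                 track_id = as.character(track_id),
                 duration_s = length(samples) / fs),
            class = "audio_track")
}

#' @export
print.audio_track <- function(x, ...) {
  cat(sprintf("<audio_track '%s'> %.2f s @ %g Hz (%d samples)\n",
              x$track_id, x$duration_s, x$fs, length(x$samples)))
  invisible(x)
}

#' EEG epochs container
#'
#' Channel x time x track array plus sampling and recording metadata. The
#' `band` tag records which filtering stage produced the data.
#'
#' @param data Numeric array, channel x time x track (a channel x time matrix
#'   is promoted to a single track).
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector of channel names (10-20 style).
#' @param band One of `"raw"`, `"full"`, `"delta"`, `"theta"`.
#' @param epoch_window_s Length-2 numeric, epoch start/end in seconds relative
#'   to stimulus onset.
#' @param onset_sample Sample index (1-based) of stimulus onset within the
#'   epoch.
#' @param subject_id,group Labels carried through to tidy outputs.
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, fs, channel_labels = NULL, band = "raw",
                       epoch_window_s = c(-5, 70), onset_sample = NULL,
                       subject_id = "subject", group = "NA") {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_invalid("`data` must be a channel x time x track array")
  assert_scalar_num(fs, "fs", positive = TRUE)
  band <- match.arg(band, c("raw", "full", "delta", "theta"))
  if (anyNA(data)) stop_invalid("`data` contains NA")
  nch <- dim(data)[1L]
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(nch))
  if (length(channel_labels) != nch)
    stop_dimension("channel_labels length ", length(channel_labels),
                   " != channel count ", nch)
  if (is.null(onset_sample))
    onset_sample <- as.integer(round(-epoch_window_s[1] * fs)) + 1L
  structure(list(data = data, fs = fs,
                 channel_labels = as.character(channel_labels), band = band,
                 epoch_window_s = as.numeric(epoch_window_s),
                 onset_sample = as.integer(onset_sample),
                 subject_id = as.character(subject_id),
                 group = as.character(group)),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs %s/%s> %d ch x %d samples x %d tracks @ %g Hz, band=%s\n",
              x$subject_id, x$group, d[1], d[2], d[3], x$fs, x$band))
  invisible(x)
}

n_tracks <- function(epochs) dim(epochs$data)[3L]
n_channels <- function(epochs) dim(epochs$data)[1L]

# Post-onset slice of one track as a time x channel matrix (the orientation
# the regression code wants).
post_onset_matrix <- function(epochs, track, n_samples = NULL) {
  x <- t(epochs$data[, epochs$onset_sample:dim(epochs$data)[2L], track,
                     drop = TRUE])
  if (!is.null(n_samples)) {
    if (nrow(x) < n_samples)
      stop_dimension("track ", track, " has ", nrow(x),
                     " post-onset samples, need ", n_samples)
    x <- x[seq_len(n_samples), , drop = FALSE]
  }
  x
}
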