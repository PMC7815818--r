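# Portable on-disk formats: RIFF/WAVE audio (PCM16 and IEEE float32) and the
# pipeline's EEG/feature container — a raw little-endian float64 payload with
# a JSON sidecar carrying dimensions and recording metadata. Both are plain
# binary + text and need no external libraries.

#' Read a WAV file into an [audio_track()]
#'
#' Supports uncompressed PCM (8/16/32 bit) and IEEE float32/float64 WAV.
#' Stereo files are averaged to mono, matching diotic presentation of a
#' single-source stimulus.
#'
#' @param path Path to a `.wav` file.
#' @param track_id Label for the track; defaults to the file name.
#' @return An [audio_track()] object.
#' @export
read_wav <- function(path, track_id = basename(path)) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop_invalid("not a RIFF/WAVE file: ", path)
  readBin(con, "integer", 1L, 4L, endian = "little")
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop_invalid("not a WAVE file: ", path)
  fmt <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        format = readBin(con, "integer", 1L, 2L, endian = "little"),
        n_channels = readBin(con, "integer", 1L, 2L, endian = "little"),
        fs = readBin(con, "integer", 1L, 4L, endian = "little"),
        byte_rate = readBin(con, "integer", 1L, 4L, endian = "little"),
        block_align = readBin(con, "integer", 1L, 2L, endian = "little"),
        bits = readBin(con, "integer", 1L, 2L, endian = "little"))
      if (sz > 16L) readBin(con, "raw", sz - 16L)
    } else if (id == "data") {
      if (is.null(fmt)) stop_invalid("malformed WAV: data before fmt chunk")
      bytes_per <- fmt$bits / 8L
      n <- sz / bytes_per
      if (fmt$format == 1L) {
        samples <- readBin(con, "integer", n, bytes_per, signed = fmt$bits > 8,
                           endian = "little") / 2^(fmt$bits - 1)
      } else if (fmt$format == 3L) {
        samples <- readBin(con, "double", n, bytes_per, endian = "little")
      } else stop_invalid("unsupported WAV format code ", fmt$format)
      break
    } else {
      readBin(con, "raw", sz + sz %% 2L)
    }
  }
  if (is.null(samples)) stop_invalid("no data chunk found in ", path)
  if (fmt$n_channels > 1L) {
    samples <- colMeans(matrix(samples, nrow = fmt$n_channels))
  }
  audio_track(samples, fmt$fs, track_id = track_id)
}

#' Write an [audio_track()] to a WAV file
#'
#' @param track An [audio_track()].
#' @param path Output path.
#' @param format `"float32"` (IEEE float) or `"pcm16"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(track, path, format = c("float32", "pcm16")) {
  format <- match.arg(format)
  x <- track$samples
  n <- length(x)
  bits <- if (format == "float32") 32L else 16L
  bytes_per <- bits / 8L
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(if (format == "float32") 3L else 1L, con, 2L, endian = "little")
  writeBin(1L, con, 2L, endian = "little")
  writeBin(as.integer(track$fs), con, 4L, endian = "little")
  writeBin(as.integer(track$fs * bytes_per), con, 4L, endian = "little")
  writeBin(as.integer(bytes_per), con, 2L, endian = "little")
  writeBin(as.integer(bits), con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4L, endian = "little")
  if (format == "float32") {
    writeBin(x, con, 4L, endian = "little")
  } else {
    writeBin(as.integer(pmax(pmin(round(x * 32768), 32767), -32768)), con,
             2L, endian = "little")
  }
  invisible(path)
}

#' Write EEG epochs to the portable container
#'
#' The container is a pair of files: `<path>.dat` holding the
#' channel-fastest float64 payload, and `<path>.json` holding dimensions,
#' sampling rate, channel labels and recording metadata.
#'
#' @param epochs An [eeg_epochs()] object.
#' @param path Output path stem (no extension).
#' @return `path`, invisibly.
#' @export
write_eeg_container <- function(epochs, path) {
  meta <- list(
    dims = dim(epochs$data),
    fs = epochs$fs,
    channel_labels = epochs$channel_labels,
    band = epochs$band,
    epoch_window_s = epochs$epoch_window_s,
    onset_sample = epochs$onset_sample,
    subject_id = epochs$subject_id,
    group = epochs$group)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.vector(epochs$data), con, 8L, endian = "little")
  invisible(path)
}

#' Read EEG epochs from the portable container
#'
#' @param path Path stem written by [write_eeg_container()].
#' @return An [eeg_epochs()] object.
#' @export
read_eeg_container <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  dims <- as.integer(meta$dims)
  con <- file(paste0(path, ".dat"), "rb")
  on.exit(close(con))
  x <- readBin(con, "double", prod(dims), 8L, endian = "little")
  eeg_epochs(array(x, dims), fs = meta$fs,
             channel_labels = meta$channel_labels, band = meta$band,
             epoch_window_s = unlist(meta$epoch_window_s),
             onset_sample = meta$onset_sample,
             subject_id = meta$subject_id, group = meta$group)
}
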