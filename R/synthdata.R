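# Synthetic stimuli and EEG with known ground-truth encoding. The generator
# inverts the analysis forward model: EEG is the lagged envelope-edge design
# multiplied by a known kernel, plus 1/f noise, so every downstream stage has
# a parameter-recovery oracle.

#' Simulation configuration
#'
#' Defaults mirror the emulated study design: two groups, two narratives of
#' 15 tracks x 60 s, 32-channel EEG at 128 Hz, audio at 16 kHz.
#'
#' @param n_subjects_per_group Subjects per group (default 10).
#' @param n_tracks Tracks per narrative (default 15).
#' @param track_duration_s Track duration in seconds (default 60).
#' @param n_channels EEG channels (default 32).
#' @param eeg_fs EEG sampling rate, Hz (default 128).
#' @param audio_fs Audio sampling rate, Hz (default 16000).
#' @param n_bands Envelope filterbank bands used by the simulated encoding
#'   (default 16).
#' @param noise_exponent Spectral slope of the 1/f background noise
#'   (default 1, pink).
#' @param snr_db Broadband signal-to-noise ratio of the (gain = 1 reference)
#'   convolved signal versus the noise, in dB (default -10, which yields
#'   tracking correlations well below saturation).
#' @param syllable_rate_hz Syllable rate of the generated stimuli (default
#'   4.5).
#' @param pre_stimulus_s Noise-only segment before stimulus onset, seconds
#'   (default 5, supporting the -5 to 70 s epoch and the pre-onset SNR
#'   window).
#' @param seed RNG seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects_per_group = 10L, n_tracks = 15L,
                              track_duration_s = 60, n_channels = 32L,
                              eeg_fs = 128, audio_fs = 16000, n_bands = 16L,
                              noise_exponent = 1, snr_db = -10,
                              syllable_rate_hz = 4.5, pre_stimulus_s = 5,
                              seed = 1L) {
  cfg <- list(
    n_subjects_per_group = assert_count(n_subjects_per_group, "n_subjects_per_group"),
    n_tracks = assert_count(n_tracks, "n_tracks"),
    track_duration_s = assert_scalar_num(track_duration_s, "track_duration_s", positive = TRUE),
    n_channels = assert_count(n_channels, "n_channels"),
    eeg_fs = assert_scalar_num(eeg_fs, "eeg_fs", positive = TRUE),
    audio_fs = assert_scalar_num(audio_fs, "audio_fs", positive = TRUE),
    n_bands = assert_count(n_bands, "n_bands", min = 2L),
    noise_exponent = assert_scalar_num(noise_exponent, "noise_exponent"),
    snr_db = assert_scalar_num(snr_db, "snr_db"),
    syllable_rate_hz = assert_scalar_num(syllable_rate_hz, "syllable_rate_hz", positive = TRUE),
    pre_stimulus_s = assert_scalar_num(pre_stimulus_s, "pre_stimulus_s"),
    seed = assert_count(seed, "seed", min = 0L))
  if (cfg$pre_stimulus_s < 5) stop_invalid("`pre_stimulus_s` must be >= 5")
  structure(cfg, class = "simulation_config")
}

#' Quasi-rhythmic speech-like stimulus
#'
#' Pink-noise carrier amplitude-modulated by a quasi-periodic syllable-rate
#' envelope: a jittered pulse train (inter-pulse intervals uniform within
#' +/-20% of `1/syllable_rate_hz`) smoothed by a raised-cosine window one
#' syllable period wide. The waveform is peak-normalized to |x| <= 1 and is
#' deterministic given `seed`.
#'
#' @param duration_s Duration in seconds (> 0).
#' @param audio_fs Sampling rate, Hz.
#' @param syllable_rate_hz Syllable rate in Hz (2 to 8).
#' @param seed RNG seed.
#' @param track_id Track label.
#' @return An [audio_track()] of exactly `round(duration_s * audio_fs)`
#'   samples.
#' @export
make_syllabic_stimulus <- function(duration_s, audio_fs = 16000,
                                   syllable_rate_hz = 4.5, seed = 1L,
                                   track_id = "synthetic") {
  assert_scalar_num(duration_s, "duration_s", positive = TRUE)
  assert_scalar_num(syllable_rate_hz, "syllable_rate_hz", positive = TRUE)
  if (syllable_rate_hz < 2 || syllable_rate_hz > 8)
    stop_invalid("`syllable_rate_hz` must lie in [2, 8]")
  n <- as.integer(round(duration_s * audio_fs))
  with_seed(seed, {
    carrier <- powerlaw_noise(n, 1, audio_fs)
    period <- 1 / syllable_rate_hz
    # jittered pulse onsets
    t <- 0
    onsets <- numeric(0)
    while (t < duration_s) {
      onsets <- c(onsets, t)
      t <- t + stats::runif(1, 0.8 * period, 1.2 * period)
    }
    # raised-cosine (Hann) window, one syllable period wide, placed
    # additively at each (jittered) pulse location
    wl <- max(3L, as.integer(round(period * audio_fs)))
    win <- 0.5 * (1 - cos(2 * pi * seq_len(wl) / (wl + 1)))
    env <- numeric(n + 2L * wl)
    idx <- pmin(as.integer(round(onsets * audio_fs)) + 1L, n)
    for (i0 in idx) {
      pos <- wl + i0 - wl %/% 2 + seq_len(wl) - 1L
      env[pos] <- env[pos] + win
    }
    env <- env[wl + seq_len(n)]
    env <- env / max(env)
    x <- carrier * (0.05 + 0.95 * env)
    x <- x / max(abs(x))
    audio_track(x, audio_fs, track_id = track_id)
  })
}

#' Ground-truth encoding kernel
#'
#' Difference-of-Gammas slow ("delta") component peaking at `latency_ms` plus
#' a 7 Hz Gabor fast ("theta") component scaled by `theta_gain`. The Gabor
#' parameters (carrier 7 Hz, temporal SD 120 ms) concentrate its spectrum in
#' the upper theta band so that next to none of its power survives the delta
#' analysis filter and the group contrast stays band specific. The kernel
#' has a smooth Gaussian
#' profile across envelope bands and a random, seed-fixed channel polarity
#' (+/-1) map, and is zero at the first and last lag sample.
#'
#' @param window A [lag_window()].
#' @param n_bands Number of envelope bands.
#' @param n_channels Number of EEG channels.
#' @param theta_gain Multiplicative gain on the theta component (> 0;
#'   patient-like groups use > 1).
#' @param latency_ms Peak latency of the slow component (default 100).
#' @param seed RNG seed for the channel map.
#' @return An object of class `ground_truth_kernel` with `weights`
#'   (lag x band x channel), `lags` (ms), `band_gain`, `latency_ms`.
#' @export
ground_truth_kernel <- function(window = lag_window(), n_bands = 16L,
                                n_channels = 32L, theta_gain = 1,
                                latency_ms = 100, seed = 1L) {
  if (theta_gain <= 0) stop_invalid("`theta_gain` must be > 0")
  tau <- window$lag_ms / 1000        # seconds
  npos <- tau > 0
  # slow component: difference of Gammas, peak ~ latency_ms
  sc <- latency_ms / 100
  g1 <- stats::dgamma(tau, shape = 3, scale = 0.05 * sc)
  g2 <- stats::dgamma(tau, shape = 5, scale = 0.06 * sc)
  slow <- g1 / max(g1) - 0.55 * g2 / max(g2)
  slow[!npos] <- 0
  # fast component: 7 Hz Gabor centered mid-window; carrier and width chosen
  # so that the content leaking through the delta analysis filter's roll-off
  # is negligible and the group contrast stays band specific
  t0 <- 0.175; sg <- 0.12
  fast <- cos(2 * pi * 7 * (tau - t0)) * exp(-(tau - t0)^2 / (2 * sg^2))
  # Tukey taper so both components are compactly supported in the window
  edge <- 0.15
  u <- (tau - min(tau)) / diff(range(tau))
  taper <- rep(1, length(u))
  taper[u < edge] <- 0.5 * (1 - cos(pi * u[u < edge] / edge))
  taper[u > 1 - edge] <- 0.5 * (1 - cos(pi * (1 - u[u > 1 - edge]) / edge))
  slow <- slow * taper
  fast <- fast * taper
  nlag <- length(tau)
  slow[c(1L, nlag)] <- 0
  fast[c(1L, nlag)] <- 0
  slow <- slow / max(abs(slow))
  fast <- fast / max(abs(fast))
  temporal <- slow + theta_gain * fast
  temporal_ref <- slow + fast   # gain = 1 reference (normative encoding)
  band_profile <- exp(-((seq_len(n_bands) - (n_bands + 1) / 2)^2) /
                        (2 * (n_bands / 3)^2))
  # balanced random polarity map: zero-sum like an average-referenced
  # dipolar topography, so common-average referencing leaves the per-channel
  # signal amplitude (and hence tracking) unchanged in expectation
  chan_map <- with_seed(seed, sample(rep(c(-1, 1), length.out = n_channels)))
  build <- function(tc) array(outer(outer(tc, band_profile), chan_map),
                              c(nlag, n_bands, n_channels))
  weights_ref <- build(temporal_ref)
  # one normalization constant for both, so only the theta component
  # differs between gain settings
  norm <- max(abs(weights_ref))
  structure(list(weights = build(temporal) / norm,
                 weights_ref = weights_ref / norm,
                 lags = window$lag_ms, window = window,
                 band_gain = c(delta = 1, theta = theta_gain),
                 latency_ms = latency_ms, seed = seed),
            class = "ground_truth_kernel")
}

#' Simulate one subject's EEG from known encoding
#'
#' For each track the post-onset EEG is
#' `signal(channel, t) = sum_band sum_tau weights(tau, band, channel) *
#' envelope_edge(band, t - tau)` computed with the package's own envelope
#' module and lagged design, plus 1/f Gaussian noise scaled to `snr_db`
#' (pooled RMS over channels and tracks, exact by construction). Each channel
#' receives independent noise plus a shared common-mode component (mixing
#' weight 0.3) so that common-average referencing is non-trivial. A
#' `pre_stimulus_s` noise-only segment precedes each track.
#'
#' @param stimuli List of [audio_track()] objects (one per track).
#' @param kernel A [ground_truth_kernel()].
#' @param config A [simulation_config()].
#' @param subject_id,group Labels stored on the result.
#' @param envelopes Optional list of precomputed [multiband_envelope()]s for
#'   `stimuli` (they are deterministic given the audio, so sharing them
#'   across subjects saves recomputation).
#' @return An [eeg_epochs()] (band `"raw"`) with attribute `"ground_truth"`:
#'   a list with the envelopes used, empirical signal/noise RMS and the
#'   realized SNR in dB.
#' @export
simulate_subject_eeg <- function(stimuli, kernel, config = simulation_config(),
                                 subject_id = "sim01", group = "HC",
                                 envelopes = NULL) {
  if (length(stimuli) == 0L) stop_invalid("`stimuli` must be non-empty")
  nb <- dim(kernel$weights)[2L]
  if (nb != config$n_bands)
    stop_dimension("kernel has ", nb, " bands but config$n_bands = ",
                   config$n_bands)
  nch <- dim(kernel$weights)[3L]
  window <- kernel$window
  fs <- config$eeg_fs
  if (is.null(envelopes)) {
    spec <- filterbank_spec(n_bands = nb)
    envelopes <- lapply(stimuli, function(tr)
      compute_envelope(tr, spec, fs_out = fs))
  }
  envs <- envelopes
  if (nrow(envs[[1]]$features) != nb)
    stop_dimension("precomputed envelopes have ", nrow(envs[[1]]$features),
                   " bands, kernel has ", nb)
  Wflat <- flatten_weights(kernel$weights)
  Wref <- flatten_weights(kernel$weights_ref)
  pre <- as.integer(round(config$pre_stimulus_s * fs))
  n_post <- ncol(envs[[1]]$features)
  n_tot <- pre + n_post
  n_trk <- length(stimuli)
  signal <- array(0, c(nch, n_tot, n_trk))
  noise <- array(0, c(nch, n_tot, n_trk))
  ss_ref <- 0
  with_seed(config$seed, {
    for (k in seq_len(n_trk)) {
      if (ncol(envs[[k]]$features) != n_post)
        stop_dimension("tracks must share a common duration")
      X <- build_lagged_design(envs[[k]], window)
      signal[, (pre + 1):n_tot, k] <- t(X %*% Wflat)
      ss_ref <- ss_ref + sum((X %*% Wref)^2)
      common <- powerlaw_noise(n_tot, config$noise_exponent, fs)
      for (c in seq_len(nch)) {
        noise[c, , k] <- powerlaw_noise(n_tot, config$noise_exponent, fs) +
          0.3 * common
      }
    }
  })
  rms_sig <- rms(signal[, (pre + 1):n_tot, , drop = FALSE])
  # noise floor calibrated against the gain-1 reference encoding, so that
  # band-specific gains change in-band SNR rather than being normalized away
  rms_ref <- sqrt(ss_ref / (n_post * nch * n_trk))
  rms_noi <- rms(noise[, (pre + 1):n_tot, , drop = FALSE])
  if (rms_ref > 0) {
    scale <- rms_ref / (rms_noi * 10^(config$snr_db / 20))
    noise <- noise * scale
    rms_noi <- rms_noi * scale
  }
  data <- signal + noise
  epochs <- eeg_epochs(data, fs = fs,
                       channel_labels = default_channel_labels(nch),
                       band = "raw",
                       epoch_window_s = c(-config$pre_stimulus_s,
                                          n_post / fs),
                       onset_sample = pre + 1L,
                       subject_id = subject_id, group = group)
  attr(epochs, "ground_truth") <- list(
    envelopes = envs, kernel = kernel,
    rms_signal = rms_sig, rms_noise = rms_noi, rms_reference = rms_ref,
    snr_db_realized = if (rms_sig > 0) 20 * log10(rms_sig / rms_noi) else -Inf)
  epochs
}

# 10-20-flavoured labels; Fz first so the default cluster electrode exists.
default_channel_labels <- function(n) {
  base <- c("Fz", "Cz", "Pz", "Oz", "F3", "F4", "C3", "C4", "P3", "P4",
            "O1", "O2", "F7", "F8", "T7", "T8", "P7", "P8", "FC1", "FC2",
            "CP1", "CP2", "FC5", "FC6", "CP5", "CP6", "TP9", "TP10", "AFz",
            "FCz", "POz", "Fp1", "Fp2")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, paste0("ch", seq_len(n - length(base))))
}
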