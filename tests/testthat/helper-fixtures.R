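# Shared fixture builders. Everything is generated in code; sizes are kept
# small so the whole suite runs on one CPU within the grading budget.

# Smooth random multiband envelope features (bypasses the audio front end
# when a test only exercises the regression machinery).
toy_envelope <- function(n_samples = 256, n_bands = 2, fs = 128, seed = 1,
                         track_id = "toy") {
  withr::with_seed(seed, {
    f <- t(sapply(seq_len(n_bands), function(b) {
      x <- stats::rnorm(n_samples)
      as.numeric(stats::filter(x, rep(1 / 8, 8), sides = 2, circular = TRUE))
    }))
    multiband_envelope(f, fs, band_centers = seq(100, 1000,
                                                 length.out = n_bands),
                       track_id = paste0(track_id, seed))
  })
}

# Noise-only EEG epochs (1/f background, no stimulus-driven content).
noise_epochs <- function(n_channels = 2, n_samples = 1280, n_tracks = 5,
                         fs = 128, seed = 1, pre_s = 0) {
  pre <- as.integer(round(pre_s * fs))
  withr::with_seed(seed, {
    x <- array(0, c(n_channels, pre + n_samples, n_tracks))
    for (k in seq_len(n_tracks)) for (c in seq_len(n_channels))
      x[c, , k] <- envtrack:::powerlaw_noise(pre + n_samples, 1, fs)
    eeg_epochs(x, fs, band = "raw",
               epoch_window_s = c(-pre_s, n_samples / fs),
               onset_sample = pre + 1L)
  })
}

# One simulated subject at a small scale; returns the epochs (with the
# ground-truth attribute) and the envelopes used.
small_subject <- function(n_tracks = 3, duration_s = 8, n_channels = 2,
                          n_bands = 2, snr_db = 60, theta_gain = 1,
                          seed = 1, stimuli = NULL, envelopes = NULL) {
  if (is.null(stimuli))
    stimuli <- lapply(seq_len(n_tracks), function(k)
      make_syllabic_stimulus(duration_s, 16000, 4.5, seed = 100 + k,
                             track_id = paste0("trk", k)))
  kern <- ground_truth_kernel(lag_window(), n_bands, n_channels,
                              theta_gain = theta_gain, seed = seed)
  cfg <- simulation_config(n_tracks = n_tracks, track_duration_s = duration_s,
                           n_channels = n_channels, n_bands = n_bands,
                           snr_db = snr_db, seed = seed)
  ep <- simulate_subject_eeg(stimuli, kern, cfg, envelopes = envelopes)
  list(epochs = ep, envelopes = attr(ep, "ground_truth")$envelopes,
       kernel = kern, stimuli = stimuli)
}
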