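test_that("syllabic stimulus: length, determinism, modulation peak", {
  au <- make_syllabic_stimulus(1, 16000, 4, seed = 3)
  expect_length(au$samples, 16000)
  expect_lte(max(abs(au$samples)), 1)
  au2 <- make_syllabic_stimulus(1, 16000, 4, seed = 3)
  expect_identical(au$samples, au2$samples)
  expect_error(make_syllabic_stimulus(-1, 16000, 4),
               class = "envtrack_invalid_argument")
  expect_error(make_syllabic_stimulus(1, 16000, 12),
               class = "envtrack_invalid_argument")

  # broadband Hilbert-envelope modulation spectrum peaks at the syllable
  # rate (FFT oracle), 4.5 +/- 1 Hz
  long <- make_syllabic_stimulus(60, 16000, 4.5, seed = 1)
  env <- envtrack:::hilbert_env(long$samples, pad = 16000)
  er <- envtrack:::resample_fft(env - mean(env), 16000, 128)
  S <- abs(stats::fft(er))^2
  f <- seq(0, 128, length.out = length(er) + 1)[seq_along(er)]
  sel <- f > 1.5 & f < 12
  expect_lt(abs(f[sel][which.max(S[sel])] - 4.5), 1)
})

test_that("ground-truth kernel satisfies its invariants", {
  win <- lag_window()
  k <- ground_truth_kernel(win, n_bands = 4, n_channels = 8,
                           theta_gain = 2, seed = 1)
  expect_true(all(is.finite(k$weights)))
  nlag <- length(win$lags)
  expect_true(all(k$weights[1, , ] == 0))
  expect_true(all(k$weights[nlag, , ] == 0))
  expect_equal(unname(k$band_gain["theta"]), 2)
  expect_error(ground_truth_kernel(win, 4, 8, theta_gain = 0),
               class = "envtrack_invalid_argument")
  # polarity map is balanced, so common-average referencing cannot cancel it
  k2 <- ground_truth_kernel(win, 4, 8, seed = 5)
  pol <- sign(k2$weights[20, 2, ])
  expect_equal(sum(pol), 0)
})

test_that("simulated EEG hits the requested SNR and spectral slope", {
  sub <- small_subject(n_tracks = 3, duration_s = 8, snr_db = -3, seed = 6)
  gt <- attr(sub$epochs, "ground_truth")
  # at theta_gain = 1 the realized broadband SNR matches by construction
  expect_lt(abs(gt$snr_db_realized - (-3)), 0.5)
  # pre-stimulus segment is noise only
  pre <- sub$epochs$data[, 1:sub$epochs$onset_sample - 1, ]
  expect_gt(sd(pre), 0)
  expect_equal(dim(sub$epochs$data)[2],
               sub$epochs$onset_sample - 1 + ncol(sub$envelopes[[1]]$features))

  # 1/f spectral slope of the generated noise within 0.2 of -1
  x <- envtrack:::with_seed(11, envtrack:::powerlaw_noise(120 * 128, 1, 128))
  S <- abs(stats::fft(x))^2
  f <- seq(0, 128, length.out = length(x) + 1)[seq_along(x)]
  sel <- f >= 1 & f <= 30
  lf <- log10(f[sel]); lS <- log10(S[sel])
  # average the log-periodogram in log-spaced bins before fitting
  bins <- cut(lf, 24)
  slope <- coef(lm(tapply(lS, bins, mean) ~ tapply(lf, bins, mean)))[2]
  expect_lt(abs(slope - (-1)), 0.2)
})

test_that("simulation is deterministic and a zero kernel yields pure noise", {
  s1 <- small_subject(seed = 8)
  s2 <- small_subject(seed = 8)
  expect_identical(s1$epochs$data, s2$epochs$data)

  kern0 <- s1$kernel
  kern0$weights[] <- 0
  kern0$weights_ref[] <- 0
  cfg <- simulation_config(n_tracks = 3, track_duration_s = 8,
                           n_channels = 2, n_bands = 2, snr_db = 60, seed = 8)
  ep0 <- simulate_subject_eeg(s1$stimuli, kern0, cfg,
                              envelopes = s1$envelopes)
  gt0 <- attr(ep0, "ground_truth")
  expect_equal(gt0$rms_signal, 0)
  expect_gt(sd(ep0$data), 0)
})

test_that("theta gain raises theta-band tracking for matched noise", {
  stim <- lapply(1:3, function(k)
    make_syllabic_stimulus(8, 16000, 4.5, seed = 200 + k,
                           track_id = paste0("t", k)))
  base <- small_subject(stimuli = stim, snr_db = -8, theta_gain = 1, seed = 21)
  gain <- small_subject(stimuli = stim, envelopes = base$envelopes,
                        snr_db = -8, theta_gain = 2, seed = 21)
  win <- lag_window()
  r1 <- crossval_tracking(base$envelopes,
                          preprocess_epochs(base$epochs, "theta"), win)$r_mean
  r2 <- crossval_tracking(base$envelopes,
                          preprocess_epochs(gain$epochs, "theta"), win)$r_mean
  expect_gt(r2, r1)
})
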