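test_that("lagged design: lag arithmetic, single-lag identity, shifts", {
  win <- lag_window(-100, 450, 128)
  # round(-0.1*128) = -13, round(0.45*128) = 58, inclusive
  expect_equal(win$lags, seq.int(round(-0.1 * 128), round(0.45 * 128)))
  env16 <- toy_envelope(n_samples = 200, n_bands = 16)
  X <- build_lagged_design(env16, win)
  expect_equal(ncol(X), 16 * length(win$lags) + 1)
  expect_equal(nrow(X), 200)
  expect_true(all(X[, 1] == 1))

  # single-lag window: design is the feature vector plus intercept
  env1 <- toy_envelope(n_samples = 64, n_bands = 1)
  X0 <- build_lagged_design(env1, lag_window(-1e-9, 1e-9, 128))
  expect_equal(ncol(X0), 2)
  expect_equal(X0[, 2], env1$features[1, ])

  # construction property: column for lag tau holds env(t - tau)
  env2 <- toy_envelope(n_samples = 64, n_bands = 2, seed = 3)
  win2 <- lag_window(-3000 / 128, 3000 / 128, 128)  # lags -3..3 in samples
  X2 <- build_lagged_design(env2, win2)
  lags <- attr(X2, "lags")
  for (li in seq_along(lags)) {
    tau <- lags[li]
    t <- 30
    expect_equal(X2[t, 1 + (li - 1) * 2 + 1:2], env2$features[, t - tau])
  }
  expect_error(build_lagged_design(env2, lag_window(fs = 64)),
               class = "envtrack_invalid_argument")
})

test_that("ridge fit: exact recovery, shrinkage, and the gram oracle", {
  env <- toy_envelope(n_samples = 300, n_bands = 2, seed = 4)
  win <- lag_window(-50, 100, 128)
  X <- build_lagged_design(env, win)
  p <- ncol(X)
  set.seed(5)
  w_true <- matrix(rnorm(p * 3), p, 3)
  Y <- X %*% w_true
  fit <- fit_ridge(X, Y, lambda = 0)
  W_flat <- rbind(fit$intercept, envtrack:::flatten_weights(fit$weights)[-1, ])
  expect_equal(W_flat, w_true, tolerance = 1e-6, ignore_attr = TRUE)

  # monotone shrinkage of the coefficient norm in lambda
  norms <- sapply(c(0, 1, 10, 100, 1e4), function(l)
    sum(fit_ridge(X, Y, l)$weights^2))
  expect_true(all(diff(norms) < 0))

  # explicit normal-equations oracle on a small system
  Xs <- cbind(1, matrix(rnorm(10), 5, 2))
  Ys <- matrix(rnorm(5), 5, 1)
  for (l in c(0, 1, 100)) {
    XtX <- t(Xs) %*% Xs
    m <- sum(diag(XtX)) / 3
    pen <- diag(c(0, l * m, l * m))
    w_o <- solve(XtX + pen, t(Xs) %*% Ys)
    fit_s <- fit_ridge(Xs, Ys, l)
    expect_equal(c(fit_s$intercept, as.vector(fit_s$weights)), as.vector(w_o),
                 tolerance = 1e-8)
  }
  expect_error(fit_ridge(X, Y[-1, , drop = FALSE], 1),
               class = "envtrack_dimension_error")
})

test_that("prediction is linear and exact on a consistent system", {
  env <- toy_envelope(n_samples = 256, n_bands = 2, seed = 6)
  win <- lag_window(-50, 150, 128)
  X <- build_lagged_design(env, win)
  set.seed(7)
  Y <- X %*% matrix(rnorm(ncol(X) * 2), ncol(X), 2)
  fit <- fit_ridge(X, Y, 0)
  pred <- predict_eeg(fit, env, win)
  expect_gt(min(diag(cor(pred, Y))), 1 - 1e-10)

  zero <- fit
  zero$weights[] <- 0
  pz <- predict_eeg(zero, env, win)
  expect_true(all(abs(sweep(pz, 2, fit$intercept)) < 1e-12))

  env2 <- env; env2$features <- 2 * env$features
  p2 <- predict_eeg(fit, env2, win)
  expect_equal(sweep(p2, 2, fit$intercept),
               2 * sweep(pred, 2, fit$intercept), tolerance = 1e-9)

  env3 <- toy_envelope(n_samples = 256, n_bands = 3)
  expect_error(predict_eeg(fit, env3, win),
               class = "envtrack_dimension_error")
})

test_that("cross-validated tracking: high SNR, pairing invariance, errors", {
  sub <- small_subject(n_tracks = 3, duration_s = 8, snr_db = 60, seed = 10)
  win <- lag_window()
  # raw band: the generating kernel lies inside the lag window, so the fit
  # is consistent and tracking approaches 1 at high SNR
  ep <- zscore_subject(common_average_reference(sub$epochs))
  tr <- crossval_tracking(sub$envelopes, ep, win)
  expect_gt(tr$r_mean, 0.9)
  expect_true(all(tr$r_per_track_channel >= -1 & tr$r_per_track_channel <= 1))

  # permuting track order of both envs and epochs identically is a no-op
  perm <- c(3, 1, 2)
  ep_p <- ep
  ep_p$data <- ep$data[, , perm]
  tr_p <- crossval_tracking(sub$envelopes[perm], ep_p, win)
  expect_equal(tr_p$r_mean, tr$r_mean, tolerance = 1e-12)
  expect_equal(tr_p$r_per_track_channel[order(perm), ],
               tr$r_per_track_channel, tolerance = 1e-12)
  expect_equal(tr_p$lambda_selected, tr$lambda_selected)

  expect_error(crossval_tracking(sub$envelopes[1:2],
                                 ep, win),
               class = "envtrack_insufficient_data")
})

test_that("stimulus-independent EEG gives tracking near zero", {
  envs <- lapply(1:5, function(k) toy_envelope(1280, 2, seed = 40 + k,
                                               track_id = "n"))
  ep <- noise_epochs(n_channels = 2, n_samples = 1280, n_tracks = 5, seed = 41)
  tr <- crossval_tracking(envs, ep, lag_window(), lambda_grid = 1)
  expect_lt(abs(mean(tr$r_per_track_channel)),
            2 / sqrt(1280 * 5 * 2) * 3)
})

test_that("permutation chance level is deterministic and needs variety", {
  envs <- lapply(1:4, function(k) toy_envelope(640, 2, seed = 50 + k,
                                               track_id = "p"))
  ep <- noise_epochs(n_channels = 2, n_samples = 640, n_tracks = 4, seed = 51)
  c1 <- permutation_chance_level(envs, ep, lag_window(), lambda = 1,
                                 n_perm = 120, seed = 9)
  c2 <- permutation_chance_level(envs, ep, lag_window(), lambda = 1,
                                 n_perm = 120, seed = 9)
  expect_identical(as.numeric(c1), as.numeric(c2))
  expect_length(attr(c1, "null_distribution"), 120)
  expect_error(permutation_chance_level(envs[1:2], noise_epochs(2, 640, 2),
                                        lag_window(), 1, 120),
               class = "envtrack_insufficient_data")
  expect_error(permutation_chance_level(envs, ep, lag_window(), 1, n_perm = 50),
               class = "envtrack_invalid_argument")
})

test_that("kernel recovery error shrinks as SNR grows", {
  stim <- lapply(1:3, function(k)
    make_syllabic_stimulus(8, 16000, 4.5, seed = 300 + k,
                           track_id = paste0("t", k)))
  win <- lag_window()
  envs <- NULL
  nrmse <- sapply(c(-10, 0, 10, 60), function(snr) {
    mean(sapply(1:6, function(s) {
      sub <- small_subject(stimuli = stim, envelopes = envs, snr_db = snr,
                           seed = 400 + s)
      envs <<- sub$envelopes
      fit <- subject_trf(sub$envelopes, sub$epochs, win, lambda = 0)
      sqrt(mean((fit$weights - sub$kernel$weights)^2)) /
        sd(as.vector(sub$kernel$weights))
    }))
  })
  expect_true(all(diff(nrmse) < 0))
  expect_lt(nrmse[4], 0.05)
})
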