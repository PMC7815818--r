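# Forward TRF estimation: time-lagged design matrices, ridge regression with
# an unpenalized intercept, leave-one-track-out cross-validation with
# per-track model averaging (the mTRF convention), and permutation-derived
# chance levels from mismatched stimulus/EEG pairings.

#' Lag window for TRF estimation
#'
#' Lag samples are `round(t_min_ms * fs / 1000) : round(t_max_ms * fs / 1000)`,
#' inclusive of both endpoints. Positive lags mean the stimulus precedes the
#' EEG (causal response).
#'
#' @param t_min_ms,t_max_ms Window edges in milliseconds (defaults -100 and
#'   450).
#' @param fs Sampling rate of both the feature and EEG time axes, Hz.
#' @return An object of class `lag_window`.
#' @export
lag_window <- function(t_min_ms = -100, t_max_ms = 450, fs = 128) {
  if (t_min_ms >= t_max_ms) stop_invalid("t_min_ms must be < t_max_ms")
  assert_scalar_num(fs, "fs", positive = TRUE)
  lags <- seq.int(round(t_min_ms * fs / 1000), round(t_max_ms * fs / 1000))
  structure(list(t_min_ms = t_min_ms, t_max_ms = t_max_ms, fs = fs,
                 lags = lags, lag_ms = lags * 1000 / fs),
            class = "lag_window")
}

#' Time-lagged design matrix
#'
#' Row `t` contains `env(band, t - tau)` for every lag `tau` in the window and
#' every band, zero-padded where `t - tau` falls outside the track. Columns
#' are ordered lag-major, band-minor (all bands at the first lag, then all
#' bands at the next lag, ...), preceded by an all-ones intercept column.
#'
#' @param env A [multiband_envelope()].
#' @param window A [lag_window()]; its `fs` must equal `env$fs`.
#' @return A samples x (1 + lags * bands) numeric matrix with attributes
#'   `lags` and `n_bands`.
#' @export
build_lagged_design <- function(env, window = lag_window(fs = env$fs)) {
  stopifnot(inherits(env, "multiband_envelope"))
  if (!isTRUE(all.equal(env$fs, window$fs)))
    stop_invalid("envelope rate (", env$fs, ") != lag window rate (", window$fs, ")")
  F <- t(env$features)           # time x band
  n <- nrow(F); nb <- ncol(F)
  lags <- window$lags
  X <- matrix(0, n, 1L + length(lags) * nb)
  X[, 1L] <- 1
  for (li in seq_along(lags)) {
    tau <- lags[li]
    cols <- 1L + (li - 1L) * nb + seq_len(nb)
    src <- seq_len(n) - tau
    ok <- src >= 1L & src <= n
    X[ok, cols] <- F[src[ok], , drop = FALSE]
  }
  attr(X, "lags") <- lags
  attr(X, "n_bands") <- nb
  X
}

# Solve the penalized normal equations for all channels at once.
# XtX includes the intercept row/column; the intercept is unpenalized.
# lambda is scaled by m = trace(XtX)/ncol(XtX) so that its effective size is
# comparable across track lengths and feature scalings.
ridge_solve <- function(XtX, XtY, lambda, m = sum(diag(XtX)) / ncol(XtX)) {
  p <- ncol(XtX)
  pen <- rep(lambda * m, p)
  pen[1L] <- 0
  A <- XtX + diag(pen, p)
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) {
    if (lambda == 0)
      stop_degenerate("normal equations are rank deficient; use lambda > 0")
    stop_degenerate("penalized system could not be factorized")
  }
  backsolve(R, backsolve(R, XtY, transpose = TRUE))
}

#' Fit a ridge-regularized TRF
#'
#' Solves `w = (X'X + lambda * m * I)^-1 X'y` per EEG channel, where
#' `m = trace(X'X) / ncol(X)` and the leading intercept column is left
#' unpenalized.
#'
#' @param design Design matrix from [build_lagged_design()].
#' @param eeg Samples x channels EEG matrix (same rows as `design`).
#' @param lambda Ridge parameter, >= 0.
#' @param lag_axis_ms,band_centers Optional metadata stored on the model.
#' @return An object of class `trf_model` with `weights` (lag x band x
#'   channel), `intercept` (per channel), `lambda`.
#' @export
fit_ridge <- function(design, eeg, lambda, lag_axis_ms = NULL,
                      band_centers = NULL) {
  if (is.vector(eeg)) eeg <- matrix(eeg, ncol = 1L)
  if (nrow(design) != nrow(eeg))
    stop_dimension("design has ", nrow(design), " rows but eeg has ", nrow(eeg))
  if (lambda < 0) stop_invalid("`lambda` must be >= 0")
  XtX <- crossprod(design)
  XtY <- crossprod(design, eeg)
  W <- ridge_solve(XtX, XtY, lambda)
  trf_model_from_flat(W, design, lambda, lag_axis_ms, band_centers)
}

trf_model_from_flat <- function(W, design, lambda, lag_axis_ms = NULL,
                                band_centers = NULL) {
  lags <- attr(design, "lags")
  nb <- attr(design, "n_bands")
  if (is.null(lags) || is.null(nb)) {   # plain design matrix: 1 "band"
    lags <- seq_len(nrow(W) - 1L)
    nb <- 1L
  }
  nch <- ncol(W)
  weights <- array(W[-1L, , drop = FALSE], c(nb, length(lags), nch))
  weights <- aperm(weights, c(2L, 1L, 3L))  # lag x band x channel
  structure(list(weights = weights, intercept = W[1L, ], lambda = lambda,
                 lag_axis_ms = if (is.null(lag_axis_ms)) lags else lag_axis_ms,
                 band_centers = band_centers),
            class = "trf_model")
}

#' @export
print.trf_model <- function(x, ...) {
  d <- dim(x$weights)
  cat(sprintf("<trf_model> %d lags x %d bands x %d channels, lambda = %g\n",
              d[1], d[2], d[3], x$lambda))
  invisible(x)
}

# Flatten a lag x band x channel weight array to the (1 + lag*band) x channel
# layout of the design matrix (zero intercept row).
flatten_weights <- function(weights) {
  d <- dim(weights)
  W <- matrix(aperm(weights, c(2L, 1L, 3L)), d[1] * d[2], d[3])
  rbind(0, W)
}

#' Predict EEG from a TRF model
#'
#' @param model A [trf_model()].
#' @param env A [multiband_envelope()] with the model's band count.
#' @param window The [lag_window()] the model was fit with.
#' @return Samples x channels matrix of predicted EEG.
#' @export
predict_eeg <- function(model, env, window = lag_window(fs = env$fs)) {
  if (dim(model$weights)[2L] != nrow(env$features))
    stop_dimension("model has ", dim(model$weights)[2L], " bands but envelope has ",
                   nrow(env$features))
  if (dim(model$weights)[1L] != length(window$lags))
    stop_dimension("model lag count != window lag count")
  X <- build_lagged_design(env, window)
  W <- flatten_weights(model$weights)
  W[1L, ] <- model$intercept
  X %*% W
}

#' Cross-validated tracking result container
#'
#' @param r Track x channel matrix of Pearson correlations.
#' @param lambda_selected Selected ridge parameter.
#' @param band EEG band label.
#' @param lambda_grid,grand_means Grid searched and the grand-mean r per
#'   grid value.
#' @param chance_level Permutation 97.5th-percentile chance level (NA until
#'   computed).
#' @return An object of class `tracking_result`. `r_mean` is the mean over
#'   tracks then channels (the cortical tracking metric).
#' @export
tracking_result <- function(r, lambda_selected, band = "raw",
                            lambda_grid = NULL, grand_means = NULL,
                            chance_level = NA_real_) {
  structure(list(r_per_track_channel = r,
                 r_mean = mean(colMeans(r)),
                 chance_level = chance_level,
                 lambda_selected = lambda_selected,
                 lambda_grid = lambda_grid, grand_means = grand_means,
                 band = band),
            class = "tracking_result")
}

#' @export
print.tracking_result <- function(x, ...) {
  cat(sprintf("<tracking_result band=%s> r_mean = %.4f (lambda* = %g, chance = %s)\n",
              x$band, x$r_mean, x$lambda_selected,
              ifelse(is.na(x$chance_level), "NA",
                     sprintf("%.4f", x$chance_level))))
  invisible(x)
}

# Per-track gram matrices, shared across subjects through `cache` (an
# environment): the design depends only on the stimulus, not the EEG.
design_gram <- function(env, window, cache = NULL) {
  key <- NULL
  if (!is.null(cache)) {
    key <- paste(env$track_id, nrow(env$features), ncol(env$features),
                 sprintf("%.12e", sum(env$features)),
                 window$t_min_ms, window$t_max_ms, window$fs, sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
  }
  X <- build_lagged_design(env, window)
  out <- list(X = X, XtX = crossprod(X), key = key)
  out$m <- sum(diag(out$XtX)) / ncol(out$XtX)
  if (!is.null(key)) cache[[key]] <- out
  out
}

# Cholesky factor of (XtX + lambda*m*P), cached per (track, lambda).
gram_chol <- function(g, lambda, cache = NULL, key_base = NULL) {
  key <- if (!is.null(cache) && !is.null(key_base))
    paste0(key_base, "|chol|", lambda) else NULL
  if (!is.null(key) && !is.null(cache[[key]])) return(cache[[key]])
  p <- ncol(g$XtX)
  pen <- rep(lambda * g$m, p); pen[1L] <- 0
  R <- chol(g$XtX + diag(pen, p))
  if (!is.null(key)) cache[[key]] <- R
  R
}

#' Leave-one-track-out cross-validated tracking
#'
#' For each ridge parameter in `lambda_grid` and each held-out track `k`, a
#' TRF is fit to every training track separately and the per-track models are
#' averaged to form the fold model (mTRF convention); the fold model predicts
#' the held-out track and per-channel Pearson correlations are recorded.
#' The grid value maximizing the grand-mean correlation is selected.
#' Correlations use only post-onset samples.
#'
#' @param envs List of [multiband_envelope()], one per track, aligned with
#'   the tracks in `epochs`.
#' @param epochs An [eeg_epochs()] object.
#' @param window A [lag_window()].
#' @param lambda_grid Ridge parameters to search (default decade steps
#'   `10^(-6:6)`; the penalty is normalized by the mean diagonal of X'X, so
#'   values well below 1 approach the unpenalized fit).
#' @param cache Optional environment for sharing design-matrix work across
#'   subjects presented with the same stimuli.
#' @return A [tracking_result()].
#' @export
crossval_tracking <- function(envs, epochs, window = lag_window(fs = epochs$fs),
                              lambda_grid = 10^(-6:6), cache = NULL) {
  n <- length(envs)
  if (n < 3L) stop_insufficient("need >= 3 tracks for cross-validation, got ", n)
  if (n_tracks(epochs) != n)
    stop_dimension("number of envelopes (", n, ") != number of EEG tracks (",
                   n_tracks(epochs), ")")
  nch <- n_channels(epochs)
  grams <- lapply(envs, design_gram, window = window, cache = cache)
  Ys <- lapply(seq_len(n), function(k)
    post_onset_matrix(epochs, k, n_samples = ncol(envs[[k]]$features)))
  XtYs <- lapply(seq_len(n), function(k) crossprod(grams[[k]]$X, Ys[[k]]))
  p <- ncol(grams[[1]]$XtX)
  best <- NULL
  grand_means <- numeric(length(lambda_grid))
  for (li in seq_along(lambda_grid)) {
    lam <- lambda_grid[li]
    Ws <- array(0, c(p, nch, n))
    for (i in seq_len(n)) {
      R <- gram_chol(grams[[i]], lam, cache, grams[[i]]$key)
      Ws[, , i] <- backsolve(R, backsolve(R, XtYs[[i]], transpose = TRUE))
    }
    r_mat <- matrix(NA_real_, n, nch)
    Wsum <- apply(Ws, c(1, 2), sum)
    for (k in seq_len(n)) {
      wbar <- (Wsum - Ws[, , k]) / (n - 1)
      pred <- grams[[k]]$X %*% wbar
      r_mat[k, ] <- colwise_pearson(pred, Ys[[k]])
    }
    grand_means[li] <- mean(colMeans(r_mat))
    if (is.null(best) || grand_means[li] > best$gm) {
      best <- list(gm = grand_means[li], r = r_mat, lambda = lam)
    }
  }
  tracking_result(best$r, best$lambda, band = epochs$band,
                  lambda_grid = lambda_grid, grand_means = grand_means)
}

#' Fit one subject-level TRF at a fixed ridge parameter
#'
#' Averages per-track TRFs over all tracks (the model used on every fold,
#' without holding one out) — the natural summary for group comparison of
#' TRF time courses.
#'
#' @inheritParams crossval_tracking
#' @param lambda Ridge parameter.
#' @return A [trf_model()].
#' @export
subject_trf <- function(envs, epochs, window = lag_window(fs = epochs$fs),
                        lambda = 1, cache = NULL) {
  n <- length(envs)
  grams <- lapply(envs, design_gram, window = window, cache = cache)
  p <- ncol(grams[[1]]$XtX)
  nch <- n_channels(epochs)
  Wacc <- matrix(0, p, nch)
  for (i in seq_len(n)) {
    Y <- post_onset_matrix(epochs, i, n_samples = ncol(envs[[i]]$features))
    R <- gram_chol(grams[[i]], lambda, cache, grams[[i]]$key)
    Wacc <- Wacc + backsolve(R, backsolve(R, crossprod(grams[[i]]$X, Y),
                                          transpose = TRUE))
  }
  W <- Wacc / n
  trf_model_from_flat(W, grams[[1]]$X, lambda,
                      lag_axis_ms = window$lag_ms,
                      band_centers = envs[[1]]$band_centers)
}

#' Permutation chance level of the tracking metric
#'
#' Re-pairs stimulus tracks with non-matching EEG tracks (uniformly sampled
#' derangements), recomputes the cross-validated grand-mean correlation for
#' each permutation, and returns the 97.5th percentile of the permuted
#' distribution. Deterministic given `seed`.
#'
#' @inheritParams crossval_tracking
#' @param lambda Ridge parameter used for every permutation (typically the
#'   subject's selected value).
#' @param n_perm Number of permutations (>= 100).
#' @param seed RNG seed.
#' @param probs Percentile to return (default 0.975).
#' @return Scalar chance level, with the permutation distribution in
#'   attribute `"null_distribution"`.
#' @export
permutation_chance_level <- function(envs, epochs,
                                     window = lag_window(fs = epochs$fs),
                                     lambda = 1, n_perm = 1000, seed = 1,
                                     probs = 0.975, cache = NULL) {
  n <- length(envs)
  if (n < 3L)
    stop_insufficient("need >= 3 tracks to sample non-trivial derangements")
  if (n_perm < 100L) stop_invalid("`n_perm` must be >= 100")
  nch <- n_channels(epochs)
  grams <- lapply(envs, design_gram, window = window, cache = cache)
  ns <- ncol(envs[[1]]$features)
  Ys <- lapply(seq_len(n), function(k) post_onset_matrix(epochs, k, ns))
  p <- ncol(grams[[1]]$XtX)
  # per-pair weights: model trained on (env_i, eeg_j)
  W <- array(0, c(p, nch, n, n))
  for (i in seq_len(n)) {
    R <- gram_chol(grams[[i]], lambda, cache, grams[[i]]$key)
    for (j in seq_len(n)) {
      XtY <- crossprod(grams[[i]]$X, Ys[[j]])
      W[, , i, j] <- backsolve(R, backsolve(R, XtY, transpose = TRUE))
    }
  }
  bytes <- 8 * ns * nch * n^3
  use_cache <- bytes < 1.5e9
  if (use_cache) {
    # P[, , i, j, k]: prediction on track k's design of the (i, j) model
    PM <- array(0, c(ns * nch, n, n, n))
    Wflat <- matrix(W, p, nch * n * n)
    for (k in seq_len(n)) {
      PM[, , , k] <- grams[[k]]$X %*% Wflat
    }
    dim(PM) <- c(ns, nch, n, n, n)
  }
  Yc <- lapply(Ys, function(y) sweep(y, 2L, colMeans(y)))
  Ysd <- lapply(Yc, function(y) sqrt(colSums(y^2)))
  null_r <- with_seed(seed, {
    vapply(seq_len(n_perm), function(pp) {
      repeat {
        perm <- sample.int(n)
        if (!any(perm == seq_len(n))) break
      }
      rs <- matrix(NA_real_, n, nch)
      for (k in seq_len(n)) {
        others <- setdiff(seq_len(n), k)
        if (use_cache) {
          pred <- matrix(0, ns, nch)
          for (i in others) pred <- pred + PM[, , i, perm[i], k]
          pred <- pred / (n - 1)
        } else {
          wbar <- matrix(0, p, nch)
          for (i in others) wbar <- wbar + W[, , i, perm[i]]
          pred <- grams[[k]]$X %*% (wbar / (n - 1))
        }
        pc <- sweep(pred, 2L, colMeans(pred))
        num <- colSums(pc * Yc[[perm[k]]])
        den <- sqrt(colSums(pc^2)) * Ysd[[perm[k]]]
        rs[k, ] <- ifelse(den > 0, num / den, NA_real_)
      }
      mean(colMeans(rs))
    }, numeric(1))
  })
  out <- unname(stats::quantile(null_r, probs, type = 7))
  attr(out, "null_distribution") <- null_r
  out
}
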