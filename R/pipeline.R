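# End-to-end orchestration: simulate (or ingest) stimuli and EEG, extract
# envelope features, preprocess per band, cross-validate tracking, and run
# the group statistics, with a reproducibility manifest.

#' Study run configuration
#'
#' Defaults describe the emulated study (two groups of 10, two narratives of
#' 15 x 60 s tracks, 32 channels, 16 envelope bands); tests and demos pass
#' smaller values. The patient-like group's kernel carries `theta_gain_patient`
#' on its theta component; per-subject SNR is jittered by `snr_sd_db` around
#' `snr_db` to emulate between-subject signal-quality variation.
#'
#' @param n_subjects_per_group,n_narratives,n_tracks,track_duration_s,n_channels,n_bands
#'   Design sizes.
#' @param eeg_fs,audio_fs Sampling rates, Hz.
#' @param bands Character vector of analysis bands (subset of
#'   `"full"`, `"delta"`, `"theta"`).
#' @param snr_db,snr_sd_db Group-level broadband SNR and its between-subject
#'   SD, dB.
#' @param theta_gain_patient,theta_gain_control Theta-component gains of the
#'   two groups' ground-truth kernels.
#' @param syllable_rates_hz One syllable rate per narrative (narratives
#'   differ in speech rate).
#' @param lag_t_min_ms,lag_t_max_ms TRF lag window, ms.
#' @param lambda_grid Ridge grid for cross-validation.
#' @param n_perm_chance Permutations for the chance level (0 disables).
#' @param n_perm_cluster Permutations for the TRF cluster test (0 disables).
#' @param cluster_electrode Channel label for the TRF cluster comparison.
#' @param cluster_band Band whose TRFs are compared between groups.
#' @param zscore_mode `"pooled"` or `"per_channel"`.
#' @param rectify Rectify envelope edges (default FALSE, signed).
#' @param seed Master seed; all stage seeds derive from it.
#' @param out_dir Output directory (`NULL` for no files).
#' @return An object of class `run_config`.
#' @export
run_config <- function(n_subjects_per_group = 10L, n_narratives = 2L,
                       n_tracks = 15L, track_duration_s = 60,
                       n_channels = 32L, n_bands = 16L, eeg_fs = 128,
                       audio_fs = 16000, bands = c("delta", "theta"),
                       snr_db = -10, snr_sd_db = 2,
                       theta_gain_patient = 2, theta_gain_control = 1,
                       syllable_rates_hz = c(4.5, 4.0),
                       lag_t_min_ms = -100, lag_t_max_ms = 450,
                       lambda_grid = 10^(-6:6), n_perm_chance = 0L,
                       n_perm_cluster = 0L, cluster_electrode = "Fz",
                       cluster_band = "theta",
                       zscore_mode = "pooled", rectify = FALSE, seed = 1L,
                       out_dir = NULL) {
  known <- c("full", "delta", "theta")
  bad <- setdiff(bands, known)
  if (length(bad))
    stop_invalid("unknown band name in `bands`: ", paste(bad, collapse = ", "))
  if (length(syllable_rates_hz) < n_narratives)
    syllable_rates_hz <- rep_len(syllable_rates_hz, n_narratives)
  structure(list(
    n_subjects_per_group = assert_count(n_subjects_per_group, "n_subjects_per_group"),
    n_narratives = assert_count(n_narratives, "n_narratives"),
    n_tracks = assert_count(n_tracks, "n_tracks", min = 3L),
    track_duration_s = track_duration_s, n_channels = n_channels,
    n_bands = n_bands, eeg_fs = eeg_fs, audio_fs = audio_fs, bands = bands,
    snr_db = snr_db, snr_sd_db = snr_sd_db,
    theta_gain_patient = theta_gain_patient,
    theta_gain_control = theta_gain_control,
    syllable_rates_hz = syllable_rates_hz,
    lag_t_min_ms = lag_t_min_ms, lag_t_max_ms = lag_t_max_ms,
    lambda_grid = lambda_grid,
    n_perm_chance = as.integer(n_perm_chance),
    n_perm_cluster = as.integer(n_perm_cluster),
    cluster_electrode = cluster_electrode, cluster_band = cluster_band,
    zscore_mode = match.arg(zscore_mode, c("pooled", "per_channel")),
    rectify = isTRUE(rectify),
    seed = assert_count(seed, "seed", min = 0L), out_dir = out_dir),
    class = "run_config")
}

# Small deterministic seed-derivation stream (kept below 2^31).
derive_seed <- function(seed, ...) {
  ix <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (k in ix) s <- (s * 69069 + k) %% 2147483647
  as.integer(s)
}

#' Run a full simulated study
#'
#' Simulate -> envelope -> preprocess -> cross-validated TRF per band ->
#' group statistics. Per-subject failures are recorded in the manifest
#' without aborting the remaining subjects. Design matrices and Cholesky
#' factors are cached and shared across subjects (all subjects hear the same
#' narratives).
#'
#' @param config A [run_config()].
#' @param verbose Print per-stage progress.
#' @return Invisibly, a list with `tracking` (tidy data.frame), `anova`
#'   (per band), `chance` (per band, if enabled), `cluster` (if enabled),
#'   `trfs` (per subject, if cluster enabled), `manifest`.
#' @export
run_study <- function(config = run_config(), verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t_start <- Sys.time()
  window <- lag_window(config$lag_t_min_ms, config$lag_t_max_ms, config$eeg_fs)
  spec <- filterbank_spec(n_bands = config$n_bands)
  cache <- new.env(parent = emptyenv())
  groups <- c("HC", "lvPPA")
  gains <- c(HC = config$theta_gain_control, lvPPA = config$theta_gain_patient)
  say <- function(...) if (verbose) message(sprintf(...))

  # stimuli + envelopes, shared by all subjects
  envs <- vector("list", config$n_narratives)
  stimuli <- vector("list", config$n_narratives)
  for (nar in seq_len(config$n_narratives)) {
    stimuli[[nar]] <- lapply(seq_len(config$n_tracks), function(k)
      make_syllabic_stimulus(config$track_duration_s, config$audio_fs,
                             config$syllable_rates_hz[nar],
                             seed = derive_seed(config$seed, 1, nar, k),
                             track_id = sprintf("nar%d_trk%02d", nar, k)))
    envs[[nar]] <- lapply(stimuli[[nar]], function(tr)
      compute_envelope(tr, spec, fs_out = config$eeg_fs,
                       rectify = config$rectify))
    say("narrative %d: %d envelopes computed", nar, config$n_tracks)
  }

  rows <- list()
  errors <- list()
  trf_store <- list()
  subj_id <- 0L
  for (gi in seq_along(groups)) {
    grp <- groups[gi]
    for (si in seq_len(config$n_subjects_per_group)) {
      subj_id <- subj_id + 1L
      sid <- sprintf("%s%02d", tolower(grp), si)
      res <- tryCatch({
        kernel <- ground_truth_kernel(window, config$n_bands,
                                      config$n_channels,
                                      theta_gain = gains[[grp]],
                                      seed = derive_seed(config$seed, 2, subj_id))
        snr_i <- config$snr_db + with_seed(
          derive_seed(config$seed, 3, subj_id), stats::rnorm(1, 0, config$snr_sd_db))
        for (nar in seq_len(config$n_narratives)) {
          scfg <- simulation_config(
            n_subjects_per_group = 1L, n_tracks = config$n_tracks,
            track_duration_s = config$track_duration_s,
            n_channels = config$n_channels, eeg_fs = config$eeg_fs,
            audio_fs = config$audio_fs, n_bands = config$n_bands,
            snr_db = snr_i, seed = derive_seed(config$seed, 4, subj_id, nar))
          raw <- simulate_subject_eeg(stimuli[[nar]], kernel, scfg,
                                      subject_id = sid, group = grp,
                                      envelopes = envs[[nar]])
          for (band in config$bands) {
            ep <- preprocess_epochs(raw, band, config$zscore_mode)
            tr <- crossval_tracking(envs[[nar]], ep, window,
                                    config$lambda_grid, cache = cache)
            chance <- NA_real_
            if (config$n_perm_chance > 0) {
              chance <- as.numeric(permutation_chance_level(
                envs[[nar]], ep, window, lambda = tr$lambda_selected,
                n_perm = config$n_perm_chance,
                seed = derive_seed(config$seed, 5, subj_id, nar), cache = cache))
            }
            rows[[length(rows) + 1L]] <- data.frame(
              subject = sid, group = grp, narrative = nar, band = band,
              r_mean = tr$r_mean, lambda = tr$lambda_selected,
              chance_level = chance, snr_db = snr_i)
            if (config$n_perm_cluster > 0 && band == config$cluster_band) {
              model <- subject_trf(envs[[nar]], ep, window,
                                   lambda = tr$lambda_selected, cache = cache)
              ei <- match(config$cluster_electrode, ep$channel_labels)
              if (is.na(ei)) stop_invalid("electrode ", config$cluster_electrode,
                                          " not found")
              # band-averaged TRF time course at the chosen electrode
              trf_store[[sid]][[nar]] <- rowMeans(model$weights[, , ei])
            }
          }
        }
        say("subject %s (%s) done", sid, grp)
        TRUE
      }, error = function(e) e)
      if (inherits(res, "error")) {
        errors[[sid]] <- conditionMessage(res)
        say("subject %s FAILED: %s", sid, conditionMessage(res))
      }
    }
  }
  tracking <- do.call(rbind, rows)

  anovas <- list()
  for (band in config$bands) {
    tb <- tracking[tracking$band == band, ]
    wide <- stats::reshape(tb[, c("subject", "group", "narrative", "r_mean")],
                           direction = "wide", idvar = c("subject", "group"),
                           timevar = "narrative")
    vals <- as.matrix(wide[, grep("^r_mean", names(wide)), drop = FALSE])
    if (ncol(vals) == 2 && nrow(vals) >= 4 && !anyNA(vals) &&
        length(unique(wide$group)) == 2) {
      anovas[[band]] <- mixed_anova_2x2(vals, wide$group)
    }
  }

  cluster <- NULL
  if (config$n_perm_cluster > 0 && length(trf_store)) {
    grp_of <- function(sid) ifelse(grepl("^hc", sid), "HC", "lvPPA")
    per_nar <- list()
    for (nar in seq_len(config$n_narratives)) {
      A <- do.call(rbind, lapply(names(trf_store)[grp_of(names(trf_store)) == "lvPPA"],
                                 function(s) trf_store[[s]][[nar]]))
      B <- do.call(rbind, lapply(names(trf_store)[grp_of(names(trf_store)) == "HC"],
                                 function(s) trf_store[[s]][[nar]]))
      per_nar[[nar]] <- cluster_permutation_trf(
        A, B, n_perm = config$n_perm_cluster,
        seed = derive_seed(config$seed, 6, nar),
        lag_axis_ms = window$lag_ms)
    }
    cluster <- per_nar
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("envtrack")),
    seed = config$seed,
    config = config[setdiff(names(config), "out_dir")],
    n_subjects_done = subj_id - length(errors),
    errors = errors,
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
    timestamp = format(t_start, "%Y-%m-%dT%H:%M:%S%z"))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    tpath <- file.path(config$out_dir, "tracking.csv")
    utils::write.csv(tracking, tpath, row.names = FALSE)
    checks <- c(tracking.csv = unname(tools::md5sum(tpath)))
    for (band in names(anovas)) {
      ap <- file.path(config$out_dir, paste0("anova_", band, ".csv"))
      utils::write.csv(as.data.frame(anovas[[band]]), ap, row.names = FALSE)
      checks[paste0("anova_", band, ".csv")] <- unname(tools::md5sum(ap))
    }
    manifest$checksums <- as.list(checks)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }

  invisible(list(tracking = tracking, anova = anovas, cluster = cluster,
                 trfs = trf_store, manifest = manifest))
}
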