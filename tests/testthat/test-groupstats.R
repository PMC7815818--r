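test_that("EEG SNR proxy behaves like an RMS ratio", {
  fs <- 128
  pre_s <- 5
  n_post <- 20 * fs
  set.seed(12)
  noise <- array(rnorm(2 * (pre_s * fs + n_post) * 3), c(2, pre_s * fs + n_post, 3))
  ep <- eeg_epochs(noise, fs, epoch_window_s = c(-pre_s, 20))
  r1 <- eeg_snr(ep, post_window_s = c(1.6, 18), pre_window_s = c(-2.6, -1.6))
  expect_equal(r1$snr, 1, tolerance = 0.05)

  # post amplitude exactly doubled -> snr doubles
  ep2 <- ep
  ep2$data[, (pre_s * fs + 1):(pre_s * fs + n_post), ] <-
    2 * ep2$data[, (pre_s * fs + 1):(pre_s * fs + n_post), ]
  r2 <- eeg_snr(ep2, post_window_s = c(1.6, 18), pre_window_s = c(-2.6, -1.6))
  expect_equal(r2$snr, 2 * r1$snr, tolerance = 1e-10)

  # equal-power signal + noise post-onset -> snr ~ sqrt(2) (power addition)
  ep3 <- ep
  sig <- array(rnorm(2 * n_post * 3), c(2, n_post, 3))
  ep3$data[, (pre_s * fs + 1):(pre_s * fs + n_post), ] <-
    ep3$data[, (pre_s * fs + 1):(pre_s * fs + n_post), ] + sig
  r3 <- eeg_snr(ep3, post_window_s = c(1.6, 18), pre_window_s = c(-2.6, -1.6))
  expect_equal(r3$snr, sqrt(2), tolerance = 0.05)

  expect_error(eeg_snr(ep, post_window_s = c(1.6, 30)),
               class = "envtrack_invalid_argument")
  ez <- ep
  ez$data[, 1:(pre_s * fs), ] <- 0
  expect_error(eeg_snr(ez, post_window_s = c(1.6, 18)),
               class = "envtrack_degenerate_input")
})

test_that("RAU transform: exact midpoint, formula, monotonicity, mid-range", {
  # midpoint maps to exactly 50 (the two arcsines sum to pi/2)
  expect_equal(rau_transform(15, 30), 50, tolerance = 1e-12)
  # direct evaluation oracle at the floor
  theta <- asin(0) + asin(sqrt(1 / 31))
  expect_equal(rau_transform(0, 30), (146 / pi) * theta - 23,
               tolerance = 1e-12)
  # strictly increasing in `correct`
  expect_true(all(diff(rau_transform(0:25, 25)) > 0))
  # within 5 of percent correct over the mid-range
  p <- seq(0.2, 0.8, by = 0.05)
  expect_true(all(abs(rau_transform(round(100 * p), 100) - 100 * p) < 5))
  expect_error(rau_transform(31, 30), class = "envtrack_invalid_argument")
})

test_that("mixed ANOVA matches base aov() on a random balanced design", {
  set.seed(20)
  vals <- matrix(rnorm(40, mean = rep(c(0, 0.5), each = 20)), 20, 2)
  grp <- rep(c("HC", "lvPPA"), each = 10)
  out <- mixed_anova_2x2(vals, grp)
  expect_equal(out$df1, rep(1L, 3))
  expect_equal(out$df2, rep(18L, 3))

  # independent oracle: base R aov() with an Error stratum
  long <- data.frame(y = c(vals[, 1], vals[, 2]),
                     cond = factor(rep(c("a", "b"), each = 20)),
                     group = factor(rep(grp, 2)),
                     subj = factor(rep(seq_len(20), 2)))
  fit <- stats::aov(y ~ group * cond + Error(subj / cond), data = long)
  s <- summary(fit)
  between <- s[["Error: subj"]][[1]]
  within <- s[["Error: subj:cond"]][[1]]
  expect_equal(out$F[out$effect == "group"], between["group", "F value"],
               tolerance = 1e-8)
  expect_equal(out$F[out$effect == "condition"], within["cond", "F value"],
               tolerance = 1e-8)
  expect_equal(out$F[out$effect == "group:condition"],
               within["group:cond", "F value"], tolerance = 1e-8)
  expect_equal(out$p[out$effect == "group"], between["group", "Pr(>F)"],
               tolerance = 1e-8)
  # generalized eta squared against its defining SS ratio
  ss_err <- between["Residuals", "Sum Sq"] + within["Residuals", "Sum Sq"]
  for (i in 1:3) {
    ss_eff <- c(between["group", "Sum Sq"], within["cond", "Sum Sq"],
                within["group:cond", "Sum Sq"])[i]
    expect_equal(out$ges[i], ss_eff / (ss_eff + ss_err), tolerance = 1e-8)
  }
})

test_that("mixed ANOVA degenerate and invalid inputs", {
  vals <- matrix(rep(c(1, 2), each = 8), 8, 2)
  grp <- rep(c("A", "B"), each = 4)
  # identical rows within and across groups: all effects except condition zero
  same <- matrix(1, 8, 2)
  out0 <- mixed_anova_2x2(same, grp)
  expect_equal(out0$F, rep(0, 3))
  # noiseless additive group shift: zero error SS with non-zero effect
  shift <- matrix(rep(c(0, 0, 0, 0, 1, 1, 1, 1), 2), 8, 2)
  expect_error(mixed_anova_2x2(shift, grp),
               class = "envtrack_degenerate_input")
  expect_error(mixed_anova_2x2(vals[, c(1, 1, 2)], grp),
               class = "envtrack_invalid_argument")
  expect_error(mixed_anova_2x2(vals, rep("A", 8)),
               class = "envtrack_invalid_argument")
  expect_error(mixed_anova_2x2(vals, c("A", rep("B", 7))),
               class = "envtrack_insufficient_data")
})

test_that("rank-sum z agrees with exact enumeration for small groups", {
  set.seed(30)
  for (n in c(5, 6)) {
    x <- rnorm(n); y <- rnorm(n) + 0.8
    z <- wilcoxon_ranksum_z(x, y)
    # exact two-sided p by enumerating all group assignments
    pool <- c(x, y)
    rk <- rank(pool)
    combos <- utils::combn(2 * n, n)
    Ws <- colSums(matrix(rk[combos], n))
    w_obs <- sum(rk[seq_len(n)])
    mu <- n * (2 * n + 1) / 2
    p_exact <- mean(abs(Ws - mu) >= abs(w_obs - mu) - 1e-12)
    # continuity-corrected normal p implied by the z statistic
    sigma <- (w_obs - mu) / z
    p_normal <- 2 * pnorm(-(abs(w_obs - mu) - 0.5) / sigma)
    expect_lt(abs(p_normal - p_exact), 0.05)
    expect_equal(sign(z), sign(w_obs - mu))
  }
})

test_that("cluster permutation recovers a constructed effect", {
  win <- lag_window()
  L <- length(win$lags)
  set.seed(31)
  smooth_trfs <- function(n) t(sapply(seq_len(n), function(i)
    as.numeric(stats::filter(rnorm(L), rep(1 / 5, 5), sides = 2,
                             circular = TRUE))))
  A <- smooth_trfs(8)
  B <- smooth_trfs(8)
  eff <- win$lag_ms >= 50 & win$lag_ms <= 150
  B[, eff] <- B[, eff] + 2.5
  res <- cluster_permutation_trf(B, A, n_perm = 500, seed = 2,
                                 lag_axis_ms = win$lag_ms)
  sig <- res$clusters[res$clusters$p < 0.05, ]
  expect_gte(nrow(sig), 1)
  step_ms <- 1000 / 128
  main <- sig[which.max(abs(sig$mass)), ]
  expect_lte(main$lag_start_ms, 50 + 2 * step_ms)
  expect_gte(main$lag_end_ms, 150 - 2 * step_ms)
  expect_true(all(res$zmap[eff] > 0))
})

test_that("cluster permutation is exchangeable and two-sided", {
  win <- lag_window()
  L <- length(win$lags)
  set.seed(33)
  A <- matrix(rnorm(6 * L), 6)
  B <- matrix(rnorm(6 * L), 6)
  r1 <- cluster_permutation_trf(A, B, n_perm = 200, seed = 4)
  # permuting subject order within a group changes nothing
  r2 <- cluster_permutation_trf(A[c(3, 1, 2, 6, 5, 4), ], B,
                                n_perm = 200, seed = 4)
  expect_equal(r1$zmap, r2$zmap)
  expect_equal(r1$clusters, r2$clusters)
  # swapping the group labels flips the z map, keeps cluster masses (up to
  # sign) and extents; p values agree up to permutation sampling noise
  r3 <- cluster_permutation_trf(B, A, n_perm = 200, seed = 4)
  expect_equal(r3$zmap, -r1$zmap, tolerance = 1e-12)
  expect_equal(abs(r3$clusters$mass), abs(r1$clusters$mass), tolerance = 1e-12)
  expect_equal(r3$clusters$start, r1$clusters$start)
  # the canonical null makes the p values identical too
  expect_equal(r3$clusters$p, r1$clusters$p, tolerance = 1e-12)
  expect_warning(cluster_permutation_trf(A, B, n_perm = 50, seed = 1),
                 "coarse")
  expect_error(cluster_permutation_trf(A, B[, -1], n_perm = 200),
               class = "envtrack_dimension_error")
})
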