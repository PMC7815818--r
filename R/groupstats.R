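# Group-level statistics: EEG SNR proxy, rationalized arcsine transform,
# 2x2 mixed ANOVA with generalized eta squared, and cluster-based
# permutation comparison of TRF time courses.

#' EEG signal-to-noise proxy
#'
#' Ratio of the pooled root-mean-square of post-stimulus-onset data to that
#' of pre-stimulus-onset data, pooled over channels and tracks.
#'
#' @param epochs An [eeg_epochs()].
#' @param post_window_s Post-onset window in seconds (default `c(1.6, 55)`).
#' @param pre_window_s Pre-onset window in seconds (default `c(-2.6, -1.6)`).
#' @return An object of class `snr_record` with fields `snr`, `subject_id`,
#'   `group`, and the windows used.
#' @export
eeg_snr <- function(epochs, post_window_s = c(1.6, 55),
                    pre_window_s = c(-2.6, -1.6)) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (pre_window_s[2] > 0)
    stop_invalid("pre-stimulus window must precede onset")
  idx <- function(w) {
    i0 <- epochs$onset_sample + as.integer(round(w[1] * epochs$fs))
    i1 <- epochs$onset_sample + as.integer(round(w[2] * epochs$fs)) - 1L
    if (i0 < 1L || i1 > dim(epochs$data)[2L])
      stop_invalid("window [", w[1], ", ", w[2], "] s lies outside the epoch")
    i0:i1
  }
  post <- rms(epochs$data[, idx(post_window_s), , drop = FALSE])
  pre <- rms(epochs$data[, idx(pre_window_s), , drop = FALSE])
  if (pre == 0) stop_degenerate("pre-stimulus RMS is zero")
  structure(list(snr = post / pre, subject_id = epochs$subject_id,
                 group = epochs$group, post_window_s = post_window_s,
                 pre_window_s = pre_window_s),
            class = "snr_record")
}

#' Rationalized arcsine transform (RAU)
#'
#' Studebaker's (1985) rationalized arcsine units:
#' `theta = asin(sqrt(x / (n + 1))) + asin(sqrt((x + 1) / (n + 1)))`,
#' `RAU = (146 / pi) * theta - 23`. Midpoint scores map to 50 RAU; the scale
#' is approximately linear in percent correct over the mid-range and
#' stabilizes variance near ceiling and floor.
#'
#' @param correct Number of correct responses (vectorized).
#' @param total Total number of items (>= 1).
#' @return RAU values.
#' @export
rau_transform <- function(correct, total) {
  if (any(total < 1)) stop_invalid("`total` must be >= 1")
  if (any(correct < 0) || any(correct > total))
    stop_invalid("`correct` must lie in [0, total]")
  theta <- asin(sqrt(correct / (total + 1))) +
    asin(sqrt((correct + 1) / (total + 1)))
  (146 / pi) * theta - 23
}

#' Two-by-two mixed ANOVA
#'
#' Classical mixed-model decomposition for a design with one between-subjects
#' factor (2 groups) and one within-subjects factor (2 conditions): the group
#' effect is tested against subject-within-group error; the condition and
#' interaction effects against the subject x condition residual. With
#' unequal group sizes the within-subject effects use unweighted (Type III)
#' marginal means. Generalized eta squared follows the Olejnik-Algina
#' convention: `SS_effect / (SS_effect + all error SS)`.
#'
#' @param values Subjects x 2 numeric matrix (one column per within-subject
#'   condition).
#' @param group_labels Length-`nrow(values)` vector with exactly 2 distinct
#'   values.
#' @return An object of class `anova_table`: a data.frame with one row per
#'   effect (`group`, `condition`, `group:condition`) and columns `F`,
#'   `df1`, `df2`, `p`, `ges`.
#' @export
mixed_anova_2x2 <- function(values, group_labels) {
  values <- as.matrix(values)
  if (ncol(values) != 2L)
    stop_invalid("`values` must have exactly 2 condition columns")
  if (anyNA(values)) stop_invalid("incomplete design: missing cells")
  g <- factor(group_labels)
  if (nlevels(g) != 2L)
    stop_invalid("exactly 2 groups required, got ", nlevels(g))
  nj <- table(g)
  if (any(nj < 2L)) stop_insufficient(">= 2 subjects per group required")
  N <- nrow(values)
  s <- rowSums(values)     # between-subject contrast (scaled by sqrt(2))
  d <- values[, 2L] - values[, 1L]  # within-subject contrast
  ms_g <- tapply(s, g, mean)
  md_g <- tapply(d, g, mean)
  # one-way decompositions on the contrast scores; /2 maps back to y scale
  ss_s_between <- sum(nj * (ms_g - mean(s))^2)
  ss_s_within <- sum((s - ms_g[g])^2)
  ss_d_between <- sum(nj * (md_g - mean(d))^2)
  ss_d_within <- sum((d - md_g[g])^2)
  est_c <- mean(md_g)               # unweighted condition effect
  ss_c_d <- est_c^2 * nlevels(g)^2 / sum(1 / nj)
  ss <- c(group = ss_s_between / 2, condition = ss_c_d / 2,
          interaction = ss_d_between / 2)
  ss_err <- c(group = ss_s_within / 2, condition = ss_d_within / 2,
              interaction = ss_d_within / 2)
  df2 <- N - 2L
  Fv <- pv <- ges <- numeric(3L)
  for (i in 1:3) {
    if (ss_err[i] == 0) {
      if (ss[i] == 0) { Fv[i] <- 0; pv[i] <- 1 }
      else stop_degenerate("zero error sum of squares with non-zero effect (",
                           names(ss)[i], "): degenerate noiseless design")
    } else {
      Fv[i] <- (ss[i] / 1) / (ss_err[i] / df2)
      pv[i] <- stats::pf(Fv[i], 1, df2, lower.tail = FALSE)
    }
    ges[i] <- if (ss[i] == 0) 0 else
      ss[i] / (ss[i] + ss_s_within / 2 + ss_d_within / 2)
  }
  out <- data.frame(effect = c("group", "condition", "group:condition"),
                    F = Fv, df1 = 1L, df2 = df2, p = pv, ges = ges,
                    ss = unname(ss), ss_error = unname(ss_err))
  class(out) <- c("anova_table", "data.frame")
  out
}

#' @export
print.anova_table <- function(x, ...) {
  cat("2 x 2 mixed ANOVA\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-16s F(%d,%d) = %8.3f, p = %.4g, ges = %.3f\n",
                x$effect[i], x$df1[i], x$df2[i], x$F[i], x$p[i], x$ges[i]))
  }
  invisible(x)
}

# Column-wise Wilcoxon rank-sum z (group A vs rest) for an N x L matrix,
# mid-ranks with tie correction, normal approximation, no continuity
# correction (two-sided use).
ranksum_z_matrix <- function(X, idxA) {
  N <- nrow(X); nA <- length(idxA); nB <- N - nA
  Rk <- apply(X, 2L, rank)
  W <- colSums(Rk[idxA, , drop = FALSE])
  mu <- nA * (N + 1) / 2
  tiecor <- apply(X, 2L, function(col) {
    t <- table(col)
    sum(t^3 - t)
  })
  s2 <- nA * nB / 12 * ((N + 1) - tiecor / (N * (N - 1)))
  z <- (W - mu) / sqrt(s2)
  z[s2 == 0] <- 0
  z
}

#' Wilcoxon rank-sum z statistic
#'
#' Mid-rank, tie-corrected normal approximation of the two-sample rank-sum
#' statistic (positive when `x` tends to exceed `y`).
#'
#' @param x,y Numeric samples.
#' @return Scalar z.
#' @export
wilcoxon_ranksum_z <- function(x, y) {
  unname(ranksum_z_matrix(matrix(c(x, y), ncol = 1L), seq_along(x)))
}

#' Cluster-based permutation comparison of TRF time courses
#'
#' Per lag sample, a two-tailed Wilcoxon rank-sum z compares the two groups.
#' Candidate clusters are maximal contiguous runs with `|z|` above
#' `qnorm(1 - alpha_cluster / 2)`; cluster mass is the signed sum of z over
#' the run. The null distribution is the maximum absolute cluster mass over
#' `n_perm` random relabelings of group membership; each observed cluster's
#' p-value is the proportion of null maxima at or above its absolute mass.
#'
#' @param trfs_a,trfs_b Subjects x lag matrices of TRF time courses (one
#'   electrode, typically band-averaged), equal lag axes.
#' @param n_perm Number of permutations (default 1000; < 100 draws a
#'   warning).
#' @param alpha_cluster Sample-level two-tailed threshold (default 0.05).
#' @param seed RNG seed.
#' @param lag_axis_ms Optional lag axis for reporting cluster extents.
#' @return An object of class `cluster_result`: list with `zmap`, `clusters`
#'   (data.frame: start, end, lag range in ms, mass, p), `sig_mask`
#'   (p < 0.05), `n_perm`.
#' @export
cluster_permutation_trf <- function(trfs_a, trfs_b, n_perm = 1000,
                                    alpha_cluster = 0.05, seed = 1L,
                                    lag_axis_ms = NULL) {
  trfs_a <- as.matrix(trfs_a); trfs_b <- as.matrix(trfs_b)
  if (ncol(trfs_a) != ncol(trfs_b))
    stop_dimension("groups have different lag axes")
  if (nrow(trfs_a) < 2L || nrow(trfs_b) < 2L)
    stop_insufficient(">= 2 subjects per group required")
  if (n_perm < 100L)
    warning("n_perm < 100 gives a very coarse null distribution")
  nA <- nrow(trfs_a); nB <- nrow(trfs_b); N <- nA + nB
  L <- ncol(trfs_a)
  X <- rbind(trfs_a, trfs_b)
  zcrit <- stats::qnorm(1 - alpha_cluster / 2)
  # canonical (lexicographic) row order makes the permutation null invariant
  # to the order subjects are supplied in; the observed statistic keeps the
  # original group labels
  can <- do.call(order, as.data.frame(X))
  # ranks and tie corrections per lag are label-invariant: precompute
  Rk <- apply(X, 2L, rank)
  tiecor <- apply(X, 2L, function(col) { t <- table(col); sum(t^3 - t) })
  s2 <- nA * nB / 12 * ((N + 1) - tiecor / (N * (N - 1)))
  mu <- nA * (N + 1) / 2
  zfun <- function(idxA) {
    z <- (colSums(Rk[idxA, , drop = FALSE]) - mu) / sqrt(s2)
    z[s2 == 0] <- 0
    z
  }
  find_clusters <- function(z) {
    above <- abs(z) > zcrit
    if (!any(above)) return(NULL)
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    data.frame(start = starts[keep], end = ends[keep],
               mass = vapply(keep, function(i)
                 sum(z[starts[i]:ends[i]]), numeric(1)))
  }
  z_obs <- zfun(seq_len(nA))
  obs <- find_clusters(z_obs)
  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      cl <- find_clusters(zfun(can[sample.int(N, nA)]))
      if (is.null(cl)) 0 else max(abs(cl$mass))
    }, numeric(1))
  })
  sig_mask <- rep(FALSE, L)
  if (!is.null(obs)) {
    obs$p <- vapply(obs$mass, function(m) mean(null_max >= abs(m)), numeric(1))
    if (is.null(lag_axis_ms)) lag_axis_ms <- seq_len(L)
    obs$lag_start_ms <- lag_axis_ms[obs$start]
    obs$lag_end_ms <- lag_axis_ms[obs$end]
    for (i in seq_len(nrow(obs))) {
      if (obs$p[i] < 0.05) sig_mask[obs$start[i]:obs$end[i]] <- TRUE
    }
  } else {
    obs <- data.frame(start = integer(0), end = integer(0),
                      mass = numeric(0), p = numeric(0),
                      lag_start_ms = numeric(0), lag_end_ms = numeric(0))
  }
  structure(list(zmap = z_obs, clusters = obs, sig_mask = sig_mask,
                 n_perm = n_perm, alpha_cluster = alpha_cluster,
                 null_max = null_max),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d clusters (n_perm = %d)\n",
              nrow(x$clusters), x$n_perm))
  if (nrow(x$clusters) > 0) {
    for (i in seq_len(nrow(x$clusters))) {
      cat(sprintf("  [%g, %g] ms  mass = %.2f  p = %.3f%s\n",
                  x$clusters$lag_start_ms[i], x$clusters$lag_end_ms[i],
                  x$clusters$mass[i], x$clusters$p[i],
                  ifelse(x$clusters$p[i] < 0.05, " *", "")))
    }
  }
  invisible(x)
}
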