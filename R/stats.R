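#' Signal-detection sensitivity index (d-prime)
#'
#' `d' = z(hit rate) - z(false-alarm rate)` under the equal-variance Gaussian
#' model. Extreme rates are adjusted before the probit transform: a rate of 0
#' becomes `1/(2N)` and a rate of 1 becomes `1 - 1/(2N)`, with `N` the number
#' of trials of that type.
#'
#' @param n_hits,n_misses Signal-present outcome counts.
#' @param n_fas,n_crs Signal-absent outcome counts (false alarms, correct
#'   rejections).
#' @return The sensitivity index, a scalar.
#' @export
dprime <- function(n_hits, n_misses, n_fas, n_crs) {
  n_signal <- n_hits + n_misses
  n_noise <- n_fas + n_crs
  if (n_signal <= 0 || n_noise <= 0)
    stop("need at least one signal and one noise trial")
  adjust <- function(r, n) {
    if (r == 0) 1 / (2 * n) else if (r == 1) 1 - 1 / (2 * n) else r
  }
  hr <- adjust(n_hits / n_signal, n_signal)
  fa <- adjust(n_fas / n_noise, n_noise)
  qnorm(hr) - qnorm(fa)
}

#' Outcome counts from a behavioral record
#'
#' @param behavior Data frame with logical `signal_present` and
#'   `response_present` columns (see [generate_behavior()]).
#' @return Named vector `n_hits`, `n_misses`, `n_fas`, `n_crs`.
#' @export
behavior_counts <- function(behavior) {
  s <- behavior$signal_present
  r <- behavior$response_present
  c(n_hits = sum(s & r), n_misses = sum(s & !r),
    n_fas = sum(!s & r), n_crs = sum(!s & !r))
}

#' Two-sided Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped; the exact null distribution is used for up
#' to 25 nonzero differences without ties, the tie-corrected normal
#' approximation otherwise. When all differences are zero the test is
#' maximally non-significant (p = 1).
#'
#' @param paired_a,paired_b Numeric vectors of equal length (>= 5).
#' @return Two-sided p-value.
#' @export
signed_rank_test <- function(paired_a, paired_b) {
  if (length(paired_a) != length(paired_b))
    stop("paired samples must have equal length")
  if (length(paired_a) < 5) stop("need at least 5 pairs")
  d <- paired_a - paired_b
  d <- d[d != 0]
  if (length(d) == 0) return(1)
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  suppressWarnings(
    wilcox.test(d, mu = 0, alternative = "two.sided", exact = exact,
                correct = FALSE)$p.value
  )
}

#' False-discovery-rate correction (Benjamini-Hochberg)
#'
#' Step-up procedure: with ordered p-values `p_(1) <= ... <= p_(m)`, rejects
#' all hypotheses with `p <= p_(k*)` where
#' `k* = max{k : p_(k) <= k q / m}`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return Logical rejection mask aligned with `p_values`.
#' @export
fdr_correct <- function(p_values, q = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH") <= q
}

#' Sign-permutation cluster-size inference
#'
#' Nonparametric inference for across-subject effect time series (or
#' train-by-test time maps) already centered on their null value (for
#' instance decoding accuracy minus 50, or correlation minus 0). Under the
#' null, each subject's effect is symmetric around zero, so the permutation
#' distribution is generated by randomly multiplying whole subjects by +1 or
#' -1. The observed statistic is the across-subject mean per cell; the
#' cluster-defining point-wise threshold is the `1 - cdt` quantile of each
#' cell's permutation distribution; clusters are connected supra-threshold
#' cells (adjacent samples for series, 4-connectivity for maps); the cluster
#' statistic is its size in cells, and the corrected p-value is the fraction
#' of permutations whose maximum cluster size reaches the observed size,
#' with the observed map included (`+1` in numerator and denominator), so p
#' is never below `1/(n_perm + 1)`.
#'
#' @param subject_effects Matrix `subjects x time`, or array
#'   `subjects x time1 x time2`, of null-centered effects.
#' @param n_perm Number of sign permutations (default 1000; below 100 a
#'   warning is issued).
#' @param cdt Cluster-defining threshold, point-wise (default 0.05).
#' @param alpha Cluster-level significance threshold (default 0.05).
#' @param tail `"greater"` (one-sided, default), `"less"`, or `"two.sided"`.
#' @param seed Integer seed for the permutation draws.
#' @return An object of class `cluster_result`: `sig_mask` (logical, shaped
#'   like one subject's effect), `clusters` (data frame: id, size, p,
#'   significant), `threshold` (per-cell cluster-defining threshold),
#'   `params`.
#' @export
sign_permutation_clusters <- function(subject_effects, n_perm = 1000,
                                      cdt = 0.05, alpha = 0.05,
                                      tail = c("greater", "less", "two.sided"),
                                      seed = 1) {
  tail <- match.arg(tail)
  dm <- dim(subject_effects)
  if (is.null(dm) || length(dm) < 2)
    stop("subject_effects must be a subjects x time matrix or subjects x t1 x t2 array")
  S <- dm[1]
  if (S < 2) stop("need at least 2 subjects")
  if (n_perm < 100) warning("fewer than 100 permutations; p-values are coarse")
  map_dim <- if (length(dm) == 2) c(1L, dm[2]) else dm[2:3]
  eff <- matrix(subject_effects, nrow = S)
  if (tail == "less") eff <- -eff

  stat_obs <- colMeans(eff)
  flips <- with_seed(seed,
    matrix(sample(c(-1, 1), n_perm * S, replace = TRUE), n_perm, S))
  perm_stats <- (flips %*% eff) / S
  if (tail == "two.sided") {
    stat_obs <- abs(stat_obs)
    perm_stats <- abs(perm_stats)
  }
  thr <- apply(perm_stats, 2, quantile, probs = 1 - cdt, names = FALSE)

  as_map <- function(v) matrix(v, nrow = map_dim[1], ncol = map_dim[2])
  obs_mask <- as_map(stat_obs > thr)
  lab <- .label_components_cpp(obs_mask)
  null_max <- vapply(seq_len(n_perm), function(p) {
    m <- as_map(perm_stats[p, ] > thr)
    sz <- .label_components_cpp(m)$sizes
    if (length(sz)) max(sz) else 0L
  }, integer(1))

  sizes <- lab$sizes
  pvals <- vapply(sizes, function(s) (1 + sum(null_max >= s)) / (n_perm + 1),
                  numeric(1))
  clusters <- data.frame(id = seq_along(sizes), size = sizes, p = pvals,
                         significant = pvals <= alpha)
  sig_mask <- matrix(FALSE, map_dim[1], map_dim[2])
  for (k in seq_along(sizes))
    if (clusters$significant[k]) sig_mask[lab$labels == k] <- TRUE
  if (length(dm) == 2) {
    sig_mask <- as.vector(sig_mask)
    thr_out <- as.vector(thr)
  } else {
    thr_out <- as_map(thr)
  }
  structure(list(sig_mask = sig_mask, clusters = clusters,
                 labels = lab$labels, threshold = thr_out,
                 params = list(n_perm = n_perm, cdt = cdt, alpha = alpha,
                               tail = tail, seed = seed)),
            class = "cluster_result")
}

# cluster-defining per-time threshold from the sign-permutation distribution
# (used by the bootstrap onset rule)
pointwise_threshold <- function(eff, n_perm, cdt, seed) {
  S <- nrow(eff)
  flips <- with_seed(seed,
    matrix(sample(c(-1, 1), n_perm * S, replace = TRUE), n_perm, S))
  perm_stats <- (flips %*% eff) / S
  apply(perm_stats, 2, quantile, probs = 1 - cdt, names = FALSE)
}

# first time index opening a run of >= k consecutive supra-threshold samples
first_sustained <- function(above, k) {
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  hit <- which(r$values & r$lengths >= k)
  if (length(hit) == 0) NA_integer_ else starts[hit[1]]
}

#' Bootstrap peak or onset latency with percentile confidence interval
#'
#' The point estimate comes from the original subject-averaged time series:
#' for `kind = "peak"`, the time of the maximum within the search window;
#' for `kind = "onset"`, the first time point of the earliest significant
#' cluster from [sign_permutation_clusters()] applied within the window.
#' Each of `n_boot` bootstrap replicates resamples subjects with
#' replacement, averages, and extracts the latency; for onset inside
#' replicates (where nested cluster inference is infeasible) the rule is the
#' first run of at least `min_consec_ms` milliseconds exceeding the
#' point-wise cluster-defining threshold computed once on the original data.
#' The 95% confidence interval is the 2.5/97.5 percentile of the bootstrap
#' latency distribution, which may exclude the plug-in point estimate.
#' Replicates with undefined latency (flat window, or nothing
#' supra-threshold) are excluded and counted.
#'
#' @param subject_series Matrix `subjects x time` (>= 2 subjects). For onset
#'   latency the series must be null-centered (e.g. accuracy minus chance);
#'   use `null_value` to shift.
#' @param time Numeric time axis, ms.
#' @param kind `"peak"` or `"onset"`.
#' @param window Search window `c(start, end)` in ms.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @param null_value Null value subtracted before onset detection (default
#'   0; e.g. 50 for decoding accuracies).
#' @param cdt,n_perm Cluster-defining threshold and permutation count for
#'   the onset rules.
#' @param min_consec_ms Minimum sustained supra-threshold duration (ms) for
#'   the within-replicate onset rule.
#' @return An object of class `latency_estimate`: `kind`, `point_ms`,
#'   `ci_low_ms`, `ci_high_ms`, `n_boot`, `n_undefined`, `search_window`.
#' @export
bootstrap_latency <- function(subject_series, time,
                              kind = c("peak", "onset"),
                              window = range(time), n_boot = 1000, seed = 1,
                              null_value = 0, cdt = 0.05, n_perm = 1000,
                              min_consec_ms = 5) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(subject_series), ncol(subject_series) == length(time))
  if (nrow(subject_series) < 2) stop("need at least 2 subjects")
  if (window[1] < min(time) || window[2] > max(time))
    stop("search window must lie within the time axis")
  widx <- which(time >= window[1] & time <= window[2])
  wt <- time[widx]
  eff <- subject_series[, widx, drop = FALSE] - null_value
  S <- nrow(eff)

  peak_of <- function(avg) {
    if (max(avg) - min(avg) <= 0) return(NA_real_)
    wt[which.max(avg)]
  }
  dt <- if (length(wt) > 1) stats::median(diff(wt)) else 1
  k_consec <- max(1L, as.integer(round(min_consec_ms / dt)))

  if (kind == "onset") {
    clu <- sign_permutation_clusters(eff, n_perm = n_perm, cdt = cdt,
                                     alpha = 0.05, tail = "greater",
                                     seed = derive_seed(seed, 1))
    sig <- which(clu$sig_mask)
    point <- if (length(sig)) wt[min(sig)] else NA_real_
    thr <- pointwise_threshold(eff, n_perm, cdt, derive_seed(seed, 1))
  } else {
    point <- peak_of(colMeans(eff))
    thr <- NULL
  }

  boots <- with_seed(derive_seed(seed, 2), {
    vapply(seq_len(n_boot), function(b) {
      avg <- colMeans(eff[sample.int(S, S, replace = TRUE), , drop = FALSE])
      if (kind == "peak") peak_of(avg)
      else {
        i <- first_sustained(avg > thr, k_consec)
        if (is.na(i)) NA_real_ else wt[i]
      }
    }, numeric(1))
  })
  ok <- !is.na(boots)
  ci <- if (any(ok)) quantile(boots[ok], c(0.025, 0.975), names = FALSE)
        else c(NA_real_, NA_real_)
  structure(list(kind = kind, point_ms = point, ci_low_ms = ci[1],
                 ci_high_ms = ci[2], n_boot = n_boot,
                 n_undefined = sum(!ok), search_window = window,
                 boot_latencies = boots),
            class = "latency_estimate")
}

#' @export
print.latency_estimate <- function(x, ...) {
  cat(sprintf("<latency_estimate> %s = %s ms, 95%% CI [%s, %s] (%d bootstraps, %d undefined)\n",
              x$kind, format(x$point_ms), format(x$ci_low_ms),
              format(x$ci_high_ms), x$n_boot, x$n_undefined))
  invisible(x)
}

#' Bootstrap test for a latency difference between two cohorts
#'
#' Builds the bootstrap distribution of the latency difference (cohort A
#' minus cohort B) and evaluates how often it crosses zero: the two-sided
#' p-value is `2 * min(P(diff <= 0), P(diff >= 0))`, floored at `1/n_boot`
#' and capped at 1. In unpaired mode (the default, for between-subject
#' comparisons) the two cohorts are resampled independently in every
#' replicate; in paired mode one resampling of subject indices is applied to
#' both cohorts.
#'
#' @param series_a,series_b Matrices `subjects x time` on a shared time
#'   axis.
#' @param time Time axis, ms.
#' @param kind `"peak"` or `"onset"`.
#' @param window Search window, ms.
#' @param n_boot Number of bootstrap replicates.
#' @param paired Paired resampling (requires equal subject counts).
#' @param seed Integer seed.
#' @param null_value,cdt,n_perm,min_consec_ms As in [bootstrap_latency()].
#' @return List with `p`, `diff_point` (plug-in difference), `n_defined`
#'   (replicates where both latencies existed), `boot_diffs`.
#' @export
bootstrap_latency_difference <- function(series_a, series_b, time,
                                         kind = c("peak", "onset"),
                                         window = range(time), n_boot = 1000,
                                         paired = FALSE, seed = 1,
                                         null_value = 0, cdt = 0.05,
                                         n_perm = 1000, min_consec_ms = 5) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(series_a), is.matrix(series_b),
            ncol(series_a) == length(time), ncol(series_b) == length(time))
  if (paired && nrow(series_a) != nrow(series_b))
    stop("paired mode requires matching subject counts")
  widx <- which(time >= window[1] & time <= window[2])
  wt <- time[widx]
  ea <- series_a[, widx, drop = FALSE] - null_value
  eb <- series_b[, widx, drop = FALSE] - null_value
  dt <- if (length(wt) > 1) stats::median(diff(wt)) else 1
  k_consec <- max(1L, as.integer(round(min_consec_ms / dt)))

  thr_a <- thr_b <- NULL
  if (kind == "onset") {
    thr_a <- pointwise_threshold(ea, n_perm, cdt, derive_seed(seed, 11))
    thr_b <- pointwise_threshold(eb, n_perm, cdt, derive_seed(seed, 12))
  }
  lat_of <- function(avg, thr) {
    if (kind == "peak") {
      if (max(avg) - min(avg) <= 0) return(NA_real_)
      wt[which.max(avg)]
    } else {
      i <- first_sustained(avg > thr, k_consec)
      if (is.na(i)) NA_real_ else wt[i]
    }
  }
  point_diff <- lat_of(colMeans(ea), thr_a) - lat_of(colMeans(eb), thr_b)

  diffs <- with_seed(derive_seed(seed, 13), {
    vapply(seq_len(n_boot), function(b) {
      if (paired) {
        idx <- sample.int(nrow(ea), nrow(ea), replace = TRUE)
        la <- lat_of(colMeans(ea[idx, , drop = FALSE]), thr_a)
        lb <- lat_of(colMeans(eb[idx, , drop = FALSE]), thr_b)
      } else {
        la <- lat_of(colMeans(ea[sample.int(nrow(ea), nrow(ea), replace = TRUE),
                                 , drop = FALSE]), thr_a)
        lb <- lat_of(colMeans(eb[sample.int(nrow(eb), nrow(eb), replace = TRUE),
                                 , drop = FALSE]), thr_b)
      }
      la - lb
    }, numeric(1))
  })
  ok <- !is.na(diffs)
  if (!any(ok)) return(list(p = NA_real_, diff_point = point_diff,
                            n_defined = 0L, boot_diffs = diffs))
  d <- diffs[ok]
  p <- 2 * min(mean(d <= 0), mean(d >= 0))
  p <- min(1, max(p, 1 / n_boot))
  list(p = p, diff_point = point_diff, n_defined = sum(ok), boot_diffs = diffs)
}
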