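#' Temporal envelope of an evoked pattern component
#'
#' A Gaussian bump parameterized by onset, peak and full width at half
#' maximum, truncated to zero before the onset. This is the temporal profile
#' that scales a spatial pattern component in the synthetic MEG generator:
#' smooth ramp to a peak followed by a decay, the shape typical of
#' stimulus-evoked decodable information.
#'
#' @param onset Truncation onset in ms; the envelope is exactly zero before it.
#' @param peak Time of the maximum, ms. Must exceed `onset`.
#' @param fwhm Full width at half maximum, ms.
#' @param amplitude Peak amplitude (arbitrary units, >= 0). Zero yields a
#'   component that is absent altogether.
#' @return An object of class `envelope`.
#' @export
envelope <- function(onset, peak, fwhm, amplitude = 1) {
  stopifnot(is.numeric(onset), is.numeric(peak), is.numeric(fwhm))
  if (onset >= peak) stop("envelope onset must precede its peak")
  if (fwhm <= 0) stop("envelope fwhm must be positive")
  if (amplitude < 0) stop("envelope amplitude must be >= 0")
  structure(list(onset = onset, peak = peak, fwhm = fwhm,
                 amplitude = amplitude),
            class = "envelope")
}

#' Evaluate an envelope on a time grid
#'
#' @param env An [envelope()].
#' @param t Numeric vector of times, ms.
#' @return Numeric vector of envelope values.
#' @export
eval_envelope <- function(env, t) {
  stopifnot(inherits(env, "envelope"))
  s <- env$fwhm / (2 * sqrt(2 * log(2)))
  v <- env$amplitude * exp(-0.5 * ((t - env$peak) / s)^2)
  v[t < env$onset] <- 0
  v
}

#' Specification of a synthetic MEG cohort
#'
#' Bundles every parameter of the synthetic generator. The defaults mirror a
#' rapid-serial-visual-presentation study design: 24 target conditions (12
#' faces, 12 objects), 30 trials per condition, 306 sensors, epochs from
#' -300 to 900 ms at a 1 ms step. Each trial is the sum of a
#' condition-specific spatial pattern scaled by the identity envelope, a
#' category-specific pattern scaled by the category envelope, and i.i.d.
#' Gaussian sensor noise. Pattern vectors are drawn once per subject from a
#' standard Gaussian and unit-normalized, which keeps the signal-to-noise
#' ratio interpretable across channel counts.
#'
#' @param n_subjects Number of simulated subjects.
#' @param n_conditions Number of conditions; must be even when two categories
#'   are requested (half per category).
#' @param categories Character vector of two category names; the first half of
#'   the conditions belongs to the first category.
#' @param n_trials_per_condition Trials recorded per condition.
#' @param n_channels Number of sensors.
#' @param time_lim Epoch limits `c(start, stop)` in ms relative to target
#'   onset.
#' @param time_step Sampling step, ms (> 0).
#' @param identity_envelope [envelope()] of the condition-identity component.
#' @param category_envelope [envelope()] of the categorical (face-vs-object)
#'   component.
#' @param noise_sd Standard deviation of the additive Gaussian sensor noise,
#'   per sample and channel.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the spec including this seed.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_subjects = 17,
                       n_conditions = 24,
                       categories = c("face", "object"),
                       n_trials_per_condition = 30,
                       n_channels = 306,
                       time_lim = c(-300, 900),
                       time_step = 1,
                       identity_envelope = envelope(50, 100, 100, amplitude = 2),
                       category_envelope = envelope(110, 170, 120, amplitude = 1),
                       noise_sd = 1,
                       seed = 1) {
  stopifnot(n_subjects >= 1, n_conditions >= 2, n_trials_per_condition >= 1,
            n_channels >= 1, length(time_lim) == 2, time_lim[1] < time_lim[2])
  if (time_step <= 0) stop("time_step must be > 0")
  if (length(categories) == 2 && n_conditions %% 2 != 0)
    stop("n_conditions must be even when two categories are requested")
  stopifnot(inherits(identity_envelope, "envelope"),
            inherits(category_envelope, "envelope"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(n_subjects = n_subjects, n_conditions = n_conditions,
                 categories = categories,
                 n_trials_per_condition = n_trials_per_condition,
                 n_channels = n_channels, time_lim = time_lim,
                 time_step = time_step,
                 identity_envelope = identity_envelope,
                 category_envelope = category_envelope,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synth_spec")
}

spec_time_axis <- function(spec) seq(spec$time_lim[1], spec$time_lim[2],
                                     by = spec$time_step)

spec_condition_ids <- function(spec) {
  if (length(spec$categories) == 2) {
    per <- spec$n_conditions / 2
    c(sprintf("%s%02d", spec$categories[1], seq_len(per)),
      sprintf("%s%02d", spec$categories[2], seq_len(per)))
  } else {
    sprintf("cond%02d", seq_len(spec$n_conditions))
  }
}

spec_category_of <- function(spec) {
  ids <- spec_condition_ids(spec)
  if (length(spec$categories) == 2) {
    per <- spec$n_conditions / 2
    stats::setNames(rep(spec$categories, each = per), ids)
  } else {
    stats::setNames(rep("all", spec$n_conditions), ids)
  }
}

unit_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  m / nrm
}

#' Generate a synthetic MEG cohort with known ground truth
#'
#' Simulates one [meg_epochs] object per subject. Each trial of condition `c`
#' in category `k` is `e_id(t) * p_c + e_cat(t) * q_k + noise`, where `p_c`
#' and `q_k` are per-subject unit-norm channel patterns and `e_id`, `e_cat`
#' the two envelopes. The returned ground truth carries the realized
#' patterns, the noiseless condition-by-condition-by-time Euclidean
#' dissimilarity geometry (averaged over subjects), and the true envelope
#' latencies, which downstream parameter-recovery tests treat as the oracle.
#'
#' @param spec A [synth_spec()].
#' @return A list with elements `subjects` (list of [meg_epochs]), `truth`
#'   (list: `patterns`, `geometry`, `time`, `true_peaks`, `true_onsets`,
#'   `envelopes`), and `spec`.
#' @export
generate_meg_subjects <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  t_ax <- spec_time_axis(spec)
  for (nm in c("identity_envelope", "category_envelope")) {
    pk <- spec[[nm]]$peak
    if (pk < min(t_ax) || pk > max(t_ax))
      stop(sprintf("%s peak (%g ms) lies outside the time axis [%g, %g]",
                   nm, pk, min(t_ax), max(t_ax)))
  }
  C <- spec$n_conditions
  d <- spec$n_channels
  Tn <- length(t_ax)
  ntr <- spec$n_trials_per_condition
  ids <- spec_condition_ids(spec)
  cat_of <- spec_category_of(spec)
  cat_idx <- match(cat_of, unique(cat_of))
  e_id <- eval_envelope(spec$identity_envelope, t_ax)
  e_cat <- if (length(spec$categories) == 2)
    eval_envelope(spec$category_envelope, t_ax) else numeric(Tn)

  subjects <- vector("list", spec$n_subjects)
  patterns <- vector("list", spec$n_subjects)
  # pairwise Gram pieces for the noiseless geometry, accumulated over subjects
  geom_acc <- array(0, dim = c(C, C, Tn))

  with_seed(spec$seed, {
    for (s in seq_len(spec$n_subjects)) {
      p <- unit_rows(matrix(rnorm(C * d), C, d))          # condition patterns
      q <- unit_rows(matrix(rnorm(2 * d), 2, d))          # category patterns
      if (length(spec$categories) != 2) q[] <- 0
      patterns[[s]] <- list(condition = p, category = q)

      labels <- rep(ids, each = ntr)
      data <- array(rnorm(C * ntr * d * Tn, sd = spec$noise_sd),
                    dim = c(C * ntr, d, Tn))
      for (c in seq_len(C)) {
        sig <- outer(p[c, ], e_id) + outer(q[cat_idx[c], ], e_cat)  # d x Tn
        rows <- ((c - 1) * ntr + 1):(c * ntr)
        for (r in rows) data[r, , ] <- data[r, , ] + sig
      }
      bl_end <- max(min(t_ax), min(0, max(t_ax)))   # pre-stimulus if available
      subjects[[s]] <- meg_epochs(data = data, labels = labels,
                                  time = t_ax,
                                  sampling_rate = 1000 / spec$time_step,
                                  baseline = c(min(t_ax), bl_end),
                                  category_of = cat_of)

      # noiseless dissimilarity geometry via pattern Gram terms
      dp <- as.matrix(stats::dist(p))^2
      qc <- q[cat_idx, , drop = FALSE]
      dq <- as.matrix(stats::dist(qc))^2
      geom_acc <- geom_acc + geometry_from_patterns(dp, dq, p, qc, e_id, e_cat)
    }
  })

  geometry <- geom_acc / spec$n_subjects
  dimnames(geometry) <- list(ids, ids, NULL)
  truth <- list(
    patterns = patterns,
    geometry = geometry,
    time = t_ax,
    true_peaks = c(identity = spec$identity_envelope$peak,
                   category = spec$category_envelope$peak),
    true_onsets = c(identity = spec$identity_envelope$onset,
                    category = spec$category_envelope$onset),
    envelopes = list(identity = spec$identity_envelope,
                     category = spec$category_envelope)
  )
  list(subjects = subjects, truth = truth, spec = spec)
}

# |e1 (p_i - p_j) + e2 (q_i - q_j)|  for all pairs and times, via the three
# time-independent Gram pieces (squared pattern distances and the cross term)
geometry_from_patterns <- function(dp, dq, p, qc, e_id, e_cat) {
  C <- nrow(p)
  Tn <- length(e_id)
  pq <- tcrossprod(p, qc)  # p_i . q_j
  cross <- matrix(0, C, C)
  for (i in seq_len(C)) for (j in seq_len(C))
    cross[i, j] <- pq[i, i] - pq[i, j] - pq[j, i] + pq[j, j]
  g <- array(0, dim = c(C, C, Tn))
  for (t in seq_len(Tn)) {
    v <- e_id[t]^2 * dp + 2 * e_id[t] * e_cat[t] * cross + e_cat[t]^2 * dq
    v[v < 0] <- 0
    g[, , t] <- sqrt(v)
  }
  g
}

#' Generate fMRI-like voxel patterns realizing a target dissimilarity geometry
#'
#' Constructs a conditions-by-voxels pattern matrix whose correlation RDM
#' (1 - Pearson) reproduces the requested geometry exactly in the noiseless
#' case. The target correlation matrix `C = 1 - G` is factorized by its
#' eigendecomposition (negative eigenvalues are clipped, with a warning, when
#' the geometry is not embeddable at the requested rank) and the factor
#' loadings are applied to an exactly orthonormal, zero-mean voxel basis, so
#' the sample Pearson correlations equal the target up to the clipping error.
#' Gaussian noise of standard deviation `noise_sd` is then added per voxel.
#'
#' @param geometry Symmetric non-negative conditions-by-conditions
#'   dissimilarity matrix on the 1 - Pearson scale (entries in `[0, 2]`).
#' @param n_voxels Number of voxels (must exceed the factor rank; otherwise
#'   the best rank-`n_voxels - 1` approximation is returned with a warning).
#' @param noise_sd Standard deviation of additive voxel noise.
#' @param seed Integer seed; identical seeds give identical output.
#' @param roi_id Label for the region the patterns stand for.
#' @return A [pattern_set] with `conditions x n_voxels` responses.
#' @export
generate_fmri_patterns <- function(geometry, n_voxels, noise_sd = 0, seed = 1,
                                   roi_id = "synthetic_roi") {
  stopifnot(is.matrix(geometry), nrow(geometry) == ncol(geometry))
  if (max(abs(geometry - t(geometry))) > 1e-8)
    stop("geometry must be symmetric")
  if (min(geometry) < 0) stop("geometry must be non-negative")
  k <- nrow(geometry)
  stopifnot(n_voxels >= 2)
  Ctar <- 1 - geometry
  diag(Ctar) <- 1
  eg <- eigen((Ctar + t(Ctar)) / 2, symmetric = TRUE)
  pos <- eg$values > 1e-10 * max(abs(eg$values), 1)
  if (any(eg$values < -1e-8 * max(abs(eg$values), 1)))
    warning("geometry is not exactly embeddable; negative eigenvalues clipped, returning best approximation")
  r <- sum(pos)
  if (r > n_voxels - 1) {
    warning(sprintf(
      "geometry rank %d exceeds what %d voxels can carry; truncated to rank %d (best approximation)",
      r, n_voxels, n_voxels - 1))
    r <- n_voxels - 1
  }
  L <- eg$vectors[, seq_len(r), drop = FALSE] %*%
    diag(sqrt(eg$values[seq_len(r)]), r)
  L <- unit_rows(L)
  X <- with_seed(seed, {
    Z <- matrix(rnorm(n_voxels * r), n_voxels, r)
    # zero-mean orthonormal basis: QR of [1, Z], drop the constant column
    Q <- qr.Q(qr(cbind(1, Z)))[, -1, drop = FALSE]
    resp <- L %*% t(Q)
    if (noise_sd > 0)
      resp <- resp + matrix(rnorm(k * n_voxels, sd = noise_sd), k, n_voxels)
    resp
  })
  rownames(X) <- rownames(geometry)
  pattern_set(responses = X, roi_id = roi_id)
}

#' Generate behavioral trials under the equal-variance Gaussian model
#'
#' Simulates yes/no detection trials whose hit and false-alarm probabilities
#' follow the equal-variance signal-detection model at sensitivity
#' `target_dprime` and criterion `criterion`: hit rate
#' `pnorm(dprime / 2 - criterion)`, false-alarm rate
#' `pnorm(-dprime / 2 - criterion)`. The d-prime recovered by [dprime()] from
#' the simulated counts converges to the target as the trial counts grow.
#'
#' @param target_dprime True sensitivity index.
#' @param criterion Decision criterion (0 = unbiased).
#' @param n_signal Number of signal-present trials (> 0).
#' @param n_noise Number of signal-absent trials (> 0).
#' @param seed Integer seed.
#' @param condition_speed Optional condition label attached to every trial.
#' @return Data frame with columns `trial`, `signal_present`,
#'   `response_present`, `condition_speed`.
#' @export
generate_behavior <- function(target_dprime, criterion = 0, n_signal, n_noise,
                              seed = 1, condition_speed = "default") {
  if (n_signal <= 0) stop("n_signal must be > 0")
  if (n_noise <= 0) stop("n_noise must be > 0")
  hit_p <- pnorm(target_dprime / 2 - criterion)
  fa_p <- pnorm(-target_dprime / 2 - criterion)
  with_seed(seed, {
    resp_sig <- runif(n_signal) < hit_p
    resp_noise <- runif(n_noise) < fa_p
    data.frame(
      trial = seq_len(n_signal + n_noise),
      signal_present = c(rep(TRUE, n_signal), rep(FALSE, n_noise)),
      response_present = c(resp_sig, resp_noise),
      condition_speed = condition_speed,
      stringsAsFactors = FALSE
    )
  })
}

#' Envelope presets emulating graded presentation rates
#'
#' Three envelope settings emulating progressively faster rapid serial
#' visual presentation. Faster presentation disrupts the feedforward sweep
#' and delays category-selective feedback, which the generator renders as:
#' a narrower, weaker identity envelope (less accumulated identity evidence,
#' crossing the detection threshold later) and a later, weaker category
#' envelope (delayed categorical emergence). The analysis chain is expected
#' to *recover* the resulting ordinal structure — lower peak decoding, later
#' decoding onset, later categorical-division peak — from data generated
#' under these presets.
#'
#' @return Named list of three settings (`slow`, `medium`, `fast`), each a
#'   list with `identity_envelope` and `category_envelope`.
#' @export
rsvp_rate_settings <- function() {
  list(
    slow = list(identity_envelope = envelope(30, 100, 100, amplitude = 2.0),
                category_envelope = envelope(80, 150, 100, amplitude = 1.0)),
    medium = list(identity_envelope = envelope(50, 100, 70, amplitude = 1.6),
                  category_envelope = envelope(120, 190, 100, amplitude = 0.8)),
    fast = list(identity_envelope = envelope(65, 100, 45, amplitude = 1.2),
                category_envelope = envelope(160, 230, 100, amplitude = 0.6))
  )
}
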