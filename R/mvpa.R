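#' Decoding parameters
#'
#' Parameters of the time-resolved pairwise decoding procedure: trials are
#' sub-averaged in random groups (default 3) into pseudo-trials, a linear
#' SVM with fixed cost (default 1) is evaluated by leave-one-pseudo-trial-
#' per-class-out cross-validation, and the whole procedure is repeated
#' (default 100 times) with fresh random sub-averaging, averaging accuracies
#' over repetitions.
#'
#' @param group_size Trials per pseudo-trial (>= 1).
#' @param n_repetitions Number of random sub-averaging repetitions (>= 1).
#' @param svm_cost SVM regularization parameter C.
#' @param seed Integer seed governing all randomness of the procedure.
#' @param stride Time-axis decimation stride (1 = every sample). The native
#'   1 ms step is the default; a stride permits desk-scale runs.
#' @return An object of class `decoding_params`.
#' @export
decoding_params <- function(group_size = 3, n_repetitions = 100, svm_cost = 1,
                            seed = 1, stride = 1) {
  stopifnot(group_size >= 1, n_repetitions >= 1, svm_cost > 0, stride >= 1)
  structure(list(group_size = as.integer(group_size),
                 n_repetitions = as.integer(n_repetitions),
                 svm_cost = svm_cost, seed = as.integer(seed),
                 stride = as.integer(stride)),
            class = "decoding_params")
}

#' Sub-average trials into pseudo-trials
#'
#' Randomly partitions the trials of one condition into groups of
#' `group_size` and returns the group means ("pseudo-trials"). With `n`
#' trials, `floor(n / group_size)` pseudo-trials are formed; each source
#' trial is used at most once and remainder trials are dropped for this
#' draw (randomness across repetitions recycles all trials). Randomness is
#' taken from the caller's RNG state.
#'
#' @param x Array with trials along the first extent (`n x channels x time`
#'   or `n x channels`).
#' @param group_size Trials per group.
#' @return Array of `floor(n / group_size)` pseudo-trials with the remaining
#'   extents of `x`.
#' @export
subaverage_trials <- function(x, group_size) {
  dm <- dim(x)
  if (is.null(dm)) dm <- length(x)
  n <- dm[1]
  if (n < group_size)
    stop(sprintf("need at least group_size (%d) trials, got %d", group_size, n))
  M <- n %/% group_size
  perm <- sample.int(n)
  out <- array(0, dim = c(M, dm[-1]))
  for (m in seq_len(M)) {
    rows <- perm[((m - 1) * group_size + 1):(m * group_size)]
    sub <- if (length(dm) == 3) x[rows, , , drop = FALSE]
           else x[rows, , drop = FALSE]
    if (length(dm) == 3) out[m, , ] <- colMeans(sub, dims = 1)
    else out[m, ] <- colMeans(sub)
  }
  out
}

# one repetition's pseudo-trials for every condition (list of M_c x d x T)
make_pseudotrials <- function(data, labels, conds, group_size) {
  lapply(conds, function(cc) {
    subaverage_trials(data[labels == cc, , , drop = FALSE], group_size)
  })
}

#' Time-resolved pairwise decoding into an RDM time course
#'
#' For every pair of conditions and every time point, classifies the two
#' conditions from channel pattern vectors with a linear SVM under
#' leave-one-pseudo-trial-per-class-out cross-validation: each fold holds
#' out one pseudo-trial of each class (two test vectors) and trains on the
#' remaining `2(M-1)`, giving `M` folds. Accuracies are averaged over folds,
#' then over `n_repetitions` random sub-averaging draws, and populate a
#' symmetric conditions-by-conditions decoding matrix per time point (the
#' MEG representational dissimilarity matrix), with an undefined diagonal.
#' When the two conditions have unequal numbers of pseudo-trials, the pair
#' uses the smaller count so folds stay balanced. A test vector landing
#' exactly on the decision boundary counts as incorrect.
#'
#' @param epochs A [meg_epochs]; needs >= 2 conditions and per-condition
#'   trial counts of at least `group_size * 2` (so that M >= 2).
#' @param params A [decoding_params()].
#' @return An object of class `time_rdm`: `accuracy`
#'   (`conditions x conditions x time`, percent, diagonal `NA`), `time`,
#'   `conditions`, `category_of`, `params`.
#' @export
pairwise_decoding_timecourse <- function(epochs, params = decoding_params()) {
  stopifnot(inherits(epochs, "meg_epochs"), inherits(params, "decoding_params"))
  conds <- unique(epochs$labels)
  C <- length(conds)
  if (C < 2) stop("need at least 2 conditions")
  sel <- seq(1, length(epochs$time), by = params$stride)
  data <- epochs$data[, , sel, drop = FALSE]
  d <- dim(data)[2]
  Tn <- length(sel)
  pr <- all_pairs(C)
  acc <- array(0, dim = c(C, C, Tn))
  with_seed(params$seed, {
    for (rep_i in seq_len(params$n_repetitions)) {
      ps <- make_pseudotrials(data, epochs$labels, conds, params$group_size)
      for (k in seq_len(nrow(pr))) {
        i <- pr[k, 1]; j <- pr[k, 2]
        M <- min(dim(ps[[i]])[1], dim(ps[[j]])[1])
        if (M < 2)
          stop("fewer than 2 pseudo-trials per condition; decrease group_size or add trials")
        a <- ps[[i]][seq_len(M), , , drop = FALSE]
        b <- ps[[j]][seq_len(M), , , drop = FALSE]
        v <- .decode_pair_cpp(as.numeric(a), as.numeric(b), M, d, Tn,
                              params$svm_cost)
        acc[i, j, ] <- acc[i, j, ] + v
      }
    }
  })
  acc <- acc / params$n_repetitions
  for (k in seq_len(nrow(pr)))                  # fill both triangles
    acc[pr[k, 2], pr[k, 1], ] <- acc[pr[k, 1], pr[k, 2], ]
  for (c in seq_len(C)) acc[c, c, ] <- NA_real_
  dimnames(acc) <- list(conds, conds, NULL)
  structure(list(accuracy = acc, time = epochs$time[sel], conditions = conds,
                 category_of = epochs$category_of, params = params),
            class = "time_rdm")
}

#' @export
print.time_rdm <- function(x, ...) {
  d <- dim(x$accuracy)
  cat(sprintf("<time_rdm> %d x %d conditions x %d timepoints (%g..%g ms)\n",
              d[1], d[2], d[3], min(x$time), max(x$time)))
  invisible(x)
}

#' Average RDM time courses across subjects
#'
#' @param rdms List of [time_rdm] objects with identical conditions and time
#'   axes.
#' @return A subject-averaged `time_rdm`.
#' @export
average_rdms <- function(rdms) {
  stopifnot(length(rdms) >= 1)
  base <- rdms[[1]]
  for (r in rdms[-1]) {
    if (!identical(r$conditions, base$conditions) ||
        !isTRUE(all.equal(r$time, base$time)))
      stop("RDMs must share conditions and time axis")
  }
  base$accuracy <- Reduce(`+`, lapply(rdms, `[[`, "accuracy")) / length(rdms)
  base
}

#' Partition of condition pairs by category membership
#'
#' Splits all unordered condition pairs into within-category pairs of the
#' first category, within-category pairs of the second, and between-category
#' pairs. The three sets are disjoint and together exhaust the
#' `C * (C - 1) / 2` pairs.
#'
#' @param conditions Character vector of condition ids (RDM order).
#' @param category_of Named vector mapping condition id to one of exactly two
#'   category labels.
#' @return An object of class `pair_partition` with index-matrix elements
#'   `within_A`, `within_B`, `between` and a `categories` attribute.
#' @export
pair_partition <- function(conditions, category_of) {
  cats <- category_of[conditions]
  if (any(is.na(cats))) stop("every condition needs a category")
  lev <- unique(cats)
  if (length(lev) != 2) stop("exactly two categories required")
  pr <- all_pairs(length(conditions))
  ci <- cats[pr[, 1]]
  cj <- cats[pr[, 2]]
  structure(list(
    within_A = pr[ci == lev[1] & cj == lev[1], , drop = FALSE],
    within_B = pr[ci == lev[2] & cj == lev[2], , drop = FALSE],
    between = pr[ci != cj, , drop = FALSE],
    categories = lev
  ), class = "pair_partition")
}

#' Average decoding accuracy over a set of condition pairs
#'
#' Per time point, the unweighted mean of the RDM entries over the listed
#' unordered pairs ("grand total" decoding when all pairs are used).
#'
#' @param rdm A [time_rdm].
#' @param pairs Two-column index matrix of condition pairs, or `"all"` for
#'   every pair.
#' @return Numeric accuracy time series (percent), one value per time point.
#' @export
partition_mean <- function(rdm, pairs = "all") {
  stopifnot(inherits(rdm, "time_rdm"))
  C <- length(rdm$conditions)
  if (identical(pairs, "all")) pairs <- all_pairs(C)
  if (!is.matrix(pairs) || ncol(pairs) != 2 || nrow(pairs) == 0)
    stop("pairs must be a non-empty two-column matrix (or \"all\")")
  if (any(pairs < 1 | pairs > C)) stop("pair indices out of range")
  Tn <- dim(rdm$accuracy)[3]
  vapply(seq_len(Tn), function(t) {
    mean(rdm$accuracy[, , t][pairs])
  }, numeric(1))
}

#' Categorical-division time series
#'
#' The categorical effect index: mean between-category decoding accuracy
#' minus mean within-category accuracy (both categories pooled with equal
#' pair weight) at every time point. Positive values indicate that the
#' decoding geometry clusters by category.
#'
#' @param rdm A [time_rdm].
#' @param partition A [pair_partition()] valid for the RDM's conditions.
#' @return Numeric difference time series (percentage points).
#' @export
categorical_division <- function(rdm, partition) {
  stopifnot(inherits(partition, "pair_partition"))
  within <- rbind(partition$within_A, partition$within_B)
  partition_mean(rdm, partition$between) - partition_mean(rdm, within)
}

#' Temporal generalization of pairwise decoding
#'
#' Trains the pairwise classifier at each training time point and tests it
#' at every testing time point, using the same pseudo-trials and folds as
#' [pairwise_decoding_timecourse()]; with the same `params$seed` the
#' diagonal of the grand-average map therefore reproduces the grand-average
#' time-resolved decoding exactly.
#'
#' @param epochs A [meg_epochs].
#' @param params A [decoding_params()].
#' @param keep_pairs Keep the per-pair maps (`conditions x conditions`
#'   list)? Off by default to bound memory.
#' @return An object of class `tg_map`: `accuracy` (training time x testing
#'   time grand-average grid, percent), `time`, `conditions`, optionally
#'   `pair_maps`.
#' @export
temporal_generalization <- function(epochs, params = decoding_params(),
                                    keep_pairs = FALSE) {
  stopifnot(inherits(epochs, "meg_epochs"), inherits(params, "decoding_params"))
  conds <- unique(epochs$labels)
  C <- length(conds)
  if (C < 2) stop("need at least 2 conditions")
  sel <- seq(1, length(epochs$time), by = params$stride)
  data <- epochs$data[, , sel, drop = FALSE]
  d <- dim(data)[2]
  Tn <- length(sel)
  pr <- all_pairs(C)
  grand <- matrix(0, Tn, Tn)
  pair_maps <- if (keep_pairs)
    stats::setNames(vector("list", nrow(pr)),
                    paste(conds[pr[, 1]], conds[pr[, 2]], sep = "|")) else NULL
  with_seed(params$seed, {
    for (rep_i in seq_len(params$n_repetitions)) {
      ps <- make_pseudotrials(data, epochs$labels, conds, params$group_size)
      for (k in seq_len(nrow(pr))) {
        i <- pr[k, 1]; j <- pr[k, 2]
        M <- min(dim(ps[[i]])[1], dim(ps[[j]])[1])
        if (M < 2)
          stop("fewer than 2 pseudo-trials per condition; decrease group_size or add trials")
        a <- ps[[i]][seq_len(M), , , drop = FALSE]
        b <- ps[[j]][seq_len(M), , , drop = FALSE]
        m <- .tgm_pair_cpp(as.numeric(a), as.numeric(b), M, d, Tn,
                           params$svm_cost)
        grand <- grand + m
        if (keep_pairs) {
          if (is.null(pair_maps[[k]])) pair_maps[[k]] <- m
          else pair_maps[[k]] <- pair_maps[[k]] + m
        }
      }
    }
  })
  grand <- grand / (nrow(pr) * params$n_repetitions)
  if (keep_pairs)
    pair_maps <- lapply(pair_maps, function(m) m / params$n_repetitions)
  structure(list(accuracy = grand, time = epochs$time[sel],
                 conditions = conds, pair_maps = pair_maps, params = params),
            class = "tg_map")
}

#' Direct category decoding with leave-exemplar-pairs-out cross-validation
#'
#' Trains a linear SVM to discriminate the two categories directly from
#' pseudo-trial patterns, holding out one exemplar of each category per
#' fold so that test exemplars never contribute training data (the
#' generalization-across-exemplars scheme). Chance is 50%.
#'
#' @param epochs A [meg_epochs] whose `category_of` maps conditions to two
#'   categories with at least two exemplars each.
#' @param params A [decoding_params()].
#' @return Numeric accuracy time series (percent).
#' @export
direct_category_decoding <- function(epochs, params = decoding_params()) {
  stopifnot(inherits(epochs, "meg_epochs"))
  if (is.null(epochs$category_of)) stop("epochs lack a category_of mapping")
  conds <- unique(epochs$labels)
  cats <- epochs$category_of[conds]
  lev <- unique(cats)
  if (length(lev) != 2) stop("exactly two categories required")
  ex_a <- conds[cats == lev[1]]
  ex_b <- conds[cats == lev[2]]
  if (length(ex_a) < 2 || length(ex_b) < 2)
    stop("each category needs at least two exemplars for exemplar-held-out folds")
  sel <- seq(1, length(epochs$time), by = params$stride)
  data <- epochs$data[, , sel, drop = FALSE]
  d <- dim(data)[2]
  Tn <- length(sel)
  n_folds <- min(length(ex_a), length(ex_b))
  acc <- numeric(Tn)
  n_eval <- 0
  with_seed(params$seed, {
    for (rep_i in seq_len(params$n_repetitions)) {
      ps <- make_pseudotrials(data, epochs$labels, conds, params$group_size)
      names(ps) <- conds
      perm_a <- sample(ex_a)
      perm_b <- sample(ex_b)
      for (f in seq_len(n_folds)) {
        test_conds <- c(perm_a[f], perm_b[f])
        train_conds <- setdiff(conds, test_conds)
        ytr <- ifelse(cats[train_conds] == lev[1], 1L, -1L)
        ytr <- rep(ytr, times = vapply(ps[train_conds],
                                       function(p) dim(p)[1], integer(1)))
        yte <- ifelse(cats[test_conds] == lev[1], 1L, -1L)
        yte <- rep(yte, times = vapply(ps[test_conds],
                                       function(p) dim(p)[1], integer(1)))
        slice_t <- function(p, t) matrix(p[, , t], nrow = dim(p)[1])
        for (t in seq_len(Tn)) {
          Xtr <- do.call(rbind, lapply(ps[train_conds], slice_t, t = t))
          Xte <- do.call(rbind, lapply(ps[test_conds], slice_t, t = t))
          mod <- .svm_linear_cpp(Xtr, ytr, params$svm_cost)
          dec <- as.numeric(Xte %*% mod$w + mod$b)
          acc[t] <- acc[t] + sum((dec > 0 & yte > 0) | (dec < 0 & yte < 0))
        }
        n_eval <- n_eval + length(yte)
      }
    }
  })
  100 * acc / n_eval
}
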