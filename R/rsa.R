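#' Condition-by-voxel response pattern set
#'
#' The fMRI-side container: one response pattern per condition for a region
#' (t-statistic units for real data, arbitrary for synthetic), optionally
#' with integer 3-D voxel coordinates for searchlight analysis.
#'
#' @param responses Numeric matrix `conditions x voxels`; row names are
#'   condition ids.
#' @param roi_id Region label.
#' @param coords Optional integer matrix `voxels x 3` of unique grid
#'   coordinates.
#' @return An object of class `pattern_set`.
#' @export
pattern_set <- function(responses, roi_id = "roi", coords = NULL) {
  stopifnot(is.matrix(responses), nrow(responses) >= 2, ncol(responses) >= 2)
  if (is.null(rownames(responses)))
    rownames(responses) <- sprintf("cond%02d", seq_len(nrow(responses)))
  if (!is.null(coords)) {
    stopifnot(is.matrix(coords), ncol(coords) == 3,
              nrow(coords) == ncol(responses))
    if (anyDuplicated(as.data.frame(coords)))
      stop("voxel coordinates must be unique")
  }
  structure(list(responses = responses, roi_id = roi_id, coords = coords),
            class = "pattern_set")
}

#' Representational dissimilarity matrix
#'
#' Symmetric conditions-by-conditions dissimilarity matrix on the
#' 1 - Pearson scale (range 0..2, diagonal 0).
#'
#' @param dissimilarity Symmetric numeric matrix.
#' @param condition_ids Condition ids (defaults to row names).
#' @return An object of class `rdm`.
#' @export
rdm <- function(dissimilarity, condition_ids = rownames(dissimilarity)) {
  stopifnot(is.matrix(dissimilarity),
            nrow(dissimilarity) == ncol(dissimilarity))
  if (max(abs(dissimilarity - t(dissimilarity))) > 1e-8)
    stop("dissimilarity must be symmetric")
  if (is.null(condition_ids))
    condition_ids <- sprintf("cond%02d", seq_len(nrow(dissimilarity)))
  dimnames(dissimilarity) <- list(condition_ids, condition_ids)
  structure(list(dissimilarity = dissimilarity,
                 condition_ids = condition_ids),
            class = "rdm")
}

#' Correlation RDM from a pattern set
#'
#' Entry `(i, j)` is `1 - Pearson(pattern_i, pattern_j)`; symmetric with a
#' zero diagonal.
#'
#' @param patterns A [pattern_set()]; every condition's pattern must have
#'   nonzero variance across voxels.
#' @return An [rdm].
#' @export
correlation_rdm <- function(patterns) {
  stopifnot(inherits(patterns, "pattern_set"))
  v <- apply(patterns$responses, 1, stats::var)
  if (any(v == 0))
    stop(sprintf("zero-variance pattern for condition(s): %s",
                 paste(rownames(patterns$responses)[v == 0], collapse = ", ")))
  d <- 1 - cor(t(patterns$responses))
  d <- (d + t(d)) / 2
  diag(d) <- 0
  rdm(d, rownames(patterns$responses))
}

#' Searchlight correlation RDMs
#'
#' For every voxel, gathers the in-mask voxels within a sphere of the given
#' radius (center-to-center Euclidean distance in voxel units, boundary
#' inclusive) and computes the correlation RDM of the neighborhood patterns.
#' Neighborhoods are truncated at the mask edge; centers whose neighborhood
#' holds fewer than two voxels are skipped with a warning.
#'
#' @param patterns A [pattern_set()] with voxel coordinates.
#' @param radius Sphere radius in voxel units (default 4).
#' @return Named list of [rdm] objects keyed `"x_y_z"` by center coordinate.
#' @export
searchlight_rdms <- function(patterns, radius = 4) {
  stopifnot(inherits(patterns, "pattern_set"))
  if (is.null(patterns$coords))
    stop("searchlight requires voxel coordinates")
  xyz <- patterns$coords
  nv <- nrow(xyz)
  out <- list()
  skipped <- 0
  for (v in seq_len(nv)) {
    d2 <- (xyz[, 1] - xyz[v, 1])^2 + (xyz[, 2] - xyz[v, 2])^2 +
      (xyz[, 3] - xyz[v, 3])^2
    nb <- which(d2 <= radius^2)
    if (length(nb) < 2) {
      skipped <- skipped + 1
      next
    }
    key <- paste(xyz[v, ], collapse = "_")
    r <- correlation_rdm(
      pattern_set(patterns$responses[, nb, drop = FALSE],
                  roi_id = paste0(patterns$roi_id, "@", key)))
    attr(r, "n_voxels") <- length(nb)
    out[[key]] <- r
  }
  if (skipped > 0)
    warning(sprintf("%d searchlight center(s) skipped (neighborhood < 2 voxels)",
                    skipped))
  out
}

#' MEG-fMRI fusion by rank correlation
#'
#' For every time point, vectorizes the strictly-lower triangle of the
#' (subject-averaged) MEG decoding RDM and of each fMRI RDM in the shared
#' fixed order and computes Spearman's rank correlation (average ranks for
#' ties), yielding one representational-similarity time course per fMRI
#' subject. Decoding-accuracy slices are used directly as dissimilarities
#' (higher accuracy = more dissimilar); no rescaling is needed since only
#' ranks enter.
#'
#' @param meg_rdm A [time_rdm] (typically subject-averaged via
#'   [average_rdms()]).
#' @param fmri_rdms A single [rdm] or list of [rdm]s (one per fMRI subject)
#'   with matching condition ids and ordering.
#' @param roi_id Region label attached to the output.
#' @return Data frame of class `fusion_series` with columns `time_ms`,
#'   `rho`, `subject`, `roi`. A constant RDM vector at some time point
#'   yields `NA` there.
#' @export
fusion_timecourse <- function(meg_rdm, fmri_rdms, roi_id = "roi") {
  stopifnot(inherits(meg_rdm, "time_rdm"))
  if (inherits(fmri_rdms, "rdm")) fmri_rdms <- list(fmri_rdms)
  C <- length(meg_rdm$conditions)
  idx <- ltri_index(C)
  Tn <- dim(meg_rdm$accuracy)[3]
  meg_vecs <- vapply(seq_len(Tn),
                     function(t) meg_rdm$accuracy[, , t][idx],
                     numeric(nrow(idx)))
  out <- lapply(seq_along(fmri_rdms), function(s) {
    fr <- fmri_rdms[[s]]
    stopifnot(inherits(fr, "rdm"))
    if (!identical(as.character(fr$condition_ids),
                   as.character(meg_rdm$conditions)))
      stop("condition ids of MEG and fMRI RDMs must match (same order)")
    fv <- fr$dissimilarity[idx]
    rho <- vapply(seq_len(Tn), function(t) {
      mv <- meg_vecs[, t]
      if (sd(mv) == 0 || sd(fv) == 0) return(NA_real_)
      cor(mv, fv, method = "spearman")
    }, numeric(1))
    data.frame(time_ms = meg_rdm$time, rho = rho, subject = s, roi = roi_id,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  class(res) <- c("fusion_series", class(res))
  res
}

#' Metric multidimensional scaling of an RDM
#'
#' Embeds conditions into `n_dims` dimensions by metric stress majorization
#' (SMACOF-style Guttman transforms) from a deterministic classical-scaling
#' start (`stats::cmdscale`). The output is centered at the origin and each
#' dimension's sign is fixed so that its largest-magnitude coordinate is
#' positive, making the embedding deterministic. Accuracy slices of a
#' decoding RDM can be passed directly as dissimilarities.
#'
#' @param x An [rdm], or a symmetric non-negative dissimilarity matrix (for
#'   instance one time slice of a [time_rdm]'s accuracy array with the
#'   diagonal set to 0).
#' @param n_dims Embedding dimensionality (default 2).
#' @param max_iter,tol Majorization iteration cap and relative stress
#'   convergence tolerance.
#' @return Matrix `conditions x n_dims` of coordinates, with a `stress`
#'   attribute (raw metric stress).
#' @export
mds_embed <- function(x, n_dims = 2, max_iter = 300, tol = 1e-10) {
  D <- if (inherits(x, "rdm")) x$dissimilarity else x
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (max(abs(D - t(D))) > 1e-8) stop("dissimilarities must be symmetric")
  if (min(D) < 0) stop("dissimilarities must be non-negative")
  n <- nrow(D)
  diag(D) <- 0
  X <- suppressWarnings(cmdscale(D, k = min(n_dims, n - 1)))
  if (ncol(X) < n_dims)                         # degenerate geometries
    X <- cbind(X, matrix(0, n, n_dims - ncol(X)))
  stress_of <- function(X) {
    E <- as.matrix(stats::dist(X))
    sum((D[upper.tri(D)] - E[upper.tri(E)])^2)
  }
  s_old <- stress_of(X)
  for (it in seq_len(max_iter)) {
    E <- as.matrix(stats::dist(X))
    B <- matrix(0, n, n)
    nz <- E > 0
    B[nz] <- -D[nz] / E[nz]
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    X_new <- B %*% X / n
    s_new <- stress_of(X_new)
    X <- X_new
    if (s_old - s_new <= tol * max(s_old, .Machine$double.eps)) break
    s_old <- s_new
  }
  X <- sweep(X, 2, colMeans(X))
  for (k in seq_len(ncol(X))) {
    m <- which.max(abs(X[, k]))
    if (X[m, k] < 0) X[, k] <- -X[, k]
  }
  rownames(X) <- if (inherits(x, "rdm")) x$condition_ids else rownames(D)
  colnames(X) <- paste0("dim", seq_len(ncol(X)))
  attr(X, "stress") <- stress_of(X)
  X
}
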