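#' @useDynLib megfusion, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor cmdscale pnorm qnorm quantile rnorm runif rbinom
#'   wilcox.test p.adjust sd
#' @importFrom utils write.csv packageVersion
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards so library code never perturbs user
# randomness.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Derive a stream seed from a master seed; stays within 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483647 + 104729 * as.numeric(k)) %% 2147483647)
}

#' All unordered condition pairs
#'
#' Enumerates the `n * (n - 1) / 2` unordered pairs of `n` conditions as a
#' two-column matrix `(i, j)` with `i < j`, in row-major order.
#'
#' @param n Number of conditions.
#' @return Integer matrix with columns `i`, `j`.
#' @export
all_pairs <- function(n) {
  stopifnot(n >= 2)
  j <- unlist(lapply(2:n, function(k) rep.int(k, k - 1L)))
  i <- unlist(lapply(2:n, function(k) seq_len(k - 1L)))
  cbind(i = as.integer(i), j = as.integer(j))
}

# Fixed lower-triangle vectorization order shared by every RDM consumer:
# row-major over i > j, i.e. (2,1), (3,1), (3,2), (4,1), ...
ltri_index <- function(n) {
  i <- unlist(lapply(2:n, function(k) rep.int(k, k - 1L)))
  j <- unlist(lapply(2:n, function(k) seq_len(k - 1L)))
  cbind(as.integer(i), as.integer(j))
}

#' Vectorize the lower triangle of a square matrix
#'
#' Extracts the strictly-lower-triangular entries in the package-wide fixed
#' order (row-major, `i > j`), the serialization order used for all RDM
#' comparisons.
#'
#' @param m Square matrix.
#' @return Numeric vector of length `n * (n - 1) / 2`.
#' @export
rdm_vec <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m), nrow(m) >= 2)
  m[ltri_index(nrow(m))]
}
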