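test_that("d-prime follows the probit definition with extreme-rate correction", {
  expect_equal(dprime(50, 50, 50, 50), 0)
  # hits 90/100, FAs 10/100: z(0.9) - z(0.1)
  expect_equal(dprime(90, 10, 10, 90), qnorm(0.9) - qnorm(0.1))
  expect_equal(dprime(90, 10, 10, 90), 2.563103, tolerance = 1e-6)
  # perfect hit rate replaced by 1 - 1/(2N) before the probit
  expect_equal(dprime(100, 0, 10, 90),
               qnorm(1 - 1 / 200) - qnorm(0.1))
  expect_error(dprime(0, 0, 5, 5), "at least one")
  # exchanging hits and false alarms flips the sign
  for (i in 1:10) {
    set.seed(i)
    k <- sample(0:20, 4, replace = TRUE) + c(1, 0, 1, 0)
    expect_equal(dprime(k[1], k[2], k[3], k[4]),
                 -dprime(k[3], k[4], k[1], k[2]))
  }
})

test_that("signed-rank test is exact for small n and symmetric in its arguments", {
  a <- c(3, 5, 1, 7, 2, 9)
  expect_equal(signed_rank_test(a, a), 1)
  # n = 6, all differences positive: exact two-sided p = 2/2^6
  b <- a - c(0.5, 0.4, 0.3, 0.2, 0.7, 0.6)
  expect_equal(signed_rank_test(a, b), 2 / 2^6)
  expect_equal(signed_rank_test(b, a), signed_rank_test(a, b))
  expect_error(signed_rank_test(1:3, 2:4), "at least 5")
  # large-sample branch stays a valid probability
  set.seed(2)
  x <- rnorm(40); y <- x + rnorm(40, 0.2)
  p <- signed_rank_test(x, y)
  expect_true(p >= 0 && p <= 1)
})

test_that("FDR correction reproduces the step-up rule exactly", {
  expect_true(all(fdr_correct(rep(0.001, 10))))
  expect_true(all(fdr_correct(c(0.01, 0.02, 0.03, 0.04), q = 0.05)))
  expect_false(any(fdr_correct(rep(1, 6))))
  expect_error(fdr_correct(c(0.5, 1.2)), "0, 1")

  # property: agree with the exhaustive definition for random inputs
  step_up <- function(p, q) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    k <- which(ps <= seq_len(m) * q / m)
    rej <- logical(m)
    if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
    rej
  }
  for (i in 1:50) {
    set.seed(i)
    m <- sample(1:12, 1)
    p <- round(runif(m), 3)
    expect_identical(fdr_correct(p, 0.05), step_up(p, 0.05))
  }
})

test_that("cluster inference finds a dominant effect with the smallest possible p", {
  set.seed(3)
  tm <- 60
  eff <- matrix(rnorm(12 * tm, 0, 0.1), 12, tm)
  eff[, 11:40] <- eff[, 11:40] + 3            # huge sustained effect
  cl <- sign_permutation_clusters(eff, n_perm = 500, seed = 4)
  sig <- cl$clusters[cl$clusters$significant, ]
  expect_equal(nrow(sig), 1)
  # the cluster spans the effect window (chance neighbors at the 5% CDT may
  # attach to its edges); sign flips that leave most subjects positive can
  # tie the observed extent, so the corrected p sits at or just above the
  # 1/(n_perm + 1) floor but well inside significance
  expect_true(all(11:40 %in% which(cl$sig_mask)))
  expect_gte(sig$size, 30)
  expect_gte(sig$p, 1 / 501)
  expect_lte(sig$p, 0.05)
  # flipping all subjects' signs removes one-sided significance
  cl_neg <- sign_permutation_clusters(-eff, n_perm = 500, seed = 4)
  expect_equal(sum(cl_neg$clusters$significant), 0)
})

test_that("2-D cluster inference reduces to the 1-D result for one-row maps", {
  set.seed(5)
  eff <- matrix(rnorm(10 * 50), 10, 50)
  eff[, 20:30] <- eff[, 20:30] + 1.2
  c1 <- sign_permutation_clusters(eff, n_perm = 300, seed = 7)
  arr <- array(eff, c(10, 1, 50))
  c2 <- sign_permutation_clusters(arr, n_perm = 300, seed = 7)
  expect_equal(as.vector(c2$sig_mask), c1$sig_mask)
  expect_equal(c2$clusters$p, c1$clusters$p)
  expect_warning(sign_permutation_clusters(eff, n_perm = 50, seed = 1),
                 "coarse")
  expect_error(sign_permutation_clusters(eff[1, , drop = FALSE]), "2 subjects")
})

test_that("bootstrap peak latency collapses for identical subjects and tracks a known peak", {
  tm <- seq(0, 200, by = 5)
  bump <- exp(-0.5 * ((tm - 100) / 20)^2)
  same <- matrix(rep(bump, 6), 6, byrow = TRUE)
  est <- bootstrap_latency(same, tm, "peak", n_boot = 200, seed = 1)
  expect_equal(est$point_ms, 100)
  expect_equal(est$ci_low_ms, 100)
  expect_equal(est$ci_high_ms, 100)
  expect_equal(est$n_undefined, 0)

  # noisy cohort: point estimate near truth, CI sane and seed-stable
  set.seed(9)
  noisy <- same + matrix(rnorm(6 * length(tm), 0, 0.15), 6)
  e1 <- bootstrap_latency(noisy, tm, "peak", window = c(0, 200),
                          n_boot = 500, seed = 2)
  e2 <- bootstrap_latency(noisy, tm, "peak", window = c(0, 200),
                          n_boot = 500, seed = 2)
  expect_identical(e1$boot_latencies, e2$boot_latencies)
  expect_true(e1$ci_low_ms <= e1$ci_high_ms)
  expect_lt(abs(e1$point_ms - 100), 20)
})

test_that("bootstrap onset latency finds the first sustained supra-threshold time", {
  tm <- seq(0, 300, by = 5)
  sig <- ifelse(tm >= 120 & tm <= 250, 2, 0)
  set.seed(11)
  coh <- matrix(rep(sig, 8), 8, byrow = TRUE) +
    matrix(rnorm(8 * length(tm), 0, 0.3), 8)
  est <- bootstrap_latency(coh, tm, "onset", window = c(0, 300),
                           n_boot = 200, seed = 3, n_perm = 500)
  expect_lt(abs(est$point_ms - 120), 20)
  expect_true(est$ci_low_ms <= est$ci_high_ms)
  # a flat null series yields undefined onsets, counted not crashed
  null <- matrix(rnorm(8 * length(tm), 0, 0.3), 8)
  est0 <- bootstrap_latency(null, tm, "onset", window = c(0, 300),
                            n_boot = 100, seed = 4, n_perm = 300,
                            min_consec_ms = 25)
  expect_true(is.na(est0$point_ms))
  expect_gt(est0$n_undefined, 0)
})

test_that("bootstrap latency differences separate distinct cohorts and accept identical ones", {
  tm <- seq(0, 300, by = 5)
  bump <- function(mu) exp(-0.5 * ((tm - mu) / 15)^2)
  set.seed(13)
  a <- matrix(rep(bump(100), 10), 10, byrow = TRUE) +
    matrix(rnorm(10 * length(tm), 0, 0.05), 10)
  b <- matrix(rep(bump(220), 10), 10, byrow = TRUE) +
    matrix(rnorm(10 * length(tm), 0, 0.05), 10)
  gap <- bootstrap_latency_difference(a, b, tm, "peak", n_boot = 500, seed = 5)
  expect_equal(gap$p, 1 / 500)               # the floor
  expect_lt(gap$diff_point, -100)

  same <- bootstrap_latency_difference(a, a + matrix(rnorm(10 * length(tm), 0, 0.05), 10),
                                       tm, "peak", n_boot = 500, seed = 6)
  expect_gt(same$p, 0.2)
  expect_error(bootstrap_latency_difference(a, b[1:5, ], tm, "peak",
                                            paired = TRUE), "matching")
})
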