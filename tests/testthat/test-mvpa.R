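test_that("sub-averaging forms floor(n/g) disjoint group means", {
  set.seed(1)
  x30 <- array(rnorm(30 * 2 * 3), c(30, 2, 3))
  expect_equal(dim(subaverage_trials(x30, 3))[1], 10)
  # 3 trials, group 3 -> the single pseudo-trial is the plain mean
  x3 <- array(rnorm(3 * 2 * 3), c(3, 2, 3))
  expect_equal(subaverage_trials(x3, 3)[1, , ], colMeans(x3, dims = 1))
  # 7 trials, group 3 -> 2 pseudo-trials, one trial dropped; groups disjoint
  x7 <- array(rep(2^(0:6), 2 * 3), c(7, 2, 3))   # distinct powers of two
  ps <- subaverage_trials(x7, 3)
  expect_equal(dim(ps)[1], 2)
  used <- round(3 * ps[, 1, 1])                  # each value = sum of 3 powers
  bits <- unlist(lapply(used, function(v) which(intToBits(v) == 1)))
  expect_equal(anyDuplicated(bits), 0)           # no trial reused
  expect_error(subaverage_trials(x3, 5), "at least")
})

test_that("single-channel M=2 decoding matches the exhaustive fold enumeration", {
  # group_size 1 keeps raw trials as pseudo-trials. Class A trials {0, 1},
  # class B {2.6, 10} at t1; every training pair is separated by more than
  # sqrt(2), so at C = 1 the margin is hard and the boundary is the training
  # midpoint. Enumerating the folds by hand under either random pairing of
  # pseudo-trials: a1 = 0 and a2 = 1 always fall nearest class A (correct),
  # b2 = 10 nearest class B (correct), while b1 = 2.6 always falls on the
  # class-A side of any midpoint (1.3, 1.8, 5 or 5.5) and is always wrong:
  # accuracy = 3/4. At t2, classes {0, 1} vs {4, 5} separate cleanly under
  # every fold: accuracy = 1.
  ep <- manual_epochs(list(
    A = rbind(c(0, 0), c(1, 1)),
    B = rbind(c(2.6, 4), c(10, 5))
  ))
  for (reps in c(1, 7)) {
    r <- pairwise_decoding_timecourse(
      ep, decoding_params(group_size = 1, n_repetitions = reps, seed = reps))
    expect_equal(unname(r$accuracy[1, 2, ]), c(75, 100))
  }
})

test_that("the compiled SVM reproduces libsvm decisions fold by fold", {
  # dual-route check: package decoding vs an e1071 (libsvm) re-implementation
  # of the same folds on the same pseudo-trials
  spec <- small_spec(n_conditions = 2, n_trials = 8, n_channels = 4,
                     time_lim = c(0, 40), seed = 33, noise_sd = 1,
                     id_env = envelope(5, 20, 20, amplitude = 1.5),
                     cat_env = envelope(5, 25, 20, amplitude = 0.5))
  ep <- generate_meg_subjects(spec)$subjects[[1]]
  params <- decoding_params(group_size = 1, n_repetitions = 1, seed = 9)
  r <- pairwise_decoding_timecourse(ep, params)

  conds <- unique(ep$labels)
  set.seed(params$seed)                       # replicate the pseudo-trial draw
  ps <- lapply(conds, function(cc)
    subaverage_trials(ep$data[ep$labels == cc, , , drop = FALSE], 1))
  M <- dim(ps[[1]])[1]
  Tn <- length(ep$time)
  ref <- vapply(seq_len(Tn), function(t) {
    correct <- 0
    for (k in seq_len(M)) {
      tr_a <- ps[[1]][-k, , t]; tr_b <- ps[[2]][-k, , t]
      X <- rbind(tr_a, tr_b)
      y <- factor(rep(c(1, -1), each = M - 1), levels = c(1, -1))
      fit <- e1071::svm(X, y, kernel = "linear", cost = 1, scale = FALSE)
      pred <- predict(fit, rbind(ps[[1]][k, , t], ps[[2]][k, , t]))
      correct <- correct + sum(pred == c("1", "-1"))
    }
    100 * correct / (2 * M)
  }, numeric(1))
  expect_equal(unname(r$accuracy[1, 2, ]), ref)
})

test_that("decoding matrices are symmetric, NA on the diagonal, and seed-deterministic", {
  spec <- small_spec(seed = 12)
  ep <- generate_meg_subjects(spec)$subjects[[1]]
  p <- decoding_params(group_size = 3, n_repetitions = 2, seed = 5)
  r1 <- pairwise_decoding_timecourse(ep, p)
  r2 <- pairwise_decoding_timecourse(ep, p)
  expect_identical(r1$accuracy, r2$accuracy)
  a <- r1$accuracy
  expect_true(all(is.na(a[cbind(1:4, 1:4, 1)])))
  for (t in c(1, dim(a)[3]))
    expect_identical(a[, , t], t(a[, , t]))
  expect_true(all(a >= 0 & a <= 100, na.rm = TRUE))
})

test_that("null data decodes at chance and separable patterns at ceiling", {
  null_spec <- small_spec(n_conditions = 4, seed = 8, noise_sd = 1,
                          id_env = envelope(40, 100, 60, amplitude = 0),
                          cat_env = envelope(110, 170, 80, amplitude = 0))
  ep <- generate_meg_subjects(null_spec)$subjects[[1]]
  r <- pairwise_decoding_timecourse(ep, decoding_params(3, 3, seed = 2))
  g <- partition_mean(r)
  expect_lt(abs(mean(g) - 50), 2.5)

  hot_spec <- small_spec(seed = 4, noise_sd = 0.2,
                         id_env = envelope(40, 100, 60, amplitude = 3))
  eph <- generate_meg_subjects(hot_spec)$subjects[[1]]
  rh <- pairwise_decoding_timecourse(eph, decoding_params(3, 2, seed = 3))
  expect_equal(partition_mean(rh)[which(rh$time == 100)], 100)
})

test_that("partition means count pairs correctly and divisions subtract cleanly", {
  expect_equal(nrow(all_pairs(24)), 276)
  expect_equal(nrow(all_pairs(12)), 66)
  conds <- c(sprintf("face%02d", 1:2), sprintf("object%02d", 1:2))
  cat_of <- setNames(rep(c("face", "object"), each = 2), conds)
  part <- pair_partition(conds, cat_of)
  expect_equal(nrow(part$within_A), 1)
  expect_equal(nrow(part$within_B), 1)
  expect_equal(nrow(part$between), 4)
  # disjoint and exhaustive
  all6 <- rbind(part$within_A, part$within_B, part$between)
  expect_equal(nrow(unique(all6)), 6)

  acc <- array(NA_real_, c(4, 4, 3))
  pr <- all_pairs(4)
  for (k in seq_len(nrow(pr))) {
    v <- if (any(k == which(pr[, 1] <= 2 & pr[, 2] <= 2 |
                            pr[, 1] >= 3 & pr[, 2] >= 3))) 55 else 60
    acc[pr[k, 1], pr[k, 2], ] <- v
    acc[pr[k, 2], pr[k, 1], ] <- v
  }
  fake <- structure(list(accuracy = acc, time = c(0, 10, 20),
                         conditions = conds, category_of = cat_of,
                         params = NULL), class = "time_rdm")
  expect_equal(partition_mean(fake, part$between), rep(60, 3))
  expect_equal(categorical_division(fake, part), rep(5, 3))
  expect_error(partition_mean(fake, matrix(numeric(0), 0, 2)), "non-empty")
})

test_that("categorical division vanishes for exchangeable conditions", {
  spec <- small_spec(n_conditions = 4, seed = 19, noise_sd = 1,
                     id_env = envelope(40, 100, 60, amplitude = 1.2),
                     cat_env = envelope(110, 170, 80, amplitude = 0))
  ep <- generate_meg_subjects(spec)$subjects[[1]]
  r <- pairwise_decoding_timecourse(ep, decoding_params(3, 3, seed = 6))
  part <- pair_partition(r$conditions, r$category_of)
  divis <- categorical_division(r, part)
  # no categorical component: the division hovers around zero
  expect_lt(abs(mean(divis)), 3 * sd(divis) / sqrt(length(divis) / 4))
})

test_that("temporal generalization shares its diagonal with time-resolved decoding", {
  ep <- generate_meg_subjects(small_spec(n_conditions = 4, seed = 14,
                                         time_lim = c(-50, 200)))$subjects[[1]]
  p <- decoding_params(group_size = 3, n_repetitions = 2, seed = 17)
  r <- pairwise_decoding_timecourse(ep, p)
  tg <- temporal_generalization(ep, p)
  expect_equal(diag(tg$accuracy), unname(partition_mean(r)), tolerance = 1e-12)
  expect_true(all(tg$accuracy >= 0 & tg$accuracy <= 100))
})

test_that("a sustained pattern generalizes across its whole interval", {
  # constant pattern from 100 to 250 ms: training anywhere in the interval
  # should test successfully anywhere else in it
  tm <- seq(-50, 300, by = 10)
  n <- 8
  dat <- array(rnorm(2 * n * 4 * length(tm), sd = 0.3), c(2 * n, 4, length(tm)))
  patt <- c(2, -2, 1, -1)
  on <- tm >= 100 & tm <= 250
  for (tr in 1:n) dat[tr, , on] <- dat[tr, , on] + patt
  ep <- meg_epochs(dat, rep(c("a", "b"), each = n), tm, 100,
                   baseline = c(-50, 0))
  tg <- temporal_generalization(ep, decoding_params(2, 2, seed = 21))
  inside <- mean(tg$accuracy[on, on])
  cross <- mean(tg$accuracy[!on, on])
  expect_gt(inside, 95)
  expect_lt(cross, inside - 20)
})

test_that("direct category decoding generalizes across exemplars", {
  spec <- small_spec(n_conditions = 6, seed = 23, noise_sd = 0.7,
                     id_env = envelope(40, 100, 60, amplitude = 0.5),
                     cat_env = envelope(110, 170, 80, amplitude = 2))
  ep <- generate_meg_subjects(spec)$subjects[[1]]
  acc <- direct_category_decoding(ep, decoding_params(3, 2, seed = 3))
  tm <- seq(-100, 350, by = 10)
  expect_gt(acc[which(tm == 170)], 90)
  expect_lt(mean(acc[tm < 0]), 65)

  null_ep <- generate_meg_subjects(
    small_spec(n_conditions = 6, seed = 29, noise_sd = 1,
               id_env = envelope(40, 100, 60, amplitude = 0),
               cat_env = envelope(110, 170, 80, amplitude = 0)))$subjects[[1]]
  acc0 <- direct_category_decoding(null_ep, decoding_params(3, 2, seed = 4))
  expect_lt(abs(mean(acc0) - 50), 5)

  two <- generate_meg_subjects(small_spec(n_conditions = 2, seed = 1))$subjects[[1]]
  expect_error(direct_category_decoding(two, decoding_params(3, 1, seed = 1)),
               "two exemplars")
})

test_that("ROI decoding is channel slicing: a channel subset gives the same result as a smaller recording", {
  spec <- small_spec(seed = 31, n_channels = 10, time_lim = c(0, 100),
                     id_env = envelope(10, 50, 40, amplitude = 1.2),
                     cat_env = envelope(20, 80, 40, amplitude = 1))
  ep <- generate_meg_subjects(spec)$subjects[[1]]
  roi <- ep
  roi$data <- ep$data[, 3:6, , drop = FALSE]
  p <- decoding_params(3, 2, seed = 2)
  direct <- pairwise_decoding_timecourse(roi, p)
  # identical construction from scratch
  again <- roi
  expect_identical(pairwise_decoding_timecourse(again, p)$accuracy,
                   direct$accuracy)
  expect_equal(dim(direct$accuracy)[1:2], c(4L, 4L))
})

test_that("lower noise strictly improves expected decoding accuracy", {
  means <- vapply(c(2, 1, 0.5), function(ns) {
    reps <- vapply(1:20, function(r) {
      spec <- small_spec(n_conditions = 2, n_trials = 8, n_channels = 6,
                         time_lim = c(60, 140), seed = 1000 * ns + r,
                         noise_sd = ns,
                         id_env = envelope(65, 100, 60, amplitude = 1),
                         cat_env = envelope(65, 100, 60, amplitude = 0))
      ep <- generate_meg_subjects(spec)$subjects[[1]]
      r2 <- pairwise_decoding_timecourse(ep, decoding_params(2, 1, seed = r))
      mean(partition_mean(r2))
    }, numeric(1))
    mean(reps)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
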