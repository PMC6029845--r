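test_that("correlation RDMs follow the 1 - Pearson definition", {
  x <- c(1, 2, 3, 4)
  p <- pattern_set(rbind(a = x, b = x, c = -x,
                         # deviations (-1.5,.5,-.5,1.5) vs (-1.5,-.5,.5,1.5):
                         # r = 4/5 by hand, so dissimilarity = 0.2
                         d = c(1, 3, 2, 4)))
  r <- correlation_rdm(p)
  expect_equal(r$dissimilarity["a", "b"], 0)          # identical -> 0
  expect_equal(r$dissimilarity["a", "c"], 2)          # negation -> 2
  expect_equal(r$dissimilarity["a", "d"], 0.2)
  expect_equal(diag(r$dissimilarity), rep(0, 4), ignore_attr = TRUE)
  expect_identical(r$dissimilarity, t(r$dissimilarity))

  bad <- pattern_set(rbind(a = x, flat = c(2, 2, 2, 2)))
  expect_error(correlation_rdm(bad), "flat")
})

test_that("searchlight neighborhoods match brute-force lattice counts", {
  # full 9^3 cube, interior center: neighborhood size must equal the number
  # of lattice offsets with squared norm <= r^2
  grid <- as.matrix(expand.grid(x = 0:8, y = 0:8, z = 0:8))
  off <- as.matrix(expand.grid(-4:4, -4:4, -4:4))
  lattice_count <- function(r) sum(rowSums(off^2) <= r^2)
  set.seed(5)
  resp <- matrix(rnorm(3 * nrow(grid)), 3, nrow(grid))
  ps <- pattern_set(resp, coords = grid)
  for (r in 1:4) {
    out <- searchlight_rdms(ps, radius = r)
    centre <- out[["4_4_4"]]
    expect_s3_class(centre, "rdm")
    expect_equal(attr(centre, "n_voxels"), lattice_count(r))
    # edge truncation: the corner voxel sees only its in-mask octant
    corner_d2 <- rowSums(grid^2)
    expect_equal(attr(out[["0_0_0"]], "n_voxels"), sum(corner_d2 <= r^2))
  }
  # brute-force lattice enumeration gives 7, 33, 123, 257 for radii 1..4
  expect_equal(vapply(1:4, lattice_count, numeric(1)), c(7, 33, 123, 257))
})

test_that("degenerate searchlights are skipped or rejected", {
  grid <- as.matrix(expand.grid(0:2, 0:2, 0:1))
  set.seed(6)
  ps <- pattern_set(matrix(rnorm(3 * nrow(grid)), 3, nrow(grid)),
                    coords = grid)
  expect_warning(out <- searchlight_rdms(ps, radius = 0), "skipped")
  expect_equal(length(out), 0)
  uni <- pattern_set(matrix(1:18 * 0 + rep(c(1, 1, 1), 6), 3, nrow(grid)),
                     coords = grid)
  uni$responses[] <- 1                      # all conditions identical, flat
  expect_error(suppressWarnings(searchlight_rdms(uni, radius = 2)),
               "zero-variance")
})

test_that("fusion is a rank statistic: self-fusion 1, reversal -1, monotone-invariant", {
  spec <- small_spec(n_conditions = 6, seed = 41)
  ep <- generate_meg_subjects(spec)$subjects[[1]]
  meg <- pairwise_decoding_timecourse(ep, decoding_params(3, 2, seed = 8))
  ti <- which(meg$time == 170)
  slice <- meg$accuracy[, , ti]
  diag(slice) <- 0
  self <- fusion_timecourse(meg, rdm(slice, meg$conditions))
  expect_equal(self$rho[ti], 1)

  # rank-reversed copy: rho = -1 at that time point
  rev_slice <- max(slice) - slice
  diag(rev_slice) <- 0
  revd <- fusion_timecourse(meg, rdm(rev_slice, meg$conditions))
  expect_equal(revd$rho[ti], -1)

  # strictly monotone transform of the fMRI RDM leaves every rho unchanged
  mono <- slice^3 + 2 * slice
  diag(mono) <- 0
  expect_equal(fusion_timecourse(meg, rdm(mono, meg$conditions))$rho,
               self$rho)

  wrong <- rdm(slice, rev(meg$conditions))
  expect_error(fusion_timecourse(meg, wrong), "match")
})

test_that("fusion of independent RDMs is null with SD near 1/sqrt(n_pairs - 1)", {
  # 24 conditions -> 276 pairs; Spearman null SD is 1/sqrt(275)
  C <- 24
  set.seed(77)
  acc <- array(NA_real_, c(C, C, 1))
  pr <- all_pairs(C)
  v <- rnorm(nrow(pr))
  for (k in seq_len(nrow(pr))) {
    acc[pr[k, 1], pr[k, 2], 1] <- v[k]
    acc[pr[k, 2], pr[k, 1], 1] <- v[k]
  }
  fake <- structure(list(accuracy = acc, time = 0,
                         conditions = sprintf("c%02d", 1:C),
                         category_of = NULL, params = NULL),
                    class = "time_rdm")
  rhos <- vapply(1:200, function(i) {
    m <- matrix(0, C, C)
    m[lower.tri(m)] <- rnorm(nrow(pr))
    m <- m + t(m)
    fusion_timecourse(fake, rdm(m, fake$conditions))$rho
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.02)
  expect_lt(abs(sd(rhos) - 1 / sqrt(275)), 0.015)
})

test_that("fusion records missing values for constant RDM vectors", {
  acc <- array(NA_real_, c(3, 3, 2))
  acc[, , 1] <- 60; acc[, , 2] <- matrix(c(NA, 55, 60, 55, NA, 65,
                                           60, 65, NA), 3, 3)
  diag(acc[, , 1]) <- NA
  fake <- structure(list(accuracy = acc, time = c(0, 10),
                         conditions = c("a", "b", "c"), category_of = NULL,
                         params = NULL), class = "time_rdm")
  fr <- rdm(matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3), c("a", "b", "c"))
  fs <- fusion_timecourse(fake, fr)
  expect_true(is.na(fs$rho[1]))              # constant MEG vector at t = 0
  expect_false(is.na(fs$rho[2]))
})

test_that("metric MDS embeds simple geometries exactly", {
  d2 <- matrix(c(0, 3, 3, 0), 2, 2)
  x2 <- mds_embed(rdm(d2), n_dims = 2)
  expect_equal(as.numeric(dist(x2)), 3, tolerance = 1e-6)
  expect_equal(colMeans(x2), c(0, 0), ignore_attr = TRUE, tolerance = 1e-10)

  # equilateral triangle: all embedded distances equal
  d3 <- matrix(1, 3, 3) - diag(3)
  x3 <- mds_embed(rdm(d3), n_dims = 2)
  expect_equal(max(dist(x3)) - min(dist(x3)), 0, tolerance = 1e-6)

  # two tight pairs far apart: between-centroid distance dominates
  d4 <- matrix(5, 4, 4)
  d4[1, 2] <- d4[2, 1] <- 0.5
  d4[3, 4] <- d4[4, 3] <- 0.5
  diag(d4) <- 0
  x4 <- mds_embed(rdm(d4), n_dims = 2)
  cen <- rbind(colMeans(x4[1:2, ]), colMeans(x4[3:4, ]))
  expect_gt(dist(cen)[1], max(dist(x4[1:2, ]), dist(x4[3:4, ])))

  # all-equal dissimilarities embed without crashing and deterministically
  x_deg <- mds_embed(rdm(d3), n_dims = 2)
  expect_identical(x_deg, mds_embed(rdm(d3), n_dims = 2))
})
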