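test_that("the covariate-free GLM t equals the pooled two-sample t", {
  set.seed(41)
  grp <- rep(c("patient", "control"), each = 6)
  Y <- matrix(stats::rnorm(12 * 25), 12)
  des <- group_design(grp)
  out <- voxelwise_glm_t(Y, des)
  expect_equal(out$df, 10L)
  for (v in c(1, 7, 25)) {
    tt <- stats::t.test(Y[grp == "patient", v], Y[grp == "control", v],
                        var.equal = TRUE)
    expect_equal(out$t[v], unname(tt$statistic), tolerance = 1e-10)
  }
})

test_that("null t maps follow the Student t reference distribution", {
  vals <- unlist(lapply(1:20, function(s) {
    set.seed(400 + s)
    grp <- sample(rep(c("patient", "control"), each = 10))
    des <- group_design(grp, mean_fd = stats::runif(20, 0, 0.1),
                        age = stats::rnorm(20, 40, 8))
    Y <- matrix(stats::rnorm(20 * 50), 20)
    voxelwise_glm_t(Y, des)$t
  }))
  ks <- stats::ks.test(vals, function(q) stats::pt(q, 16))
  expect_gt(ks$p.value, 0.01)
})

test_that("degenerate identical maps give guarded zero t", {
  Y <- matrix(1, 10, 5)
  des <- group_design(rep(c("patient", "control"), each = 5))
  expect_warning(out <- voxelwise_glm_t(Y, des), "zero-variance")
  expect_equal(out$t, rep(0, 5))
})

test_that("permutation FWE p-values are valid, seeded and monotone in |t|", {
  set.seed(43)
  grp <- rep(c("patient", "control"), each = 8)
  des <- group_design(grp, mean_fd = stats::runif(16, 0, 0.1),
                      age = stats::rnorm(16, 40, 8))
  Y <- matrix(stats::rnorm(16 * 30), 16)
  Y[grp == "patient", 1] <- Y[grp == "patient", 1] + 3  # one strong voxel
  a <- permutation_fwe(Y, des, n_perm = 300, seed = 5)
  b <- permutation_fwe(Y, des, n_perm = 300, seed = 5)
  expect_identical(a$p_fwe, b$p_fwe)
  expect_true(all(a$p_fwe >= 1 / 301 & a$p_fwe <= 1))
  # FWE p never below the per-voxel parametric p
  p_unc <- 2 * stats::pt(-abs(a$t), a$df)
  expect_true(all(a$p_fwe >= p_unc - 1e-12))
  ord <- order(abs(a$t))
  expect_true(all(diff(a$p_fwe[ord]) <= 1e-12))
  expect_lt(a$p_fwe[1], 0.05)
  # identical maps: everything at p = 1
  flat <- matrix(rep(stats::rnorm(30), each = 16), 16)
  suppressWarnings(nul <- permutation_fwe(flat, des, n_perm = 150, seed = 2))
  expect_true(all(nul$p_fwe == 1))
})

test_that("doubling the permutation count moves p by at most 2 binomial SE", {
  set.seed(44)
  grp <- rep(c("patient", "control"), each = 7)
  des <- group_design(grp)
  Y <- matrix(stats::rnorm(14 * 20), 14)
  p1 <- permutation_fwe(Y, des, n_perm = 500, seed = 1)$p_fwe
  p2 <- permutation_fwe(Y, des, n_perm = 1000, seed = 1)$p_fwe
  se <- sqrt(p2 * (1 - p2) / 501)
  expect_true(all(abs(p1 - p2) <= 2 * se + 1e-12))
})

test_that("cluster extraction respects extent, connectivity and sign", {
  dm <- c(6L, 6L, 6L)
  mask <- dense_mask(dm)
  tmap <- rep(0, mask$n_voxels)
  pmap <- rep(1, mask$n_voxels)
  # a contiguous 19-voxel blob: a 3 x 3 x 2 block plus one attached voxel
  blob <- as.matrix(expand.grid(i = 2:4, j = 2:4, k = 2:3))
  blob <- rbind(blob, c(5, 4, 3))
  pos <- match(coords_to_linear_test(blob, dm), mask$idx)
  tmap[pos] <- -5
  tmap[pos[1]] <- -6
  pmap[pos] <- 0.01
  cl <- extract_clusters(tmap, pmap, mask, alpha = 0.05)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$n_voxels, 19L)
  expect_equal(cl[[1]]$peak_t, -6)
  expect_equal(cl[[1]]$sign, -1L)
  expect_equal(cl[[1]]$peak_ijk, c(2L, 2L, 2L))
  # nothing significant: empty list
  expect_length(extract_clusters(tmap, rep(1, mask$n_voxels), mask), 0L)
  # diagonal contact merges under 26- but not 6-connectivity
  t2 <- rep(0, mask$n_voxels); p2 <- rep(1, mask$n_voxels)
  dpos <- match(coords_to_linear_test(rbind(c(1, 1, 1), c(2, 2, 1)), dm),
                mask$idx)
  t2[dpos] <- 4; p2[dpos] <- 0.01
  expect_length(extract_clusters(t2, p2, mask, connectivity = 26), 1L)
  expect_length(extract_clusters(t2, p2, mask, connectivity = 6), 2L)
  # opposite signs never merge
  t3 <- rep(0, mask$n_voxels); p3 <- rep(1, mask$n_voxels)
  apos <- match(coords_to_linear_test(rbind(c(1, 1, 1), c(1, 2, 1)), dm),
                mask$idx)
  t3[apos] <- c(4, -4); p3[apos] <- 0.01
  expect_length(extract_clusters(t3, p3, mask, connectivity = 26), 2L)
})

test_that("cluster features reduce to the obvious special cases", {
  dm <- c(4L, 4L, 4L)
  mask <- dense_mask(dm)
  t1 <- rep(0, mask$n_voxels); p1 <- rep(1, mask$n_voxels)
  t1[5] <- 4; p1[5] <- 0.01
  cl <- extract_clusters(t1, p1, mask)[[1]]
  expect_equal(cl$n_voxels, 1L)
  Z <- matrix(stats::rnorm(3 * mask$n_voxels), 3)
  expect_equal(cluster_mean_feature(Z, cl), Z[, 5])
  const <- matrix(2.5, 3, mask$n_voxels)
  expect_equal(cluster_mean_feature(const, cl), rep(2.5, 3))
})

test_that("Pearson correlation matches the exact t transform and cor.test", {
  set.seed(46)
  x <- stats::rnorm(19); y <- stats::rnorm(19)
  out <- pearson_r_p(x, y)
  ct <- stats::cor.test(x, y)
  expect_equal(out$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(out$p, ct$p.value, tolerance = 1e-12)
  same <- pearson_r_p(x, x)
  expect_equal(same$r, 1)
  expect_equal(same$p, 0)
  xo <- c(1, -1, 1, -1); yo <- c(1, 1, -1, -1)
  orth <- pearson_r_p(xo, yo)
  expect_equal(orth$r, 0)
  expect_equal(orth$p, 1)
  expect_error(pearson_r_p(rep(1, 5), y[1:5]), "zero variance")
  expect_equal(pearson_p_from_r(out$r, 19), out$p, tolerance = 1e-12)
})

test_that("Bonferroni threshold is alpha over the number of tests", {
  expect_equal(bonferroni_threshold(0.05, 2), 0.025)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.1, 5), 0.02)
})

test_that("the summary-statistic t-test matches a raw-data oracle", {
  eq <- ttest_from_summary(5, 1, 10, 5, 1, 12)
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
  set.seed(47)
  x <- stats::rnorm(14); y <- stats::rnorm(18)
  x <- (x - mean(x)) / stats::sd(x) * 1.3 + 2.1
  y <- (y - mean(y)) / stats::sd(y) * 0.8 + 1.6
  out <- ttest_from_summary(2.1, 1.3, 14, 1.6, 0.8, 18)
  tt <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(out$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(out$p, tt$p.value, tolerance = 1e-10)
  expect_equal(out$df, 30)
})

test_that("the 2x2 chi-square equals the direct expected-count formula", {
  prop <- chi2_2x2(10, 10, 10, 10)
  expect_equal(prop$chi2, 0)
  expect_equal(prop$p, 1)
  a <- 9; b <- 10; c <- 6; d <- 15
  out <- chi2_2x2(a, b, c, d)
  n <- a + b + c + d
  E <- outer(c(a + b, c + d), c(a + c, b + d)) / n
  O <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  expect_equal(out$chi2, sum((O - E)^2 / E), tolerance = 1e-12)
  expect_equal(out$df, 1)
  expect_error(chi2_2x2(0, 0, 3, 4), "margin")
})

test_that("ROI-to-ROI connectivity testing recovers planted decoupling", {
  # identical region series give r = 1, clipped before Fisher z
  dm <- c(3L, 3L, 3L)
  set.seed(48)
  base <- stats::rnorm(30)
  mat <- matrix(stats::rnorm(27 * 30), 27, 30)
  mat[1, ] <- base; mat[2, ] <- base  # subject 1: identical region series
  series <- c(list(mat),
              replicate(5, matrix(stats::rnorm(27 * 30), 27, 30),
                        simplify = FALSE))
  ma <- array(FALSE, dm); ma[1] <- TRUE
  mb <- array(FALSE, dm); mb[2] <- TRUE
  grp <- rep(c("patient", "control"), 3)
  ws <- testthat::capture_warnings(out <- roi_fc_group_test(series, ma, mb,
                                                            grp))
  expect_true(any(grepl("clipped", ws)))
  expect_equal(unname(out$z[1]), atanh(1 - 1e-7))

  # patients' two planted clusters share less of the global signal
  cfg <- sim_config(n_patients = 6, n_controls = 6, n_volumes = 120,
                    motion_spike_rate = 0, seed = 49)
  coh <- generate_cohort(cfg)
  dm2 <- coh$truth$grid_shape
  mk <- function(idx) { a <- array(FALSE, dm2); a[idx] <- TRUE; a }
  series2 <- lapply(coh$subjects, function(s)
    matrix(s$bold$data, prod(dm2)))
  res <- roi_fc_group_test(series2,
                           mk(coh$truth$cluster_voxels[[1]]$idx),
                           mk(coh$truth$cluster_voxels[[2]]$idx),
                           vapply(coh$subjects, `[[`, "", "group"))
  expect_lt(res$mean_patient, res$mean_control)
  expect_lt(res$t, 0)
})

test_that("ROI test type-I error is near nominal under the null", {
  set.seed(50)
  dm <- c(3L, 3L, 1L)
  ma <- array(FALSE, dm); ma[1:3] <- TRUE
  mb <- array(FALSE, dm); mb[4:6] <- TRUE
  grp <- rep(c("patient", "control"), each = 6)
  hits <- mean(replicate(500, {
    series <- replicate(12, matrix(stats::rnorm(9 * 60), 9),
                        simplify = FALSE)
    roi_fc_group_test(series, ma, mb, grp)$p < 0.05
  }))
  expect_gt(hits, 0.02)
  expect_lt(hits, 0.08)
})
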