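make_bold <- function(dm = c(4, 4, 4), nt = 20, fill = NULL, seed = 1) {
  set.seed(seed)
  data <- if (is.null(fill)) array(stats::rnorm(prod(dm) * nt), c(dm, nt))
  else array(fill, c(dm, nt))
  bold4d(data, voxel_size_mm = 3, tr_s = 2)
}

test_that("initial-volume discard drops exactly the leading frames", {
  b <- make_bold(nt = 250)
  out <- discard_initial(b, 10)
  expect_equal(n_volumes(out), 240L)
  expect_identical(out$data[, , , 1], b$data[, , , 11])
  expect_identical(discard_initial(b, 0), b)
  expect_error(discard_initial(make_bold(nt = 5), 10), "too short")
})

test_that("Gaussian smoothing matches a direct convolution oracle", {
  # unit impulse at the centre of a 9^3 grid, 4 mm FWHM on 3 mm voxels
  dm <- c(9L, 9L, 9L)
  arr <- array(0, c(dm, 1L))
  arr[5, 5, 5, 1] <- 1
  b <- bold4d(arr, voxel_size_mm = 3, tr_s = 2)
  out <- smooth_gaussian(b, fwhm_mm = 4)
  sigma <- 4 / (2 * sqrt(2 * log(2))) / 3
  expect_equal(sigma, 0.56619, tolerance = 1e-4)
  # oracle: dense 3D kernel placed at the impulse (support is interior)
  r <- max(1L, ceiling(4 * sigma))
  k1 <- stats::dnorm(-r:r, sd = sigma)
  k1 <- k1 / sum(k1)
  k3 <- outer(outer(k1, k1), k1)
  dim(k3) <- rep(2L * r + 1L, 3L)
  oracle <- array(0, dm)
  oracle[(5 - r):(5 + r), (5 - r):(5 + r), (5 - r):(5 + r)] <- k3
  expect_equal(out$data[, , , 1], oracle, tolerance = 1e-12)
  expect_equal(sum(out$data), 1, tolerance = 1e-6)
})

test_that("smoothing is the identity for fwhm 0 and for constant volumes", {
  b <- make_bold(nt = 3)
  expect_identical(smooth_gaussian(b, 0), b)
  const <- make_bold(nt = 2, fill = 7)
  expect_equal(smooth_gaussian(const, 4)$data, const$data, tolerance = 1e-12)
})

test_that("linear detrending removes exactly the first-order trend", {
  t_ <- 1:50
  ts <- rbind(2 + 3 * t_, 5 - 0.2 * t_)
  out <- detrend_linear(ts)
  expect_equal(max(abs(out)), 0, tolerance = 1e-9)
  # residual slope of a noisy series is numerically zero
  set.seed(4)
  y <- matrix(stats::rnorm(200), 2)
  res <- detrend_linear(y)
  for (i in 1:2) {
    fit <- stats::lm.fit(cbind(1, seq_len(100)), res[i, ])
    expect_lt(max(abs(fit$coefficients)), 1e-10)
  }
  # a passband sine's amplitude is preserved within 2%
  n <- 100
  s <- sin(2 * pi * 0.05 * (1:n) * 2)  # 0.05 Hz at TR 2
  out <- detrend_linear(matrix(s, 1))
  amp <- function(x) 2 * max(Mod(stats::fft(x))) / length(x)
  expect_equal(amp(out[1, ]) / amp(s), 1, tolerance = 0.02)
})

test_that("band-pass keeps the passband, kills the stopband, shifts nothing", {
  n <- 200; tr <- 2
  t_ <- seq_len(n)
  pass <- sin(2 * pi * 0.05 * t_ * tr)
  stop_ <- sin(2 * pi * 0.2 * t_ * tr)
  out_pass <- bandpass(matrix(pass, 1), tr)[1, ]
  out_stop <- bandpass(matrix(stop_, 1), tr)[1, ]
  expect_gte(stats::sd(out_pass) / stats::sd(pass), 0.95)
  expect_lte(stats::sd(out_stop) / stats::sd(stop_), 0.05)
  # zero phase: an exact-bin passband sinusoid passes through unshifted
  expect_equal(out_pass, pass, tolerance = 1e-6)
  expect_equal(bandpass(matrix(0, 2, n), tr), matrix(0, 2, n))
  expect_error(bandpass(matrix(pass, 1), tr, low_hz = 0.01, high_hz = 0.3),
               "Nyquist")
})

test_that("Friston-24 expansion follows the lag-and-square definition", {
  z <- friston24(matrix(0, 10, 6))
  expect_identical(dim(z), c(10L, 24L))
  expect_true(all(z == 0))
  m <- matrix(0, 10, 6)
  m[, 2] <- 1:10
  f <- friston24(m)
  expect_equal(f[, 2], 1:10)            # p(t)
  expect_equal(f[, 8], c(0, 1:9))       # p(t-1), first row zeroed
  expect_equal(f[, 14], (1:10)^2)       # p(t)^2
  expect_equal(f[, 20], c(0, (1:9)^2))  # p(t-1)^2
  expect_error(friston24(matrix(0, 10, 5)), "6 columns")
})

test_that("framewise displacement follows the Power formula", {
  expect_equal(framewise_displacement(matrix(1, 5, 6))$fd, rep(0, 5))
  m <- matrix(0, 3, 6)
  m[2, ] <- c(0.1, 0.1, 0.1, 0.001, 0.001, 0.001)
  fd <- framewise_displacement(m, head_radius_mm = 50)
  expect_equal(fd$fd[2], 0.45)
  expect_equal(fd$fd[1], 0)
  # linearity: doubling the motion doubles every FD entry
  fd2 <- framewise_displacement(2 * m, head_radius_mm = 50)
  expect_equal(fd2$fd, 2 * fd$fd)
  expect_equal(fd$mean_fd, mean(fd$fd))
})

test_that("gross-motion exclusion uses strict thresholds", {
  m <- matrix(0, 5, 6)
  expect_false(qc_exclude(m))
  m[3, 1] <- 2.1
  expect_true(qc_exclude(m))
  m[3, 1] <- 2            # exactly at the limit: kept
  m[4, 5] <- 2 * pi / 180 # exactly 2 degrees: kept
  expect_false(qc_exclude(m))
  m[4, 5] <- 2.05 * pi / 180
  expect_true(qc_exclude(m))
})

test_that("nuisance regression produces design-orthogonal residuals", {
  set.seed(8)
  nt <- 60
  design <- matrix(stats::rnorm(nt * 5), nt)
  colnames(design) <- paste0("c", 1:5)
  ts <- matrix(stats::rnorm(20 * nt), 20)
  res <- nuisance_regress(ts, design)
  dots <- res %*% design
  expect_lt(max(abs(dots)), 1e-8)
  # a series equal to a design column is annihilated
  one <- nuisance_regress(matrix(design[, 3], 1), design)
  expect_lt(max(abs(one)), 1e-10)
  # an all-zero design plus intercept just de-means
  z <- nuisance_regress(ts, matrix(0, nt, 3))
  expect_equal(z, ts - rowMeans(ts), tolerance = 1e-12)
  # collinear designs fail naming the offending column
  bad <- cbind(design, c5_copy = design[, 5])
  expect_error(nuisance_regress(ts, bad), "c5_copy")
})

test_that("scrubbing censors exactly the FD-exceeding volumes", {
  ts <- matrix(seq_len(8), 2)
  sc <- scrub(ts, c(0, 0.1, 0.25, 0.15), threshold_mm = 0.2,
              min_volumes = 1)
  expect_equal(sc$censor$kept, c(1L, 2L, 4L))
  expect_equal(sc$data, ts[, c(1, 2, 4)])
  expect_equal(sc$n_censored, 1L)
  # exactly at the threshold is kept (strict >)
  sc2 <- scrub(ts, c(0, 0.2, 0.2, 0.2), min_volumes = 1)
  expect_equal(sc2$censor$kept, 1:4)
  # all-zero FD is the identity
  expect_equal(scrub(ts, rep(0, 4), min_volumes = 1)$data, ts)
  expect_warning(scrub(ts, c(0, 0.5, 0.5, 0.5), min_volumes = 2), "flagged")
})

test_that("tissue mean signal averages exactly the masked voxels", {
  b <- make_bold(dm = c(3, 3, 3), nt = 5)
  mask1 <- array(FALSE, c(3, 3, 3)); mask1[2, 2, 2] <- TRUE
  expect_equal(tissue_mean_signal(b, mask1), b$data[2, 2, 2, ])
  const <- make_bold(dm = c(3, 3, 3), nt = 4, fill = 3.5)
  maskA <- array(c(TRUE, rep(FALSE, 26)), c(3, 3, 3))
  expect_equal(tissue_mean_signal(const, maskA), rep(3.5, 4))
  mask2 <- array(FALSE, c(3, 3, 3)); mask2[c(1, 5)] <- TRUE
  mat <- matrix(b$data, 27)
  expect_equal(tissue_mean_signal(b, mask2), (mat[1, ] + mat[5, ]) / 2)
  expect_error(tissue_mean_signal(b, array(FALSE, c(3, 3, 3))), "empty")
})

test_that("a planted passband latent survives the full chain", {
  # no-motion, low-noise cohort; correlate the post-chain gray-matter mean
  # against the generator's own shared latent signal
  cfg <- sim_config(n_patients = 1, n_controls = 1, n_volumes = 120,
                    noise_sd = 0.1, motion_spike_rate = 0, seed = 31)
  coh <- generate_cohort(cfg)
  tis <- coh$truth$tissue
  sub <- coh$subjects[[2]]  # control: full baseline coupling everywhere
  sub$motion[] <- 0
  res <- preprocess_subject(sub$bold, sub$motion, tis$wm > 0.8,
                            tis$csf > 0.8, min_volumes = 40)
  expect_false(res$excluded)
  gm_mean <- colMeans(res$ts[which(tis$gm_mask), ])
  g <- coh$truth$latents[[2]][-(1:10)]
  expect_gte(abs(stats::cor(gm_mean, g)), 0.9)
  # rerun is bit-identical
  res2 <- preprocess_subject(sub$bold, sub$motion, tis$wm > 0.8,
                             tis$csf > 0.8, min_volumes = 40)
  expect_identical(res$ts, res2$ts)
})
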