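#' Discard initial volumes
#'
#' Drops the first `n_discard` volumes of a BOLD series (steady-state
#' settling of the scanner signal); the remaining frames are unchanged.
#'
#' @param bold A [bold4d()].
#' @param n_discard Number of leading volumes to remove (default 10).
#' @return A [bold4d()] with `n_discard` fewer volumes.
#' @export
discard_initial <- function(bold, n_discard = 10) {
  stopifnot(inherits(bold, "bold4d"))
  n_discard <- as.integer(n_discard)
  if (n_discard < 0) stopf("'n_discard' must be >= 0")
  if (n_discard == 0L) return(bold)
  nt <- n_volumes(bold)
  if (nt <= n_discard) {
    stopf("series too short: %d volumes, cannot discard %d", nt, n_discard)
  }
  bold4d(bold$data[, , , (n_discard + 1L):nt, drop = FALSE],
         bold$voxel_size_mm, bold$tr_s)
}

# 1D convolution matrix with symmetric (reflective) boundary handling
conv_matrix_1d <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (o in -r:r) {
      j <- i + o
      # mirror about the edge samples' outer boundary: 0 -> 1, -1 -> 2, ...
      while (j < 1L || j > n) {
        if (j < 1L) j <- 1L - j
        if (j > n) j <- 2L * n + 1L - j
      }
      K[i, j] <- K[i, j] + kernel[o + r + 1L]
    }
  }
  K
}

apply_along_axis <- function(arr, axis, K) {
  dm <- dim(arr)
  perm <- c(axis, setdiff(seq_along(dm), axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = dm[axis])
  m <- K %*% m
  a <- array(m, dim = dm[perm])
  aperm(a, order(perm))
}

#' Spatial Gaussian smoothing
#'
#' Convolves each volume with a separable isotropic 3D Gaussian of the given
#' full width at half maximum. The kernel standard deviation is
#' `fwhm / (2 * sqrt(2 * log(2)))` mm, converted to voxels via the voxel
#' size. Boundaries are handled by reflection, so the total intensity of
#' each volume is conserved and a constant volume is left unchanged.
#'
#' @param bold A [bold4d()].
#' @param fwhm_mm Full width at half maximum of the kernel, mm; 0 is the
#'   identity.
#' @return Smoothed [bold4d()].
#' @export
smooth_gaussian <- function(bold, fwhm_mm = 4) {
  stopifnot(inherits(bold, "bold4d"))
  if (fwhm_mm < 0) stopf("'fwhm_mm' must be >= 0")
  if (fwhm_mm == 0) return(bold)
  if (any(bold$voxel_size_mm <= 0)) stopf("voxel size must be positive")
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  dm <- dim(bold$data)
  out <- bold$data
  for (axis in 1:3) {
    sigma_vox <- sigma_mm / bold$voxel_size_mm[axis]
    r <- max(1L, ceiling(4 * sigma_vox))
    k <- stats::dnorm(-r:r, sd = sigma_vox)
    k <- k / sum(k)
    K <- conv_matrix_1d(dm[axis], k)
    out <- apply_along_axis(out, axis, K)
  }
  bold4d(out, bold$voxel_size_mm, bold$tr_s)
}

#' Linear detrending of voxel time series
#'
#' Removes the per-voxel least-squares line (intercept and slope in time);
#' the residuals are orthogonal to both the constant and the linear term.
#'
#' @param ts_matrix Voxels x time numeric matrix.
#' @return Matrix of the same shape.
#' @export
detrend_linear <- function(ts_matrix) {
  ts_matrix <- as.matrix(ts_matrix)
  nt <- ncol(ts_matrix)
  if (nt < 3L) stopf("need at least 3 time points to detrend")
  X <- cbind(1, seq_len(nt) - (nt + 1) / 2)
  B <- ts_matrix %*% X %*% solve(crossprod(X))
  ts_matrix - B %*% t(X)
}

#' Zero-phase band-pass filter
#'
#' Frequency-domain masking with cosine-tapered transition bands: the DFT of
#' each voxel series is multiplied by a real gain that is 1 inside
#' `[low_hz, high_hz]`, rolls off as a raised cosine over a narrow
#' transition band (`taper_hz` wide) on each side, and is 0 beyond. A real
#' symmetric gain introduces no phase shift.
#'
#' @param ts_matrix Voxels x time matrix.
#' @param tr_s Sampling interval, seconds.
#' @param low_hz,high_hz Passband edges, Hz; require
#'   `0 <= low_hz < high_hz < 1 / (2 * tr_s)`.
#' @param taper_hz Transition half-band width, Hz.
#' @return Filtered matrix of the same shape.
#' @export
bandpass <- function(ts_matrix, tr_s, low_hz = 0.01, high_hz = 0.08,
                     taper_hz = 0.002) {
  ts_matrix <- as.matrix(ts_matrix)
  nyquist <- 1 / (2 * tr_s)
  if (!(low_hz >= 0 && low_hz < high_hz && high_hz < nyquist)) {
    stopf("need 0 <= low_hz < high_hz < Nyquist (%g Hz)", nyquist)
  }
  nt <- ncol(ts_matrix)
  f <- pmin(0:(nt - 1L), nt - (0:(nt - 1L))) / (nt * tr_s)
  gain <- numeric(nt)
  gain[f >= low_hz & f <= high_hz] <- 1
  if (taper_hz > 0) {
    lo0 <- max(low_hz - taper_hz, 0)
    ramp_lo <- f >= lo0 & f < low_hz
    gain[ramp_lo] <- 0.5 * (1 - cos(pi * (f[ramp_lo] - lo0) / (low_hz - lo0)))
    ramp_hi <- f > high_hz & f <= high_hz + taper_hz
    gain[ramp_hi] <- 0.5 * (1 + cos(pi * (f[ramp_hi] - high_hz) / taper_hz))
  }
  Y <- stats::mvfft(t(ts_matrix))
  t(Re(stats::mvfft(Y * gain, inverse = TRUE)) / nt)
}

#' Friston-24 motion regressor expansion
#'
#' Expands the 6 rigid-body motion parameters p(t) into the 24-regressor
#' set: `[p(t), p(t-1), p(t)^2, p(t-1)^2]`. The first row of each lagged
#' column is set to 0 so the time dimension is preserved.
#'
#' @param motion T x 6 matrix (tx, ty, tz in mm; rx, ry, rz in radians).
#' @return T x 24 matrix with descriptive column names.
#' @export
friston24 <- function(motion) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stopf("motion must have 6 columns, got %d",
                                ncol(motion))
  lag1 <- rbind(0, motion[-nrow(motion), , drop = FALSE])
  out <- cbind(motion, lag1, motion^2, lag1^2)
  base <- c("tx", "ty", "tz", "rx", "ry", "rz")
  colnames(out) <- c(base, paste0(base, "_lag"), paste0(base, "_sq"),
                     paste0(base, "_lag_sq"))
  out
}

#' Framewise displacement
#'
#' Power-style framewise displacement: for each volume t >= 2,
#' `FD_t = sum(|delta translation|) + r * sum(|delta rotation|)` with
#' rotations (radians) converted to arc length on a sphere of radius `r`
#' (default 50 mm). The first entry is defined as 0.
#'
#' @param motion T x 6 motion matrix (translations mm, rotations radians).
#' @param head_radius_mm Sphere radius for the rotation arc length.
#' @return List of class `fd_series`: `fd` (length T, mm) and `mean_fd`.
#' @export
framewise_displacement <- function(motion, head_radius_mm = 50) {
  motion <- as.matrix(motion)
  if (nrow(motion) < 2L) stopf("need at least 2 volumes for FD")
  if (!all(is.finite(motion))) stopf("motion parameters must be finite")
  d <- abs(diff(motion))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            head_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
  structure(list(fd = fd, mean_fd = mean(fd),
                 head_radius_mm = head_radius_mm), class = "fd_series")
}

#' Gross-motion exclusion rule
#'
#' Flags a subject for exclusion if head movement strictly exceeded
#' `max_trans_mm` of translation or `max_rot_deg` of rotation in any
#' direction at any time point. Values exactly at the limit are kept.
#'
#' @param motion T x 6 motion matrix (translations mm, rotations radians).
#' @param max_trans_mm Translation limit, mm.
#' @param max_rot_deg Rotation limit, degrees.
#' @return Logical: `TRUE` if the subject should be excluded.
#' @export
qc_exclude <- function(motion, max_trans_mm = 2, max_rot_deg = 2) {
  motion <- as.matrix(motion)
  any(abs(motion[, 1:3]) > max_trans_mm) ||
    any(abs(motion[, 4:6]) * 180 / pi > max_rot_deg)
}

#' Nuisance regression
#'
#' Regresses each voxel time series on an intercept plus the given nuisance
#' design (typically Friston-24 motion regressors and the mean white-matter
#' and CSF signals) and returns the residuals, which are orthogonal to
#' every design column. The global (whole-brain mean) signal is not part of
#' the design and is not removed.
#'
#' @param ts_matrix Voxels x time matrix.
#' @param design T x p nuisance regressor matrix.
#' @return Voxels x time residual matrix.
#' @export
nuisance_regress <- function(ts_matrix, design) {
  ts_matrix <- as.matrix(ts_matrix)
  design <- as.matrix(design)
  nt <- ncol(ts_matrix)
  if (nrow(design) != nt) {
    stopf("design has %d rows but series has %d time points",
          nrow(design), nt)
  }
  # all-zero regressors carry no signal; drop them rather than flag the
  # design as collinear with itself
  if (ncol(design)) {
    design <- design[, colSums(design != 0) > 0L, drop = FALSE]
  }
  X <- cbind(`(intercept)` = 1, design)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stopf("rank-deficient nuisance design; collinear column(s): %s",
          paste(dropped, collapse = ", "))
  }
  Q <- qr.Q(qx)
  Y <- t(ts_matrix)
  t(Y - Q %*% crossprod(Q, Y))
}

#' Motion scrubbing (volume censoring)
#'
#' Removes the time points whose framewise displacement strictly exceeds
#' the threshold; the kept columns preserve their order. A subject with
#' fewer than `min_volumes` surviving volumes is flagged.
#'
#' @param ts_matrix Voxels x time matrix.
#' @param fd An `fd_series` from [framewise_displacement()] (or a numeric
#'   vector of per-volume FD, mm).
#' @param threshold_mm Censoring threshold, mm.
#' @param min_volumes Minimum surviving volumes before the subject is
#'   flagged.
#' @return List of class `scrub_result`: `data` (censored matrix), `censor`
#'   (a `censor_mask` with kept 1-based indices and the threshold),
#'   `flagged`, `n_censored`.
#' @export
scrub <- function(ts_matrix, fd, threshold_mm = 0.2, min_volumes = 50) {
  ts_matrix <- as.matrix(ts_matrix)
  fdv <- if (inherits(fd, "fd_series")) fd$fd else as.numeric(fd)
  if (length(fdv) != ncol(ts_matrix)) {
    stopf("FD length %d does not match %d time points",
          length(fdv), ncol(ts_matrix))
  }
  kept <- which(!(fdv > threshold_mm))
  flagged <- length(kept) < min_volumes
  if (flagged) {
    warnf("only %d volumes survive scrubbing (minimum %d): subject flagged",
          length(kept), min_volumes)
  }
  structure(list(
    data = ts_matrix[, kept, drop = FALSE],
    censor = structure(list(kept = kept, threshold_mm = threshold_mm),
                       class = "censor_mask"),
    flagged = flagged,
    n_censored = length(fdv) - length(kept)), class = "scrub_result")
}

#' Mean signal over a tissue mask
#'
#' Per-volume mean of the series of all voxels inside a mask (e.g. white
#' matter or CSF), used as a nuisance regressor.
#'
#' @param x A [bold4d()] or a voxels x time matrix.
#' @param tissue_mask Logical array (same grid as the volume) or linear
#'   voxel indices.
#' @return Numeric vector, one value per volume.
#' @export
tissue_mean_signal <- function(x, tissue_mask) {
  mat <- if (inherits(x, "bold4d")) as_vox_time(x$data) else as.matrix(x)
  idx <- if (is.logical(tissue_mask)) which(tissue_mask) else
    as.integer(tissue_mask)
  if (!length(idx)) stopf("tissue mask is empty")
  if (max(idx) > nrow(mat)) stopf("mask indices exceed the voxel count")
  colMeans(mat[idx, , drop = FALSE])
}

#' Full per-subject preprocessing chain
#'
#' Applies, in fixed order: initial-volume discard, Gaussian smoothing,
#' linear detrending, band-pass filtering, nuisance regression (Friston-24
#' motion expansion plus mean white-matter and CSF signals extracted from
#' the filtered data) and framewise-displacement scrubbing. The gross
#' motion exclusion rule (2 mm / 2 degrees by default) is evaluated on the
#' full motion trace and reported; it does not interrupt processing.
#'
#' @param bold A [bold4d()] (raw but spatially aligned).
#' @param motion T x 6 motion matrix matching the raw volume count.
#' @param wm_mask,csf_mask Logical arrays or linear indices of white-matter
#'   and CSF voxels (used for nuisance signal extraction).
#' @param n_discard,fwhm_mm,low_hz,high_hz Early-stage parameters; defaults
#'   follow the standard chain (discard 10, 4 mm FWHM, 0.01-0.08 Hz).
#' @param fd_threshold_mm,head_radius_mm,min_volumes Scrubbing parameters
#'   (censor at FD > 0.2 mm on a 50 mm head radius; flag below 50 surviving
#'   volumes).
#' @param max_trans_mm,max_rot_deg Gross-motion exclusion limits.
#' @return List of class `preproc_result`: `ts` (voxels x kept-time
#'   residual matrix), `censor`, `fd` (`fd_series`), `excluded` (QC flag),
#'   `flagged` (too few surviving volumes), `n_censored`, `dim` (grid),
#'   `tr_s`.
#' @export
preprocess_subject <- function(bold, motion, wm_mask, csf_mask,
                               n_discard = 10, fwhm_mm = 4,
                               low_hz = 0.01, high_hz = 0.08,
                               fd_threshold_mm = 0.2, head_radius_mm = 50,
                               min_volumes = 50,
                               max_trans_mm = 2, max_rot_deg = 2) {
  stopifnot(inherits(bold, "bold4d"))
  motion <- as.matrix(motion)
  if (nrow(motion) != n_volumes(bold)) {
    stopf("motion has %d rows but BOLD has %d volumes",
          nrow(motion), n_volumes(bold))
  }
  excluded <- qc_exclude(motion, max_trans_mm, max_rot_deg)
  b <- discard_initial(bold, n_discard)
  motion_pd <- motion[-seq_len(n_discard), , drop = FALSE]
  b <- smooth_gaussian(b, fwhm_mm)
  mat <- as_vox_time(b$data)
  mat <- detrend_linear(mat)
  mat <- bandpass(mat, b$tr_s, low_hz, high_hz)
  design <- cbind(friston24(motion_pd),
                  wm = tissue_mean_signal(mat, wm_mask),
                  csf = tissue_mean_signal(mat, csf_mask))
  # constant regressors (e.g. a motionless axis) duplicate the intercept
  keep_col <- apply(design, 2L, function(x) stats::sd(x) > 0)
  mat <- nuisance_regress(mat, design[, keep_col, drop = FALSE])
  fd <- framewise_displacement(motion_pd, head_radius_mm)
  sc <- scrub(mat, fd, fd_threshold_mm, min_volumes)
  structure(list(ts = sc$data, censor = sc$censor, fd = fd,
                 excluded = excluded, flagged = sc$flagged,
                 n_censored = sc$n_censored,
                 dim = dim(b$data)[1:3], tr_s = b$tr_s),
            class = "preproc_result")
}

#' Light per-subject preparation for replicate simulations
#'
#' Computes framewise displacement, applies the gross-motion exclusion
#' rule and scrubbing, and passes the series through otherwise untouched.
#' Intended for simulation studies that evaluate the inference stages over
#' many replicate cohorts, where the generated signals are already
#' band-limited and carry no nuisance structure.
#'
#' @inheritParams preprocess_subject
#' @return A `preproc_result`, as from [preprocess_subject()].
#' @export
preprocess_light <- function(bold, motion,
                             fd_threshold_mm = 0.2, head_radius_mm = 50,
                             min_volumes = 50,
                             max_trans_mm = 2, max_rot_deg = 2) {
  stopifnot(inherits(bold, "bold4d"))
  motion <- as.matrix(motion)
  if (nrow(motion) != n_volumes(bold)) {
    stopf("motion has %d rows but BOLD has %d volumes",
          nrow(motion), n_volumes(bold))
  }
  excluded <- qc_exclude(motion, max_trans_mm, max_rot_deg)
  fd <- framewise_displacement(motion, head_radius_mm)
  sc <- scrub(as_vox_time(bold$data), fd, fd_threshold_mm, min_volumes)
  structure(list(ts = sc$data, censor = sc$censor, fd = fd,
                 excluded = excluded, flagged = sc$flagged,
                 n_censored = sc$n_censored,
                 dim = dim(bold$data)[1:3], tr_s = bold$tr_s),
            class = "preproc_result")
}
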