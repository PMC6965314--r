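#' Gray-matter mask from a tissue probability map
#'
#' Voxels whose gray-matter probability strictly exceeds the threshold
#' (conventionally 0.2) define the domain on which global functional
#' connectivity is computed.
#'
#' @param prob_map 3D array of probabilities in `[0, 1]`.
#' @param threshold Inclusion threshold; strict `>`.
#' @return Object of class `gray_mask`: `mask` (logical array), `idx`
#'   (linear voxel indices), `dim`, `n_voxels`.
#' @export
gray_matter_mask <- function(prob_map, threshold = 0.2) {
  if (!is.array(prob_map) || length(dim(prob_map)) != 3L) {
    stopf("'prob_map' must be a 3D array")
  }
  if (any(prob_map < 0 | prob_map > 1, na.rm = TRUE)) {
    stopf("probabilities must lie in [0, 1]")
  }
  mask <- prob_map > threshold
  mask[is.na(mask)] <- FALSE
  idx <- which(mask)
  if (length(idx) < 2L) {
    stopf("gray-matter mask has %d voxel(s); need at least 2", length(idx))
  }
  structure(list(mask = mask, idx = idx, dim = dim(prob_map),
                 n_voxels = length(idx), threshold = threshold),
            class = "gray_mask")
}

#' @export
print.gray_mask <- function(x, ...) {
  cat(sprintf("<gray_mask> %d voxels on a %s grid (prob > %g)\n",
              x$n_voxels, paste(x$dim, collapse = "x"), x$threshold))
  invisible(x)
}

#' Row-wise standardization of voxel time series
#'
#' Centers each row to mean 0 and scales it to population SD 1 (so that
#' `row %*% row == T` and the dot product of two standardized rows divided
#' by T is exactly their Pearson correlation). Zero-variance rows cannot be
#' standardized and are flagged.
#'
#' @param ts_matrix Voxels x time matrix, `T >= 3`.
#' @return List: `x` (standardized matrix; flagged rows left as zeros),
#'   `zero_variance` (logical per row).
#' @export
standardize <- function(ts_matrix) {
  ts_matrix <- as.matrix(ts_matrix)
  nt <- ncol(ts_matrix)
  if (nt < 3L) stopf("need T >= 3 time points")
  m <- rowMeans(ts_matrix)
  cen <- ts_matrix - m
  s <- sqrt(rowMeans(cen^2))
  zero <- s < .Machine$double.eps^0.5 * pmax(abs(m), 1)
  s[zero] <- 1
  out <- cen / s
  out[zero, ] <- 0
  list(x = out, zero_variance = zero)
}

#' Global functional connectivity, fast path
#'
#' For standardized rows, each voxel's mean Pearson correlation with every
#' other voxel reduces to `r_i = ((x_i . S) / T - 1) / (V - 1)` with
#' `S = colSums(x)`: a single matrix-vector product, O(V T) instead of the
#' O(V^2 T) pairwise definition. Must agree with [gfc_bruteforce()] to
#' 1e-10.
#'
#' @param std_matrix Voxels x time matrix standardized by [standardize()].
#' @return Numeric vector of per-voxel mean correlations, in `[-1, 1]`.
#' @export
gfc_fast <- function(std_matrix) {
  std_matrix <- as.matrix(std_matrix)
  v <- nrow(std_matrix)
  if (v < 2L) stopf("need at least 2 voxels")
  nt <- ncol(std_matrix)
  S <- colSums(std_matrix)
  (as.vector(std_matrix %*% S) / nt - 1) / (v - 1)
}

#' Global functional connectivity, brute-force oracle
#'
#' The literal definition: the full pairwise Pearson correlation matrix of
#' the voxel series, then `r_i = mean over j != i of r_ij`. Quadratic in
#' the voxel count; kept as the independent oracle for [gfc_fast()].
#'
#' @param std_matrix Voxels x time matrix (any scaling; Pearson is
#'   scale-free).
#' @return Numeric vector of per-voxel mean correlations.
#' @export
gfc_bruteforce <- function(std_matrix) {
  std_matrix <- as.matrix(std_matrix)
  v <- nrow(std_matrix)
  if (v < 2L) stopf("need at least 2 voxels")
  R <- stats::cor(t(std_matrix))
  (rowSums(R) - 1) / (v - 1)
}

#' Fisher r-to-z transform
#'
#' `z = atanh(r)`, the variance-stabilizing transform of a correlation.
#' Correlations at exactly +/-1 are clipped to `1 - 1e-7` in magnitude
#' (with a warning) so the transform stays finite.
#'
#' @param r Correlation value(s), `|r| <= 1`.
#' @return Fisher z value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) {
    stopf("|r| > 1 is not a correlation")
  }
  clip <- abs(r) >= 1 - 1e-7
  if (any(clip, na.rm = TRUE)) {
    warnf("%d correlation(s) at |r| ~ 1 clipped to 1 - 1e-7 before atanh",
          sum(clip, na.rm = TRUE))
    r[which(clip)] <- sign(r[which(clip)]) * (1 - 1e-7)
  }
  atanh(r)
}

#' Subject-level GFC map
#'
#' Computes, over the kept (non-censored) time points only, each
#' gray-matter voxel's mean correlation with all other gray-matter voxels,
#' Fisher z-transforms the averaged correlations, and writes the result
#' back into volume space with `NaN` outside the mask. Voxels with zero
#' variance over the kept time points are removed from the map (with a
#' warning) and left `NaN`.
#'
#' @param x A [bold4d()] of preprocessed data, or a voxels x time matrix
#'   over the full grid.
#' @param mask A [gray_matter_mask()].
#' @param censor Optional `censor_mask` (from [scrub()]) restricting the
#'   time points used; `NULL` keeps all.
#' @param min_volumes Minimum usable time points.
#' @return Object of class `gfc_map`: `z`, `r` (per mask voxel; `NA` where
#'   dropped), `volume` (3D array of z, `NaN` off-mask), `mask`,
#'   `t_effective`, `n_voxels`.
#' @export
gfc_subject <- function(x, mask, censor = NULL, min_volumes = 50) {
  stopifnot(inherits(mask, "gray_mask"))
  mat <- if (inherits(x, "bold4d")) {
    if (!identical(dim(x$data)[1:3], as.integer(mask$dim))) {
      stopf("BOLD grid %s does not match mask grid %s",
            paste(dim(x$data)[1:3], collapse = "x"),
            paste(mask$dim, collapse = "x"))
    }
    as_vox_time(x$data)
  } else {
    as.matrix(x)
  }
  if (nrow(mat) != prod(mask$dim)) {
    stopf("series matrix has %d rows; mask grid implies %d voxels",
          nrow(mat), prod(mask$dim))
  }
  if (!is.null(censor)) {
    stopifnot(inherits(censor, "censor_mask"))
    mat <- mat[, censor$kept, drop = FALSE]
  }
  if (ncol(mat) < min_volumes) {
    stopf("only %d usable volumes (minimum %d)", ncol(mat), min_volumes)
  }
  gm <- mat[mask$idx, , drop = FALSE]
  st <- standardize(gm)
  use <- !st$zero_variance
  if (any(!use)) {
    warnf("%d zero-variance voxel(s) excluded from the GFC map", sum(!use))
  }
  if (sum(use) < 2L) stopf("fewer than 2 usable gray-matter voxels")
  rbar <- gfc_fast(st$x[use, , drop = FALSE])
  r_full <- rep(NA_real_, mask$n_voxels)
  r_full[use] <- rbar
  z_full <- rep(NA_real_, mask$n_voxels)
  z_full[use] <- fisher_z(rbar)
  vol <- array(NaN, dim = mask$dim)
  vol[mask$idx] <- z_full
  structure(list(z = z_full, r = r_full, volume = vol, mask = mask,
                 t_effective = ncol(mat), n_voxels = mask$n_voxels),
            class = "gfc_map")
}
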