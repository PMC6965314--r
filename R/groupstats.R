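#' Group-comparison design matrix
#'
#' Builds the subjects x 4 design for the covariate-adjusted voxel-wise
#' group comparison: intercept, group indicator (patient = 1, control = 0),
#' mean framewise displacement and age as covariates of no interest.
#'
#' @param group Character/factor of "patient"/"control", one per subject.
#' @param mean_fd Per-subject mean FD, mm.
#' @param age Per-subject age, years.
#' @return Matrix of class `group_design`, columns
#'   `(intercept, group, mean_fd, age)`.
#' @export
group_design <- function(group, mean_fd = NULL, age = NULL) {
  g <- as.character(group)
  if (!all(g %in% c("patient", "control"))) {
    stopf("group labels must be 'patient' or 'control'")
  }
  if (sum(g == "patient") < 2L || sum(g == "control") < 2L) {
    stopf("need at least 2 subjects per group")
  }
  X <- cbind(intercept = 1, group = as.numeric(g == "patient"))
  if (!is.null(mean_fd)) X <- cbind(X, mean_fd = as.numeric(mean_fd))
  if (!is.null(age)) X <- cbind(X, age = as.numeric(age))
  if (qr(X)$rank < ncol(X)) stopf("design matrix is rank deficient")
  structure(X, class = c("group_design", "matrix"))
}

# t statistics for the group column of X, for every column of Y (n x V).
# Precomputed pieces are reused across permutations.
glm_t_engine <- function(X) {
  XtXi <- solve(crossprod(X))
  A <- XtXi %*% t(X)
  cvar <- XtXi[2L, 2L]
  df <- nrow(X) - ncol(X)
  list(
    df = df,
    tstat = function(Y) {
      B <- A %*% Y
      R <- Y - X %*% B
      s2 <- colSums(R^2) / df
      se <- sqrt(s2 * cvar)
      tt <- B[2L, ] / se
      tt[se == 0] <- 0
      tt
    },
    fitted_nuisance = NULL)
}

#' Voxel-wise covariate-adjusted group t map
#'
#' Fits, per voxel, an ordinary least-squares model of the Fisher-z GFC
#' value on the [group_design()] and returns the t statistic of the group
#' coefficient (patient minus control, adjusted for the covariates). With
#' a 4-column design the degrees of freedom are `n - 4`. Voxels with zero
#' residual variance (identical values across subjects) get t = 0 with a
#' warning.
#'
#' @param z_maps Subjects x voxels matrix of Fisher-z GFC values.
#' @param design A [group_design()].
#' @return List: `t` (per voxel), `df`.
#' @export
voxelwise_glm_t <- function(z_maps, design) {
  Y <- as.matrix(z_maps)
  X <- unclass(design)
  if (nrow(Y) != nrow(X)) {
    stopf("%d map rows but %d design rows", nrow(Y), nrow(X))
  }
  eng <- glm_t_engine(X)
  tt <- eng$tstat(Y)
  if (any(tt == 0 & matrixStats_colsd_zero(Y))) {
    warnf("zero-variance voxel(s): t set to 0")
  }
  list(t = tt, df = eng$df)
}

# columns of Y with (numerically) zero variance across subjects
matrixStats_colsd_zero <- function(Y) {
  m <- colMeans(Y)
  v <- colMeans(Y^2) - m^2
  v <= .Machine$double.eps * pmax(m^2, 1)
}

#' Permutation-based family-wise error control (maxT, Freedman-Lane)
#'
#' Strong FWE control for the voxel-wise group comparison without
#' distributional or smoothness assumptions. Nuisance covariates are
#' handled by the Freedman-Lane scheme: the maps are regressed on the
#' covariates only, the residuals are permuted over subjects, the covariate
#' fit is added back, and the group t map is recomputed; the maximum |t|
#' over voxels of each permutation forms the null distribution. The
#' adjusted p-value of voxel i is `(1 + #{perm max >= |t_i|}) / (n_perm +
#' 1)`, which can never be exactly zero.
#'
#' @param z_maps Subjects x voxels matrix of Fisher-z GFC values.
#' @param design A [group_design()] (column 2 is the group indicator).
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed for the permutation stream.
#' @param alpha Significance level used only to warn when `n_perm` is too
#'   small to resolve it.
#' @return Object of class `stat_map_result`: `t`, `df`, `p_fwe`,
#'   `max_t_null`, `n_perm`, `seed`.
#' @export
permutation_fwe <- function(z_maps, design, n_perm = 1000, seed = 1L,
                            alpha = 0.05) {
  Y <- as.matrix(z_maps)
  X <- unclass(design)
  n <- nrow(X)
  if (nrow(Y) != n) stopf("%d map rows but %d design rows", nrow(Y), n)
  n_perm <- assert_count(n_perm, "n_perm")
  if (n_perm < 100L) stopf("'n_perm' must be >= 100")
  if (1 / (n_perm + 1) > alpha / 10) {
    warnf("n_perm = %d gives minimum p = %.4g; coarse for alpha = %g",
          n_perm, 1 / (n_perm + 1), alpha)
  }
  eng <- glm_t_engine(X)
  t_obs <- eng$tstat(Y)

  # Freedman-Lane: reduced (nuisance-only) model fit + permuted residuals
  Z <- X[, -2L, drop = FALSE]
  QZ <- qr.Q(qr(Z))
  fitted_z <- QZ %*% crossprod(QZ, Y)
  resid_z <- Y - fitted_z
  max_t_null <- numeric(n_perm)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- sample.int(n)
      Ystar <- fitted_z + resid_z[perm, , drop = FALSE]
      max_t_null[b] <- max(abs(eng$tstat(Ystar)))
    }
  })
  abs_t <- abs(t_obs)
  ord <- order(abs_t)
  # vectorized counting of #{null >= |t_i|}
  cnt <- length(max_t_null) -
    findInterval(abs_t - 1e-12, sort(max_t_null))
  p_fwe <- (1 + cnt) / (n_perm + 1)
  structure(list(t = t_obs, df = eng$df, p_fwe = p_fwe,
                 max_t_null = max_t_null, n_perm = n_perm, seed = seed),
            class = "stat_map_result")
}

neighbor_offsets <- function(connectivity) {
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  switch(as.character(connectivity),
         "6" = offs[rowSums(abs(offs)) == 1, , drop = FALSE],
         "18" = offs[rowSums(abs(offs)) <= 2, , drop = FALSE],
         "26" = offs,
         stopf("connectivity must be 6, 18 or 26"))
}

#' Extract significant clusters from a thresholded statistic map
#'
#' Groups voxels with FWE-adjusted p below `alpha` into connected
#' components, separately for positive and negative t, under the chosen
#' voxel connectivity (6 faces / 18 faces+edges / 26 full neighborhood).
#' Clusters are returned sorted by descending peak |t|, ties broken by
#' lexicographic peak coordinate; the peak of each cluster is its largest
#' |t| voxel (same tie-break).
#'
#' @param t_map Per-mask-voxel t statistics.
#' @param p_fwe Per-mask-voxel FWE-adjusted p-values.
#' @param mask A [gray_matter_mask()] giving the volume geometry.
#' @param alpha Significance threshold (strict `<`).
#' @param connectivity 6, 18 or 26.
#' @param voxel_size_mm Optional voxel size used to report peak coordinates
#'   in mm (relative to the volume origin).
#' @return List of `cluster_record`s: `peak_ijk` (1-based voxel), `peak_mm`
#'   (or NULL), `n_voxels`, `peak_t`, `sign`, `p_fwe_peak`, `idx` (linear
#'   array indices), `mask_pos` (positions within the mask vector). Empty
#'   list if nothing survives.
#' @export
extract_clusters <- function(t_map, p_fwe, mask, alpha = 0.05,
                             connectivity = 26, voxel_size_mm = NULL) {
  stopifnot(inherits(mask, "gray_mask"))
  if (length(t_map) != mask$n_voxels || length(p_fwe) != mask$n_voxels) {
    stopf("t and p vectors must have one entry per mask voxel")
  }
  sig <- which(p_fwe < alpha & !is.na(t_map))
  if (!length(sig)) return(list())
  offs <- neighbor_offsets(connectivity)
  dm <- mask$dim
  coords <- linear_to_coords(mask$idx[sig], dm)
  # label volume: position within `sig` at each significant voxel
  pos_vol <- array(0L, dim = dm)
  pos_vol[mask$idx[sig]] <- seq_along(sig)
  sgn <- sign(t_map[sig])
  visited <- logical(length(sig))
  clusters <- list()
  for (start in seq_along(sig)) {
    if (visited[start]) next
    comp <- integer(0)
    queue <- start
    visited[start] <- TRUE
    while (length(queue)) {
      cur <- queue[[1L]]
      queue <- queue[-1L]
      comp <- c(comp, cur)
      cc <- coords[cur, ]
      for (o in seq_len(nrow(offs))) {
        ni <- cc[1L] + offs[o, 1L]
        nj <- cc[2L] + offs[o, 2L]
        nk <- cc[3L] + offs[o, 3L]
        if (ni < 1L || nj < 1L || nk < 1L ||
            ni > dm[1L] || nj > dm[2L] || nk > dm[3L]) next
        p <- pos_vol[ni, nj, nk]
        if (p > 0L && !visited[p] && sgn[p] == sgn[start]) {
          visited[p] <- TRUE
          queue <- c(queue, p)
        }
      }
    }
    members <- sig[comp]
    mt <- abs(t_map[members])
    mc <- linear_to_coords(mask$idx[members], dm)
    o <- order(-mt, mc[, 1L], mc[, 2L], mc[, 3L])
    peak <- members[o[1L]]
    peak_ijk <- as.integer(linear_to_coords(mask$idx[peak], dm))
    clusters[[length(clusters) + 1L]] <- structure(list(
      peak_ijk = peak_ijk,
      peak_mm = if (!is.null(voxel_size_mm))
        (peak_ijk - 1) * voxel_size_mm else NULL,
      n_voxels = length(members),
      peak_t = t_map[peak],
      sign = as.integer(sgn[comp[1L]]),
      p_fwe_peak = p_fwe[peak],
      idx = mask$idx[members],
      mask_pos = members), class = "cluster_record")
  }
  pk <- vapply(clusters, function(cl) abs(cl$peak_t), numeric(1L))
  pc <- t(vapply(clusters, function(cl) cl$peak_ijk, integer(3L)))
  clusters[order(-pk, pc[, 1L], pc[, 2L], pc[, 3L])]
}

#' Cluster table
#'
#' Flattens a list of `cluster_record`s into a data.frame suitable for a
#' TSV report (peak voxel, optional mm coordinates, extent, peak t,
#' FWE-adjusted p at the peak).
#'
#' @param clusters List from [extract_clusters()].
#' @return data.frame with one row per cluster.
#' @export
cluster_table <- function(clusters) {
  if (!length(clusters)) {
    return(data.frame(peak_i = integer(), peak_j = integer(),
                      peak_k = integer(), n_voxels = integer(),
                      peak_t = numeric(), p_fwe = numeric()))
  }
  do.call(rbind, lapply(clusters, function(cl) {
    data.frame(peak_i = cl$peak_ijk[1L], peak_j = cl$peak_ijk[2L],
               peak_k = cl$peak_ijk[3L], n_voxels = cl$n_voxels,
               peak_t = cl$peak_t, p_fwe = cl$p_fwe_peak)
  }))
}

#' Mean cluster feature per subject
#'
#' The mean Fisher-z GFC over a cluster's voxels, one scalar per subject —
#' the feature used for clinical correlation and classification.
#'
#' @param z_maps Subjects x voxels matrix (mask space).
#' @param cluster A `cluster_record` from [extract_clusters()].
#' @return Numeric vector, one value per subject.
#' @export
cluster_mean_feature <- function(z_maps, cluster) {
  stopifnot(inherits(cluster, "cluster_record"))
  Y <- as.matrix(z_maps)
  pos <- cluster$mask_pos
  if (!length(pos)) stopf("cluster is empty")
  if (max(pos) > ncol(Y)) stopf("cluster voxels fall outside the mask")
  rowMeans(Y[, pos, drop = FALSE])
}

#' Pearson correlation with two-tailed p-value
#'
#' Sample Pearson correlation and its two-tailed p-value from the exact
#' t transform `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom.
#'
#' @param x,y Numeric vectors of equal length, `n >= 4`.
#' @return List: `r`, `p`, `n`, `df`.
#' @export
pearson_r_p <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stopf("x and y lengths differ")
  n <- length(x)
  if (n < 4L) stopf("need n >= 4")
  if (!all(is.finite(x)) || !all(is.finite(y))) stopf("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stopf("zero variance in x or y")
  }
  r <- as.numeric(stats::cor(x, y))
  df <- n - 2L
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt(df / (1 - r^2))
    2 * stats::pt(-abs(tt), df)
  }
  list(r = r, p = p, n = n, df = df)
}

#' Two-tailed p-value for a reported correlation coefficient
#'
#' The exact t transform applied to a correlation value alone — useful to
#' check a published `(r, n)` pair: `t = r * sqrt((n - 2) / (1 - r^2))`
#' referred to a Student t distribution on `n - 2` degrees of freedom.
#'
#' @param r Correlation coefficient, `|r| < 1`.
#' @param n Sample size (>= 4).
#' @return Two-tailed p-value.
#' @export
pearson_p_from_r <- function(r, n) {
  n <- assert_count(n, "n")
  if (n < 4L) stopf("need n >= 4")
  if (abs(r) >= 1) return(0)
  df <- n - 2L
  tt <- r * sqrt(df / (1 - r^2))
  2 * stats::pt(-abs(tt), df)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Family-wise level.
#' @param m Number of tests (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 1L) {
  m <- assert_count(m, "m")
  alpha / m
}

#' Two-sample t-test from summary statistics
#'
#' Pooled-variance (Student) two-sample t-test computed from group means,
#' SDs and sizes — the form needed to check demographic tables that report
#' only mean +/- SD. A Welch variant is available.
#'
#' @param m1,s1,n1 Mean, SD, size of group 1.
#' @param m2,s2,n2 Mean, SD, size of group 2.
#' @param pooled Use the pooled-variance Student test (default); otherwise
#'   Welch.
#' @return List: `t`, `df`, `p` (two-tailed).
#' @export
ttest_from_summary <- function(m1, s1, n1, m2, s2, n2, pooled = TRUE) {
  n1 <- assert_count(n1, "n1"); n2 <- assert_count(n2, "n2")
  if (n1 < 2L || n2 < 2L) stopf("need n >= 2 per group")
  if (s1 <= 0 || s2 <= 0) stopf("SDs must be positive")
  if (pooled) {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
    tt <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se2 <- s1^2 / n1 + s2^2 / n2
    tt <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  }
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df))
}

#' 2x2 chi-square test of independence
#'
#' Pearson chi-square on the table `[[a, b], [c, d]]`, without Yates
#' continuity correction by default (the convention that matches standard
#' demographic-table reporting).
#'
#' @param a,b First row counts (e.g. patients male/female).
#' @param c,d Second row counts.
#' @param continuity Apply the Yates correction.
#' @return List: `chi2`, `df` (= 1), `p`.
#' @export
chi2_2x2 <- function(a, b, c, d, continuity = FALSE) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stopf("counts must be non-negative integers")
  }
  tab <- matrix(counts, nrow = 2L, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stopf("zero margin in the 2x2 table")
  }
  ct <- stats::chisq.test(tab, correct = continuity)
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' ROI-to-ROI functional connectivity group test
#'
#' For each subject, the Pearson correlation between the mean time series
#' of two regions (e.g. primary motor cortex and supplementary motor area)
#' is Fisher z-transformed; the z values are then compared between groups
#' with a pooled two-sample t-test.
#'
#' @param series_list List of voxels x time matrices (full grid), one per
#'   subject.
#' @param mask_a,mask_b Logical arrays or linear voxel indices of the two
#'   regions.
#' @param groups "patient"/"control" label per subject.
#' @return List: `z` (per subject), `t`, `df`, `p`, `mean_patient`,
#'   `mean_control`.
#' @export
roi_fc_group_test <- function(series_list, mask_a, mask_b, groups) {
  g <- as.character(groups)
  if (length(series_list) != length(g)) {
    stopf("one group label per subject required")
  }
  if (sum(g == "patient") < 2L || sum(g == "control") < 2L) {
    stopf("need at least 2 subjects per group")
  }
  z <- vapply(series_list, function(mat) {
    sa <- tissue_mean_signal(mat, mask_a)
    sb <- tissue_mean_signal(mat, mask_b)
    if (stats::sd(sa) == 0 || stats::sd(sb) == 0) {
      stopf("degenerate (constant) region-mean series")
    }
    fisher_z(stats::cor(sa, sb))
  }, numeric(1L))
  tt <- stats::t.test(z[g == "patient"], z[g == "control"],
                      var.equal = TRUE)
  list(z = z, t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value,
       mean_patient = mean(z[g == "patient"]),
       mean_control = mean(z[g == "control"]))
}
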