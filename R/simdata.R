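#' Configuration for a synthetic resting-state cohort
#'
#' Defines the study conditions for [generate_cohort()]: a two-group cohort
#' (patients vs controls) of 4D BOLD series on a small 3D grid, with a
#' latent-signal connectivity model in which one or more compact gray-matter
#' clusters have reduced global coupling in patients, motion traces with
#' occasional framewise-displacement spikes, and a clinical severity score
#' negatively related to the planted cluster coupling.
#'
#' The defaults mirror the emulated study: 19 patients vs 21 controls,
#' 250 volumes at TR = 2 s, 3 mm isotropic voxels, and a patient severity
#' score distributed 16.32 +/- 4.45. Two radius-1 clusters are planted in
#' the gray-matter shell of a 12^3 grid.
#'
#' @param n_patients,n_controls Group sizes.
#' @param grid_shape Integer length-3: voxel counts per axis.
#' @param voxel_size_mm Isotropic voxel edge, mm.
#' @param n_volumes Number of volumes acquired (before any discarding).
#' @param tr_s Repetition time, seconds.
#' @param n_latents Number of band-limited latent signals mixed into the
#'   shared gray-matter signal.
#' @param baseline_coupling Coupling weight of gray-matter voxels onto the
#'   shared latent signal, in `[0, 1]`.
#' @param effect_delta Coupling reduction applied to cluster voxels in
#'   patients; must satisfy `baseline_coupling - effect_delta >= 0`.
#' @param cluster_specs List of cluster definitions, each
#'   `list(center = c(i, j, k), radius = r)` with radius in voxels
#'   (Euclidean ball, intersected with gray matter).
#' @param noise_sd Standard deviation of i.i.d. Gaussian voxel noise
#'   (arbitrary BOLD units).
#' @param motion_spike_rate Per-volume probability of a head-motion spike
#'   large enough to push framewise displacement above 0.2 mm.
#' @param coupling_sd Between-subject SD of the planted coupling weight;
#'   this is what gives the score-coupling correlation something to vary
#'   over.
#' @param score_slope Clinical-score units per unit coupling (negative
#'   plants a negative GFC-severity correlation).
#' @param score_noise_sd SD of the score residual.
#' @param seed Integer RNG seed; equal configs generate identical cohorts.
#' @return A validated list of class `sim_config`.
#' @seealso [generate_cohort()], [write_cohort()]
#' @export
sim_config <- function(n_patients = 19, n_controls = 21,
                       grid_shape = c(12L, 12L, 12L),
                       voxel_size_mm = 3, n_volumes = 250, tr_s = 2,
                       n_latents = 2,
                       baseline_coupling = 0.6, effect_delta = 0.4,
                       cluster_specs = list(
                         list(center = c(9L, 9L, 7L), radius = 1),
                         list(center = c(4L, 4L, 7L), radius = 1)),
                       noise_sd = 1, motion_spike_rate = 0.02,
                       coupling_sd = 0.15,
                       score_slope = -20, score_noise_sd = 3.3,
                       seed = 1L) {
  cfg <- list(
    n_patients = assert_count(n_patients, "n_patients"),
    n_controls = assert_count(n_controls, "n_controls"),
    grid_shape = vapply(seq_len(3L), function(i)
      assert_count(grid_shape[i], "grid_shape"), integer(1L)),
    voxel_size_mm = assert_positive(voxel_size_mm, "voxel_size_mm"),
    n_volumes = assert_count(n_volumes, "n_volumes"),
    tr_s = assert_positive(tr_s, "tr_s"),
    n_latents = assert_count(n_latents, "n_latents"),
    baseline_coupling = as.numeric(baseline_coupling),
    effect_delta = as.numeric(effect_delta),
    cluster_specs = cluster_specs,
    noise_sd = assert_positive(noise_sd, "noise_sd"),
    motion_spike_rate = as.numeric(motion_spike_rate),
    coupling_sd = as.numeric(coupling_sd),
    score_slope = as.numeric(score_slope),
    score_noise_sd = as.numeric(score_noise_sd),
    seed = as.integer(seed))
  if (length(grid_shape) != 3L) stopf("'grid_shape' must have length 3")
  if (cfg$baseline_coupling < 0 || cfg$baseline_coupling > 1) {
    stopf("'baseline_coupling' must lie in [0, 1]")
  }
  if (cfg$effect_delta < 0 || cfg$baseline_coupling - cfg$effect_delta < 0) {
    stopf("need 0 <= effect_delta <= baseline_coupling")
  }
  if (cfg$motion_spike_rate < 0 || cfg$motion_spike_rate > 1) {
    stopf("'motion_spike_rate' must be a probability")
  }
  if (cfg$coupling_sd < 0 || cfg$score_noise_sd < 0) {
    stopf("SDs must be non-negative")
  }
  if (!length(cfg$cluster_specs)) stopf("need at least one cluster spec")
  for (cs in cfg$cluster_specs) {
    if (is.null(cs$center) || is.null(cs$radius) || length(cs$center) != 3L) {
      stopf("each cluster spec needs $center (length 3) and $radius")
    }
    diam <- 2 * cs$radius + 1
    if (any(cfg$grid_shape < diam)) {
      stopf("degenerate grid: dimension smaller than cluster diameter %g", diam)
    }
  }
  structure(cfg, class = "sim_config")
}

#' Tissue probability maps for the simulated grid
#'
#' Partitions the grid into three disjoint geometric compartments by scaled
#' Chebyshev distance from the grid centre: a white-matter core, a
#' gray-matter shell, a cerebrospinal-fluid rim, and empty background
#' outside. Each compartment's own probability map is 0.9 inside it, 0.05 in
#' the other two compartments and 0 in background, so the conventional
#' strict thresholds (gray > 0.2, white/CSF > 0.8) recover the compartments
#' exactly.
#'
#' @param grid_shape Integer length-3 voxel counts.
#' @return List with 3D arrays `gm`, `wm`, `csf` (probabilities) and logical
#'   arrays `gm_mask`, `wm_mask`, `csf_mask`.
#' @export
tissue_probability_maps <- function(grid_shape) {
  dm <- as.integer(grid_shape)
  ax <- lapply(dm, function(n) abs(seq_len(n) - (n + 1) / 2) / ((n - 1) / 2))
  dx <- array(rep(ax[[1L]], times = dm[2L] * dm[3L]), dim = dm)
  dy <- array(rep(rep(ax[[2L]], each = dm[1L]), times = dm[3L]), dim = dm)
  dz <- array(rep(ax[[3L]], each = dm[1L] * dm[2L]), dim = dm)
  d <- pmax(dx, dy, dz)
  wm_mask <- d <= 0.3
  gm_mask <- d > 0.3 & d <= 0.65
  csf_mask <- d > 0.65 & d <= 0.85
  inside <- wm_mask | gm_mask | csf_mask
  mk <- function(own) {
    p <- array(0, dim = dm)
    p[inside] <- 0.05
    p[own] <- 0.9
    p
  }
  list(gm = mk(gm_mask), wm = mk(wm_mask), csf = mk(csf_mask),
       gm_mask = gm_mask, wm_mask = wm_mask, csf_mask = csf_mask)
}

#' Band-limited random signal
#'
#' Synthesizes a zero-mean, unit-variance signal whose spectral support lies
#' in `[low_hz, high_hz]`, by assigning unit amplitude and uniform random
#' phase to each DFT bin in the band and inverse-transforming. Because the
#' energy sits strictly inside the passband, a matched band-pass filter
#' leaves such a signal nearly untouched.
#'
#' @param n Number of time points.
#' @param tr_s Sampling interval, seconds.
#' @param low_hz,high_hz Band edges, Hz.
#' @return Numeric vector of length `n` with population SD 1.
#' @export
sim_band_limited_signal <- function(n, tr_s, low_hz = 0.01, high_hz = 0.08) {
  n <- assert_count(n, "n")
  freqs <- seq_len(floor(n / 2)) / (n * tr_s)
  band <- which(freqs >= low_hz & freqs <= high_hz)
  if (!length(band)) stopf("no DFT bin falls inside [%g, %g] Hz", low_hz, high_hz)
  spec <- complex(n)
  phases <- stats::runif(length(band), 0, 2 * pi)
  spec[band + 1L] <- exp(1i * phases)
  # conjugate symmetry for a real signal
  spec[n + 1L - band] <- Conj(spec[band + 1L])
  g <- Re(stats::fft(spec, inverse = TRUE)) / n
  g <- g - mean(g)
  g / sqrt(mean(g^2))
}

cluster_ball_voxels <- function(center, radius, gm_mask) {
  dm <- dim(gm_mask)
  rng <- function(c0, n) max(1L, floor(c0 - radius)):min(n, ceiling(c0 + radius))
  grid <- expand.grid(i = rng(center[1L], dm[1L]),
                      j = rng(center[2L], dm[2L]),
                      k = rng(center[3L], dm[3L]))
  d2 <- (grid$i - center[1L])^2 + (grid$j - center[2L])^2 +
    (grid$k - center[3L])^2
  grid <- grid[d2 <= radius^2 + 1e-9, , drop = FALSE]
  idx <- coords_to_linear(as.matrix(grid), dm)
  idx <- idx[gm_mask[idx]]
  if (!length(idx)) {
    stopf("cluster at (%s) radius %g contains no gray-matter voxel",
          paste(center, collapse = ","), radius)
  }
  sort(idx)
}

sim_motion_trace <- function(n_volumes, spike_rate) {
  trans <- vapply(1:3, function(i) cumsum(stats::rnorm(n_volumes, 0, 0.002)),
                  numeric(n_volumes))
  rot <- vapply(1:3, function(i) cumsum(stats::rnorm(n_volumes, 0, 2e-5)),
                numeric(n_volumes))
  spikes <- which(stats::runif(n_volumes) < spike_rate)
  spikes <- spikes[spikes > 1L]
  # one-volume translation offsets; |delta| = 0.36 mm at entry and exit,
  # comfortably above the 0.2 mm scrubbing threshold
  trans[spikes, ] <- trans[spikes, ] + 0.12
  m <- cbind(trans, rot)
  colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  m
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lo & draw <= hi
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Generate a synthetic two-group resting-state cohort
#'
#' Simulates per-subject 4D BOLD series under a latent-signal connectivity
#' model. Each subject's gray-matter voxels load with weight `w` onto a
#' shared band-limited (0.01-0.08 Hz) latent signal, plus i.i.d. Gaussian
#' noise, a weak linear drift, and small leakage of compartment-specific
#' white-matter and CSF signals. Cluster voxels in patients have their
#' loading reduced by `effect_delta`, which lowers their correlation with
#' the rest of gray matter and hence their global functional connectivity.
#' Patient severity scores are generated as
#' `intercept + score_slope * coupling + noise`, with the intercept chosen
#' so the expected patient score matches the configured target (16.32 under
#' defaults).
#'
#' @param config A [sim_config()].
#' @return A list of class `gfc_cohort` with elements
#'   \describe{
#'     \item{subjects}{list of `synthetic_subject`s: `id`, `group`
#'       ("patient"/"control"), `age`, `sex`, `score` (NA for controls),
#'       `bold` ([bold4d()]), `motion` (T x 6 matrix).}
#'     \item{truth}{`synthetic_truth`: cluster voxel indices, per-subject
#'       planted coupling, score slope, each subject's shared latent signal
#'       (for signal-recovery checks), tissue maps, grid geometry.}
#'   }
#' @examples
#' cfg <- sim_config(n_patients = 3, n_controls = 3, n_volumes = 40, seed = 7)
#' coh <- generate_cohort(cfg)
#' length(coh$subjects)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    dm <- config$grid_shape
    n_vox <- prod(dm)
    n_t <- config$n_volumes
    tissue <- tissue_probability_maps(dm)
    gm_idx <- which(tissue$gm_mask)
    wm_idx <- which(tissue$wm_mask)
    csf_idx <- which(tissue$csf_mask)
    cluster_idx <- lapply(config$cluster_specs, function(cs)
      cluster_ball_voxels(cs$center, cs$radius, tissue$gm_mask))
    all_cluster <- sort(unique(unlist(cluster_idx)))

    n_total <- config$n_patients + config$n_controls
    groups <- c(rep("patient", config$n_patients),
                rep("control", config$n_controls))
    ids <- c(sprintf("sub-p%02d", seq_len(config$n_patients)),
             sprintf("sub-c%02d", seq_len(config$n_controls)))
    ages <- round(rnorm_trunc(n_total, 39, 9, 18, 60), 1)
    sexes <- ifelse(stats::runif(n_total) < 0.375, "M", "F")

    base_cl <- ifelse(groups == "patient",
                      config$baseline_coupling - config$effect_delta,
                      config$baseline_coupling)
    coupling <- pmax(base_cl + stats::rnorm(n_total, 0, config$coupling_sd), 0)
    intercept <- 16.32 - config$score_slope *
      (config$baseline_coupling - config$effect_delta)
    scores <- ifelse(groups == "patient",
                     intercept + config$score_slope * coupling +
                       stats::rnorm(n_total, 0, config$score_noise_sd),
                     NA_real_)

    subjects <- vector("list", n_total)
    latents <- vector("list", n_total)
    for (s in seq_len(n_total)) {
      lat_k <- vapply(seq_len(config$n_latents), function(k)
        sim_band_limited_signal(n_t, config$tr_s), numeric(n_t))
      g <- rowSums(lat_k)
      g <- (g - mean(g)) / sqrt(mean((g - mean(g))^2))
      latents[[s]] <- g
      wm_sig <- sim_band_limited_signal(n_t, config$tr_s)
      csf_sig <- sim_band_limited_signal(n_t, config$tr_s)

      w <- numeric(n_vox)
      w[gm_idx] <- config$baseline_coupling +
        (coupling[s] - base_cl[s])  # subject-level jitter shared across GM
      w[all_cluster] <- coupling[s]
      mat <- w %o% g
      mat[wm_idx, ] <- mat[wm_idx, ] + rep(0.6 * wm_sig, each = length(wm_idx))
      mat[csf_idx, ] <- mat[csf_idx, ] +
        rep(0.6 * csf_sig, each = length(csf_idx))
      mat[gm_idx, ] <- mat[gm_idx, ] +
        rep(0.1 * wm_sig + 0.1 * csf_sig, each = length(gm_idx))
      # weak per-voxel linear drift (scanner trend)
      slope <- stats::rnorm(n_vox, 0, config$noise_sd / n_t)
      mat <- mat + slope %o% (seq_len(n_t) - (n_t + 1) / 2)
      mat <- mat + matrix(stats::rnorm(n_vox * n_t, 0, config$noise_sd),
                          n_vox, n_t)

      subjects[[s]] <- structure(list(
        id = ids[s], group = groups[s], age = ages[s], sex = sexes[s],
        score = scores[s],
        bold = bold4d(vox_time_to_4d(mat, dm), config$voxel_size_mm,
                      config$tr_s),
        motion = sim_motion_trace(n_t, config$motion_spike_rate)),
        class = "synthetic_subject")
    }

    truth <- structure(list(
      cluster_voxels = lapply(seq_along(cluster_idx), function(i) list(
        center = config$cluster_specs[[i]]$center,
        radius = config$cluster_specs[[i]]$radius,
        idx = cluster_idx[[i]],
        coords = linear_to_coords(cluster_idx[[i]], dm))),
      coupling = data.frame(id = ids, group = groups, coupling = coupling,
                            stringsAsFactors = FALSE),
      score_slope = config$score_slope,
      latents = latents,
      tissue = tissue, grid_shape = dm,
      voxel_size_mm = config$voxel_size_mm,
      config = config), class = "synthetic_truth")

    structure(list(subjects = subjects, truth = truth), class = "gfc_cohort")
  })
}

#' Write a synthetic cohort to disk in standard formats
#'
#' One gzipped NIfTI-1 BOLD file and one 6-column whitespace-delimited
#' motion text file per subject, tissue probability NIfTIs, a participants
#' TSV (`id group age sex score`) and a `truth.json` describing the planted
#' effects. The files round-trip through [read_bold()], [read_motion()] and
#' [read_participants()].
#'
#' @param cohort A `gfc_cohort` from [generate_cohort()].
#' @param out_dir Output directory; created if missing.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return Invisibly, a data.frame manifest with columns `kind`, `id`,
#'   `path`.
#' @export
write_cohort <- function(cohort, out_dir, overwrite = FALSE) {
  stopifnot(inherits(cohort, "gfc_cohort"))
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !overwrite) {
    stopf("directory '%s' exists and is non-empty; use overwrite = TRUE",
          out_dir)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  add <- function(kind, id, path) {
    manifest[[length(manifest) + 1L]] <<-
      data.frame(kind = kind, id = id, path = path, stringsAsFactors = FALSE)
  }
  for (sub in cohort$subjects) {
    bp <- file.path(out_dir, paste0(sub$id, "_bold.nii.gz"))
    write_bold(sub$bold, bp)
    add("bold", sub$id, bp)
    mp <- file.path(out_dir, paste0(sub$id, "_motion.txt"))
    write_motion(sub$motion, mp)
    add("motion", sub$id, mp)
  }
  tis <- cohort$truth$tissue
  vs <- cohort$truth$voxel_size_mm
  for (nm in c("gm", "wm", "csf")) {
    tp <- file.path(out_dir, paste0(nm, "_prob.nii.gz"))
    write_volume(tis[[nm]], tp, voxel_size_mm = vs)
    add("tissue", nm, tp)
  }
  pt <- data.frame(
    id = vapply(cohort$subjects, `[[`, "", "id"),
    group = vapply(cohort$subjects, `[[`, "", "group"),
    age = vapply(cohort$subjects, `[[`, 0, "age"),
    sex = vapply(cohort$subjects, `[[`, "", "sex"),
    score = vapply(cohort$subjects, `[[`, 0, "score"),
    stringsAsFactors = FALSE)
  pp <- file.path(out_dir, "participants.tsv")
  write_participants(pt, pp)
  add("participants", NA_character_, pp)
  truth_json <- list(
    clusters = lapply(cohort$truth$cluster_voxels, function(cl) list(
      center = cl$center, radius = cl$radius, idx = cl$idx)),
    coupling = cohort$truth$coupling,
    score_slope = cohort$truth$score_slope,
    grid_shape = cohort$truth$grid_shape,
    voxel_size_mm = cohort$truth$voxel_size_mm,
    seed = cohort$truth$config$seed)
  tj <- file.path(out_dir, "truth.json")
  jsonlite::write_json(truth_json, tj, auto_unbox = TRUE, digits = NA)
  add("truth", NA_character_, tj)
  invisible(do.call(rbind, manifest))
}
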