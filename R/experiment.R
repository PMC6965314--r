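#' Configuration for a full GFC experiment
#'
#' Bundles the stage parameters of the whole pipeline with their standard
#' defaults: discard 10 volumes, 4 mm FWHM smoothing, 0.01-0.08 Hz band,
#' gray-matter threshold 0.2, FD scrubbing at 0.2 mm, mean-FD and age as
#' covariates, voxel-level FWE at alpha = 0.05 via maxT permutation, 5-fold
#' and permutation SVM validation. Unknown keys are rejected.
#'
#' @param sim A [sim_config()] describing the cohort (used when the
#'   experiment simulates its own data).
#' @param n_discard,fwhm_mm,band,gm_threshold,fd_threshold_mm Preprocessing
#'   and masking parameters (`band` is `c(low_hz, high_hz)`).
#' @param head_radius_mm,min_volumes,max_trans_mm,max_rot_deg Motion QC
#'   parameters.
#' @param alpha,n_perm,connectivity Group-inference parameters.
#' @param k,n_perm_svm Classifier validation parameters.
#' @param seed Global seed for permutation streams and fold assignment.
#' @return List of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       n_discard = 10, fwhm_mm = 4, band = c(0.01, 0.08),
                       gm_threshold = 0.2, fd_threshold_mm = 0.2,
                       head_radius_mm = 50, min_volumes = 50,
                       max_trans_mm = 2, max_rot_deg = 2,
                       alpha = 0.05, n_perm = 500, connectivity = 26,
                       k = 5, n_perm_svm = 1000, seed = 1L) {
  stopifnot(inherits(sim, "sim_config"))
  if (length(band) != 2L || band[1L] >= band[2L]) {
    stopf("'band' must be c(low_hz, high_hz) with low < high")
  }
  structure(list(
    sim = sim, n_discard = as.integer(n_discard),
    fwhm_mm = as.numeric(fwhm_mm), band = as.numeric(band),
    gm_threshold = as.numeric(gm_threshold),
    fd_threshold_mm = as.numeric(fd_threshold_mm),
    head_radius_mm = as.numeric(head_radius_mm),
    min_volumes = as.integer(min_volumes),
    max_trans_mm = as.numeric(max_trans_mm),
    max_rot_deg = as.numeric(max_rot_deg),
    alpha = as.numeric(alpha), n_perm = as.integer(n_perm),
    connectivity = as.integer(connectivity),
    k = as.integer(k), n_perm_svm = as.integer(n_perm_svm),
    seed = as.integer(seed)), class = "run_config")
}

#' Serialize / deserialize a run configuration
#'
#' Lossless JSON round-trip of a [run_config()]; unknown keys in the file
#' are rejected.
#'
#' @param config A `run_config`.
#' @param path JSON file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known_sim <- names(formals(sim_config))
  known_run <- setdiff(names(formals(run_config)), "sim")
  if (length(bad <- setdiff(names(x), c(known_run, "sim")))) {
    stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
  }
  if (length(bad <- setdiff(names(x$sim), known_sim))) {
    stopf("unknown sim config key(s): %s", paste(bad, collapse = ", "))
  }
  sim <- x$sim
  # jsonlite simplifies the cluster list; rebuild it explicitly
  cs <- sim$cluster_specs
  if (is.data.frame(cs)) {
    sim$cluster_specs <- lapply(seq_len(nrow(cs)), function(i)
      list(center = unlist(cs$center[i]), radius = cs$radius[i]))
  } else if (is.list(cs)) {
    sim$cluster_specs <- lapply(cs, function(e)
      list(center = unlist(e$center), radius = e$radius))
  }
  x$sim <- do.call(sim_config, sim)
  do.call(run_config, x)
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  write_run_config(config, tf)
  unname(tools::md5sum(tf))
}

#' Run the full GFC experiment on a synthetic cohort
#'
#' Executes the whole chain: cohort simulation, per-subject preprocessing
#' (with the gross-motion exclusion rule applied before group statistics),
#' subject-level GFC maps on the shared gray-matter mask, covariate-adjusted
#' voxel-wise group comparison with permutation (maxT) FWE control, cluster
#' extraction, per-cluster feature extraction with clinical-score Pearson
#' correlation (Bonferroni threshold over clusters), and SVM classification
#' of patients vs controls from each cluster feature (leave-one-out, k-fold
#' and label-permutation validation).
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, stat maps (NIfTI),
#'   the cluster table (TSV), per-cluster feature/score scatter data (TSV),
#'   the participants table and a JSON report with seeds and the config
#'   hash are written there.
#' @param cohort Optional pre-generated `gfc_cohort` (defaults to
#'   `generate_cohort(config$sim)`).
#' @param preprocess `"full"` runs the whole preprocessing chain.
#'   `"light"` computes framewise displacement, applies the gross-motion
#'   rule and scrubbing, and feeds the otherwise untouched series to the
#'   GFC stage — the variant used for large replicate simulation studies,
#'   where the generated latent signals are already band-limited and there
#'   is no nuisance structure to remove.
#' @param classify Run the SVM stage for each significant cluster (the
#'   most expensive stage; disable for replicate simulations that only
#'   need detection and correlation).
#' @return List of class `gfc_experiment` with elements `participants`,
#'   `mask`, `z_maps`, `stat` (`stat_map_result`), `clusters`,
#'   `cluster_results` (per cluster: feature vector, group means, Pearson
#'   r/p vs score, classifier reports), `bonferroni_alpha`, `config_hash`,
#'   `truth`.
#' @export
run_experiment <- function(config = run_config(), out_dir = NULL,
                           cohort = NULL, preprocess = c("full", "light"),
                           classify = TRUE) {
  stopifnot(inherits(config, "run_config"))
  preprocess <- match.arg(preprocess)
  cohort <- cohort %||% generate_cohort(config$sim)
  truth <- cohort$truth
  tissue <- truth$tissue
  wm_seed <- tissue$wm > 0.8
  csf_seed <- tissue$csf > 0.8

  pre <- lapply(cohort$subjects, function(sub) {
    if (preprocess == "full") {
      preprocess_subject(sub$bold, sub$motion, wm_seed, csf_seed,
                         n_discard = config$n_discard,
                         fwhm_mm = config$fwhm_mm,
                         low_hz = config$band[1L], high_hz = config$band[2L],
                         fd_threshold_mm = config$fd_threshold_mm,
                         head_radius_mm = config$head_radius_mm,
                         min_volumes = config$min_volumes,
                         max_trans_mm = config$max_trans_mm,
                         max_rot_deg = config$max_rot_deg)
    } else {
      preprocess_light(sub$bold, sub$motion,
                       fd_threshold_mm = config$fd_threshold_mm,
                       head_radius_mm = config$head_radius_mm,
                       min_volumes = config$min_volumes,
                       max_trans_mm = config$max_trans_mm,
                       max_rot_deg = config$max_rot_deg)
    }
  })
  participants <- data.frame(
    id = vapply(cohort$subjects, `[[`, "", "id"),
    group = vapply(cohort$subjects, `[[`, "", "group"),
    age = vapply(cohort$subjects, `[[`, 0, "age"),
    sex = vapply(cohort$subjects, `[[`, "", "sex"),
    score = vapply(cohort$subjects, `[[`, 0, "score"),
    mean_fd = vapply(pre, function(p) p$fd$mean_fd, 0),
    n_censored = vapply(pre, function(p) p$n_censored, 0L),
    excluded = vapply(pre, function(p) p$excluded || p$flagged, NA),
    stringsAsFactors = FALSE)

  keep <- !participants$excluded
  if (sum(participants$group[keep] == "patient") < 2L ||
      sum(participants$group[keep] == "control") < 2L) {
    stopf("group stats: fewer than 2 usable subjects in a group after QC")
  }

  mask <- gray_matter_mask(tissue$gm, config$gm_threshold)
  maps <- lapply(which(keep), function(i) {
    gfc_subject(vox_time_to_4d(pre[[i]]$ts, pre[[i]]$dim) |>
                  bold4d(truth$voxel_size_mm, pre[[i]]$tr_s),
                mask, censor = NULL, min_volumes = config$min_volumes)
  })
  z_maps <- do.call(rbind, lapply(maps, `[[`, "z"))
  # voxels dropped (zero variance) in any subject are excluded listwise
  ok_vox <- colSums(is.na(z_maps)) == 0L
  z_use <- z_maps[, ok_vox, drop = FALSE]
  mask_use <- mask
  mask_use$idx <- mask$idx[ok_vox]
  mask_use$n_voxels <- sum(ok_vox)
  mask_use$mask <- array(FALSE, dim = mask$dim)
  mask_use$mask[mask_use$idx] <- TRUE

  kept_pt <- participants[keep, ]
  design <- group_design(kept_pt$group, kept_pt$mean_fd, kept_pt$age)
  stat <- permutation_fwe(z_use, design, n_perm = config$n_perm,
                          seed = config$seed, alpha = config$alpha)
  clusters <- extract_clusters(stat$t, stat$p_fwe, mask_use,
                               alpha = config$alpha,
                               connectivity = config$connectivity,
                               voxel_size_mm = truth$voxel_size_mm)
  bonf <- if (length(clusters)) {
    bonferroni_threshold(config$alpha, length(clusters))
  } else config$alpha

  cluster_results <- lapply(clusters, function(cl) {
    feat <- cluster_mean_feature(z_use, cl)
    is_pat <- kept_pt$group == "patient"
    corr <- if (sum(is_pat & is.finite(kept_pt$score)) >= 4L) {
      pearson_r_p(feat[is_pat], kept_pt$score[is_pat])
    } else NULL
    out <- list(feature = feat,
                mean_patient = mean(feat[is_pat]),
                mean_control = mean(feat[!is_pat]),
                correlation = corr)
    if (classify) {
      ft <- feature_table(matrix(feat, ncol = 1L), kept_pt$group, kept_pt$id)
      out$loo <- svm_loo(ft)
      out$kfold <- svm_kfold(ft, k = config$k, seed = config$seed)
      out$permutation <- svm_permutation_test(ft, n_perm = config$n_perm_svm,
                                              seed = config$seed)
    }
    out
  })

  result <- structure(list(
    participants = participants, mask = mask_use, z_maps = z_use,
    stat = stat, clusters = clusters, cluster_results = cluster_results,
    bonferroni_alpha = bonf, config = config,
    config_hash = config_hash(config), truth = truth),
    class = "gfc_experiment")

  if (!is.null(out_dir)) write_experiment(result, out_dir)
  result
}

write_experiment <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mask <- result$mask
  vs <- result$truth$voxel_size_mm
  tvol <- array(NaN, dim = mask$dim); tvol[mask$idx] <- result$stat$t
  pvol <- array(NaN, dim = mask$dim); pvol[mask$idx] <- result$stat$p_fwe
  write_volume(tvol, file.path(out_dir, "group_tmap.nii.gz"), vs)
  write_volume(pvol, file.path(out_dir, "group_fwe_p.nii.gz"), vs)
  write_volume(mask$mask + 0, file.path(out_dir, "gm_mask.nii.gz"), vs)
  utils::write.table(cluster_table(result$clusters),
                     file.path(out_dir, "clusters.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_participants(result$participants,
                     file.path(out_dir, "participants.tsv"))
  keep <- !result$participants$excluded
  for (i in seq_along(result$cluster_results)) {
    cr <- result$cluster_results[[i]]
    scatter <- data.frame(id = result$participants$id[keep],
                          group = result$participants$group[keep],
                          feature = cr$feature,
                          score = result$participants$score[keep])
    utils::write.table(scatter,
                       file.path(out_dir,
                                 sprintf("cluster%02d_feature.tsv", i)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  report <- list(
    config_hash = result$config_hash,
    seed = result$config$seed,
    n_perm = result$stat$n_perm,
    alpha = result$config$alpha,
    bonferroni_alpha = result$bonferroni_alpha,
    df = result$stat$df,
    n_clusters = length(result$clusters),
    clusters = lapply(seq_along(result$cluster_results), function(i) {
      cl <- result$clusters[[i]]; cr <- result$cluster_results[[i]]
      list(peak_ijk = cl$peak_ijk, n_voxels = cl$n_voxels,
           peak_t = cl$peak_t, p_fwe = cl$p_fwe_peak,
           mean_patient = cr$mean_patient, mean_control = cr$mean_control,
           corr_r = cr$correlation$r %||% NA,
           corr_p = cr$correlation$p %||% NA,
           loo_accuracy = cr$loo$accuracy %||% NA,
           loo_sensitivity = cr$loo$sensitivity %||% NA,
           loo_specificity = cr$loo$specificity %||% NA,
           kfold_accuracy = cr$kfold$accuracy %||% NA,
           permutation_p = cr$permutation$p %||% NA)
    }))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(out_dir)
}

#' @export
print.gfc_experiment <- function(x, ...) {
  cat(sprintf("<gfc_experiment> %d subjects (%d excluded), %d mask voxels\n",
              nrow(x$participants), sum(x$participants$excluded),
              x$mask$n_voxels))
  cat(sprintf("  %d significant cluster(s) at FWE alpha = %g, %d perms\n",
              length(x$clusters), x$config$alpha, x$stat$n_perm))
  for (i in seq_along(x$cluster_results)) {
    cl <- x$clusters[[i]]; cr <- x$cluster_results[[i]]
    cat(sprintf(
      "  cluster %d: peak (%s), %d voxels, t=%.2f, LOO acc %.1f%%%s\n",
      i, paste(cl$peak_ijk, collapse = ","), cl$n_voxels, cl$peak_t,
      cr$loo$accuracy %||% NA,
      if (!is.null(cr$correlation))
        sprintf(", score r=%.3f (p=%.3f)", cr$correlation$r,
                cr$correlation$p) else ""))
  }
  invisible(x)
}
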