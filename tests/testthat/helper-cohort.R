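# Small cohort configurations reused across test files. Sizes are kept
# deliberately small; the full-size study conditions are exercised in the
# acceptance suite.

small_sim <- function(seed = 1L, ...) {
  args <- list(n_patients = 4, n_controls = 4, n_volumes = 80, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# light-path GFC maps for a cohort: FD + scrubbing + GFC on the shared
# gray-matter mask; returns subjects x voxels z matrix plus metadata
light_gfc <- function(cohort, min_volumes = 50) {
  mask <- gray_matter_mask(cohort$truth$tissue$gm, 0.2)
  pre <- lapply(cohort$subjects, function(s) preprocess_light(s$bold, s$motion,
                                                             min_volumes = min_volumes))
  z <- do.call(rbind, lapply(pre, function(p)
    gfc_subject(p$ts, mask, min_volumes = min_volumes)$z))
  list(z = z, mask = mask,
       group = vapply(cohort$subjects, `[[`, "", "group"),
       mean_fd = vapply(pre, function(p) p$fd$mean_fd, 0),
       age = vapply(cohort$subjects, `[[`, 0, "age"),
       score = vapply(cohort$subjects, `[[`, 0, "score"))
}

config_hash_test <- gfconn:::config_hash

# 1-based (i,j,k) -> linear index, independent of the package's own helper
coords_to_linear_test <- function(coords, dm) {
  coords <- matrix(as.integer(coords), ncol = 3L)
  (coords[, 3L] - 1L) * dm[1L] * dm[2L] +
    (coords[, 2L] - 1L) * dm[1L] + coords[, 1L]
}

# all-included gray mask on a small grid, for constructed map tests
dense_mask <- function(dm) {
  gray_matter_mask(array(0.9, dim = dm), 0.2)
}
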