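# gfconn

Voxel-wise **global-brain functional connectivity (GFC)** analysis for
resting-state fMRI, as an R package with a built-in synthetic-cohort
generator so the entire chain is testable without scanner data.

GFC asks, for every gray-matter voxel, how strongly its BOLD time series
correlates on average with *every other* gray-matter voxel — a seed-free
alternative to region-of-interest connectivity. For voxel *i* with
standardized series *xᵢ(t)* among *V* gray-matter voxels,

```
GFC_i = (1 / (V - 1)) * Σ_{j ≠ i} r_ij,      z_i = atanh(GFC_i)
```

The package implements the full analysis used in case–control studies of
this statistic (the motivating application is reduced motor-network GFC in
cervical dystonia patients versus healthy controls):

* **Preprocessing** (`preprocess_subject`): initial-volume discard, 4 mm
  FWHM Gaussian smoothing, linear detrending, zero-phase 0.01–0.08 Hz
  band-pass, Friston-24 + white-matter + CSF nuisance regression (global
  signal deliberately kept), framewise-displacement scrubbing at 0.2 mm,
  and the 2 mm / 2° gross-motion exclusion rule.
* **GFC metric** (`gfc_subject`, `gfc_fast`, `gfc_bruteforce`,
  `fisher_z`): an O(VT) fast path held to 1e-10 agreement with the literal
  O(V²T) pairwise definition, which is kept as an oracle.
* **Group inference** (`voxelwise_glm_t`, `permutation_fwe`,
  `extract_clusters`): per-voxel OLS with mean-FD and age covariates,
  family-wise error control by maxT permutation with Freedman–Lane
  covariate handling, signed connected-component cluster reporting.
* **Clinical correlation** (`cluster_mean_feature`, `pearson_r_p`,
  `bonferroni_threshold`) and demographic-table utilities
  (`ttest_from_summary`, `chi2_2x2`, `pearson_p_from_r`).
* **Classification** (`svm_loo`, `svm_kfold`, `svm_permutation_test`,
  `region_features`): RBF-kernel SVM (via e1071) with hand-rolled
  leave-one-out, stratified k-fold and label-permutation validation.
* **Simulation** (`sim_config`, `generate_cohort`, `write_cohort`): seeded
  cohorts — 19 patients / 21 controls, 250 volumes at TR 2 s by default —
  with band-limited latent signals, planted low-coupling clusters, motion
  spikes and a severity score negatively tied to cluster coupling.
* **IO** (`read_bold`, `read_motion`, `read_participants`,
  `run_experiment`): NIfTI-1 volumes (via RNifti), 6-column motion text
  files, TSV tables, JSON reports with config hashes and seeds.

## Worked example

Simulate a cohort at the default study conditions, run the whole chain,
and inspect the result:

```r
library(gfconn)

cfg <- run_config(sim = sim_config(seed = 1),
                  n_perm = 500, n_perm_svm = 1000, seed = 1)
res <- run_experiment(cfg)
print(res)
#> <gfc_experiment> 40 subjects (0 excluded), 448 mask voxels
#>   2 significant cluster(s) at FWE alpha = 0.05, 500 perms
#>   cluster 1: peak (9,9,7), 4 voxels, t=-4.60, LOO acc 72.5%, score r=-0.689 (p=0.001)
#>   cluster 2: peak (4,4,7), 5 voxels, t=-4.54, LOO acc 70.0%, score r=-0.696 (p=0.001)
```

Reading this output: both planted low-coupling clusters (centred at voxels
(9,9,7) and (4,4,7)) were detected at family-wise-corrected p < 0.05 with
negative group t — patients' GFC is lower; the per-subject cluster-mean
Fisher-z feature correlates negatively with the simulated severity score
in patients (r = −0.689, below the Bonferroni-corrected threshold
0.05/2 = 0.025); and the same feature separates patients from controls at
72.5% leave-one-out accuracy (permutation p = 0.003). Passing
`out_dir = "..."` additionally writes the t and FWE-p maps as NIfTI, the
cluster table and feature/score scatter data as TSV, and a JSON report.

Demographic-table checks work straight from published summaries:

```r
ttest_from_summary(38.74, 10.71, 19, 39.62, 6.62, 21)$p  # 0.7538
chi2_2x2(9, 10, 6, 15)$p                                 # 0.2201
pearson_p_from_r(-0.476, 19)                             # 0.0394
```

## Scope

The package consumes volumes that are already motion-corrected and
spatially aligned across subjects, plus their motion-parameter files.
Slice-timing correction, realignment estimation, nonlinear normalization,
random-field-theory FWE, cluster-level inference and anatomical labeling
are out of scope. See `vignettes/gfc-methods.Rmd` for the model,
assumptions, design decisions and known limitations.
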