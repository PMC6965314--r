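---
title: "Global-brain functional connectivity: model, inference and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global-brain functional connectivity: model, inference and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gfconn)
```

## The statistic

Resting-state fMRI measures a BOLD time series at every voxel. Seed-based
functional connectivity requires choosing a region of interest in advance;
global-brain functional connectivity (GFC) avoids that choice. For each
gray-matter voxel $i$ with standardized series $x_i(t)$, the statistic is
the average Pearson correlation with every other gray-matter voxel:

$$\mathrm{GFC}_i \;=\; \frac{1}{V-1}\sum_{j \ne i} r_{ij},$$

followed by the Fisher transform $z_i = \operatorname{atanh}(\mathrm{GFC}_i)$
for variance stabilization. A voxel whose intrinsic coupling to the brain's
shared fluctuations is reduced — the situation hypothesized for motor-network
regions in cervical dystonia — shows a lower $z_i$ than its neighbors and
than the corresponding voxel in healthy controls.

Computed naively, the statistic costs $O(V^2 T)$. Because
$\sum_{j} r_{ij} = x_i \cdot S / T$ with $S = \sum_j x_j$ for
population-standardized rows, `gfc_fast()` computes every voxel's mean
correlation in a single matrix–vector product, $O(VT)$. The literal pairwise
definition is retained as `gfc_bruteforce()` and the two are held to
agreement within $10^{-10}$ in the test suite; this oracle pairing is the
package's primary numerical safeguard. The Fisher transform is applied to
the *averaged* correlation (the averaged-then-transformed ordering); the
transform-then-average alternative is monotonically related, so group
inference directions are unaffected, but absolute values would differ.

The gray-matter domain is defined by a tissue probability map thresholded
strictly above 0.2, shared by all subjects.

## Preprocessing chain

`preprocess_subject()` applies, in fixed order: initial-volume discard
(default 10 volumes, scanner steady state), isotropic Gaussian smoothing
(4 mm FWHM, reflective boundaries, intensity-conserving), per-voxel linear
detrending, zero-phase band-pass filtering (0.01–0.08 Hz), nuisance
regression, and motion scrubbing. Decisions worth making explicit:

* **Band-pass filter.** Frequency-domain masking with raised-cosine
  transition bands 0.002 Hz wide. The contract is behavioral, not
  named-filter fidelity: passband amplitude preserved within 5%, stopband
  (at twice the upper edge and beyond) attenuated by at least 95%, and no
  phase shift (the gain is real and symmetric).
* **Detrend before filter.** The two steps are listed together in most
  pipeline descriptions without a defined order; detrending first avoids
  leaking the trend's broadband spectrum through the filter's transition
  bands.
* **Nuisance design.** The Friston-24 motion expansion
  $[p(t), p(t{-}1), p(t)^2, p(t{-}1)^2]$ (first lagged row zeroed so the
  time dimension is preserved) plus mean white-matter and CSF signals
  extracted from the filtered data, behind an intercept. The global (whole
  brain) mean signal is deliberately *not* removed. All-zero regressors
  (e.g. a motionless axis) are dropped; genuinely collinear regressors
  raise an error naming the offending columns. Residuals are checked to be
  orthogonal to every design column within $10^{-8}$.
* **Framewise displacement.** The displacement-sum formula
  $FD_t = \sum|\Delta d| + r\sum|\Delta \theta|$ with rotations converted
  to arc length on an $r = 50$ mm sphere; the first frame is defined 0.
  Scrubbing censors frames with $FD > 0.2$ mm (strict inequality; a frame
  at exactly the threshold is kept), after nuisance regression, so censored
  frames are excluded from correlation rather than interpolated. Subjects
  with fewer than 50 surviving volumes are flagged.
* **Gross-motion exclusion.** A subject whose translation exceeds 2 mm or
  rotation exceeds 2° in any direction at any time is excluded before group
  statistics; the rule is strict, so a subject exactly at the limit stays.

## Group inference

The subject-level $z$ maps enter a per-voxel ordinary least-squares model
with an intercept, the patient/control indicator, and mean FD and age as
covariates of no interest; the group coefficient's $t$ statistic has
$n - 4$ degrees of freedom. Family-wise error across voxels is controlled
by the **maxT permutation** method with **Freedman–Lane** covariate
handling: the maps are regressed on the covariates only, the residuals are
permuted across subjects, the covariate fit is re-added, and the maximum
$|t|$ over voxels of each of the $B$ permutations forms the null
distribution; the adjusted p-value of voxel $i$ is
$(1 + \#\{\max_b \ge |t_i|\})/(B + 1)$, which can never be exactly zero.
This is a deliberate substitution for the random-field-theory correction
used in SPM-based analyses: it is assumption-light (no smoothness
estimate, no Gaussianity), exact under exchangeability, and testable at
desk scale. Its calibration — the probability that *any* voxel of a null
map survives at $\alpha = 0.05$ — is verified on 200 replicate null
cohorts in the acceptance suite.

Suprathreshold voxels are grouped into connected components separately per
sign of $t$, under 26-connectivity by default (6 and 18 are available);
clusters are ordered by descending peak $|t|$ with lexicographic
coordinate tie-breaks, so reports are deterministic. Each cluster yields a
per-subject mean-$z$ feature used for (i) a Pearson correlation with the
clinical severity score in patients, with a Bonferroni threshold
$\alpha/m$ over the $m$ clusters, and (ii) patient/control classification.
FWE is exposed at the voxel level with cluster extent reported
descriptively; cluster-level inference (cluster-mass, TFCE) is out of
scope.

Two auxiliary testing utilities mirror what demographic tables allow a
reader to recompute: a pooled two-sample $t$ test from means, SDs and
group sizes, and a 2×2 Pearson chi-square without continuity correction
(the convention that reproduces standard table p-values; the Yates-corrected
variant is available via an argument).

## Classification

`svm_loo()`, `svm_kfold()` and `svm_permutation_test()` validate a
soft-margin support-vector classifier with a Gaussian (RBF) kernel, using
the common defaults $C = 1$ and $\gamma = 1/d$. The kernel machine itself
is delegated to e1071 (libsvm); all validation logic — leave-one-out
rotation, stratified $k$-fold with a dealt round-robin assignment (so
$k = n$ degenerates exactly to leave-one-out), label permutation — is
implemented here and never delegated. Patients are the positive class:
sensitivity is computed on patients, specificity on controls. With more
than one feature, features are z-scored with training-fold statistics
only, to avoid leakage; a single feature is used unscaled. The $k$-fold
scheme is a full rotation (every fold is the test set once) even though
single-split readings of "the fifth subgroup was taken as a test set"
exist; rotation is the standard estimator. Both plain and class-balanced
accuracy are reported for the $k$-fold scheme, since "balanced accuracy"
is ambiguous in some reports. `region_features()` additionally extracts
per-region mean-$z$ features from any integer-labeled atlas volume
(intersected with the gray-matter mask) for multi-region classification;
only a synthetic atlas is exercised in the tests — anatomical labeling
against real templates is out of scope.

## The synthetic cohort generator

No scanner data ships with the package; `generate_cohort()` produces
cohorts with known ground truth, and every downstream claim in the test
suite is a recovery or calibration statement about those conditions.

The model: each subject has a shared latent signal $g(t)$, synthesized in
the frequency domain (unit amplitude, random phase on the 0.01–0.08 Hz
bins) so that it is exactly band-limited and the band-pass stage is tested
independently of signal generation. Gray-matter voxel $i$ observes
$w_i\,g(t) + \varepsilon_{it}$ with i.i.d. Gaussian noise, a weak linear
drift, and a small (0.1) admixture of the white-matter and CSF compartment
signals; white matter and CSF are disjoint geometric compartments (core,
shell, rim, by scaled Chebyshev distance from the grid centre) with their
own latent signals, so the nuisance regression stage has genuine
structure to remove. $w_i$ equals the baseline coupling (0.6) everywhere
except the planted clusters, where patients' loading is reduced by
`effect_delta` (default 0.4). Motion traces are slow random walks with
Bernoulli spikes (rate 0.02/volume) of 0.36 mm framewise displacement,
above the 0.2 mm scrubbing threshold.

Defaults mirror the emulated study conditions: 19 patients vs 21
controls, 250 volumes at TR = 2 s, 3 mm voxels, ages drawn from
$N(39, 9^2)$ truncated to [18, 60] for both groups, and two radius-1
clusters (7 voxels each) in the gray-matter shell of a $12^3$ grid. The
pipeline itself is grid-size agnostic; the small grid is a deliberate
choice that makes replicate calibration studies (hundreds of cohorts)
tractable on one CPU.

The clinical score is
$\text{score} = a + b\,w + \eta$, patients only, with slope
$b = -20$ per coupling unit, between-subject coupling SD 0.15 and residual
SD 3.3, and $a$ chosen so the expected patient score is 16.32. Two
constraints fixed these numbers at design time: the patient score
distribution should match the emulated table (mean 16.32, SD
$\sqrt{(b \cdot 0.15)^2 + 3.3^2} \approx 4.45$), and the coupling-level
correlation ($\rho \approx -0.67$) must be strong enough that its
attenuated image in the measured cluster-mean GFC feature still has a
stable negative sign in samples of 19 patients — the property the
acceptance suite checks across 50 replicate cohorts. The between-subject
coupling SD is a necessary ingredient: with identical coupling in every
subject the score–coupling correlation would be undefined.

What the generator does *not* emulate: hemodynamic response convolution,
cardiac/respiratory physiological noise, spatial autocorrelation of the
noise field, scanner drift beyond a linear trend, multi-site effects, and
any anatomical realism. Passing tests therefore demonstrate that the
pipeline recovers effects of the planted kind under these idealized
conditions — they are evidence of implementation correctness, not of
performance on real scanner data.

## Numerical choices and degenerate inputs

* Standardization is population-style (divide by $\sqrt{T}$-normalized
  SD), so the dot product of two standardized rows over $T$ *is* the
  Pearson correlation, exactly.
* Zero-variance voxel series cannot be standardized; they are flagged,
  excluded from the mask with a warning, and left `NaN` in volume outputs.
  `NaN` is the off-mask sentinel throughout.
* Correlations at $|r| = 1$ are clipped to $1 - 10^{-7}$ (with a warning)
  before the Fisher transform.
* Voxels with zero residual variance in the group model get $t = 0$ with a
  warning rather than 0/0.
* Permutation p-values use the $(1 + \#)/(B + 1)$ estimator; a warning is
  emitted when $1/(B+1)$ is coarse relative to the requested $\alpha$.
* Equal seeds reproduce everything — cohorts, permutation streams, fold
  assignments — bit-identically, and the generator restores the caller's
  RNG state.

## Problem sizes used in the shipped studies

The test and acceptance suites run, among smaller unit fixtures: the
fast-vs-bruteforce oracle on 100 random instances (up to 100 voxels × 200
time points); family-wise error calibration on 200 null cohorts (20
subjects, $12^3$ grid, 500 permutations); planted-effect recovery on 50
replicate cohorts at full study size (19/21 subjects, 250 volumes);
classifier chance-level behavior over 200 label-randomized replicates; and
an end-to-end experiment on a 24-subject cohort through the full
preprocessing chain. Replicate loops use the light preparation path
(framewise displacement, exclusion rule and scrubbing, without smoothing
and filtering), which isolates the inference stages; the full chain is
exercised end-to-end separately. `scripts/acceptance.R` re-runs the
experiment at study size with full preprocessing and reports the computed
quantities as JSON.

## Known limitations

Voxel-level FWE only (no cluster-level inference); no anatomical
labeling; no slice-timing correction, realignment estimation or spatial
normalization — the package consumes volumes that are already aligned
across subjects, with their motion-parameter files; normality is not
formally gated before the parametric tests (the permutation path does not
need it); and the synthetic-atlas classification results say nothing
about the discriminative power of real anatomical parcellations.
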