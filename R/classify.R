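#' Feature table for classification
#'
#' Subjects x features matrix of GFC-derived scalars plus class labels.
#' "patient" is the positive class: sensitivity is computed on patients,
#' specificity on controls.
#'
#' @param features Numeric matrix (or vector for a single feature),
#'   subjects in rows.
#' @param labels "patient"/"control" per subject.
#' @param ids Optional subject identifiers.
#' @return Object of class `feature_table`.
#' @export
feature_table <- function(features, labels, ids = NULL) {
  x <- as.matrix(features)
  if (is.null(colnames(x))) {
    colnames(x) <- paste0("feature_", seq_len(ncol(x)))
  }
  lab <- as.character(labels)
  if (!all(lab %in% c("patient", "control"))) {
    stopf("labels must be 'patient' or 'control'")
  }
  if (length(lab) != nrow(x)) stopf("one label per subject required")
  if (any(!is.finite(x))) stopf("features must be finite (no missing values)")
  if (length(unique(lab)) < 2L) stopf("labels must cover both classes")
  structure(list(
    x = x,
    labels = factor(lab, levels = c("control", "patient")),
    ids = ids %||% sprintf("s%03d", seq_len(nrow(x)))),
    class = "feature_table")
}

# accuracy / sensitivity / specificity (percent) from pooled predictions
confusion_report <- function(pred, truth) {
  pred <- as.character(pred); truth <- as.character(truth)
  tp <- sum(pred == "patient" & truth == "patient")
  tn <- sum(pred == "control" & truth == "control")
  fp <- sum(pred == "patient" & truth == "control")
  fn <- sum(pred == "control" & truth == "patient")
  list(accuracy = 100 * (tp + tn) / length(truth),
       sensitivity = 100 * tp / (tp + fn),
       specificity = 100 * tn / (tn + fp),
       balanced_accuracy = 50 * (tp / (tp + fn) + tn / (tn + fp)))
}

fit_predict_svm <- function(x_train, y_train, x_test, cost, gamma, scale_feats) {
  if (nlevels(droplevels(y_train)) < 2L) {
    stopf("single-class training fold; cannot fit the classifier")
  }
  if (scale_feats) {
    mu <- colMeans(x_train)
    sd_ <- apply(x_train, 2L, stats::sd)
    sd_[sd_ == 0] <- 1
    x_train <- sweep(sweep(x_train, 2L, mu), 2L, sd_, "/")
    x_test <- sweep(sweep(x_test, 2L, mu), 2L, sd_, "/")
  }
  fit <- e1071::svm(x_train, y_train, kernel = "radial",
                    gamma = gamma, cost = cost, scale = FALSE)
  predict(fit, x_test)
}

svm_cv_predictions <- function(ft, folds, cost, gamma) {
  scale_feats <- ncol(ft$x) > 1L  # train-fold statistics only, no leakage
  pred <- factor(rep(NA_character_, nrow(ft$x)),
                 levels = levels(ft$labels))
  for (f in sort(unique(folds))) {
    test <- folds == f
    pred[test] <- fit_predict_svm(ft$x[!test, , drop = FALSE],
                                  ft$labels[!test],
                                  ft$x[test, , drop = FALSE],
                                  cost, gamma, scale_feats)
  }
  pred
}

#' Leave-one-out SVM classification
#'
#' Soft-margin support-vector classification with a Gaussian (RBF) kernel,
#' validated leave-one-out: n rounds, each training on n - 1 subjects and
#' predicting the held-out one. Defaults follow the common convention:
#' `cost = 1`, `gamma = 1 / n_features`. When there is more than one
#' feature, features are z-scored using training-fold statistics only.
#'
#' @param ft A [feature_table()].
#' @param cost Soft-margin penalty C.
#' @param gamma RBF kernel width; default `1 / n_features`.
#' @return Object of class `classifier_report`: `scheme` ("loo"),
#'   `accuracy`, `sensitivity`, `specificity`, `balanced_accuracy` (all
#'   percent), `predictions`, `labels`.
#' @export
svm_loo <- function(ft, cost = 1, gamma = NULL) {
  stopifnot(inherits(ft, "feature_table"))
  n <- nrow(ft$x)
  if (n < 4L) stopf("need at least 4 subjects")
  if (min(table(ft$labels)) < 2L) stopf("need at least 2 subjects per class")
  gamma <- gamma %||% (1 / ncol(ft$x))
  pred <- svm_cv_predictions(ft, seq_len(n), cost, gamma)
  rep_ <- confusion_report(pred, ft$labels)
  structure(c(list(scheme = "loo", predictions = pred, labels = ft$labels,
                   cost = cost, gamma = gamma), rep_),
            class = "classifier_report")
}

#' Stratified k-fold SVM cross-validation
#'
#' Full rotation over k folds (each fold is the test set exactly once),
#' stratified so both classes appear in every training set whenever the
#' class sizes allow. Global accuracy is pooled over all held-out
#' predictions.
#'
#' @param ft A [feature_table()].
#' @param k Number of folds.
#' @param stratified Stratify folds by class.
#' @param seed Integer seed controlling the random fold assignment.
#' @param cost,gamma As in [svm_loo()].
#' @return `classifier_report` with `scheme = "kfold"`, plus `k`, `folds`,
#'   `seed`.
#' @export
svm_kfold <- function(ft, k = 5, stratified = TRUE, seed = 1L,
                      cost = 1, gamma = NULL) {
  stopifnot(inherits(ft, "feature_table"))
  n <- nrow(ft$x)
  k <- assert_count(k, "k")
  if (k > n) stopf("k = %d exceeds the %d subjects", k, n)
  gamma <- gamma %||% (1 / ncol(ft$x))
  folds <- integer(n)
  with_seed(seed, {
    if (stratified) {
      # shuffle within class, then deal fold ids round-robin across the
      # concatenated classes: folds stay class-balanced and k = n reduces
      # to leave-one-out
      ord <- unlist(lapply(levels(ft$labels), function(cl) {
        ii <- which(ft$labels == cl)
        ii[sample.int(length(ii))]
      }))
      folds[ord] <- rep_len(seq_len(k), n)
    } else {
      folds <- sample(rep_len(seq_len(k), n))
    }
  })
  pred <- svm_cv_predictions(ft, folds, cost, gamma)
  rep_ <- confusion_report(pred, ft$labels)
  structure(c(list(scheme = "kfold", predictions = pred, labels = ft$labels,
                   k = k, folds = folds, seed = seed,
                   cost = cost, gamma = gamma), rep_),
            class = "classifier_report")
}

#' Permutation test of classifier performance
#'
#' Re-runs the full leave-one-out validation on `n_perm` label
#' permutations and compares the observed LOO accuracy against the null
#' accuracies: `p = (1 + #{null >= observed}) / (n_perm + 1)`.
#'
#' @param ft A [feature_table()].
#' @param n_perm Number of label permutations (>= 100).
#' @param seed Integer seed.
#' @param cost,gamma As in [svm_loo()].
#' @return List of class `svm_permutation_result`: `observed_accuracy`
#'   (percent), `p`, `null_accuracies`, `n_perm`, `seed`.
#' @export
svm_permutation_test <- function(ft, n_perm = 10000, seed = 1L,
                                 cost = 1, gamma = NULL) {
  stopifnot(inherits(ft, "feature_table"))
  n_perm <- assert_count(n_perm, "n_perm")
  if (n_perm < 100L) stopf("'n_perm' must be >= 100")
  obs <- svm_loo(ft, cost = cost, gamma = gamma)$accuracy
  null_acc <- numeric(n_perm)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      ft_b <- ft
      ft_b$labels <- ft$labels[sample.int(length(ft$labels))]
      null_acc[b] <- svm_loo(ft_b, cost = cost, gamma = gamma)$accuracy
    }
  })
  structure(list(observed_accuracy = obs,
                 p = (1 + sum(null_acc >= obs)) / (n_perm + 1),
                 null_accuracies = null_acc, n_perm = n_perm, seed = seed),
            class = "svm_permutation_result")
}

#' Atlas region-mean GFC features
#'
#' One feature column per atlas label: the mean Fisher-z GFC over that
#' label's voxels intersected with the gray-matter mask. Labels whose
#' intersection with the mask is empty are dropped with a warning.
#'
#' @param z_maps Subjects x voxels matrix in mask space.
#' @param mask The [gray_matter_mask()] the maps were computed on.
#' @param atlas Integer-labeled 3D array on the same grid (0 = background).
#' @param labels "patient"/"control" per subject.
#' @param ids Optional subject ids.
#' @return A [feature_table()] with columns `region_<label>`.
#' @export
region_features <- function(z_maps, mask, atlas, labels, ids = NULL) {
  stopifnot(inherits(mask, "gray_mask"))
  if (!identical(dim(atlas), as.integer(mask$dim)) &&
      !identical(dim(atlas), mask$dim)) {
    stopf("atlas grid does not match the mask grid")
  }
  Y <- as.matrix(z_maps)
  if (ncol(Y) != mask$n_voxels) {
    stopf("maps have %d columns; mask has %d voxels", ncol(Y), mask$n_voxels)
  }
  atlas_on_mask <- as.integer(atlas[mask$idx])
  labs <- sort(unique(atlas_on_mask[atlas_on_mask > 0L]))
  all_labs <- sort(unique(as.integer(atlas[atlas > 0L])))
  if (!length(all_labs)) stopf("atlas has no nonzero label")
  dropped <- setdiff(all_labs, labs)
  if (length(dropped)) {
    warnf("atlas label(s) %s have no gray-matter voxel; column(s) dropped",
          paste(dropped, collapse = ", "))
  }
  feat <- vapply(labs, function(l) {
    rowMeans(Y[, atlas_on_mask == l, drop = FALSE])
  }, numeric(nrow(Y)))
  feat <- matrix(feat, nrow = nrow(Y),
                 dimnames = list(NULL, paste0("region_", labs)))
  feature_table(feat, labels, ids)
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(
    "<classifier_report> scheme=%s  accuracy=%.2f%%  sens=%.2f%%  spec=%.2f%%\n",
    x$scheme, x$accuracy, x$sensitivity, x$specificity))
  invisible(x)
}
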