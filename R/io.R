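#' Read a 4D BOLD NIfTI file
#'
#' Voxel size and TR are taken from the NIfTI `pixdim` header field. A
#' missing or non-positive TR falls back to `tr_fallback` with a warning.
#' Plain `.nii` and gzipped `.nii.gz` are both accepted.
#'
#' @param path Path to a NIfTI-1 file.
#' @param tr_fallback TR (s) to use when the header lacks one.
#' @return A [bold4d()].
#' @export
read_bold <- function(path, tr_fallback = NULL) {
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) != 4L) {
    stopf("'%s' is %dD; a 4D BOLD volume is required", path, length(dm))
  }
  pd <- RNifti::pixdim(img)
  tr <- if (length(pd) >= 4L) pd[4L] else NA_real_
  if (!is.finite(tr) || tr <= 0) {
    if (is.null(tr_fallback)) {
      stopf("'%s' has no TR in its header and no fallback was given", path)
    }
    warnf("'%s' has no TR in its header; using fallback %g s",
          path, tr_fallback)
    tr <- tr_fallback
  }
  bold4d(array(as.numeric(img), dim = dm), voxel_size_mm = pd[1:3],
         tr_s = tr)
}

#' Write a 4D BOLD series as NIfTI
#'
#' @param bold A [bold4d()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
write_bold <- function(bold, path) {
  stopifnot(inherits(bold, "bold4d"))
  img <- RNifti::asNifti(bold$data)
  RNifti::pixdim(img) <- c(bold$voxel_size_mm, bold$tr_s)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a 3D volume (mask, probability map, statistic map) as NIfTI
#'
#' @param vol 3D array.
#' @param path Output path.
#' @param voxel_size_mm Voxel size, mm.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(vol, path, voxel_size_mm = 3) {
  if (length(dim(vol)) != 3L) stopf("'vol' must be a 3D array")
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- rep(voxel_size_mm, length.out = 3L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3D volume from NIfTI
#'
#' @param path NIfTI file path.
#' @return 3D numeric array with attribute `voxel_size_mm`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) != 3L) stopf("'%s' is not a 3D volume", path)
  out <- array(as.numeric(img), dim = dm)
  attr(out, "voxel_size_mm") <- RNifti::pixdim(img)[1:3]
  out
}

#' Read a rigid-body motion parameter file
#'
#' Whitespace-delimited text, one row per volume, at least 6 columns; the
#' first six are taken as tx, ty, tz (mm) and rx, ry, rz. Rotations are in
#' radians by default; `rotation_unit = "degrees"` converts them.
#'
#' @param path Text file path.
#' @param n_volumes If given, the expected row count; a mismatch is an
#'   error naming both counts.
#' @param rotation_unit "radians" (default) or "degrees".
#' @return T x 6 numeric matrix (rotations in radians).
#' @export
read_motion <- function(path, n_volumes = NULL,
                        rotation_unit = c("radians", "degrees")) {
  rotation_unit <- match.arg(rotation_unit)
  tab <- utils::read.table(path, header = FALSE)
  if (ncol(tab) < 6L) {
    stopf("'%s' has %d column(s); at least 6 required", path, ncol(tab))
  }
  m <- as.matrix(tab[, 1:6])
  if (!is.numeric(m) || any(!is.finite(m))) {
    stopf("'%s' contains non-numeric motion values", path)
  }
  if (!is.null(n_volumes) && nrow(m) != n_volumes) {
    stopf("motion file '%s' has %d rows but the BOLD series has %d volumes",
          path, nrow(m), n_volumes)
  }
  if (rotation_unit == "degrees") m[, 4:6] <- m[, 4:6] * pi / 180
  colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  m
}

#' Write a motion parameter file
#'
#' @param motion T x 6 matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_motion <- function(motion, path) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stopf("motion must have 6 columns")
  utils::write.table(format(motion, digits = 10, scientific = TRUE,
                            trim = TRUE),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read / write the participants table
#'
#' TSV with header `id group age sex score`; `score` may be NA for
#' controls. Ids must be unique and groups must be "patient"/"control".
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_participants <- function(path) {
  pt <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "group", "age", "sex", "score")
  if (!all(need %in% names(pt))) {
    stopf("participants table must have columns: %s",
          paste(need, collapse = ", "))
  }
  if (anyDuplicated(pt$id)) stopf("duplicate subject ids")
  if (!all(pt$group %in% c("patient", "control"))) {
    stopf("group must be 'patient' or 'control'")
  }
  pt
}

#' @rdname read_participants
#' @param pt data.frame with the participant columns.
#' @export
write_participants <- function(pt, path) {
  utils::write.table(pt, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing the cohort files.
#' @return List: `subjects` (each with `id`, `group`, `age`, `sex`,
#'   `score`, `bold`, `motion`), `tissue` (gm/wm/csf probability arrays),
#'   `truth` (parsed truth.json, or NULL if absent).
#' @export
read_cohort <- function(dir) {
  pt <- read_participants(file.path(dir, "participants.tsv"))
  subjects <- lapply(seq_len(nrow(pt)), function(i) {
    id <- pt$id[i]
    bold <- read_bold(file.path(dir, paste0(id, "_bold.nii.gz")))
    motion <- read_motion(file.path(dir, paste0(id, "_motion.txt")),
                          n_volumes = n_volumes(bold))
    list(id = id, group = pt$group[i], age = pt$age[i], sex = pt$sex[i],
         score = pt$score[i], bold = bold, motion = motion)
  })
  tissue <- lapply(c(gm = "gm", wm = "wm", csf = "csf"), function(nm)
    read_volume(file.path(dir, paste0(nm, "_prob.nii.gz"))))
  tf <- file.path(dir, "truth.json")
  truth <- if (file.exists(tf)) jsonlite::read_json(tf, simplifyVector = TRUE)
    else NULL
  list(subjects = subjects, tissue = tissue, truth = truth)
}
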