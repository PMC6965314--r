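#' A 4D BOLD time series
#'
#' Container for a subject's blood-oxygen-level-dependent (BOLD) volume
#' series: a 4D array indexed (x, y, z, t) together with its voxel size in
#' millimetres and repetition time (TR) in seconds.
#'
#' @param data Numeric 4D array, dimensions (x, y, z, t).
#' @param voxel_size_mm Voxel edge length(s) in mm; a scalar (isotropic) or
#'   length-3 vector.
#' @param tr_s Repetition time between volumes, in seconds.
#' @return An object of class `bold4d`.
#' @examples
#' b <- bold4d(array(rnorm(2 * 2 * 2 * 5), c(2, 2, 2, 5)), 3, 2)
#' n_volumes(b)
#' @export
bold4d <- function(data, voxel_size_mm = 3, tr_s = 2) {
  if (!is.array(data) || length(dim(data)) != 4L) {
    stopf("'data' must be a 4D array (x, y, z, t)")
  }
  if (dim(data)[4L] < 1L) stopf("t-dimension must be >= 1")
  if (!all(is.finite(data))) stopf("BOLD data must be finite")
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0)) {
    stopf("'voxel_size_mm' must be a positive scalar or length-3 vector")
  }
  tr_s <- assert_positive(tr_s, "tr_s")
  structure(list(data = data, voxel_size_mm = voxel_size_mm, tr_s = tr_s),
            class = "bold4d")
}

#' @rdname bold4d
#' @param x A `bold4d` object.
#' @export
n_volumes <- function(x) {
  stopifnot(inherits(x, "bold4d"))
  dim(x$data)[4L]
}

#' @export
print.bold4d <- function(x, ...) {
  dm <- dim(x$data)
  cat(sprintf("<bold4d> %d x %d x %d voxels, %d volumes, voxel %s mm, TR %g s\n",
              dm[1L], dm[2L], dm[3L], dm[4L],
              paste(format(x$voxel_size_mm), collapse = "x"), x$tr_s))
  invisible(x)
}
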