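# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed), kind = "Mersenne-Twister",
             normal.kind = "Inversion", sample.kind = "Rejection")
  }
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_count <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 1 || x != round(x)) {
    stopf("'%s' must be a single positive integer (got %s)", name,
          paste(format(x), collapse = ","))
  }
  as.integer(x)
}

assert_positive <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x <= 0) {
    stopf("'%s' must be a single positive number", name)
  }
  as.numeric(x)
}

# linear index <-> (i,j,k) for a 3D grid, 1-based
coords_to_linear <- function(coords, dm) {
  coords <- matrix(as.integer(coords), ncol = 3L)
  (coords[, 3L] - 1L) * dm[1L] * dm[2L] + (coords[, 2L] - 1L) * dm[1L] +
    coords[, 1L]
}

linear_to_coords <- function(idx, dm) {
  idx0 <- as.integer(idx) - 1L
  k <- idx0 %/% (dm[1L] * dm[2L])
  r <- idx0 %% (dm[1L] * dm[2L])
  j <- r %/% dm[1L]
  i <- r %% dm[1L]
  cbind(i + 1L, j + 1L, k + 1L)
}

# flatten a 4D (x,y,z,t) array into a voxels x time matrix
as_vox_time <- function(arr4d) {
  dm <- dim(arr4d)
  matrix(arr4d, nrow = prod(dm[1:3]), ncol = dm[4L])
}

vox_time_to_4d <- function(mat, dm3) {
  array(mat, dim = c(dm3, ncol(mat)))
}
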