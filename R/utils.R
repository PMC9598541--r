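# Internal helpers shared across modules.

# Signal a classed error so callers (and tests) can distinguish failure modes.
abort_cst <- function(class, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "cstflow_error", "error", "condition")))
}

#' Compare two affine matrices
#'
#' Two volumes are considered to share a grid when their 4x4 affines agree
#' elementwise within `tol`. All inter-volume operations in the package work
#' in voxel space after this check; nothing is resampled silently.
#'
#' @param a,b 4x4 numeric affine matrices (voxel -> world, RAS+).
#' @param tol absolute elementwise tolerance.
#' @return `TRUE` or `FALSE`.
#' @keywords internal
affines_equal <- function(a, b, tol = 1e-4) {
  is.matrix(a) && is.matrix(b) &&
    all(dim(a) == c(4L, 4L)) && all(dim(b) == c(4L, 4L)) &&
    all(abs(a - b) < tol)
}

check_same_grid <- function(x_img, x_aff, y_img, y_aff, what = "volumes") {
  if (!identical(dim(x_img), dim(y_img))) {
    abort_cst("cst_geometry_error",
              sprintf("%s have different grid shapes (%s vs %s)", what,
                      paste(dim(x_img), collapse = "x"),
                      paste(dim(y_img), collapse = "x")))
  }
  if (!affines_equal(x_aff, y_aff)) {
    abort_cst("cst_geometry_error",
              sprintf("%s have different affines (tolerance 1e-4)", what))
  }
  invisible(TRUE)
}

# World x-coordinate of every voxel (RAS+: x < 0 is left).
voxel_world_x <- function(dims, affine) {
  i <- rep.int(seq_len(dims[1]) - 1L, times = dims[2] * dims[3])
  j <- rep.int(rep(seq_len(dims[2]) - 1L, each = dims[1]), times = dims[3])
  k <- rep(seq_len(dims[3]) - 1L, each = dims[1] * dims[2])
  affine[1, 1] * i + affine[1, 2] * j + affine[1, 3] * k + affine[1, 4]
}

key_label <- function(structure, subdivision, hemisphere) {
  paste(hemisphere, subdivision, structure, sep = " ")
}
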