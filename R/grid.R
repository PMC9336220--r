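#' Define a 3D image grid
#'
#' An `image_grid` ties a voxel lattice to world (MNI RAS) millimetre
#' coordinates through a 4x4 affine. Voxel indices are 0-based throughout the
#' package; `vox_to_mm()` and `mm_to_vox()` convert between the two frames.
#'
#' @param shape Integer vector of length 3, voxels per axis.
#' @param voxel_size Numeric vector of length 3, voxel edge lengths in mm.
#'   Recycled from length 1.
#' @param affine Optional 4x4 matrix mapping 0-based voxel indices to mm. When
#'   omitted, the grid is centred on MNI (0, 0, 0) with axes aligned to RAS.
#' @return An object of class `image_grid` with fields `shape`, `voxel_size`
#'   and `affine`.
#' @examples
#' g <- image_grid(c(24, 28, 24), 3)
#' vox_to_mm(g, c(0, 0, 0))
#' @export
image_grid <- function(shape, voxel_size, affine = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(!is.finite(shape)) || any(shape < 1L)) {
    stop("bad shape: need 3 positive integers", call. = FALSE)
  }
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0)) {
    stop("bad voxel_size: need 3 positive reals", call. = FALSE)
  }
  if (is.null(affine)) {
    affine <- diag(4)
    diag(affine)[1:3] <- voxel_size
    affine[1:3, 4] <- -voxel_size * (shape - 1L) / 2
  }
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)) || abs(det(affine)) < 1e-12) {
    stop("affine must be an invertible 4x4 matrix", call. = FALSE)
  }
  colnorm <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (max(abs(colnorm - voxel_size)) > 1e-6) {
    stop("voxel_size inconsistent with affine column norms", call. = FALSE)
  }
  structure(
    list(shape = shape, voxel_size = voxel_size, affine = affine),
    class = "image_grid"
  )
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf(
    "<image_grid> %s voxels @ %s mm\n",
    paste(x$shape, collapse = "x"),
    paste(format(x$voxel_size, trim = TRUE), collapse = "x")
  ))
  invisible(x)
}

#' Convert between voxel indices and mm coordinates
#'
#' @param grid An [image_grid()].
#' @param ijk Matrix (or length-3 vector) of 0-based voxel indices, one row
#'   per point.
#' @param xyz Matrix (or length-3 vector) of mm coordinates, one row per point.
#' @return A numeric matrix with one row per input point.
#' @export
vox_to_mm <- function(grid, ijk) {
  ijk <- rbind_points(ijk)
  t(grid$affine %*% rbind(t(ijk), 1))[, 1:3, drop = FALSE]
}

#' @rdname vox_to_mm
#' @export
mm_to_vox <- function(grid, xyz) {
  xyz <- rbind_points(xyz)
  t(solve(grid$affine) %*% rbind(t(xyz), 1))[, 1:3, drop = FALSE]
}

rbind_points <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3, byrow = TRUE)
  storage.mode(p) <- "double"
  p
}

grids_equal <- function(a, b, tol = 1e-4) {
  identical(a$shape, b$shape) && max(abs(a$affine - b$affine)) <= tol
}

#' mm coordinates of every voxel centre
#'
#' @inheritParams vox_to_mm
#' @return A `prod(shape)` x 3 matrix in the array's column-major voxel order.
#' @keywords internal
grid_coords_mm <- function(grid) {
  ijk <- as.matrix(expand.grid(
    i = 0:(grid$shape[1] - 1L),
    j = 0:(grid$shape[2] - 1L),
    k = 0:(grid$shape[3] - 1L)
  ))
  vox_to_mm(grid, ijk)
}
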