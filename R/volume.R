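#' Volume and mask containers
#'
#' A `gmv_volume` is a 3D numeric array carrying its [image_grid()]; a
#' `gmv_mask` is the logical counterpart. Both are thin wrappers: the array is
#' the object, the grid rides along as an attribute, so all base array
#' arithmetic keeps working.
#'
#' @param values Numeric 3D array matching `grid$shape`.
#' @param grid An [image_grid()].
#' @return A `gmv_volume` (numeric array) or `gmv_mask` (logical array).
#' @export
gmv_volume <- function(values, grid) {
  values <- as.array(values)
  if (!identical(dim(values), as.integer(grid$shape))) {
    stop("value array shape must equal grid shape", call. = FALSE)
  }
  if (!all(is.finite(values))) stop("volume values must be finite", call. = FALSE)
  structure(values, grid = grid, class = c("gmv_volume", "array"))
}

#' @param included Logical 3D array matching `grid$shape`.
#' @rdname gmv_volume
#' @export
gmv_mask <- function(included, grid) {
  included <- as.array(included)
  storage.mode(included) <- "logical"
  if (!identical(dim(included), as.integer(grid$shape))) {
    stop("mask shape must equal grid shape", call. = FALSE)
  }
  if (!any(included)) stop("empty mask", call. = FALSE)
  structure(included, grid = grid, class = c("gmv_mask", "array"))
}

vol_grid <- function(x) attr(x, "grid", exact = TRUE)

#' @export
print.gmv_volume <- function(x, ...) {
  g <- vol_grid(x)
  cat(sprintf(
    "<gmv_volume> %s voxels, range [%.4g, %.4g]\n",
    paste(g$shape, collapse = "x"), min(x), max(x)
  ))
  invisible(x)
}

#' @export
print.gmv_mask <- function(x, ...) {
  g <- vol_grid(x)
  cat(sprintf(
    "<gmv_mask> %s voxels, %d included\n",
    paste(g$shape, collapse = "x"), sum(x)
  ))
  invisible(x)
}

#' Spherical region of interest
#'
#' Marks every voxel whose centre lies within `radius_mm` of `center_mm`
#' (Euclidean distance in world mm).
#'
#' @param grid An [image_grid()].
#' @param center_mm Length-3 mm coordinate.
#' @param radius_mm Sphere radius in mm, > 0.
#' @return A `gmv_mask`.
#' @export
sphere_mask <- function(grid, center_mm, radius_mm) {
  stopifnot(radius_mm > 0)
  xyz <- grid_coords_mm(grid)
  d2 <- (xyz[, 1] - center_mm[1])^2 + (xyz[, 2] - center_mm[2])^2 +
    (xyz[, 3] - center_mm[3])^2
  inc <- array(d2 <= radius_mm^2, dim = grid$shape)
  if (!any(inc)) stop("sphere contains no voxel centres", call. = FALSE)
  gmv_mask(inc, grid)
}

#' Flatten a dataset to a subjects-by-voxels matrix
#'
#' Extracts the in-mask voxels of every subject into a dense matrix whose
#' columns follow the fixed column-major (x fastest) voxel order. The returned
#' object keeps the mask and the linear voxel indices so results can be mapped
#' back onto the grid with [unflatten()].
#'
#' @param dataset A [gmv_dataset()].
#' @param mask A `gmv_mask` on the dataset's grid.
#' @return A `masked_data` object: the n x V matrix with attributes
#'   `voxel_index` (1-based linear indices into the 3D array), `mask`, and
#'   `records` (the dataset's covariate tibble).
#' @export
flatten_masked <- function(dataset, mask) {
  stopifnot(inherits(dataset, "gmv_dataset"), inherits(mask, "gmv_mask"))
  if (!grids_equal(dataset$grid, vol_grid(mask))) {
    stop("mask grid does not match dataset grid", call. = FALSE)
  }
  idx <- which(mask)
  if (length(idx) == 0L) stop("empty mask", call. = FALSE)
  n <- nrow(dataset$records)
  nvox <- prod(dataset$grid$shape)
  m <- matrix(dataset$data, nrow = nvox)[idx, , drop = FALSE]
  structure(
    t(m),
    voxel_index = idx, mask = mask, records = dataset$records,
    class = c("masked_data", "matrix", "array")
  )
}

#' Row-subset a masked data matrix, keeping its mask metadata
#'
#' @param data A `masked_data` from [flatten_masked()].
#' @param rows Row (subject) indices.
#' @return A `masked_data` over the selected rows.
#' @export
masked_rows <- function(data, rows) {
  recs <- attr(data, "records", exact = TRUE)
  structure(
    unclass(data)[rows, , drop = FALSE],
    voxel_index = attr(data, "voxel_index", exact = TRUE),
    mask = attr(data, "mask", exact = TRUE),
    records = if (!is.null(recs)) recs[rows, , drop = FALSE] else NULL,
    class = class(data)
  )
}

#' Map an in-mask vector back to a volume
#'
#' Inverse of the column extraction done by [flatten_masked()]: in-mask voxels
#' receive `values` in the same fixed order, all other voxels receive `fill`.
#'
#' @param values Numeric vector, one value per in-mask voxel.
#' @param mask A `gmv_mask`.
#' @param fill Value for out-of-mask voxels (default 0).
#' @return A `gmv_volume`.
#' @export
unflatten <- function(values, mask, fill = 0) {
  stopifnot(inherits(mask, "gmv_mask"))
  idx <- which(mask)
  if (length(values) != length(idx)) {
    stop("cardinality: value vector length must equal in-mask voxel count",
      call. = FALSE
    )
  }
  g <- vol_grid(mask)
  out <- array(fill, dim = g$shape)
  out[idx] <- values
  gmv_volume(out, g)
}
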