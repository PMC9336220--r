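#' Gaussian smoothing of a volume
#'
#' Separable Gaussian convolution with sigma = fwhm / (2 * sqrt(2 * log(2)))
#' per axis in mm, converted to voxel units by the grid's voxel size. The
#' convolution is zero-padded: the kernel is normalised to unit mass, so the
#' volume sum is conserved away from the boundary while mass leaks off the
#' edges of the grid. `fwhm = 0` is the identity.
#'
#' @param v A [gmv_volume()] (or plain 3D array if `grid` is given).
#' @param fwhm Full width at half maximum in mm; scalar or one value per axis.
#' @param grid Grid to use when `v` is a bare array.
#' @return A `gmv_volume` of the same shape.
#' @export
smooth_volume <- function(v, fwhm, grid = NULL) {
  if (is.null(grid)) grid <- vol_grid(v)
  if (length(fwhm) == 1L) fwhm <- rep(fwhm, 3L)
  if (any(fwhm < 0)) stop("bad fwhm: must be >= 0", call. = FALSE)
  arr <- array(as.numeric(v), dim = grid$shape)
  arr <- smooth_array(arr, fwhm / grid$voxel_size)
  gmv_volume(arr, grid)
}

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

# fwhm_vox: per-axis FWHM in voxel units; zero-padded separable convolution
smooth_array <- function(arr, fwhm_vox) {
  d <- dim(arr)
  ks <- lapply(seq_len(3L), function(a) {
    smooth_kernel_matrix(d[a], fwhm_vox[a] * FWHM_TO_SIGMA)
  })
  if (!is.null(ks[[1]])) {
    arr <- array(ks[[1]] %*% matrix(arr, d[1], d[2] * d[3]), d)
  }
  if (!is.null(ks[[2]])) {
    tmp <- aperm(arr, c(2L, 1L, 3L))
    tmp <- array(ks[[2]] %*% matrix(tmp, d[2], d[1] * d[3]), c(d[2], d[1], d[3]))
    arr <- aperm(tmp, c(2L, 1L, 3L))
  }
  if (!is.null(ks[[3]])) {
    arr <- array(matrix(arr, d[1] * d[2], d[3]) %*% t(ks[[3]]), d)
  }
  arr
}

# Banded convolution matrix for one axis; NULL means identity (sigma ~ 0).
# Kernel truncated at 4 sigma and normalised to unit sum BEFORE boundary
# truncation, which is what makes the convolution "zero-padded".
smooth_kernel_matrix <- function(n, sigma_vox) {
  if (sigma_vox < 1e-8) return(NULL)
  r <- max(1L, ceiling(4 * sigma_vox))
  off <- (-r):r
  w <- exp(-off^2 / (2 * sigma_vox^2))
  w <- w / sum(w)
  k <- matrix(0, n, n)
  for (m in seq_along(off)) {
    j <- seq_len(n) + off[m]
    ok <- j >= 1L & j <= n
    k[cbind(which(ok), j[ok])] <- k[cbind(which(ok), j[ok])] + w[m]
  }
  k
}
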