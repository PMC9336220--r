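#' Estimate map smoothness from residual images
#'
#' Residuals are standardised voxelwise (each voxel's residual vector across
#' images is scaled to unit sum of squares), then for every axis the
#' variance of the spatial first difference between in-mask neighbours is
#' compared with the field variance. Under a Gaussian autocorrelation
#' `rho(h) = exp(-h^2 / (4 sigma^2))` the per-axis ratio
#' `v = E[(dZ)^2] / E[Z^2] = 2 (1 - rho(h))` inverts exactly to
#' `sigma^2 = -h^2 / (4 log(1 - v/2))`; the per-image ratios are averaged
#' before inversion. FWHM is floored at half a voxel (a floor event is
#' messaged) to keep resel counts finite on near-white residuals.
#'
#' @param residuals n x V matrix of residual images over the in-mask voxels
#'   (fixed [flatten_masked()] order), n >= 3.
#' @param mask The analysis `gmv_mask`.
#' @param grid The [image_grid()] (defaults to the mask's grid).
#' @param df Error degrees of freedom behind the residuals (recorded).
#' @return A `smoothness_estimate`: `fwhm` (mm per axis), `resels`, `df`,
#'   `floored` (per-axis flag).
#' @export
estimate_smoothness <- function(residuals, mask, grid = NULL, df = NA_real_) {
  if (is.null(grid)) grid <- vol_grid(mask)
  residuals <- unclass(residuals)
  attributes(residuals) <- list(dim = dim(residuals))
  n <- nrow(residuals)
  if (n < 3L) stop("need >= 3 residual images", call. = FALSE)
  idx <- which(mask)
  if (ncol(residuals) != length(idx)) {
    stop("cardinality: one residual column per in-mask voxel", call. = FALSE)
  }
  ss <- colSums(residuals^2)
  if (any(ss <= 0)) stop("degenerate residuals: zero-variance voxel", call. = FALSE)
  u <- residuals / rep(sqrt(ss), each = n)

  shape <- grid$shape
  strides <- c(1L, shape[1], shape[1] * shape[2])
  coords <- arrayInd(idx, shape)
  inmask_pos <- integer(prod(shape))
  inmask_pos[idx] <- seq_along(idx)

  fwhm <- numeric(3)
  floored <- logical(3)
  for (a in 1:3) {
    ok <- coords[, a] < shape[a]
    nb <- inmask_pos[idx[ok] + strides[a]]
    has <- nb > 0L
    v1 <- which(ok)[has]
    v2 <- nb[has]
    if (length(v1) < 2L) {
      fwhm[a] <- 0.5 * grid$voxel_size[a]
      floored[a] <- TRUE
      next
    }
    d <- u[, v2, drop = FALSE] - u[, v1, drop = FALSE]
    num_i <- rowMeans(d^2)
    den_i <- rowMeans(u^2)
    ratio <- mean(num_i / den_i)
    rho <- 1 - ratio / 2
    h <- grid$voxel_size[a]
    est <- if (rho <= 0 || rho >= 1) 0 else {
      2 * sqrt(2 * log(2)) * sqrt(-h^2 / (4 * log(rho)))
    }
    floor_a <- 0.5 * h
    if (est < floor_a) {
      fwhm[a] <- floor_a
      floored[a] <- TRUE
    } else {
      fwhm[a] <- est
    }
  }
  if (any(floored)) {
    message(
      "smoothness floored at half a voxel on axis ",
      paste(which(floored), collapse = ",")
    )
  }
  structure(
    list(
      fwhm = fwhm,
      resels = length(idx) * prod(grid$voxel_size) / prod(fwhm),
      df = df, floored = floored
    ),
    class = "smoothness_estimate"
  )
}

#' @export
print.smoothness_estimate <- function(x, ...) {
  cat(sprintf(
    "<smoothness_estimate> FWHM [%s] mm, %.1f resels\n",
    paste(sprintf("%.2f", x$fwhm), collapse = ", "), x$resels
  ))
  invisible(x)
}

#' Statistic cutoff for a tail probability
#'
#' @param p Tail probability in (0, 1).
#' @param sidedness `"one"` (per sign branch) or `"two"`.
#' @param kind `"z"` (standard normal) or `"t"`.
#' @param df Degrees of freedom, required for `kind = "t"`.
#' @return The positive cutoff: a statistic exceeds significance when it is
#'   above the cutoff (positive branch) or below its negative (negative
#'   branch).
#' @export
p_to_threshold <- function(p, sidedness = c("one", "two"),
                           kind = c("z", "t"), df = NULL) {
  sidedness <- match.arg(sidedness)
  kind <- match.arg(kind)
  if (!is.finite(p) || p <= 0 || p >= 1) stop("bad p: need 0 < p < 1", call. = FALSE)
  pp <- if (sidedness == "two") p / 2 else p
  if (kind == "z") {
    stats::qnorm(1 - pp)
  } else {
    if (is.null(df) || df <= 0) stop("t threshold needs df > 0", call. = FALSE)
    stats::qt(1 - pp, df)
  }
}

# 3D Euler-characteristic density of a unit Gaussian field at threshold u,
# per resel (FWHM units)
ec_density_3d <- function(u) {
  (4 * log(2))^(3 / 2) * (2 * pi)^(-2) * (u^2 - 1) * exp(-u^2 / 2)
}

#' Gaussian-random-field cluster-level p-value
#'
#' Stationary-field cluster inference at a one-sided threshold `z_threshold`:
#' the expected cluster count `E[m]` comes from the 3D Euler-characteristic
#' density times the resel count, the expected suprathreshold volume `E[N]`
#' from the Gaussian tail times the in-mask voxel count, and the cluster
#' extent tail is `P(n >= k) = exp(-beta k^(2/3))` with
#' `beta = (gamma(5/2) * E[m] / E[N])^(2/3)`. The cluster p-value is
#' `1 - exp(-E[m] * P(n >= k))`. Thresholds must exceed 1 (below that the
#' expected-cluster-count approximation degenerates and the p-value is
#' reported as 1).
#'
#' @param extent Cluster extent(s) in voxels, >= 1.
#' @param smoothness A [estimate_smoothness()] result (or list with `fwhm`
#'   and `resels`).
#' @param z_threshold Positive one-sided z threshold defining the clusters.
#' @param mask The analysis mask (supplies the in-mask voxel count).
#' @return Cluster-level p-value(s), same length as `extent`.
#' @export
grf_cluster_pvalue <- function(extent, smoothness, z_threshold, mask) {
  if (any(extent < 1)) stop("extent must be >= 1", call. = FALSE)
  if (!is.finite(z_threshold) || z_threshold <= 0) {
    stop("bad threshold: z_threshold must be > 0", call. = FALSE)
  }
  if (smoothness$resels <= 0) stop("resels must be > 0", call. = FALSE)
  e_m <- smoothness$resels * ec_density_3d(z_threshold)
  if (e_m <= 0) {
    return(rep(1, length(extent)))
  }
  e_n <- sum(mask) * stats::pnorm(z_threshold, lower.tail = FALSE)
  beta <- (gamma(5 / 2) * e_m / e_n)^(2 / 3)
  p <- 1 - exp(-e_m * exp(-beta * extent^(2 / 3)))
  pmin(pmax(p, 0), 1)
}

#' Smallest extent surviving GRF cluster correction
#'
#' Closed-form inversion of [grf_cluster_pvalue()]: the smallest integer
#' extent whose cluster p-value is below `alpha`.
#'
#' @inheritParams grf_cluster_pvalue
#' @param alpha Cluster-level significance (default 0.01).
#' @return Integer critical extent (voxels); `Inf` when no finite extent
#'   reaches `alpha`.
#' @export
grf_critical_extent <- function(smoothness, z_threshold, mask, alpha = 0.01) {
  e_m <- smoothness$resels * ec_density_3d(z_threshold)
  if (e_m <= 0) {
    return(Inf)
  }
  target <- -log(1 - alpha) / e_m
  if (target >= 1) {
    return(1L)
  }
  e_n <- sum(mask) * stats::pnorm(z_threshold, lower.tail = FALSE)
  beta <- (gamma(5 / 2) * e_m / e_n)^(2 / 3)
  k <- ((-log(target)) / beta)^(3 / 2)
  kc <- max(1L, ceiling(k))
  while (grf_cluster_pvalue(kc, smoothness, z_threshold, mask) >= alpha) {
    kc <- kc + 1L
  }
  kc
}
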