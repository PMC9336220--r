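#' Order patients into a pseudo time series
#'
#' Sorts patients by ascending illness duration (stable; ties broken by
#' ascending id) and computes the duration-interval covariate: the first
#' difference of the sorted durations, with a leading 0 for the rank-1
#' patient, who has no predecessor.
#'
#' @param records Record tibble; every row must be a patient with a finite
#'   duration (controls are rejected — the pseudo time axis is patients-only).
#' @return A `pseudo_ts` tibble with columns `rank`, `subject` (row index
#'   into `records`), `id`, `duration`, `interval`.
#' @export
order_by_duration <- function(records) {
  if (nrow(records) == 0L) stop("no patients to order", call. = FALSE)
  if (any(records$group != "patient")) {
    stop("pseudo time series is patients-only; drop controls first", call. = FALSE)
  }
  if (!all(is.finite(records$duration))) {
    stop("missing duration for one or more patients", call. = FALSE)
  }
  ord <- order(records$duration, records$id)
  dur <- records$duration[ord]
  out <- tibble::tibble(
    rank = seq_along(ord), subject = ord, id = records$id[ord],
    duration = dur, interval = c(0, diff(dur))
  )
  class(out) <- c("pseudo_ts", class(out))
  out
}

#' Extract the seed series from ordered GMV maps
#'
#' For every ordered patient, the unweighted mean GMV over the voxels whose
#' centre lies within the seed sphere, intersected with the analysis mask.
#'
#' @param dataset A [gmv_dataset()].
#' @param ordering A `pseudo_ts` from [order_by_duration()] (its `subject`
#'   column indexes `dataset$records`).
#' @param seed Either a length-3 MNI mm centre (then `radius` applies) or an
#'   explicit `gmv_mask`.
#' @param mask Analysis mask (`gmv_mask`).
#' @param radius Sphere radius in mm when `seed` is a centre (default 6).
#' @return The input `ordering` with a `seed` column appended (X_t).
#' @export
extract_seed_series <- function(dataset, ordering, seed, mask, radius = 6) {
  seed_mask <- if (inherits(seed, "gmv_mask")) {
    seed
  } else {
    sphere_mask(dataset$grid, seed, radius)
  }
  if (!grids_equal(dataset$grid, vol_grid(seed_mask)) ||
    !grids_equal(dataset$grid, vol_grid(mask))) {
    stop("heterogeneous grids", call. = FALSE)
  }
  idx <- intersect(which(seed_mask), which(mask))
  if (length(idx) == 0L) stop("seed outside mask", call. = FALSE)
  flat <- matrix(dataset$data, nrow = prod(dataset$grid$shape))
  ordering$seed <- colMeans(flat[idx, ordering$subject, drop = FALSE])
  attr(ordering, "seed_voxels") <- length(idx)
  ordering
}

#' Signed-path-coefficient Granger causality
#'
#' Per voxel, ordinary least squares of the lag-p causality model over the
#' usable rows t = p+1 .. n:
#'
#' forward (seed -> voxel):
#'   `Y_t = sum_k A_k X_{t-k} + sum_k B_k Y_{t-k} + C Z_t + intercept + e_t`
#'
#' reverse (voxel -> seed):
#'   `X_t = sum_k A'_k X_{t-k} + sum_k B'_k Y_{t-k} + C' Z_t + intercept + e'_t`
#'
#' The reported signed-path coefficient is the lag-1 cross coefficient
#' (`A_1` forward, `B'_1` reverse); for p > 1 the per-lag cross coefficients
#' are summed into the map (all lags are retained in the fit). Covariate
#' columns are mean-centred over the usable rows. Voxels whose local design is
#' rank-deficient (e.g. constant Y) are flagged non-finite and excluded from
#' downstream maps.
#'
#' @param x Seed series X_t (length n, the [extract_seed_series()] output
#'   column).
#' @param y Ordered subjects-by-voxels matrix (rows in pseudo-time order); a
#'   `masked_data` keeps its mask for map reconstruction.
#' @param z Optional covariate matrix (n x q), e.g. age, sex, tiv, interval.
#' @param p Model order (number of lags, default 1).
#' @param direction `"forward"` (seed past -> voxel present) or `"reverse"`.
#' @return A `gc_fit`: coefficient matrices `A` (p x V), `B` (p x V), `C`
#'   (q x V), `intercept`, `path` (the reported signed-path coefficient per
#'   voxel), `path_se`, `residuals` (usable x V), `df`, `n_usable`, plus the
#'   mask carried from `y` when present.
#' @export
signed_path_gc <- function(x, y, z = NULL, p = 1L,
                           direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  p <- as.integer(p)
  mask <- attr(y, "mask", exact = TRUE)
  voxel_index <- attr(y, "voxel_index", exact = TRUE)
  y <- unclass(y)
  attributes(y) <- list(dim = dim(y))
  n <- length(x)
  if (nrow(y) != n) stop("cardinality: y rows must equal length(x)", call. = FALSE)
  if (!is.null(z)) {
    z <- as.matrix(z)
    if (nrow(z) != n) stop("cardinality: z rows must equal length(x)", call. = FALSE)
  }
  q <- if (is.null(z)) 0L else ncol(z)
  k <- 2L * p + q + 1L
  if (n < p + q + 3L || n - p <= k) {
    stop("too few time points for the requested model", call. = FALSE)
  }
  if (stats::sd(x) < 1e-12) stop("degenerate seed series", call. = FALSE)

  use <- (p + 1L):n
  m <- length(use)
  xlag <- vapply(seq_len(p), function(kk) x[use - kk], numeric(m))
  zc <- if (q > 0L) scale(z[use, , drop = FALSE], center = TRUE, scale = FALSE) else NULL

  if (direction == "forward") {
    resp_shared <- NULL # response differs per voxel (Y_t)
  } else {
    resp_shared <- x[use] # X_t for every voxel
  }

  if (p == 1L) {
    fit <- gc_solve_lag1(
      xlag = drop(xlag), ylag = y[use - 1L, , drop = FALSE],
      ymat = if (is.null(resp_shared)) y[use, , drop = FALSE] else
        matrix(resp_shared, m, ncol(y)),
      zc = zc, report = if (direction == "forward") "a" else "b"
    )
  } else {
    fit <- gc_solve_generic(
      xlag = xlag, y = y, use = use, p = p, zc = zc,
      resp_shared = resp_shared,
      report = if (direction == "forward") "a" else "b"
    )
  }

  structure(
    c(fit, list(
      order = p, direction = direction, n_usable = m, df = m - k,
      covariate_names = if (q > 0L) colnames(z) else character(),
      mask = mask, voxel_index = voxel_index
    )),
    class = "gc_fit"
  )
}

# Lag-1 solver via Frisch-Waugh-Lovell: residualise response and the per-voxel
# Y-lag column on the shared block W = [1, xlag, Z], then solve the remaining
# 2x2 (or 1x1) system in closed form across all voxels at once.
gc_solve_lag1 <- function(xlag, ylag, ymat, zc, report) {
  m <- length(xlag)
  nv <- ncol(ymat)
  w <- cbind(intercept = rep(1, m), if (!is.null(zc)) zc)
  qw <- qr(w)
  a <- xlag - qr.fitted(qw, xlag) # shared cross regressor, residualised
  b <- ylag - qr.fitted(qw, ylag) # per-voxel autoregressor, residualised
  yr <- ymat - qr.fitted(qw, ymat)

  aa <- sum(a * a)
  bb <- colSums(b * b)
  ab <- colSums(a * b)
  ay <- colSums(a * yr)
  by <- colSums(b * yr)
  det <- aa * bb - ab^2
  bad <- det <= max(aa, 1) * 1e-12 | bb <= 1e-24
  det[bad] <- NA_real_
  coef_a <- (bb * ay - ab * by) / det
  coef_b <- (aa * by - ab * ay) / det

  res <- yr - outer(a, coef_a) - b * matrix(coef_b, m, nv, byrow = TRUE)
  res[, bad] <- NA_real_
  k <- 2L + ncol(w)
  df <- m - k
  sigma2 <- colSums(res^2) / df
  var_a <- sigma2 * bb / det
  var_b <- sigma2 * aa / det

  # shared-block coefficients recovered from the partialled fit
  resid_shared <- ymat - outer(xlag, coef_a) - ylag * matrix(coef_b, m, nv, byrow = TRUE)
  wcoef <- qr.coef(qw, resid_shared)
  wcoef[, bad] <- NA_real_

  path <- if (report == "a") coef_a else coef_b
  path_se <- sqrt(if (report == "a") var_a else var_b)
  list(
    A = matrix(coef_a, 1L, nv), B = matrix(coef_b, 1L, nv),
    C = if (nrow(wcoef) > 1L) wcoef[-1L, , drop = FALSE] else NULL,
    intercept = wcoef[1L, ],
    path = path, path_se = path_se, residuals = res
  )
}

# generic per-voxel solve for p > 1 (small k; plain loop)
gc_solve_generic <- function(xlag, y, use, p, zc, resp_shared, report) {
  m <- length(use)
  nv <- ncol(y)
  q <- if (is.null(zc)) 0L else ncol(zc)
  k <- 2L * p + q + 1L
  a_mat <- matrix(NA_real_, p, nv)
  b_mat <- matrix(NA_real_, p, nv)
  c_mat <- if (q > 0L) matrix(NA_real_, q, nv) else NULL
  icpt <- rep(NA_real_, nv)
  path <- rep(NA_real_, nv)
  path_se <- rep(NA_real_, nv)
  res <- matrix(NA_real_, m, nv)
  for (v in seq_len(nv)) {
    ylag <- vapply(seq_len(p), function(kk) y[use - kk, v], numeric(m))
    xm <- cbind(1, xlag, ylag, zc)
    resp <- if (is.null(resp_shared)) y[use, v] else resp_shared
    qx <- qr(xm)
    if (qx$rank < k) next
    beta <- qr.coef(qx, resp)
    r <- resp - xm %*% beta
    res[, v] <- r
    icpt[v] <- beta[1L]
    a_mat[, v] <- beta[2L:(p + 1L)]
    b_mat[, v] <- beta[(p + 2L):(2L * p + 1L)]
    if (q > 0L) c_mat[, v] <- beta[(2L * p + 2L):k]
    sigma2 <- sum(r^2) / (m - k)
    cov <- sigma2 * solve(crossprod(xm))
    if (report == "a") {
      path[v] <- sum(a_mat[, v])
      path_se[v] <- sqrt(sum(cov[2L:(p + 1L), 2L:(p + 1L)]))
    } else {
      path[v] <- sum(b_mat[, v])
      path_se[v] <- sqrt(sum(cov[(p + 2L):(2L * p + 1L), (p + 2L):(2L * p + 1L)]))
    }
  }
  list(
    A = a_mat, B = b_mat, C = c_mat, intercept = icpt,
    path = path, path_se = path_se, residuals = res
  )
}

#' @export
print.gc_fit <- function(x, ...) {
  cat(sprintf(
    "<gc_fit:%s> order %d, %d usable rows, %d voxels (%d excluded)\n",
    x$direction, x$order, x$n_usable, length(x$path), sum(!is.finite(x$path))
  ))
  invisible(x)
}

#' Signed-path coefficient or z map from a GC fit
#'
#' @param fit A [signed_path_gc()] result carrying a mask.
#' @param what `"coefficient"` for the raw signed-path map, `"z"` for the
#'   standardised map (see [z_score_map()]).
#' @param z_mode Passed to [z_score_map()] when `what = "z"`.
#' @return A [stat_map()].
#' @export
gc_map <- function(fit, what = c("coefficient", "z"),
                   z_mode = c("spatial", "wald")) {
  what <- match.arg(what)
  stopifnot(inherits(fit, "gc_fit"))
  if (is.null(fit$mask)) stop("fit carries no mask; pass a masked_data y", call. = FALSE)
  cmap <- stat_map(fit$path, fit$mask,
    stat_kind = "coefficient", df = fit$df,
    provenance = sprintf("signed-path GC (%s, order %d)", fit$direction, fit$order)
  )
  if (what == "coefficient") {
    return(cmap)
  }
  z_score_map(cmap, mode = z_mode, se = fit$path_se)
}

#' Z-score a coefficient map
#'
#' Default (`"spatial"`) standardisation: `z = (v - mean) / sd` over the
#' finite in-mask values, i.e. the map is expressed in units of its own
#' spatial spread. Alternative (`"wald"`): per-voxel `z = coefficient / SE`
#' using the regression standard errors.
#'
#' @param map A [stat_map()] of coefficients.
#' @param mode `"spatial"` or `"wald"`.
#' @param se Per-voxel standard errors (required for `"wald"`).
#' @return A `stat_map` with `stat_kind = "z"`.
#' @export
z_score_map <- function(map, mode = c("spatial", "wald"), se = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(map, "stat_map"))
  v <- map$values
  fin <- is.finite(v)
  if (mode == "spatial") {
    if (sum(fin) < 2L) stop("degenerate map: need >= 2 finite values", call. = FALSE)
    s <- stats::sd(v[fin])
    if (s < 1e-15) stop("degenerate map: zero spread", call. = FALSE)
    z <- (v - mean(v[fin])) / s
  } else {
    if (is.null(se)) stop("wald mode needs per-voxel standard errors", call. = FALSE)
    z <- v / se
  }
  stat_map(z, map$mask,
    stat_kind = "z", df = map$df,
    provenance = paste0(map$provenance, sprintf(" | z (%s)", mode))
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a GC fit into one row per voxel
#'
#' @param x A `gc_fit`.
#' @param ... Unused.
#' @return A tibble with `voxel` (linear index when known), the summed cross
#'   (`path`) and autoregressive coefficients, `path_se`, and `sigma`.
#' @method tidy gc_fit
#' @export
tidy.gc_fit <- function(x, ...) {
  nv <- length(x$path)
  tibble::tibble(
    voxel = if (!is.null(x$voxel_index)) x$voxel_index else seq_len(nv),
    path = x$path,
    autoreg = colSums(x$B),
    path_se = x$path_se,
    sigma = sqrt(colSums(x$residuals^2) / x$df)
  )
}

#' One-row summary of a GC fit
#'
#' @param x A `gc_fit`.
#' @param ... Unused.
#' @return A one-row tibble: order, direction, usable rows, df, voxel counts.
#' @method glance gc_fit
#' @export
glance.gc_fit <- function(x, ...) {
  tibble::tibble(
    order = x$order, direction = x$direction,
    n_usable = x$n_usable, df = x$df,
    n_voxels = length(x$path),
    n_excluded = sum(!is.finite(x$path))
  )
}
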