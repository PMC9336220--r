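#' Build a design matrix for voxelwise group comparison
#'
#' Columns are `[intercept, group, age_c, sex_c, tiv_c]` (group only when
#' requested). Group is coded patient = 1, control = 0; sex is coded M = 0,
#' F = 1 before centring. Nuisance covariates (age, sex, tiv) are mean-centred
#' so the group coefficient is the adjusted group difference at average
#' covariate values. Nuisance columns that are constant across subjects are
#' dropped with a warning.
#'
#' @param records Subject record tibble (see [gmv_dataset()]).
#' @param include_group Include the patient-vs-control column?
#' @return A `vbm_design`: list with `matrix` (n x k), `columns`, and
#'   `group_col` (index of the group column, `NA` if absent).
#' @export
build_design <- function(records, include_group = TRUE) {
  records <- validate_records(records)
  n <- nrow(records)
  if (n < 2L) stop("need >= 2 records", call. = FALSE)
  cols <- list(intercept = rep(1, n))
  if (include_group) {
    grp <- as.numeric(records$group == "patient")
    if (length(unique(grp)) < 2L) {
      stop("collinear design: both groups required for a group column", call. = FALSE)
    }
    cols$group <- grp
  }
  nuisance <- list(
    age = records$age,
    sex = as.numeric(records$sex == "F"),
    tiv = records$tiv
  )
  for (nm in names(nuisance)) {
    v <- nuisance[[nm]]
    if (max(v) - min(v) < 1e-12) {
      warning(sprintf("dropping constant nuisance covariate '%s'", nm),
        call. = FALSE
      )
      next
    }
    cols[[nm]] <- v - mean(v)
  }
  x <- do.call(cbind, cols)
  colnames(x) <- names(cols)
  if (n < ncol(x) + 1L) stop("collinear design: n must exceed k", call. = FALSE)
  if (qr(x)$rank < ncol(x)) stop("collinear design", call. = FALSE)
  structure(
    list(
      matrix = x, columns = colnames(x),
      group_col = if (include_group) which(colnames(x) == "group") else NA_integer_
    ),
    class = "vbm_design"
  )
}

#' @export
print.vbm_design <- function(x, ...) {
  cat(sprintf(
    "<vbm_design> %d subjects x [%s]\n",
    nrow(x$matrix), paste(x$columns, collapse = ", ")
  ))
  invisible(x)
}

#' Fit the voxelwise general linear model
#'
#' Ordinary least squares of every voxel column on the design, via one QR
#' decomposition shared across voxels. Residuals are retained for smoothness
#' estimation; `df = n - rank(X)`.
#'
#' @param data Subjects-by-voxels matrix, ideally a `masked_data` from
#'   [flatten_masked()] (its mask then propagates to downstream maps).
#' @param design A [build_design()] object.
#' @return A `vbm_glm_fit`: list with `coefficients` (k x V), `residuals`
#'   (n x V), `df`, `design`, and the `mask`/`voxel_index` carried over from
#'   `data` when present.
#' @export
fit_glm_voxelwise <- function(data, design) {
  stopifnot(inherits(design, "vbm_design"))
  x <- design$matrix
  y <- unclass(data)
  attributes(y) <- list(dim = dim(data))
  if (nrow(y) != nrow(x)) {
    stop("cardinality: data rows must equal design rows", call. = FALSE)
  }
  qx <- qr(x)
  if (qx$rank < ncol(x)) stop("collinear design", call. = FALSE)
  beta <- qr.coef(qx, y)
  res <- y - x %*% beta
  structure(
    list(
      coefficients = beta, residuals = res,
      df = nrow(x) - qx$rank, design = design,
      mask = attr(data, "mask", exact = TRUE),
      voxel_index = attr(data, "voxel_index", exact = TRUE)
    ),
    class = "vbm_glm_fit"
  )
}

#' @export
print.vbm_glm_fit <- function(x, ...) {
  cat(sprintf(
    "<vbm_glm_fit> %d voxels, df = %d, terms [%s]\n",
    ncol(x$coefficients), x$df, paste(x$design$columns, collapse = ", ")
  ))
  invisible(x)
}

#' t contrast of a voxelwise GLM fit
#'
#' Computes `t = c'beta / sqrt(sigma2 * c'(X'X)^-1 c)` per voxel. Voxels with
#' zero residual variance yield non-finite t and are excluded by downstream
#' masking, never silently zeroed.
#'
#' @param fit A [fit_glm_voxelwise()] result.
#' @param contrast Numeric vector, one weight per design column.
#' @return A `stat_map` (t, with `df`) when the fit carries a mask, otherwise
#'   a plain list with `values` and `df`.
#' @export
t_contrast <- function(fit, contrast) {
  stopifnot(inherits(fit, "vbm_glm_fit"))
  x <- fit$design$matrix
  if (length(contrast) != ncol(x)) {
    stop("contrast length must equal design column count", call. = FALSE)
  }
  if (fit$df <= 0) stop("insufficient degrees of freedom", call. = FALSE)
  xtx_inv <- chol2inv(chol(crossprod(x)))
  var_c <- drop(t(contrast) %*% xtx_inv %*% contrast)
  sigma2 <- colSums(fit$residuals^2) / fit$df
  num <- drop(crossprod(contrast, fit$coefficients))
  tval <- if (all(contrast == 0)) rep(0, length(num)) else num / sqrt(sigma2 * var_c)
  if (is.null(fit$mask)) {
    return(list(values = tval, df = fit$df, stat_kind = "t"))
  }
  stat_map(tval, fit$mask,
    stat_kind = "t", df = fit$df,
    provenance = sprintf(
      "t contrast [%s] on [%s]",
      paste(contrast, collapse = ","), paste(fit$design$columns, collapse = ",")
    )
  )
}

#' Statistic map container
#'
#' Holds one scalar statistic per in-mask voxel (flat vector in the fixed
#' [flatten_masked()] order) together with the mask, the statistic kind, its
#' degrees of freedom and a provenance string.
#'
#' @param values Numeric vector over in-mask voxels (non-finite values mark
#'   excluded voxels).
#' @param mask A `gmv_mask`.
#' @param stat_kind One of `"t"`, `"z"`, `"coefficient"`.
#' @param df Degrees of freedom (required > 0 for t maps).
#' @param provenance Free-text description of how the map was computed.
#' @return A `stat_map` object.
#' @export
stat_map <- function(values, mask, stat_kind = c("t", "z", "coefficient"),
                     df = NA_real_, provenance = "") {
  stat_kind <- match.arg(stat_kind)
  idx <- which(mask)
  if (length(values) != length(idx)) {
    stop("cardinality: one value per in-mask voxel required", call. = FALSE)
  }
  if (stat_kind == "t" && (!is.finite(df) || df <= 0)) {
    stop("t maps need df > 0", call. = FALSE)
  }
  structure(
    list(
      values = as.numeric(values), mask = mask,
      stat_kind = stat_kind, df = df, provenance = provenance
    ),
    class = "stat_map"
  )
}

#' @export
print.stat_map <- function(x, ...) {
  fin <- x$values[is.finite(x$values)]
  cat(sprintf(
    "<stat_map:%s> %d in-mask voxels (%d finite), range [%.3f, %.3f]%s\n",
    x$stat_kind, length(x$values), length(fin), min(fin), max(fin),
    if (is.finite(x$df)) sprintf(", df = %g", x$df) else ""
  ))
  if (nzchar(x$provenance)) cat("  ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Render a stat map as a volume
#'
#' @param x A [stat_map()].
#' @param fill Value for out-of-mask or non-finite voxels.
#' @return A [gmv_volume()].
#' @export
as_volume <- function(x, fill = 0) {
  stopifnot(inherits(x, "stat_map"))
  v <- x$values
  v[!is.finite(v)] <- fill
  unflatten(v, x$mask, fill = fill)
}
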