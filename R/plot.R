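#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a stat map into voxel rows
#'
#' @param x A [stat_map()].
#' @param ... Unused.
#' @return A tibble with the voxel linear index, 0-based voxel coordinates,
#'   MNI mm coordinates and the statistic value (in-mask voxels only).
#' @method tidy stat_map
#' @export
tidy.stat_map <- function(x, ...) {
  grid <- vol_grid(x$mask)
  idx <- which(x$mask)
  ijk <- arrayInd(idx, grid$shape) - 1L
  mm <- vox_to_mm(grid, ijk)
  tibble::tibble(
    voxel = idx,
    i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
    x_mm = mm[, 1], y_mm = mm[, 2], z_mm = mm[, 3],
    value = x$values
  )
}

#' Axial-slice mosaic of a stat map
#'
#' @param object A [stat_map()].
#' @param slices 0-based axial (k) slice indices; defaults to 6 evenly spaced
#'   in-mask slices.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot stat_map
#' @export
autoplot.stat_map <- function(object, slices = NULL, ...) {
  df <- tidy.stat_map(object)
  if (is.null(slices)) {
    ks <- sort(unique(df$k))
    slices <- ks[unique(pmax(1L, round(seq(1L, length(ks), length.out = 6L))))]
  }
  df <- df[df$k %in% slices & is.finite(df$value), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_mm, y = .data$y_mm, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~k, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "grey95", high = "#b2182b") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      fill = object$stat_kind,
      title = if (nzchar(object$provenance)) object$provenance else NULL
    ) +
    ggplot2::theme_minimal()
}

#' Seed pseudo-time-series plot
#'
#' Seed mean GMV against illness duration over the ordered patients.
#'
#' @param series A `pseudo_ts` tibble carrying a `seed` column (from
#'   [extract_seed_series()]).
#' @return A ggplot object.
#' @export
plot_seed_series <- function(series) {
  stopifnot("seed" %in% names(series))
  ggplot2::ggplot(series, ggplot2::aes(x = .data$duration, y = .data$seed)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "illness duration (years)", y = "seed mean GMV",
      title = "seed pseudo time series"
    ) +
    ggplot2::theme_minimal()
}

#' Cluster-table overview plot
#'
#' Extent against peak statistic, split by sign, survivors emphasised.
#'
#' @param object A `cluster_table` (from [correct_map()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cluster_table
#' @export
autoplot.cluster_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  if (!"survives" %in% names(df)) df$survives <- NA
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$extent_voxels, y = .data$peak_stat,
    colour = .data$sign, shape = .data$survives
  )) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "extent (voxels)", y = "peak statistic") +
    ggplot2::theme_minimal()
}

#' One-row summary of a voxelwise GLM fit
#'
#' @param x A `vbm_glm_fit`.
#' @param ... Unused.
#' @return A one-row tibble: subjects, voxels, df, design columns.
#' @method glance vbm_glm_fit
#' @export
glance.vbm_glm_fit <- function(x, ...) {
  tibble::tibble(
    n_subjects = nrow(x$residuals),
    n_voxels = ncol(x$residuals),
    df = x$df,
    terms = paste(x$design$columns, collapse = "+")
  )
}

#' @importFrom rlang .data
NULL
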