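#' Label suprathreshold clusters of a statistic map
#'
#' Thresholds one sign branch of the map (`value > threshold` for the
#' positive branch, `value < -threshold` for the negative) and labels
#' connected components under 6-, 18- or 26-connectivity. Per cluster the
#' peak is the voxel of maximal absolute statistic, reported in MNI mm.
#'
#' @param map A [stat_map()].
#' @param threshold Positive cutoff in the map's own units.
#' @param sign `"pos"`, `"neg"`, or `"both"` (both branches stacked).
#' @param connectivity 6 (faces), 18 (+edges) or 26 (+corners; default).
#' @return A `cluster_table` tibble: `x_mm`, `y_mm`, `z_mm`, `peak_stat`,
#'   `extent_voxels`, `sign`, sorted by descending extent, with the member
#'   voxel indices in attribute `members`.
#' @export
label_clusters <- function(map, threshold, sign = c("pos", "neg", "both"),
                           connectivity = 26L) {
  sign <- match.arg(sign)
  stopifnot(inherits(map, "stat_map"), threshold > 0)
  if (sign == "both") {
    pos <- label_clusters(map, threshold, "pos", connectivity)
    neg <- label_clusters(map, threshold, "neg", connectivity)
    out <- dplyr::bind_rows(tibble::as_tibble(pos), tibble::as_tibble(neg))
    members <- c(attr(pos, "members"), attr(neg, "members"))
    ord <- order(-out$extent_voxels, out$x_mm, out$y_mm, out$z_mm)
    out <- out[ord, , drop = FALSE]
    out <- structure(out, class = c("cluster_table", class(tibble::tibble())))
    attr(out, "members") <- members[ord]
    return(out)
  }
  grid <- vol_grid(map$mask)
  inmask <- which(map$mask)
  v <- map$values
  hit <- if (sign == "pos") {
    is.finite(v) & v > threshold
  } else {
    is.finite(v) & v < -threshold
  }
  idx <- inmask[hit] # linear indices into the 3D array
  vals <- v[hit]
  empty <- cluster_table_skeleton()
  if (length(idx) == 0L) {
    attr(empty, "members") <- list()
    return(empty)
  }
  comp <- connected_components(idx, grid$shape, connectivity)
  rows <- lapply(seq_len(max(comp)), function(cl) {
    sel <- comp == cl
    cvals <- vals[sel]
    cidx <- idx[sel]
    peak <- cidx[which.max(abs(cvals))]
    mm <- vox_to_mm(grid, arrayInd(peak, grid$shape) - 1L)
    tibble::tibble(
      x_mm = mm[1], y_mm = mm[2], z_mm = mm[3],
      peak_stat = cvals[which.max(abs(cvals))],
      extent_voxels = sum(sel),
      sign = sign
    )
  })
  members <- lapply(seq_len(max(comp)), function(cl) idx[comp == cl])
  out <- dplyr::bind_rows(rows)
  ord <- order(-out$extent_voxels, out$x_mm, out$y_mm, out$z_mm)
  out <- out[ord, , drop = FALSE]
  out <- structure(out, class = c("cluster_table", class(tibble::tibble())))
  attr(out, "members") <- members[ord]
  out
}

cluster_table_skeleton <- function() {
  structure(
    tibble::tibble(
      x_mm = numeric(), y_mm = numeric(), z_mm = numeric(),
      peak_stat = numeric(), extent_voxels = integer(), sign = character()
    ),
    class = c("cluster_table", class(tibble::tibble()))
  )
}

# connected components among the given linear voxel indices; returns an
# integer component label per index
connected_components <- function(idx, shape, connectivity = 26L) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L)) {
    stop("connectivity must be 6, 18 or 26", call. = FALSE)
  }
  offs <- neighbour_offsets(connectivity)
  pos <- integer(prod(shape))
  pos[idx] <- seq_along(idx)
  coords <- arrayInd(idx, shape)
  strides <- c(1L, shape[1], shape[1] * shape[2])
  edges <- list()
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    ok <- coords[, 1] + o[1] >= 1L & coords[, 1] + o[1] <= shape[1] &
      coords[, 2] + o[2] >= 1L & coords[, 2] + o[2] <= shape[2] &
      coords[, 3] + o[3] >= 1L & coords[, 3] + o[3] <= shape[3]
    nb <- pos[idx[ok] + sum(o * strides)]
    has <- nb > 0L
    if (any(has)) {
      edges[[length(edges) + 1L]] <- cbind(which(ok)[has], nb[has])
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges) > 0L) {
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  }
  igraph::components(g)$membership
}

# unique half-space neighbour offsets for the given connectivity
neighbour_offsets <- function(connectivity) {
  full <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  full <- full[rowSums(abs(full)) > 0L, , drop = FALSE]
  ord <- full[full[, 3] > 0L | (full[, 3] == 0L & full[, 2] > 0L) |
    (full[, 3] == 0L & full[, 2] == 0L & full[, 1] > 0L), , drop = FALSE]
  manh <- rowSums(abs(ord))
  if (connectivity == 6L) {
    ord[manh == 1L, , drop = FALSE]
  } else if (connectivity == 18L) {
    ord[manh <= 2L, , drop = FALSE]
  } else {
    ord
  }
}

#' GRF-corrected cluster table for a statistic map
#'
#' Runs both sign branches at the voxel-level threshold, labels clusters,
#' assigns each a Gaussian-random-field cluster p-value from the residual
#' smoothness estimate, and flags survivors at the cluster-level alpha. For t
#' maps the voxel threshold is the t quantile at `voxel_p` while the GRF
#' formulas use the equivalent z threshold.
#'
#' @param map A [stat_map()] (t or z).
#' @param residuals n x V residual matrix used for smoothness estimation.
#' @param mask Analysis mask.
#' @param voxel_p Voxel-level one-sided p per sign branch (default 0.001).
#' @param cluster_p Cluster-level alpha (default 0.01).
#' @param connectivity 6, 18 or 26 (default 26).
#' @param smoothness Optional precomputed [estimate_smoothness()] (skips the
#'   residual step; `residuals` may then be NULL).
#' @return A `cluster_table` with `cluster_p` and `survives` columns,
#'   smoothness in attribute `smoothness`, member voxels in `members`.
#' @export
correct_map <- function(map, residuals, mask, voxel_p = 0.001,
                        cluster_p = 0.01, connectivity = 26L,
                        smoothness = NULL) {
  stopifnot(inherits(map, "stat_map"))
  if (is.null(smoothness)) {
    smoothness <- estimate_smoothness(residuals, mask, df = map$df)
  }
  thr_map <- if (map$stat_kind == "t") {
    p_to_threshold(voxel_p, "one", "t", df = map$df)
  } else {
    p_to_threshold(voxel_p, "one", "z")
  }
  thr_z <- p_to_threshold(voxel_p, "one", "z")
  tabs <- lapply(c("pos", "neg"), function(s) {
    label_clusters(map, thr_map, s, connectivity)
  })
  members <- c(attr(tabs[[1]], "members"), attr(tabs[[2]], "members"))
  out <- dplyr::bind_rows(tabs)
  if (nrow(out) > 0L) {
    out$cluster_p <- grf_cluster_pvalue(out$extent_voxels, smoothness, thr_z, mask)
    out$survives <- out$cluster_p < cluster_p
  } else {
    out$cluster_p <- numeric()
    out$survives <- logical()
  }
  ord <- order(-out$extent_voxels, out$x_mm, out$y_mm, out$z_mm)
  out <- out[ord, , drop = FALSE]
  out <- structure(out, class = c("cluster_table", class(tibble::tibble())))
  attr(out, "members") <- members[ord]
  attr(out, "smoothness") <- smoothness
  attr(out, "thresholds") <- list(
    voxel_p = voxel_p, cluster_p = cluster_p,
    stat_threshold = thr_map, z_threshold = thr_z,
    connectivity = connectivity
  )
  out
}

#' Dice overlap between a voxel set and a region mask
#'
#' `2 |A n B| / (|A| + |B|)` where A is the given voxel index set (e.g. one
#' entry of a cluster table's `members` attribute) and B the region's in-mask
#' voxels.
#'
#' @param voxels Integer vector of linear voxel indices.
#' @param region A `gmv_mask`.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_overlap <- function(voxels, region) {
  b <- which(region)
  2 * length(intersect(voxels, b)) / (length(voxels) + length(b))
}

#' Write a cluster table as TSV
#'
#' @param table A `cluster_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(table, path) {
  readr::write_tsv(tibble::as_tibble(table), path)
  invisible(path)
}
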