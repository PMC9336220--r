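#' Optimal-threshold analysis mask
#'
#' Computes the grand-mean GMV volume over all subjects and thresholds it with
#' Otsu's method (256-bin histogram over the positive values, maximising
#' between-class variance). Voxels strictly above the threshold form the
#' analysis mask — a deterministic, parameter-free stand-in for an "optimal
#' threshold" GM mask that excludes non-GM background.
#'
#' @param dataset A [gmv_dataset()].
#' @return A `gmv_mask` with attribute `threshold`.
#' @export
optimal_threshold_mask <- function(dataset) {
  stopifnot(inherits(dataset, "gmv_dataset"))
  mean_vol <- apply(dataset$data, c(1, 2, 3), mean)
  thr <- otsu_threshold(mean_vol[mean_vol > 0])
  m <- gmv_mask(mean_vol > thr, dataset$grid)
  attr(m, "threshold") <- thr
  m
}

#' Otsu threshold of a value vector
#'
#' 256-bin histogram between `min(x)` and `max(x)`; returns the bin edge
#' maximising the between-class variance. Ties go to the lowest edge.
#'
#' @param x Numeric vector of (positive) intensities.
#' @param n_bins Number of histogram bins (default 256).
#' @return The scalar threshold.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) == 0L || max(x) - min(x) < 1e-12) {
    stop("degenerate intensity distribution", call. = FALSE)
  }
  edges <- seq(min(x), max(x), length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  w0 <- cumsum(counts)
  w1 <- sum(counts) - w0
  s0 <- cumsum(counts * mids)
  mu0 <- s0 / w0
  mu1 <- (s0[n_bins] - s0) / w1
  between <- w0 * w1 * (mu0 - mu1)^2
  between[w0 == 0 | w1 == 0] <- -Inf
  edges[which.max(between) + 1L]
}
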