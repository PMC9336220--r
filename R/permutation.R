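#' Permutation null distribution of the maximal cluster extent
#'
#' Nonparametric validation oracle for the GRF cluster correction. Two
#' resampling schemes:
#'
#' * `mode = "group"`: permutes the patient/control labels (the group column
#'   of the design) and recomputes the voxelwise t map each time.
#' * `mode = "ordering"`: permutes the pseudo-time ordering of the patients
#'   (seed series, data rows and covariates jointly; the duration-interval
#'   covariate is recomputed from the permuted duration sequence) and
#'   recomputes the signed-path GC spatial-z map each time.
#'
#' Each permutation records the maximal cluster extent over both sign
#' branches at the supplied threshold. Deterministic given `rng_seed`.
#'
#' @param data A `masked_data` matrix (for `"ordering"`, rows already in
#'   pseudo-time order).
#' @param n_perm Number of permutations (>= 1; >= 100 for quantile use).
#' @param threshold Positive voxel threshold in the recomputed map's units
#'   (t for `"group"`, spatial z for `"ordering"`).
#' @param rng_seed Integer seed.
#' @param mode `"group"` or `"ordering"`.
#' @param design A [build_design()] object with a group column (`"group"`).
#' @param contrast Contrast vector for the t map (`"group"` mode).
#' @param x Seed series over the ordered patients (`"ordering"` mode).
#' @param covariates Matrix of per-patient covariates excluding the interval
#'   (ordered rows; `"ordering"` mode), or NULL.
#' @param durations Sorted durations of the ordered patients
#'   (`"ordering"` mode).
#' @param gc_order GC model order for `"ordering"` mode (default 1).
#' @param connectivity Cluster connectivity (default 26).
#' @return A `perm_null`: list with `max_extents` (length `n_perm`),
#'   `threshold`, `mode`, `n_perm`.
#' @export
permutation_cluster_null <- function(data, n_perm, threshold, rng_seed,
                                     mode = c("group", "ordering"),
                                     design = NULL, contrast = NULL,
                                     x = NULL, covariates = NULL,
                                     durations = NULL, gc_order = 1L,
                                     connectivity = 26L) {
  mode <- match.arg(mode)
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop("bad n_perm: need >= 1", call. = FALSE)
  stopifnot(threshold > 0)
  mask <- attr(data, "mask", exact = TRUE)
  if (is.null(mask)) stop("data must carry a mask (use flatten_masked)", call. = FALSE)
  n <- nrow(data)

  max_extents <- with_seed(rng_seed, {
    vapply(seq_len(n_perm), function(b) {
      perm <- sample.int(n)
      map <- if (mode == "group") {
        perm_t_map(data, design, contrast, perm)
      } else {
        perm_gc_map(data, x, covariates, durations, perm, gc_order)
      }
      tab <- label_clusters(map, threshold, "both", connectivity)
      if (nrow(tab) == 0L) 0L else max(tab$extent_voxels)
    }, integer(1))
  })
  structure(
    list(
      max_extents = max_extents, threshold = threshold,
      mode = mode, n_perm = n_perm
    ),
    class = "perm_null"
  )
}

perm_t_map <- function(data, design, contrast, perm) {
  stopifnot(inherits(design, "vbm_design"), !is.na(design$group_col))
  xp <- design$matrix
  xp[, design$group_col] <- xp[perm, design$group_col]
  d2 <- design
  d2$matrix <- xp
  t_contrast(fit_glm_voxelwise(data, d2), contrast)
}

perm_gc_map <- function(data, x, covariates, durations, perm, gc_order) {
  yp <- masked_rows(data, perm)
  xp <- x[perm]
  dp <- durations[perm]
  zp <- cbind(covariates[perm, , drop = FALSE], interval = c(0, diff(dp)))
  fit <- signed_path_gc(xp, yp, zp, p = gc_order, direction = "forward")
  gc_map(fit, "z", "spatial")
}

#' Empirical critical extent from a permutation null
#'
#' @param null A `perm_null`.
#' @param alpha Familywise level (default 0.01).
#' @return The `1 - alpha` empirical quantile of the max-extent distribution.
#' @export
perm_critical_extent <- function(null, alpha = 0.01) {
  if (null$n_perm < 100L) stop("bad n_perm: need >= 100 for quantiles", call. = FALSE)
  stats::quantile(null$max_extents, 1 - alpha, names = FALSE, type = 1)
}

#' @export
print.perm_null <- function(x, ...) {
  cat(sprintf(
    "<perm_null:%s> %d permutations at threshold %.3f; max extent median %g\n",
    x$mode, x$n_perm, x$threshold, stats::median(x$max_extents)
  ))
  invisible(x)
}
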