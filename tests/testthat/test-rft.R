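test_that("smoothness estimation recovers the generating kernel", {
  g <- image_grid(c(40, 40, 40), 1.5)
  mask <- gmv_mask(array(TRUE, c(40, 40, 40)), g)
  set.seed(19)
  n <- 20
  res <- matrix(NA_real_, n, 40^3)
  for (i in seq_len(n)) {
    res[i, ] <- as.numeric(
      smooth_array(array(rnorm(40^3), c(40, 40, 40)), fwhm_vox = rep(4, 3))
    )
  }
  sm <- estimate_smoothness(res, mask, g, df = n - 1)
  expect_true(all(abs(sm$fwhm - 6) / 6 < 0.15))
  expect_gt(sm$resels, 0)

  # unsmoothed noise estimates below two voxel widths
  res0 <- matrix(rnorm(n * 40^3), n)
  sm0 <- suppressMessages(estimate_smoothness(res0, mask, g))
  expect_true(all(sm0$fwhm < 2 * 1.5))
})

test_that("estimated FWHM in mm scales with the voxel size", {
  set.seed(23)
  n <- 12
  shape <- c(24, 24, 24)
  raw <- lapply(seq_len(n), function(i) {
    smooth_array(array(rnorm(prod(shape)), shape), fwhm_vox = rep(3, 3))
  })
  res <- do.call(rbind, lapply(raw, as.numeric))
  g1 <- image_grid(shape, 1.5)
  g2 <- image_grid(shape, 3)
  sm1 <- estimate_smoothness(res, gmv_mask(array(TRUE, shape), g1), g1)
  sm2 <- estimate_smoothness(res, gmv_mask(array(TRUE, shape), g2), g2)
  expect_equal(sm2$fwhm, 2 * sm1$fwhm, tolerance = 1e-10)
})

test_that("degenerate residual inputs are rejected", {
  g <- tiny_grid()
  mask <- gmv_mask(array(TRUE, g$shape), g)
  expect_error(
    estimate_smoothness(matrix(rnorm(2 * 216), 2), mask, g),
    ">= 3 residual images"
  )
  res <- matrix(rnorm(5 * 216), 5)
  res[, 3] <- 0
  expect_error(estimate_smoothness(res, mask, g), "degenerate residuals")
})

test_that("p_to_threshold matches the inverse CDF and is monotone", {
  expect_equal(p_to_threshold(0.5, "one", "z"), 0)
  expect_equal(p_to_threshold(0.001, "one", "z"), qnorm(0.999), tolerance = 1e-6)
  expect_gt(p_to_threshold(0.001, "one", "z"), 3.08)
  expect_lt(p_to_threshold(0.001, "one", "z"), 3.10)
  expect_equal(
    p_to_threshold(0.01, "two", "t", df = 30),
    qt(0.995, 30),
    tolerance = 1e-10
  )
  ps <- c(0.2, 0.1, 0.05, 0.01, 0.001)
  th <- vapply(ps, p_to_threshold, numeric(1), sidedness = "one", kind = "z")
  expect_true(all(diff(th) > 0))
  expect_error(p_to_threshold(0), "bad p")
  expect_error(p_to_threshold(1), "bad p")
  expect_error(p_to_threshold(0.001, "one", "t"), "df")
})

test_that("grf cluster p-values behave at the limits and monotonically", {
  sm <- list(fwhm = c(6, 6, 6), resels = 500)
  g <- image_grid(c(30, 30, 30), 1.5)
  mask <- gmv_mask(array(TRUE, g$shape), g)
  u <- 3.09

  expect_lt(grf_cluster_pvalue(1e6, sm, u, mask), 1e-10)
  p1 <- grf_cluster_pvalue(1, list(fwhm = c(2, 2, 2), resels = 27000), u, mask)
  expect_gt(p1, 0.5)

  ext <- c(10, 20, 40, 80)
  pv <- grf_cluster_pvalue(ext, sm, u, mask)
  expect_true(all(diff(pv) < 0))

  # more smoothness (fewer resels) -> larger cluster p at fixed extent
  p_smooth <- grf_cluster_pvalue(30, list(fwhm = c(8, 8, 8), resels = 200), u, mask)
  p_rough <- grf_cluster_pvalue(30, list(fwhm = c(4, 4, 4), resels = 1700), u, mask)
  expect_gt(p_smooth, p_rough)

  expect_error(grf_cluster_pvalue(0, sm, u, mask), "extent")
  expect_error(grf_cluster_pvalue(10, sm, -1, mask), "bad threshold")

  # critical extent inverts the p-value at the boundary
  kc <- grf_critical_extent(sm, u, mask, alpha = 0.01)
  expect_lt(grf_cluster_pvalue(kc, sm, u, mask), 0.01)
  if (kc > 1) expect_gte(grf_cluster_pvalue(kc - 1, sm, u, mask), 0.01)
})

test_that("cluster labelling respects connectivity and partitions the set", {
  g <- tiny_grid(c(8L, 8L, 8L))
  mask <- gmv_mask(array(TRUE, g$shape), g)
  vals <- rep(0, sum(mask))
  arr_index <- function(i, j, k) i + (j - 1L) * 8L + (k - 1L) * 64L

  # two blobs touching only at a voxel corner: (3,3,2) and (4,4,3) differ by
  # (1,1,1), so they connect under 26- but not 6-connectivity
  blob1 <- c(arr_index(2, 2, 2), arr_index(3, 2, 2), arr_index(3, 3, 2))
  blob2 <- c(arr_index(4, 4, 3), arr_index(5, 4, 3))
  vals[match(c(blob1, blob2), which(mask))] <- 5
  map <- stat_map(vals, mask, "z")

  t26 <- label_clusters(map, 3, "pos", connectivity = 26)
  expect_equal(nrow(t26), 1L)
  expect_equal(t26$extent_voxels, 5L)
  t6 <- label_clusters(map, 3, "pos", connectivity = 6)
  expect_equal(nrow(t6), 2L)
  expect_setequal(t6$extent_voxels, c(3L, 2L))

  # extents always total the suprathreshold count
  set.seed(33)
  vals2 <- rnorm(sum(mask))
  map2 <- stat_map(vals2, mask, "z")
  for (conn in c(6, 18, 26)) {
    tab <- label_clusters(map2, 1.5, "both", connectivity = conn)
    expect_equal(sum(tab$extent_voxels), sum(abs(vals2) > 1.5))
  }

  # empty suprathreshold set gives an empty table
  expect_equal(nrow(label_clusters(map, 10, "pos")), 0L)
})

test_that("cluster peaks are reported at the right MNI coordinate", {
  g <- tiny_grid(c(8L, 8L, 8L))
  mask <- gmv_mask(array(TRUE, g$shape), g)
  vals <- rep(0, 512)
  peak_lin <- 3 + 4 * 8 + 5 * 64 + 1 # 0-based voxel (3, 4, 5) -> R linear index
  vals[peak_lin] <- 7
  vals[peak_lin - 1] <- 5 # same cluster, smaller value
  map <- stat_map(vals, mask, "z")
  tab <- label_clusters(map, 3, "pos")
  expect_equal(nrow(tab), 1L)
  want <- drop(vox_to_mm(g, c(3, 4, 5)))
  expect_equal(c(tab$x_mm, tab$y_mm, tab$z_mm), want)
  expect_equal(tab$peak_stat, 7)
})

test_that("correct_map is sign-symmetric and flags survivors", {
  ds <- null_phantom(301)
  mask <- optimal_threshold_mask(ds)
  design <- build_design(ds$records)
  fit <- fit_glm_voxelwise(flatten_masked(ds, mask), design)
  map <- t_contrast(fit, as.numeric(design$columns == "group"))
  tab <- correct_map(map, fit$residuals, mask, voxel_p = 0.05, cluster_p = 0.01)

  flipped <- map
  flipped$values <- -map$values
  tab2 <- correct_map(flipped, fit$residuals, mask, voxel_p = 0.05, cluster_p = 0.01)
  expect_equal(sort(tab$extent_voxels), sort(tab2$extent_voxels))
  expect_equal(sort(tab$cluster_p), sort(tab2$cluster_p))
  expect_equal(
    table(tab$sign)[["pos"]],
    if ("neg" %in% tab2$sign) table(tab2$sign)[["neg"]] else 0L
  )
  expect_true(all(tab$survives == (tab$cluster_p < 0.01)))
  expect_true(all(diff(tab$extent_voxels) <= 0))
})
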