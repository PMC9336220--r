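test_that("duration ordering is stable with id tie-breaks and hand intervals", {
  recs <- make_records(3L, 0L, durations = c(3, 1, 2))[1:3, ]
  ts <- order_by_duration(recs)
  expect_equal(ts$duration, c(1, 2, 3))
  expect_equal(ts$interval, c(0, 1, 1))

  tied <- tibble::tibble(
    id = c("b", "a"), group = "patient", age = 50, sex = "M",
    tiv = 1.4e6, duration = c(5, 5)
  )
  expect_identical(order_by_duration(tied)$id, c("a", "b"))

  expect_equal(order_by_duration(
    make_records(3L, 0L, durations = c(1, 4, 9))[1:3, ]
  )$interval, c(0, 3, 5))

  with_na <- make_records(2L, 0L)[1:2, ]
  with_na$duration[1] <- NA
  expect_error(order_by_duration(with_na), "missing duration")
  expect_error(order_by_duration(make_records(1L, 1L)), "patients-only")
})

test_that("seed extraction averages exactly the in-sphere in-mask voxels", {
  ds <- tiny_dataset(n_pat = 3L, n_ctl = 2L, shape = c(9L, 9L, 9L), seed = 4)
  mask <- gmv_mask(array(TRUE, ds$grid$shape), ds$grid)
  pats <- subset_subjects(ds, ds$records$group == "patient")
  ordering <- order_by_duration(pats$records)

  # single-voxel seed: radius below half a voxel at a voxel centre
  centre <- vox_to_mm(ds$grid, c(4, 4, 4))
  ts1 <- extract_seed_series(pats, ordering, drop(centre), mask, radius = 1)
  expect_equal(ts1$seed, ds$data[5, 5, 5, ordering$subject], tolerance = 1e-12)

  # brute-force sphere membership oracle
  r <- 6
  xyz <- grid_coords_mm(ds$grid)
  inside <- which((xyz[, 1] - centre[1])^2 + (xyz[, 2] - centre[2])^2 +
    (xyz[, 3] - centre[3])^2 <= r^2)
  ts2 <- extract_seed_series(pats, ordering, drop(centre), mask, radius = r)
  expect_equal(attr(ts2, "seed_voxels"), length(inside))
  flat <- matrix(pats$data, nrow = prod(ds$grid$shape))
  expect_equal(ts2$seed, colMeans(flat[inside, ordering$subject]), tolerance = 1e-12)

  expect_error(
    extract_seed_series(pats, ordering, c(500, 0, 0), mask),
    "no voxel centres|seed outside mask"
  )
})

test_that("a pure lag-1 construction is recovered exactly", {
  set.seed(1)
  n <- 50
  x <- rnorm(n)
  y <- matrix(c(0, x[-n]), n, 4) # Y_t = X_{t-1}
  fit <- signed_path_gc(x, y, p = 1)
  expect_equal(unname(fit$A[1, ]), rep(1, 4), tolerance = 1e-12)
  expect_equal(unname(fit$B[1, ]), rep(0, 4), tolerance = 1e-12)
  expect_lt(max(abs(fit$residuals)), 1e-12)
  expect_equal(fit$n_usable, n - 1L)
})

test_that("gc coefficients match a hand normal-equations solve", {
  # 8-point hand dataset plus randomized instances, with 0-4 covariates
  set.seed(97)
  for (case in 1:12) {
    n <- sample(10:30, 1)
    nv <- sample(1:50, 1)
    q <- sample(0:4, 1)
    x <- rnorm(n)
    y <- matrix(rnorm(n * nv), n, nv)
    z <- if (q > 0) matrix(rnorm(n * q), n, q) else NULL
    fit <- signed_path_gc(x, y, z, p = 1)
    use <- 2:n
    zc <- if (q > 0) scale(z[use, , drop = FALSE], scale = FALSE) else NULL
    for (v in seq_len(nv)) {
      xm <- cbind(1, x[use - 1], y[use - 1, v], zc)
      beta <- solve(t(xm) %*% xm, t(xm) %*% y[use, v])
      expect_lt(abs(fit$A[1, v] - beta[2]), 1e-10)
      expect_lt(abs(fit$B[1, v] - beta[3]), 1e-10)
      expect_lt(abs(fit$intercept[v] - beta[1]), 1e-10)
      if (q > 0) expect_lt(max(abs(fit$C[, v] - beta[4:(3 + q)])), 1e-10)
    }
  }
})

test_that("higher-order fits agree with per-voxel least squares", {
  set.seed(5)
  n <- 40
  x <- rnorm(n)
  y <- matrix(rnorm(n * 6), n, 6)
  z <- matrix(rnorm(n * 2), n, 2)
  fit <- signed_path_gc(x, y, z, p = 2)
  use <- 3:n
  zc <- scale(z[use, ], scale = FALSE)
  for (v in 1:6) {
    xm <- cbind(1, x[use - 1], x[use - 2], y[use - 1, v], y[use - 2, v], zc)
    beta <- solve(t(xm) %*% xm, t(xm) %*% y[use, v])
    expect_lt(abs(fit$path[v] - (beta[2] + beta[3])), 1e-10)
  }
})

test_that("degenerate series and voxels are flagged, not silently fit", {
  set.seed(2)
  n <- 30
  y <- matrix(rnorm(n * 3), n, 3)
  expect_error(signed_path_gc(rep(1, n), y), "degenerate seed series")
  y[, 2] <- 0.5 # constant voxel: rank-deficient local design
  fit <- signed_path_gc(rnorm(n), y)
  expect_false(is.finite(fit$path[2]))
  expect_true(all(is.finite(fit$path[c(1, 3)])))
})

test_that("z-scoring normalises the map and rejects constants", {
  ds <- tiny_dataset(seed = 6)
  mask <- gmv_mask(array(TRUE, ds$grid$shape), ds$grid)
  set.seed(10)
  vals <- rnorm(sum(mask), 3, 2)
  cmap <- stat_map(vals, mask, "coefficient")
  zmap <- z_score_map(cmap)
  expect_lt(abs(mean(zmap$values)), 1e-10)
  expect_equal(sd(zmap$values), 1, tolerance = 1e-10)
  # single-voxel spot check against hand arithmetic
  expect_equal(zmap$values[7], (vals[7] - mean(vals)) / sd(vals), tolerance = 1e-12)

  expect_error(z_score_map(stat_map(rep(1, sum(mask)), mask, "coefficient")),
    "degenerate map")

  # wald mode divides by the supplied standard errors
  se <- runif(sum(mask), 0.5, 2)
  zw <- z_score_map(cmap, mode = "wald", se = se)
  expect_equal(zw$values, vals / se, tolerance = 1e-12)
})

test_that("null gc coefficients are centred with calibrated spatial z", {
  set.seed(123)
  n <- 80
  nv <- 2000
  x <- rnorm(n)
  y <- matrix(rnorm(n * nv), n, nv)
  z <- cbind(rnorm(n, 54, 9), rbinom(n, 1, 0.5), rnorm(n, 1.45e6, 1e5),
    abs(rnorm(n, 0.3, 0.2)))
  fit <- signed_path_gc(x, y, z, p = 1)
  se_mean <- sd(fit$path) / sqrt(nv)
  expect_lt(abs(mean(fit$path)), 3 * se_mean)
  zsp <- (fit$path - mean(fit$path)) / sd(fit$path)
  exceed <- mean(abs(zsp) > 1.96)
  expect_lt(abs(exceed - 0.05), 3 * sqrt(0.05 * 0.95 / nv))
})

test_that("planted follower coefficients beat background and flip with gamma", {
  at <- atrophy_spec()
  hits <- 0L
  n_seeds <- 10L
  for (s in seq_len(n_seeds)) {
    ds <- simulate_phantom(cohort_spec(rng_seed = 600 + s))
    mask <- optimal_threshold_mask(ds)
    pats <- subset_subjects(ds, ds$records$group == "patient")
    ordering <- order_by_duration(pats$records)
    series <- extract_seed_series(pats, ordering, at$seed_center, mask, radius = 6)
    ymat <- masked_rows(flatten_masked(pats, mask), series$subject)
    recs <- pats$records[series$subject, ]
    zmat <- cbind(recs$age, as.numeric(recs$sex == "F"), recs$tiv, series$interval)
    fit <- signed_path_gc(series$seed, ymat, zmat)

    fol <- which(sphere_mask(ds$grid, at$follower_center, at$follower_radius))
    seedreg <- which(sphere_mask(ds$grid, at$seed_center, at$seed_radius))
    inmask <- which(mask)
    in_fol <- inmask %in% fol
    background <- !(inmask %in% c(fol, seedreg))
    fol_mean <- mean(fit$path[in_fol], na.rm = TRUE)
    bg_q95 <- quantile(fit$path[background], 0.95, na.rm = TRUE)
    if (fol_mean > 0 && fol_mean > bg_q95) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.9 * n_seeds))
})

test_that("negating the generator lag coefficient flips recovered signs", {
  run_one <- function(gamma, seed) {
    at <- atrophy_spec(lag_coeff = gamma)
    ds <- simulate_phantom(cohort_spec(rng_seed = seed), at)
    mask <- optimal_threshold_mask(ds)
    pats <- subset_subjects(ds, ds$records$group == "patient")
    ordering <- order_by_duration(pats$records)
    series <- extract_seed_series(pats, ordering, at$seed_center, mask, radius = 6)
    ymat <- masked_rows(flatten_masked(pats, mask), series$subject)
    recs <- pats$records[series$subject, ]
    zmat <- cbind(recs$age, as.numeric(recs$sex == "F"), recs$tiv, series$interval)
    fit <- signed_path_gc(series$seed, ymat, zmat)
    fol <- which(sphere_mask(ds$grid, at$follower_center, at$follower_radius))
    fit$path[which(mask) %in% fol]
  }
  pos <- run_one(0.8, 71)
  neg <- run_one(-0.8, 71)
  expect_gt(mean(pos > 0), 0.9)
  expect_gt(mean(neg < 0), 0.9)
  expect_gt(mean(sign(pos) != sign(neg)), 0.9)
})

test_that("tidy and glance summarise gc fits", {
  set.seed(44)
  x <- rnorm(30)
  y <- matrix(rnorm(30 * 5), 30, 5)
  fit <- signed_path_gc(x, y)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 5L)
  expect_named(td, c("voxel", "path", "autoreg", "path_se", "sigma"))
  gl <- glance(fit)
  expect_equal(gl$n_voxels, 5L)
  expect_equal(gl$order, 1L)
  expect_equal(gl$n_usable, 29L)
})
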