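test_that("phantom template is a bounded head-like field on a centred grid", {
  ph <- make_phantom_grid(c(24, 28, 24), 3)
  tpl <- as.numeric(ph$template)
  expect_lte(max(tpl), 0.6 + 1e-6)
  expect_gte(min(tpl), 0)
  # ellipsoid occupancy by brute-force voxel counting
  frac <- mean(tpl > 0.3)
  expect_gt(frac, 0.5)
  expect_lt(frac, 0.7)
  # 1.5 mm voxels give a +/-1.5 affine diagonal and exact round trips
  ph2 <- make_phantom_grid(c(8, 8, 8), 1.5)
  expect_equal(diag(ph2$grid$affine)[1:3], rep(1.5, 3))
  ijk <- rbind(c(0, 0, 0), c(7, 7, 7))
  expect_lt(max(abs(mm_to_vox(ph2$grid, vox_to_mm(ph2$grid, ijk)) - ijk)), 1e-6)
  expect_error(make_phantom_grid(c(4, 8, 8)), "bad shape")
})

test_that("cohorts are deterministic and follow the requested distributions", {
  spec <- cohort_spec(rng_seed = 42L)
  expect_identical(simulate_cohort(spec), simulate_cohort(spec))

  flat <- cohort_spec(
    age_sd = 0, duration_sd = 0, tiv_sd = 0,
    n_patients = 5, n_controls = 3, rng_seed = 1
  )
  recs <- simulate_cohort(flat)
  expect_true(all(recs$age == flat$age_mean))
  expect_true(all(recs$duration[recs$group == "patient"] == flat$duration_mean))
  expect_true(all(is.na(recs$duration[recs$group == "control"])))
})

test_that("sampled durations match the truncated-normal mean from quadrature", {
  spec <- cohort_spec(n_patients = 100000L, n_controls = 2L, rng_seed = 7L)
  recs <- simulate_cohort(spec)
  d <- recs$duration[recs$group == "patient"]
  expect_gte(min(d), 0.1)
  # independent oracle: moments of N(9.24, 6.61^2) truncated below at 0.1
  mu <- spec$duration_mean
  sd <- spec$duration_sd
  zmass <- 1 - pnorm(0.1, mu, sd)
  m1 <- integrate(function(x) x * dnorm(x, mu, sd), 0.1, Inf)$value / zmass
  m2 <- integrate(function(x) x^2 * dnorm(x, mu, sd), 0.1, Inf)$value / zmass
  se <- sqrt((m2 - m1^2) / length(d))
  expect_lt(abs(mean(d) - m1), 3 * se)
})

test_that("noise-free construction identities hold exactly", {
  ph <- make_phantom_grid()
  recs <- simulate_cohort(cohort_spec(n_patients = 6, n_controls = 3, rng_seed = 5))
  at0 <- atrophy_spec(
    seed_slope = 0, lag_coeff = 0, noise_sd = 0, smooth_fwhm = 0
  )
  ds <- simulate_gmv_dataset(recs, ph, at0, rng_seed = 1)
  # null effects: every volume is template + nuisance terms only
  tpl <- as.numeric(ph$template)
  age_c <- recs$age - mean(recs$age)
  tiv_c <- recs$tiv - mean(recs$tiv)
  fol <- which(sphere_mask(ph$grid, at0$follower_center, at0$follower_radius))
  for (i in seq_len(nrow(recs))) {
    want <- tpl + at0$age_slope * age_c[i] + at0$tiv_slope * tiv_c[i]
    if (recs$group[i] == "patient") want[fol] <- tpl[fol] # lag term only there
    expect_equal(as.numeric(ds$data[, , , i]), want, tolerance = 1e-12)
  }

  # exact lag-1 identity for the follower mean
  atg <- atrophy_spec(noise_sd = 0, smooth_fwhm = 0, lag_coeff = 0.8)
  dsg <- simulate_gmv_dataset(recs, ph, atg, rng_seed = 1)
  seed_idx <- which(sphere_mask(ph$grid, atg$seed_center, atg$seed_radius))
  pat <- which(recs$group == "patient")
  ord <- pat[order(recs$duration[pat], recs$id[pat])]
  s_prev <- 0.6
  for (i in ord) {
    flat <- as.numeric(dsg$data[, , , i])
    fol_mean <- mean(flat[fol])
    tpl_fol <- mean(tpl[fol])
    expect_equal(fol_mean, tpl_fol + 0.8 * (s_prev - 0.6), tolerance = 1e-12)
    s_prev <- mean(flat[seed_idx])
  }
})

test_that("overlapping planted regions are rejected", {
  ph <- make_phantom_grid()
  recs <- simulate_cohort(cohort_spec(n_patients = 3, n_controls = 2, rng_seed = 1))
  at <- atrophy_spec(follower_center = c(18, 12, -12)) # 3 mm from the seed
  expect_error(simulate_gmv_dataset(recs, ph, at), "overlapping regions")
})

test_that("OLS of realised seed means on duration recovers the planted slope", {
  # regression-recovery oracle: unsmoothed phantom so the in-sphere mean
  # carries the nominal slope; nuisance slopes off so duration is the only
  # systematic term inside the sphere
  at <- atrophy_spec(smooth_fwhm = 0, age_slope = 0, tiv_slope = 0)
  slopes <- vapply(1:10, function(s) {
    ds <- simulate_phantom(cohort_spec(rng_seed = 400 + s), at)
    seed_reg <- sphere_mask(ds$grid, at$seed_center, at$seed_radius)
    pat <- ds$records$group == "patient"
    flat <- matrix(ds$data, nrow = prod(ds$grid$shape))
    sv <- colMeans(flat[which(seed_reg), pat, drop = FALSE])
    unname(coef(lm(sv ~ ds$records$duration[pat]))[2])
  }, numeric(1))
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - (-0.005)), 3 * se)
})

test_that("datasets are bit-identical across repeated generation", {
  ds1 <- simulate_phantom(cohort_spec(rng_seed = 9))
  ds2 <- simulate_phantom(cohort_spec(rng_seed = 9))
  expect_identical(ds1$data, ds2$data)
  expect_identical(ds1$records, ds2$records)
})

test_that("gaussian smoothing matches its closed form and conserves mass", {
  g <- image_grid(c(21, 21, 21), 1.5)
  v <- array(0, c(21, 21, 21))
  v[11, 11, 11] <- 1
  vol <- gmv_volume(v, g)
  expect_identical(as.numeric(smooth_volume(vol, 0)), as.numeric(vol))
  expect_error(smooth_volume(vol, -1), "bad fwhm")

  out <- smooth_volume(vol, 6)
  sigma <- (6 / 1.5) / (2 * sqrt(2 * log(2)))
  g1 <- function(d) exp(-d^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
  for (d in -3:3) {
    expect_equal(out[11 + d, 11, 11], g1(d) * g1(0)^2, tolerance = 1e-3)
  }
  # interior support: total mass conserved
  expect_equal(sum(out), 1, tolerance = 1e-6)

  # constant volume is unchanged away from the zero-padded boundary
  const <- gmv_volume(array(0.37, c(21, 21, 21)), g)
  sm <- smooth_volume(const, 4)
  expect_equal(sm[8:14, 8:14, 8:14], const[8:14, 8:14, 8:14], tolerance = 1e-9)
})
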