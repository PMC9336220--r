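#' Cohort specification for synthetic subjects
#'
#' Defaults describe a two-group cohort matching the demographic profile the
#' pipeline is designed for: 81 patients (age 54.15 +/- 9.26 y, illness
#' duration 9.24 +/- 6.61 y truncated at 0.1, 51/81 male) and 48 controls
#' drawn from the same age/sex distribution. TIV is drawn at
#' 1.45e6 +/- 1.3e5 mm^3.
#'
#' @param n_patients,n_controls Group sizes (each >= 2).
#' @param age_mean,age_sd Age distribution in years.
#' @param duration_mean,duration_sd Illness-duration distribution in years
#'   (patients only; truncated below at 0.1).
#' @param sex_ratio Fraction male in `[0, 1]`.
#' @param tiv_mean,tiv_sd Total intracranial volume in mm^3.
#' @param rng_seed Integer seed; the cohort is a deterministic function of the
#'   spec.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 81L, n_controls = 48L,
                        age_mean = 54.15, age_sd = 9.26,
                        duration_mean = 9.24, duration_sd = 6.61,
                        sex_ratio = 51 / 81,
                        tiv_mean = 1.45e6, tiv_sd = 1.3e5,
                        rng_seed = 1L) {
  spec <- list(
    n_patients = as.integer(n_patients), n_controls = as.integer(n_controls),
    age_mean = age_mean, age_sd = age_sd,
    duration_mean = duration_mean, duration_sd = duration_sd,
    sex_ratio = sex_ratio, tiv_mean = tiv_mean, tiv_sd = tiv_sd,
    rng_seed = as.integer(rng_seed)
  )
  if (spec$n_patients < 2L || spec$n_controls < 2L) {
    stop("counts must be >= 2", call. = FALSE)
  }
  if (age_sd < 0 || duration_sd < 0 || tiv_sd < 0) {
    stop("sds must be >= 0", call. = FALSE)
  }
  if (sex_ratio < 0 || sex_ratio > 1) stop("sex_ratio must be in [0,1]", call. = FALSE)
  structure(spec, class = "cohort_spec")
}

#' Planted-atrophy specification for the phantom
#'
#' Encodes the lag-1 structure the causal analysis is built to detect: a seed
#' sphere whose GMV declines linearly with illness duration, and a follower
#' sphere whose GMV tracks the previous-ranked patient's realised seed mean
#' with coefficient `lag_coeff`. Age and TIV act as global nuisance slopes;
#' i.i.d. Gaussian voxel noise is added and the volume smoothed.
#'
#' @param seed_center,follower_center MNI mm coordinates inside the phantom.
#' @param seed_radius,follower_radius Sphere radii in mm (> 0).
#' @param seed_slope GMV loss per year of duration (> 0 means loss).
#' @param lag_coeff Dimensionless lag-1 coupling (`gamma`); 0 disables the
#'   follower effect.
#' @param age_slope,tiv_slope Nuisance slopes (GMV units per year / per mm^3).
#' @param noise_sd Voxelwise noise sd in GMV units, before smoothing.
#' @param smooth_fwhm Smoothing FWHM in mm applied to each final volume.
#' @return An `atrophy_spec` list.
#' @export
atrophy_spec <- function(seed_center = c(15, 12, -12), seed_radius = 9,
                         seed_slope = 0.005,
                         follower_center = c(-15, -18, 9), follower_radius = 9,
                         lag_coeff = 0.8,
                         age_slope = -0.002, tiv_slope = 2e-8,
                         noise_sd = 0.02, smooth_fwhm = 6) {
  if (seed_radius <= 0 || follower_radius <= 0) stop("radii must be > 0", call. = FALSE)
  if (smooth_fwhm < 0) stop("bad fwhm: must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(
    list(
      seed_center = seed_center, seed_radius = seed_radius,
      seed_slope = seed_slope,
      follower_center = follower_center, follower_radius = follower_radius,
      lag_coeff = lag_coeff,
      age_slope = age_slope, tiv_slope = tiv_slope,
      noise_sd = noise_sd, smooth_fwhm = smooth_fwhm
    ),
    class = "atrophy_spec"
  )
}

PHANTOM_G0 <- 0.6

#' Build the phantom grid and head-like baseline template
#'
#' The template is an ellipsoid of GM density `0.6` occupying roughly 60% of
#' the grid (semi-axes 1.05x the half-extents, clipped by the box), smoothed
#' at 2 voxels FWHM so its boundary is soft. The affine centres the grid on
#' MNI (0, 0, 0).
#'
#' @param shape Grid shape, each axis >= 8.
#' @param voxel_size Voxel size in mm (scalar or length 3).
#' @return A list with elements `grid` ([image_grid()]) and `template`
#'   ([gmv_volume()]).
#' @export
make_phantom_grid <- function(shape = c(24L, 28L, 24L), voxel_size = 3) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L)) {
    stop("bad shape: need 3 dims each >= 8", call. = FALSE)
  }
  grid <- image_grid(shape, voxel_size)
  xyz <- grid_coords_mm(grid)
  semi <- 1.05 * grid$voxel_size * (shape - 1L) / 2
  inside <- (xyz[, 1] / semi[1])^2 + (xyz[, 2] / semi[2])^2 +
    (xyz[, 3] / semi[3])^2 <= 1
  template <- array(PHANTOM_G0 * inside, dim = shape)
  template <- smooth_array(template, fwhm_vox = c(2, 2, 2))
  list(grid = grid, template = gmv_volume(template, grid))
}

#' Draw a synthetic cohort
#'
#' Ages, TIV and (patients) durations are Gaussian per the cohort spec; durations are
#' truncated below at 0.1 years by inverse-CDF sampling; sex is Bernoulli in
#' the male fraction. Deterministic given `spec$rng_seed`; the caller's RNG
#' state is left untouched.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble of subject records (`id`, `group`, `age`, `sex`, `tiv`,
#'   `duration`).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$rng_seed, {
    n <- spec$n_patients + spec$n_controls
    grp <- rep(c("patient", "control"), c(spec$n_patients, spec$n_controls))
    age <- stats::rnorm(n, spec$age_mean, spec$age_sd)
    sex <- ifelse(stats::runif(n) < spec$sex_ratio, "M", "F")
    tiv <- stats::rnorm(n, spec$tiv_mean, spec$tiv_sd)
    dur <- rep(NA_real_, n)
    dur[grp == "patient"] <- rtruncnorm_low(
      spec$n_patients, spec$duration_mean, spec$duration_sd,
      lower = 0.1
    )
    tibble::tibble(
      id = sprintf("%s%03d", ifelse(grp == "patient", "p", "c"),
        c(seq_len(spec$n_patients), seq_len(spec$n_controls))
      ),
      group = grp, age = age, sex = sex, tiv = tiv, duration = dur
    )
  })
}

# inverse-CDF sampler for a normal truncated below at `lower`
rtruncnorm_low <- function(n, mean, sd, lower) {
  if (sd == 0) {
    return(rep(max(mean, lower), n))
  }
  p_lo <- stats::pnorm(lower, mean, sd)
  stats::qnorm(p_lo + stats::runif(n) * (1 - p_lo), mean, sd)
}

#' Simulate a GMV dataset with planted progressive atrophy
#'
#' Patients are ranked by ascending illness duration (ties by id). For the
#' patient at rank r with duration d:
#' seed-sphere voxels get `template - seed_slope * d` plus the nuisance terms;
#' follower-sphere voxels get `template + lag_coeff * (S[r-1] - 0.6)` where
#' `S[r-1]` is the realised (noisy, smoothed) seed mean of the previous-ranked
#' patient and `S[0] = 0.6`; all remaining voxels get the template plus
#' nuisance terms (`age_slope * (age - mean age)` and
#' `tiv_slope * (tiv - mean tiv)`, means over the whole cohort). Controls get
#' template plus nuisance only. Each volume then receives i.i.d.
#' `N(0, noise_sd^2)` voxel noise and is smoothed at `smooth_fwhm`. With
#' `noise_sd = 0` and `smooth_fwhm = 0` the construction is exact.
#'
#' @param records Cohort tibble from [simulate_cohort()].
#' @param phantom List from [make_phantom_grid()] (`grid` + `template`).
#' @param atrophy An [atrophy_spec()].
#' @param rng_seed Integer seed for the voxel noise.
#' @return A [gmv_dataset()] whose `records` carry the cohort.
#' @export
simulate_gmv_dataset <- function(records, phantom, atrophy, rng_seed = 1L) {
  records <- validate_records(records)
  grid <- phantom$grid
  template <- as.numeric(phantom$template)
  seed_idx <- which(sphere_mask(grid, atrophy$seed_center, atrophy$seed_radius))
  fol_idx <- which(sphere_mask(grid, atrophy$follower_center, atrophy$follower_radius))
  if (length(intersect(seed_idx, fol_idx)) > 0L) {
    stop("overlapping regions: seed and follower spheres intersect", call. = FALSE)
  }
  for (ctr in list(atrophy$seed_center, atrophy$follower_center)) {
    v <- mm_to_vox(grid, ctr)
    if (any(v < 0) || any(v > grid$shape - 1L)) {
      stop("region centre outside the phantom grid", call. = FALSE)
    }
  }
  n <- nrow(records)
  age_c <- records$age - mean(records$age)
  tiv_c <- records$tiv - mean(records$tiv)
  is_pat <- records$group == "patient"
  rank_order <- order(records$duration[is_pat], records$id[is_pat])
  pat_rows <- which(is_pat)[rank_order]

  fwhm_vox <- atrophy$smooth_fwhm / grid$voxel_size
  nvox <- prod(grid$shape)
  data <- array(NA_real_, dim = c(grid$shape, n))
  with_seed(rng_seed, {
    noise <- if (atrophy$noise_sd > 0) {
      matrix(stats::rnorm(nvox * n, 0, atrophy$noise_sd), nvox, n)
    } else {
      matrix(0, nvox, n)
    }
    finish <- function(vals, i) {
      vals <- vals + noise[, i]
      if (atrophy$smooth_fwhm > 0) {
        vals <- as.numeric(smooth_array(array(vals, grid$shape), fwhm_vox))
      }
      vals
    }
    for (i in which(!is_pat)) {
      vals <- template + atrophy$age_slope * age_c[i] + atrophy$tiv_slope * tiv_c[i]
      data[, , , i] <- finish(vals, i)
    }
    s_prev <- PHANTOM_G0
    for (r in seq_along(pat_rows)) {
      i <- pat_rows[r]
      nuis <- atrophy$age_slope * age_c[i] + atrophy$tiv_slope * tiv_c[i]
      vals <- template + nuis
      vals[seed_idx] <- template[seed_idx] - atrophy$seed_slope * records$duration[i] + nuis
      vals[fol_idx] <- template[fol_idx] + atrophy$lag_coeff * (s_prev - PHANTOM_G0)
      vals <- finish(vals, i)
      s_prev <- mean(vals[seed_idx])
      data[, , , i] <- vals
    }
  })
  structure(
    list(records = records, data = data, grid = grid),
    class = "gmv_dataset"
  )
}

#' One-call phantom dataset
#'
#' Convenience wrapper: draws the cohort, builds the grid/template, and
#' simulates the volumes. The voxel-noise seed is derived from the cohort seed
#' (`rng_seed + 1000`).
#'
#' @param cohort A [cohort_spec()].
#' @param atrophy An [atrophy_spec()].
#' @param shape,voxel_size Passed to [make_phantom_grid()].
#' @return A [gmv_dataset()].
#' @export
simulate_phantom <- function(cohort = cohort_spec(), atrophy = atrophy_spec(),
                             shape = c(24L, 28L, 24L), voxel_size = 3) {
  records <- simulate_cohort(cohort)
  phantom <- make_phantom_grid(shape, voxel_size)
  simulate_gmv_dataset(records, phantom, atrophy, rng_seed = cohort$rng_seed + 1000L)
}

# evaluate code under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
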