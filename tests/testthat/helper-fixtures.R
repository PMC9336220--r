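# shared fixture builders; everything is generated in code at test time

tiny_grid <- function(shape = c(6L, 6L, 6L), vox = 3) image_grid(shape, vox)

# records with deterministic covariates; patients get durations 1..n_pat
make_records <- function(n_pat = 3L, n_ctl = 3L, durations = seq_len(n_pat)) {
  n <- n_pat + n_ctl
  tibble::tibble(
    id = sprintf(
      "%s%02d", rep(c("p", "c"), c(n_pat, n_ctl)),
      c(seq_len(n_pat), seq_len(n_ctl))
    ),
    group = rep(c("patient", "control"), c(n_pat, n_ctl)),
    age = 50 + seq_len(n),
    sex = rep(c("M", "F"), length.out = n),
    tiv = 1.4e6 + 1e4 * ((seq_len(n) * 7L) %% 11L),
    duration = c(durations, rep(NA_real_, n_ctl))
  )
}

# dataset of pure-noise volumes on a tiny grid
tiny_dataset <- function(n_pat = 3L, n_ctl = 3L, shape = c(6L, 6L, 6L),
                         seed = 1L, sd = 0.05, base = 0.5) {
  grid <- tiny_grid(shape)
  set.seed(seed)
  vols <- lapply(seq_len(n_pat + n_ctl), function(i) {
    gmv_volume(array(base + rnorm(prod(shape), 0, sd), shape), grid)
  })
  gmv_dataset(make_records(n_pat, n_ctl), vols, grid)
}

# quick null phantom (no planted effects) for inference tests
null_phantom <- function(seed, n_pat = 20L, n_ctl = 20L, smooth_fwhm = 6) {
  simulate_phantom(
    cohort_spec(n_patients = n_pat, n_controls = n_ctl, rng_seed = seed),
    atrophy_spec(
      seed_slope = 0, lag_coeff = 0, age_slope = 0, tiv_slope = 0,
      smooth_fwhm = smooth_fwhm
    )
  )
}

# largest Dice between any surviving positive cluster and a region
best_pos_dice <- function(tab, region) {
  mem <- attr(tab, "members")
  keep <- which(tab$sign == "pos" & tab$survives)
  if (length(keep) == 0L) {
    return(0)
  }
  max(vapply(mem[keep], dice_overlap, numeric(1), region = region))
}
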