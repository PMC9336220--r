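#' Pipeline configuration
#'
#' One object drives the three analyses (overall comparison, stage-specific
#' comparisons, seed-based CaSCN). Data come either from NIfTI files plus a
#' covariate table (`images` / `covariates`) or from the synthetic phantom
#' (`phantom = TRUE`, with `cohort` / `atrophy` specs). Defaults mirror the
#' pipeline's reference settings: voxel p 0.001, cluster p 0.01, 6 mm seed
#' sphere, first-order GC, spatial z-scoring, median duration split.
#'
#' @param images Character vector of NIfTI paths (file input).
#' @param covariates Covariate table path (file input).
#' @param phantom Use the synthetic phantom instead of files?
#' @param cohort,atrophy Phantom specs ([cohort_spec()], [atrophy_spec()]).
#' @param shape,voxel_size Phantom grid ([make_phantom_grid()]).
#' @param mask `"auto"` (optimal-threshold mask) or a NIfTI path whose
#'   voxels > 0.5 define the mask.
#' @param stage_strategy `"median_two_stage"` or `"fixed_three_stage"`.
#' @param stage_boundaries Optional explicit boundaries (years).
#' @param seed_mni Seed centre in MNI mm. `NULL` (default) uses the phantom's
#'   planted seed centre for phantom runs; file runs must set it (the
#'   classical right-temporal-pole choice is `c(32, 15, -26)`).
#' @param seed_radius Seed sphere radius in mm (default 6).
#' @param gc_order GC model order p (default 1).
#' @param z_mode `"spatial"` or `"wald"` (see [z_score_map()]).
#' @param direction `"forward"` (seed -> voxel) or `"reverse"`.
#' @param voxel_p,cluster_p GRF thresholds (defaults 0.001 / 0.01).
#' @param connectivity Cluster connectivity (default 26).
#' @param rng_seed Integer seed for all pipeline randomness.
#' @param output_dir Optional directory for NIfTI maps, TSV tables and the
#'   provenance record.
#' @return A `cascn_config` list.
#' @export
cascn_config <- function(images = NULL, covariates = NULL,
                         phantom = is.null(images),
                         cohort = cohort_spec(), atrophy = atrophy_spec(),
                         shape = c(24L, 28L, 24L), voxel_size = 3,
                         mask = "auto",
                         stage_strategy = "median_two_stage",
                         stage_boundaries = NULL,
                         seed_mni = NULL, seed_radius = 6,
                         gc_order = 1L, z_mode = "spatial",
                         direction = "forward",
                         voxel_p = 0.001, cluster_p = 0.01,
                         connectivity = 26L, rng_seed = 1L,
                         output_dir = NULL) {
  if (!phantom && (is.null(images) || is.null(covariates))) {
    stop("missing input: images and covariates are required unless phantom = TRUE",
      call. = FALSE
    )
  }
  if (voxel_p <= 0 || voxel_p >= 1 || cluster_p <= 0 || cluster_p >= 1) {
    stop("thresholds must lie in (0, 1)", call. = FALSE)
  }
  if (phantom && is.null(seed_mni)) seed_mni <- atrophy$seed_center
  if (is.null(seed_mni)) {
    stop("missing field: seed_mni must be set for file input", call. = FALSE)
  }
  structure(
    list(
      images = images, covariates = covariates, phantom = phantom,
      cohort = cohort, atrophy = atrophy,
      shape = as.integer(shape), voxel_size = voxel_size,
      mask = mask, stage_strategy = stage_strategy,
      stage_boundaries = stage_boundaries,
      seed_mni = seed_mni, seed_radius = seed_radius,
      gc_order = as.integer(gc_order), z_mode = z_mode,
      direction = direction,
      voxel_p = voxel_p, cluster_p = cluster_p,
      connectivity = as.integer(connectivity),
      rng_seed = as.integer(rng_seed), output_dir = output_dir
    ),
    class = "cascn_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys match the [cascn_config()] arguments; `cohort` and
#' `atrophy` may be nested maps of the respective spec arguments.
#'
#' @param path YAML file.
#' @return A `cascn_config`.
#' @export
read_cascn_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$cohort)) raw$cohort <- do.call(cohort_spec, raw$cohort)
  if (!is.null(raw$atrophy)) raw$atrophy <- do.call(atrophy_spec, raw$atrophy)
  for (k in c("shape", "seed_mni")) {
    if (!is.null(raw[[k]])) raw[[k]] <- unlist(raw[[k]])
  }
  do.call(cascn_config, raw)
}

#' Materialise the configured dataset
#'
#' @param config A [cascn_config()].
#' @return A [gmv_dataset()] (simulated or loaded).
#' @export
load_config_dataset <- function(config) {
  if (config$phantom) {
    cohort <- config$cohort
    cohort$rng_seed <- config$rng_seed
    simulate_phantom(cohort, config$atrophy, config$shape, config$voxel_size)
  } else {
    load_gmv_dataset(config$images, config$covariates)
  }
}

config_mask <- function(config, dataset) {
  if (identical(config$mask, "auto")) {
    optimal_threshold_mask(dataset)
  } else {
    v <- read_gmv_volume(config$mask)
    gmv_mask(array(as.numeric(v) > 0.5, dim = dim(v)), vol_grid(v))
  }
}

run_step <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Overall patient-vs-control comparison
#'
#' Optimal-threshold mask, group + age/sex/TIV design, voxelwise t map for
#' the group contrast, and GRF cluster correction with both sign branches
#' (patients < controls reported as the negative branch).
#'
#' @param config A [cascn_config()].
#' @param dataset Optional pre-built [gmv_dataset()] (otherwise taken from
#'   the config).
#' @return A list: `table` (cluster table), `map` (t `stat_map`), `mask`,
#'   `design`.
#' @export
run_overall <- function(config, dataset = NULL) {
  run_step("overall", {
    if (is.null(dataset)) dataset <- load_config_dataset(config)
    mask <- config_mask(config, dataset)
    design <- build_design(dataset$records, include_group = TRUE)
    fit <- fit_glm_voxelwise(flatten_masked(dataset, mask), design)
    contrast <- as.numeric(design$columns == "group")
    map <- t_contrast(fit, contrast)
    table <- correct_map(
      map, fit$residuals, mask,
      voxel_p = config$voxel_p, cluster_p = config$cluster_p,
      connectivity = config$connectivity
    )
    list(table = table, map = map, mask = mask, design = design)
  })
}

#' Stage-specific comparisons
#'
#' Splits patients (plus matched controls) into duration stages and repeats
#' the overall comparison within each stage, recomputing the analysis mask
#' per stage subgroup.
#'
#' @inheritParams run_overall
#' @return A list: `split` (the [split_stages()] object) and `stages`, one
#'   `run_overall()`-style result per stage.
#' @export
run_stages <- function(config, dataset = NULL) {
  run_step("stages", {
    if (is.null(dataset)) dataset <- load_config_dataset(config)
    recs <- dataset$records
    split <- split_stages(
      recs[recs$group == "patient", ], recs[recs$group == "control", ],
      strategy = config$stage_strategy, boundaries = config$stage_boundaries
    )
    stages <- lapply(seq_len(split$n_stages), function(s) {
      ids <- split$assignment$id[split$assignment$stage == s]
      sub <- subset_subjects(dataset, recs$id %in% ids)
      run_step(sprintf("stage %d", s), {
        mask <- config_mask(config, sub)
        design <- build_design(sub$records, include_group = TRUE)
        fit <- fit_glm_voxelwise(flatten_masked(sub, mask), design)
        map <- t_contrast(fit, as.numeric(design$columns == "group"))
        table <- correct_map(
          map, fit$residuals, mask,
          voxel_p = config$voxel_p, cluster_p = config$cluster_p,
          connectivity = config$connectivity
        )
        list(table = table, map = map, mask = mask, design = design)
      })
    })
    names(stages) <- paste0("stage", seq_len(split$n_stages))
    list(split = split, stages = stages)
  })
}

#' Seed-based CaSCN analysis
#'
#' Orders the patients by illness duration, extracts the seed sphere mean as
#' the pseudo time series, fits the signed-path GC model per voxel with age,
#' sex, TIV and duration-interval covariates, z-scores the coefficient map,
#' and applies GRF cluster correction to both sign branches.
#'
#' @inheritParams run_overall
#' @return A list: `table` (signed cluster table), `map` (z `stat_map`),
#'   `coef_map`, `fit_summary` ([glance()] row), `series` (the pseudo time
#'   series tibble), `mask`.
#' @export
run_cascn <- function(config, dataset = NULL) {
  run_step("cascn", {
    if (is.null(dataset)) dataset <- load_config_dataset(config)
    mask <- config_mask(config, dataset)
    pat <- subset_subjects(dataset, dataset$records$group == "patient")
    ordering <- order_by_duration(pat$records)
    series <- extract_seed_series(
      pat, ordering, config$seed_mni, mask,
      radius = config$seed_radius
    )
    y <- masked_rows(flatten_masked(pat, mask), series$subject)
    recs <- pat$records[series$subject, ]
    z <- cbind(
      age = recs$age, sex = as.numeric(recs$sex == "F"),
      tiv = recs$tiv, interval = series$interval
    )
    fit <- signed_path_gc(series$seed, y, z,
      p = config$gc_order, direction = config$direction
    )

    fin <- is.finite(fit$path)
    mask2 <- mask
    if (!all(fin)) {
      excl <- which(mask)[!fin]
      m2 <- array(as.logical(mask), dim = vol_grid(mask)$shape)
      m2[excl] <- FALSE
      mask2 <- gmv_mask(m2, vol_grid(mask))
    }
    coef_map <- stat_map(fit$path[fin], mask2,
      stat_kind = "coefficient", df = fit$df,
      provenance = sprintf(
        "signed-path GC (%s, order %d), seed [%s] r=%gmm",
        fit$direction, fit$order,
        paste(config$seed_mni, collapse = ","), config$seed_radius
      )
    )
    map <- z_score_map(coef_map, mode = config$z_mode, se = fit$path_se[fin])
    table <- correct_map(
      map, fit$residuals[, fin, drop = FALSE], mask2,
      voxel_p = config$voxel_p, cluster_p = config$cluster_p,
      connectivity = config$connectivity
    )
    list(
      table = table, map = map, coef_map = coef_map,
      fit_summary = glance(fit), series = series, mask = mask2
    )
  })
}

#' Run the full pipeline
#'
#' Simulates or loads the dataset, then runs the overall comparison, the
#' stage-specific comparisons and the seed-based CaSCN analysis, collecting
#' cluster tables and provenance. With an `output_dir` configured, maps
#' (NIfTI), tables (TSV) and a `provenance.yaml` are written.
#'
#' @param config A [cascn_config()].
#' @param dry_run Print the stage plan and return without computing.
#' @return A `run_report`: list with `overall`, `stages`, `cascn`,
#'   `provenance`.
#' @export
run_all <- function(config, dry_run = FALSE) {
  plan <- c(
    if (config$phantom) "simulate" else "load",
    "overall", sprintf("stages (%s)", config$stage_strategy),
    sprintf("cascn (%s, order %d)", config$direction, config$gc_order)
  )
  if (dry_run) {
    cat("planned stages:", paste(plan, collapse = " -> "), "\n")
    return(invisible(plan))
  }
  dataset <- run_step(plan[1], load_config_dataset(config))
  overall <- run_overall(config, dataset)
  stages <- run_stages(config, dataset)
  cascn <- run_cascn(config, dataset)
  provenance <- list(
    package = as.character(utils::packageVersion("cascnr")),
    config = config_as_list(config),
    config_hash = rlang::hash(config_as_list(config)),
    rng_seed = config$rng_seed
  )
  report <- structure(
    list(
      overall = overall, stages = stages, cascn = cascn,
      provenance = provenance
    ),
    class = "run_report"
  )
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

# provenance echo of the analysis parameters; output_dir is a location, not
# an analysis setting, so it stays out of the record (and its hash)
config_as_list <- function(config) {
  out <- lapply(unclass(config), function(x) if (is.list(x)) unclass(x) else x)
  out$output_dir <- NULL
  out[!vapply(out, is.null, logical(1))]
}

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cluster_table(report$overall$table, file.path(dir, "overall_clusters.tsv"))
  write_gmv_volume(as_volume(report$overall$map), file.path(dir, "overall_t.nii.gz"))
  for (nm in names(report$stages$stages)) {
    write_cluster_table(
      report$stages$stages[[nm]]$table,
      file.path(dir, sprintf("%s_clusters.tsv", nm))
    )
  }
  write_cluster_table(report$cascn$table, file.path(dir, "cascn_clusters.tsv"))
  write_gmv_volume(as_volume(report$cascn$map), file.path(dir, "cascn_z.nii.gz"))
  yaml::write_yaml(report$provenance, file.path(dir, "provenance.yaml"))
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  surv <- function(tab) sprintf("%d clusters (%d surviving)", nrow(tab), sum(tab$survives))
  cat("<run_report>\n")
  cat("  overall: ", surv(x$overall$table), "\n", sep = "")
  for (nm in names(x$stages$stages)) {
    cat("  ", nm, ": ", surv(x$stages$stages[[nm]]$table), "\n", sep = "")
  }
  cat("  cascn:   ", surv(x$cascn$table), "\n", sep = "")
  invisible(x)
}
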