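#' Read and write GMV volumes as NIfTI-1
#'
#' Volumes are stored with the grid affine in both sform and qform; voxel
#' indices are 0-based per the NIfTI convention, so the affine read back maps
#' indices to MNI mm exactly as [vox_to_mm()] does.
#'
#' @param volume A [gmv_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `write_gmv_volume()` returns `path` invisibly; `read_gmv_volume()`
#'   returns a `gmv_volume`.
#' @export
write_gmv_volume <- function(volume, path) {
  g <- vol_grid(volume)
  img <- RNifti::asNifti(array(as.numeric(volume), dim = g$shape))
  RNifti::pixdim(img) <- g$voxel_size
  RNifti::sform(img) <- structure(g$affine, code = 2L)
  RNifti::qform(img) <- structure(g$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' @rdname write_gmv_volume
#' @export
read_gmv_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("expected a 3D NIfTI volume: ", path, call. = FALSE)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  g <- image_grid(d, sqrt(colSums(aff[1:3, 1:3]^2)), aff)
  gmv_volume(array(as.numeric(img), dim = d), g)
}

#' Load a GMV dataset from NIfTI files and a covariate table
#'
#' Images are matched to table rows by position after both are ordered: rows
#' are taken in file order when `id` matches the filename stems, otherwise in
#' table order. All images must share one grid (affines equal within 1e-4).
#'
#' @param image_paths Character vector of NIfTI paths, one per subject.
#' @param covariate_table Path to a CSV/TSV with header
#'   `id,group,age,sex,tiv,duration` (duration empty for controls).
#' @return A [gmv_dataset()].
#' @export
load_gmv_dataset <- function(image_paths, covariate_table) {
  if (length(image_paths) == 0L) {
    stop("cardinality: no image paths supplied", call. = FALSE)
  }
  records <- read_covariates(covariate_table)
  if (nrow(records) != length(image_paths)) {
    stop("cardinality: covariate rows and images differ in number", call. = FALSE)
  }
  stems <- sub("\\.nii(\\.gz)?$", "", basename(image_paths))
  if (setequal(stems, records$id)) {
    records <- records[match(stems, records$id), , drop = FALSE]
  }
  volumes <- lapply(image_paths, read_gmv_volume)
  gmv_dataset(records, volumes)
}

#' Read or write a subject covariate table
#'
#' @param path CSV (or TSV, by extension) file with header exactly
#'   `id,group,age,sex,tiv,duration`.
#' @return A validated tibble of subject records.
#' @export
read_covariates <- function(path) {
  reader <- if (grepl("\\.tsv$", path)) readr::read_tsv else readr::read_csv
  tab <- reader(
    path,
    col_types = readr::cols(
      id = readr::col_character(), group = readr::col_character(),
      age = readr::col_double(), sex = readr::col_character(),
      tiv = readr::col_double(), duration = readr::col_double()
    ),
    progress = FALSE
  )
  validate_records(tab)
}

#' @param records A subject record tibble.
#' @rdname read_covariates
#' @export
write_covariates <- function(records, path) {
  readr::write_csv(validate_records(records), path, na = "")
  invisible(path)
}

#' Write every volume of a dataset plus its covariates
#'
#' Writes `<id>.nii.gz` per subject plus `covariates.csv` and a
#' `provenance.yaml` sidecar into `dir`.
#'
#' @param dataset A [gmv_dataset()].
#' @param dir Output directory (created if needed).
#' @param provenance Optional named list recorded in the YAML sidecar.
#' @return Invisibly, the vector of image paths written.
#' @export
write_gmv_dataset <- function(dataset, dir, provenance = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(dataset$records$id, ".nii.gz"))
  for (i in seq_along(paths)) {
    write_gmv_volume(get_volume(dataset, i), paths[i])
  }
  write_covariates(dataset$records, file.path(dir, "covariates.csv"))
  if (!is.null(provenance)) {
    yaml::write_yaml(provenance, file.path(dir, "provenance.yaml"))
  }
  invisible(paths)
}
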