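#' Assemble a GMV dataset
#'
#' Binds one volume per subject with the subject covariate table. All volumes
#' must share one grid (affines equal within 1e-4 mm). Group is encoded
#' `"patient"` / `"control"`; illness duration must be present for every
#' patient and absent (`NA`) for every control.
#'
#' @param records Data frame with columns `id`, `group`, `age`, `sex`, `tiv`,
#'   `duration`; one row per volume, in volume order.
#' @param volumes List of `gmv_volume`s (or 3D arrays on `grid`).
#' @param grid Optional [image_grid()]; taken from the first volume when
#'   omitted.
#' @return A `gmv_dataset`: list with `records` (tibble), `data` (4D array,
#'   subject as the 4th axis) and `grid`.
#' @export
gmv_dataset <- function(records, volumes, grid = NULL) {
  records <- validate_records(records)
  if (length(volumes) < 2L || nrow(records) < 2L) {
    stop("cardinality: need at least 2 subjects", call. = FALSE)
  }
  if (nrow(records) != length(volumes)) {
    stop("cardinality: records and volumes differ in length", call. = FALSE)
  }
  if (is.null(grid)) grid <- vol_grid(volumes[[1]])
  if (is.null(grid)) stop("no grid supplied and first volume carries none", call. = FALSE)
  for (v in volumes) {
    gv <- vol_grid(v)
    if (!is.null(gv) && !grids_equal(grid, gv)) {
      stop("heterogeneous grids", call. = FALSE)
    }
    if (!identical(dim(v), as.integer(grid$shape))) {
      stop("heterogeneous grids", call. = FALSE)
    }
  }
  data <- array(
    unlist(lapply(volumes, as.vector), use.names = FALSE),
    dim = c(grid$shape, length(volumes))
  )
  structure(
    list(records = records, data = data, grid = grid),
    class = "gmv_dataset"
  )
}

validate_records <- function(records) {
  req <- c("id", "group", "age", "sex", "tiv", "duration")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols) > 0L) {
    stop(
      "covariate table lacks columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  records <- tibble::as_tibble(records)[req]
  records$id <- as.character(records$id)
  records$group <- as.character(records$group)
  records$sex <- as.character(records$sex)
  if (anyDuplicated(records$id)) stop("duplicate subject ids", call. = FALSE)
  if (!all(records$group %in% c("patient", "control"))) {
    stop("group must be 'patient' or 'control'", call. = FALSE)
  }
  if (!all(records$sex %in% c("M", "F"))) {
    stop("sex must be 'M' or 'F'", call. = FALSE)
  }
  pat <- records$group == "patient"
  if (any(pat & !is.finite(records$duration))) {
    stop("missing duration for one or more patients", call. = FALSE)
  }
  if (any(!pat & is.finite(records$duration))) {
    stop("duration must be absent (NA) for controls", call. = FALSE)
  }
  if (any(records$duration[pat] < 0)) {
    stop("duration must be >= 0", call. = FALSE)
  }
  records
}

#' @export
print.gmv_dataset <- function(x, ...) {
  cat(sprintf(
    "<gmv_dataset> %d subjects (%d patients, %d controls) on %s @ %s mm\n",
    nrow(x$records), sum(x$records$group == "patient"),
    sum(x$records$group == "control"),
    paste(x$grid$shape, collapse = "x"),
    paste(format(x$grid$voxel_size, trim = TRUE), collapse = "x")
  ))
  invisible(x)
}

#' Subset a GMV dataset by subject
#'
#' @param dataset A [gmv_dataset()].
#' @param keep Logical or integer index over subjects.
#' @return A `gmv_dataset` restricted to the selected subjects.
#' @export
subset_subjects <- function(dataset, keep) {
  idx <- seq_len(nrow(dataset$records))[keep]
  if (length(idx) < 2L) stop("cardinality: need at least 2 subjects", call. = FALSE)
  structure(
    list(
      records = dataset$records[idx, , drop = FALSE],
      data = dataset$data[, , , idx, drop = FALSE],
      grid = dataset$grid
    ),
    class = "gmv_dataset"
  )
}

#' Extract one subject's volume
#'
#' @param dataset A [gmv_dataset()].
#' @param i Subject index.
#' @return A `gmv_volume`.
#' @export
get_volume <- function(dataset, i) {
  gmv_volume(dataset$data[, , , i], dataset$grid)
}
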