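#' Split patients (and matched controls) into illness-duration stages
#'
#' Two strategies mirror the two grouping conventions the pipeline supports:
#'
#' * `median_two_stage`: the boundary is the patient median m; stage 1 is
#'   duration < m, stage 2 is duration >= m (a patient exactly at the median
#'   falls in stage 2).
#' * `fixed_three_stage`: boundaries (6, 11) years with an inclusive middle
#'   interval — stage 1 is duration < 6, stage 2 is 6 <= duration <= 11,
#'   stage 3 is duration > 11.
#'
#' Controls are allocated to stages by greedy nearest-age matching under
#' capacities proportional to the patient stage sizes (largest-remainder
#' rounding): all (control, stage) pairs are sorted by the absolute distance
#' between the control's age and the stage's patient age mean, then assigned
#' while stage capacity remains. The allocation is deterministic and reported
#' in the returned object.
#'
#' @param patients Patient record tibble (all with duration).
#' @param controls Control record tibble (may be empty).
#' @param strategy `"median_two_stage"` or `"fixed_three_stage"`.
#' @param boundaries Stage boundaries in years; defaults to the patient
#'   median (two-stage) or `c(6, 11)` (three-stage).
#' @param min_subgroup Minimum subjects per stage per group (default 3).
#' @return A `stage_split`: list with `strategy`, `boundaries`, `n_stages`,
#'   and `assignment` (tibble `id`, `group`, `stage`).
#' @export
split_stages <- function(patients, controls,
                         strategy = c("median_two_stage", "fixed_three_stage"),
                         boundaries = NULL, min_subgroup = 3L) {
  strategy <- match.arg(strategy)
  if (nrow(patients) == 0L) stop("no patients to split", call. = FALSE)
  if (!all(is.finite(patients$duration))) {
    stop("missing duration for one or more patients", call. = FALSE)
  }
  dur <- patients$duration
  if (strategy == "median_two_stage") {
    if (is.null(boundaries)) boundaries <- stats::median(dur)
    if (length(boundaries) != 1L) stop("median_two_stage needs 1 boundary", call. = FALSE)
    stage_p <- ifelse(dur < boundaries, 1L, 2L)
    n_stages <- 2L
  } else {
    if (is.null(boundaries)) boundaries <- c(6, 11)
    if (length(boundaries) != 2L || diff(boundaries) <= 0) {
      stop("fixed_three_stage needs 2 increasing boundaries", call. = FALSE)
    }
    stage_p <- ifelse(dur < boundaries[1], 1L,
      ifelse(dur <= boundaries[2], 2L, 3L)
    )
    n_stages <- 3L
  }
  assignment <- tibble::tibble(
    id = patients$id, group = "patient", stage = stage_p
  )
  if (nrow(controls) > 0L) {
    stage_means <- vapply(
      seq_len(n_stages),
      function(s) mean(patients$age[stage_p == s]), numeric(1)
    )
    caps <- largest_remainder(
      tabulate(stage_p, n_stages) / nrow(patients), nrow(controls)
    )
    pairs <- expand.grid(ctl = seq_len(nrow(controls)), stage = seq_len(n_stages))
    pairs$dist <- abs(controls$age[pairs$ctl] - stage_means[pairs$stage])
    pairs <- pairs[order(pairs$dist, pairs$ctl, pairs$stage), ]
    stage_c <- rep(NA_integer_, nrow(controls))
    left <- caps
    for (r in seq_len(nrow(pairs))) {
      ctl <- pairs$ctl[r]
      s <- pairs$stage[r]
      if (is.na(stage_c[ctl]) && left[s] > 0L) {
        stage_c[ctl] <- s
        left[s] <- left[s] - 1L
      }
    }
    assignment <- dplyr::bind_rows(
      assignment,
      tibble::tibble(id = controls$id, group = "control", stage = stage_c)
    )
  }
  counts <- table(factor(assignment$stage, seq_len(n_stages)), assignment$group)
  if (any(counts < min_subgroup)) {
    stop(sprintf("subgroup too small: fewer than %d subjects in a stage", min_subgroup),
      call. = FALSE
    )
  }
  structure(
    list(
      strategy = strategy, boundaries = boundaries,
      n_stages = n_stages, assignment = assignment
    ),
    class = "stage_split"
  )
}

# integer capacities summing to total, proportional to weights
largest_remainder <- function(weights, total) {
  raw <- weights / sum(weights) * total
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0L) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' @export
print.stage_split <- function(x, ...) {
  cat(sprintf(
    "<stage_split:%s> boundaries [%s]\n",
    x$strategy, paste(format(x$boundaries, trim = TRUE), collapse = ", ")
  ))
  print(table(x$assignment$stage, x$assignment$group))
  invisible(x)
}
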