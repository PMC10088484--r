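#' Construct a cohort object
#'
#' An `lsm_cohort` bundles everything the mapping and prediction stages
#' need: a subjects-by-ROIs damage matrix (fractions in `[0, 1]`), per-subject
#' lesion volumes, a behaviour table and the ROI lookup table. Rows of the
#' damage matrix, the volume vector and the behaviour table are aligned by
#' subject.
#'
#' @param damage Numeric matrix, subjects x ROIs, entries in `[0, 1]`,
#'   rownames = subject ids, colnames = ROI names.
#' @param lesion_volumes Named numeric vector of voxel counts, same order.
#' @param behaviour Data frame with `subject_id`, `wab_aq` (0-100) and
#'   optionally the four WAB-R subscores.
#' @param roi_table Data frame with columns `label` and `name`.
#' @param cohort_label Short label, e.g. `"acute"` or `"chronic"`.
#' @param atlas_voxels Total number of atlas-labelled voxels; used as the
#'   scaling constant for volume-only prediction features.
#' @return An object of class `lsm_cohort`.
#' @export
new_lsm_cohort <- function(damage, lesion_volumes, behaviour, roi_table,
                           cohort_label = "cohort", atlas_voxels = NULL) {
  damage <- as.matrix(damage)
  n <- nrow(damage)
  if (n == 0L) stop("cohort is empty")
  if (length(lesion_volumes) != n || nrow(behaviour) != n) {
    stop("damage matrix, lesion volumes and behaviour table disagree on ",
         "subject count (", n, ", ", length(lesion_volumes), ", ",
         nrow(behaviour), ")")
  }
  if (anyDuplicated(behaviour$subject_id)) {
    stop("duplicated subject_id in behaviour table")
  }
  if (any(damage < -1e-9) || any(damage > 1 + 1e-9)) {
    stop("damage fractions must lie in [0, 1]")
  }
  aq <- behaviour$wab_aq
  if (anyNA(aq) || any(aq < 0) || any(aq > 100)) {
    stop("wab_aq must lie in [0, 100] with no missing values")
  }
  if (ncol(damage) != nrow(roi_table)) {
    stop("damage matrix has ", ncol(damage), " columns but roi_table lists ",
         nrow(roi_table), " ROIs")
  }
  colnames(damage) <- roi_table$name
  structure(
    list(damage = damage,
         lesion_volumes = stats::setNames(as.numeric(lesion_volumes),
                                          rownames(damage)),
         behaviour = behaviour,
         roi_table = roi_table,
         cohort_label = as.character(cohort_label),
         atlas_voxels = if (is.null(atlas_voxels)) NA_real_
                        else as.numeric(atlas_voxels)),
    class = "lsm_cohort"
  )
}

#' @export
print.lsm_cohort <- function(x, ...) {
  cat("Cohort '", x$cohort_label, "': ", nrow(x$damage), " subjects, ",
      ncol(x$damage), " ROIs\n", sep = "")
  cat("  WAB-R AQ: mean ", round(mean(x$behaviour$wab_aq), 1),
      ", range ", paste(round(range(x$behaviour$wab_aq), 1), collapse = "-"),
      "\n", sep = "")
  cat("  lesion volume (voxels): mean ", round(mean(x$lesion_volumes), 1),
      ", range ", paste(round(range(x$lesion_volumes)), collapse = "-"),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.lsm_cohort <- function(object, ...) {
  cohort_descriptives(object)
}

#' Descriptive statistics for a cohort
#'
#' Mean, SD, median and range for every numeric behaviour column and for
#' lesion volume. With a single subject the SD is reported as `NA`.
#'
#' @param cohort An `lsm_cohort`.
#' @return Data frame with one row per variable and columns `variable`, `n`,
#'   `mean`, `sd`, `median`, `min`, `max`.
#' @export
cohort_descriptives <- function(cohort) {
  stopifnot(inherits(cohort, "lsm_cohort"))
  beh <- cohort$behaviour
  num_cols <- names(beh)[vapply(beh, is.numeric, logical(1))]
  vars <- c(num_cols, "lesion_volume")
  rows <- lapply(vars, function(v) {
    x <- if (v == "lesion_volume") cohort$lesion_volumes else beh[[v]]
    x <- x[!is.na(x)]
    data.frame(variable = v, n = length(x), mean = mean(x),
               sd = if (length(x) > 1L) stats::sd(x) else NA_real_,
               median = stats::median(x), min = min(x), max = max(x),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Names of behaviour scores available in a cohort
#'
#' @param cohort An `lsm_cohort`.
#' @return Character vector of numeric behaviour column names
#'   (always includes `wab_aq`).
#' @export
behaviour_names <- function(cohort) {
  stopifnot(inherits(cohort, "lsm_cohort"))
  beh <- cohort$behaviour
  nm <- names(beh)[vapply(beh, is.numeric, logical(1))]
  setdiff(nm, "subject_id")
}

cohort_scores <- function(cohort, behaviour_name) {
  if (!behaviour_name %in% names(cohort$behaviour)) {
    stop("behaviour '", behaviour_name, "' not present in cohort '",
         cohort$cohort_label, "'")
  }
  scores <- cohort$behaviour[[behaviour_name]]
  if (anyNA(scores)) stop("behaviour '", behaviour_name, "' has missing values")
  scores
}
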