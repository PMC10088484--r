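#' Quantify per-ROI damage for one subject
#'
#' For every region in the atlas, computes the fraction of that region's
#' voxels overlapped by the lesion. Lesioned voxels that fall outside every
#' atlas label still count towards the lesion volume but towards no region.
#'
#' @param mask A `lesion_mask`.
#' @param atlas A `lesion_atlas` on the same grid (dimensions and affine).
#' @return A `damage_vector` object: list with `subject_id`, `values`
#'   (named numeric in `[0, 1]`, one entry per ROI in atlas order) and
#'   `lesion_volume` (voxel count of the whole lesion).
#' @examples
#' cfg <- generative_config(grid_dims = c(12, 12, 12), n_rois = 4,
#'                          n_subjects = 3, seed = 1)
#' atlas <- make_synthetic_atlas(cfg)
#' set.seed(1)
#' mask <- simulate_lesion(atlas, target_volume = 40)
#' compute_damage_vector(mask, atlas)
#' @export
compute_damage_vector <- function(mask, atlas) {
  stopifnot(inherits(mask, "lesion_mask"), inherits(atlas, "lesion_atlas"))
  check_same_grid(mask, atlas, what = "mask and atlas")
  labels <- atlas$roi_table$label
  nbins <- max(labels)
  roi_sizes <- tabulate(atlas$grid[atlas$grid != 0L], nbins = nbins)[labels]
  hit <- atlas$grid[mask$grid != 0L]
  hit_counts <- tabulate(hit[hit != 0L], nbins = nbins)[labels]
  values <- hit_counts / roi_sizes
  names(values) <- atlas$roi_table$name
  structure(
    list(subject_id = mask$subject_id, values = values,
         lesion_volume = lesion_volume(mask)),
    class = "damage_vector"
  )
}

#' @export
print.damage_vector <- function(x, ...) {
  cat("Damage vector for subject", x$subject_id,
      "-", x$lesion_volume, "lesioned voxels\n")
  nz <- x$values[x$values > 0]
  if (length(nz) == 0L) {
    cat("  no atlas region damaged\n")
  } else {
    cat("  damaged regions:\n")
    print(round(sort(nz, decreasing = TRUE), 4))
  }
  invisible(x)
}

#' Assemble a cohort from lesion masks, an atlas and a behaviour table
#'
#' Aligns subjects by exact `subject_id` match between masks and the
#' behaviour table. Subjects present on only one side are excluded with a
#' message reporting the counts; zero overlap is an error.
#'
#' @param masks List of `lesion_mask` objects, one per subject.
#' @param atlas A `lesion_atlas` shared by all masks.
#' @param behaviour Behaviour table: a data.frame or a path to a CSV file.
#'   Must contain `subject_id` and `wab_aq` (raw 0-100 scale); the WAB-R
#'   subscores `spontaneous_speech`, `auditory_verbal_comprehension`,
#'   `repetition` and `naming` are used when present.
#' @param cohort_label Short label for the cohort (e.g. `"acute"`).
#' @return An `lsm_cohort` object; see [new_lsm_cohort()].
#' @export
build_cohort <- function(masks, atlas, behaviour, cohort_label = "cohort") {
  stopifnot(is.list(masks), length(masks) > 0L, inherits(atlas, "lesion_atlas"))
  if (is.character(behaviour)) {
    behaviour <- utils::read.csv(behaviour, stringsAsFactors = FALSE)
  }
  if (!all(c("subject_id", "wab_aq") %in% names(behaviour))) {
    stop("behaviour table must contain columns 'subject_id' and 'wab_aq'")
  }
  behaviour$subject_id <- as.character(behaviour$subject_id)
  if (anyDuplicated(behaviour$subject_id)) {
    stop("behaviour table contains duplicated subject_id: ",
         paste(unique(behaviour$subject_id[duplicated(behaviour$subject_id)]),
               collapse = ", "))
  }
  mask_ids <- vapply(masks, function(m) m$subject_id, character(1))
  if (anyDuplicated(mask_ids)) {
    stop("duplicated subject_id among masks: ",
         paste(unique(mask_ids[duplicated(mask_ids)]), collapse = ", "))
  }
  keep <- intersect(behaviour$subject_id, mask_ids)
  if (length(keep) == 0L) {
    stop("no overlapping subject_id between masks and behaviour table")
  }
  n_dropped_beh <- sum(!behaviour$subject_id %in% keep)
  n_dropped_mask <- sum(!mask_ids %in% keep)
  if (n_dropped_beh + n_dropped_mask > 0L) {
    message("build_cohort: excluded ", n_dropped_beh,
            " behaviour row(s) without masks and ", n_dropped_mask,
            " mask(s) without behaviour rows")
  }
  behaviour <- behaviour[match(keep, behaviour$subject_id), , drop = FALSE]
  masks <- masks[match(keep, mask_ids)]
  dvs <- lapply(masks, compute_damage_vector, atlas = atlas)
  damage <- do.call(rbind, lapply(dvs, function(d) d$values))
  rownames(damage) <- keep
  volumes <- vapply(dvs, function(d) d$lesion_volume, numeric(1))
  names(volumes) <- keep
  new_lsm_cohort(damage = damage, lesion_volumes = volumes,
                 behaviour = behaviour, roi_table = atlas$roi_table,
                 cohort_label = cohort_label,
                 atlas_voxels = sum(atlas$grid != 0L))
}

#' Voxelwise lesion overlap map across subjects
#'
#' Sums the binary masks voxel by voxel, giving for every voxel the number
#' of subjects lesioned there.
#'
#' @param masks List of `lesion_mask` objects on a common grid.
#' @return An `overlay_volume`: list with `grid` (integer counts),
#'   `n_subjects`, `voxel_dims`, `affine`.
#' @export
overlay_map <- function(masks) {
  stopifnot(is.list(masks), length(masks) > 0L)
  ref <- masks[[1L]]
  grid <- array(0L, dim = dim(ref$grid))
  for (m in masks) {
    stopifnot(inherits(m, "lesion_mask"))
    check_same_grid(ref, m, what = "lesion masks")
    grid <- grid + m$grid
  }
  structure(
    list(grid = grid, n_subjects = length(masks),
         voxel_dims = ref$voxel_dims, affine = ref$affine),
    class = "overlay_volume"
  )
}

#' @export
print.overlay_volume <- function(x, ...) {
  cat("Lesion overlay of", x$n_subjects, "subjects; peak overlap",
      max(x$grid), "\n")
  invisible(x)
}

#' Export a cohort's damage matrix as CSV
#'
#' One row per subject, one column per ROI name, plus `subject_id` and
#' `lesion_volume`.
#'
#' @param cohort An `lsm_cohort`.
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_damage_matrix <- function(cohort, path) {
  stopifnot(inherits(cohort, "lsm_cohort"))
  df <- data.frame(subject_id = rownames(cohort$damage),
                   cohort$damage,
                   lesion_volume = unname(cohort$lesion_volumes),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
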