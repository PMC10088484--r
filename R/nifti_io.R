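#' Read a binary lesion mask from a NIfTI-1 file
#'
#' Loads a 3-D volume and binarizes it: every nonzero (and non-missing) voxel
#' becomes 1. Hand-drawn lesion tracings are nominally binary, but
#' interpolation during spatial normalization can introduce intermediate
#' values; these are folded into the lesion with a warning.
#'
#' @param path Path to a `.nii` or `.nii.gz` file containing a 3-D volume.
#' @param subject_id Subject identifier. Defaults to the file name with the
#'   NIfTI extension stripped.
#' @param space_tag Free-text name of the reference space the mask lives in
#'   (e.g. `"MNI152"`). Not interpreted, only carried along and compared.
#' @return A `lesion_mask` object: a list with elements `subject_id`, `grid`
#'   (3-D integer array of 0/1), `voxel_dims` (mm per axis), `affine`
#'   (4x4 voxel-to-world matrix) and `space_tag`.
#' @seealso [compute_damage_vector()], [write_lesion_mask()]
#' @export
read_lesion_mask <- function(path, subject_id = NULL, space_tag = "unspecified") {
  if (!file.exists(path)) {
    stop("cannot read lesion mask: file does not exist: ", path)
  }
  img <- RNifti::readNifti(path)
  grid <- drop_trailing_units(img)
  if (length(dim(grid)) != 3L) {
    stop("lesion mask must be a 3-D volume, got ", length(dim(grid)),
         " dimensions: ", path)
  }
  vals <- as.vector(grid)
  if (anyNA(vals)) {
    warning("lesion mask contains missing voxels; treating them as 0: ", path)
    vals[is.na(vals)] <- 0
  }
  if (!all(vals %in% c(0, 1))) {
    warning("lesion mask is not binary; nonzero voxels binarized to 1: ", path)
  }
  if (is.null(subject_id)) {
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  }
  new_lesion_mask(
    subject_id = subject_id,
    grid = array(as.integer(vals != 0), dim = dim(grid)),
    voxel_dims = RNifti::pixdim(img)[seq_len(3L)],
    affine = unclass_affine(RNifti::xform(img)),
    space_tag = space_tag
  )
}

new_lesion_mask <- function(subject_id, grid, voxel_dims, affine,
                            space_tag = "unspecified") {
  stopifnot(length(dim(grid)) == 3L, length(voxel_dims) == 3L,
            all(dim(affine) == c(4L, 4L)))
  structure(
    list(subject_id = as.character(subject_id), grid = grid,
         voxel_dims = as.numeric(voxel_dims), affine = affine,
         space_tag = as.character(space_tag)),
    class = "lesion_mask"
  )
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat("Lesion mask for subject", x$subject_id, "\n")
  cat("  grid:", paste(dim(x$grid), collapse = " x "),
      " voxels of", paste(signif(x$voxel_dims, 3), collapse = " x "), "mm\n")
  cat("  lesion volume:", lesion_volume(x), "voxels\n")
  invisible(x)
}

#' Lesion volume in voxels
#'
#' @param mask A `lesion_mask`.
#' @return Number of voxels with value 1.
#' @export
lesion_volume <- function(mask) {
  stopifnot(inherits(mask, "lesion_mask"))
  sum(mask$grid != 0L)
}

#' Write a lesion mask, atlas or overlay volume to NIfTI-1
#'
#' @param x A `lesion_mask`, `lesion_atlas` or `overlay_volume`.
#' @param path Destination `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_lesion_mask <- function(x, path) {
  stopifnot(inherits(x, c("lesion_mask", "lesion_atlas", "overlay_volume")))
  int_valued <- all(abs(x$grid - round(x$grid)) < 1e-9)
  hdr <- RNifti::niftiHeader(list(
    dim = c(3L, dim(x$grid), 1L, 1L, 1L, 1L),
    pixdim = c(1, x$voxel_dims, 0, 0, 0, 0),
    sform_code = 2L,
    srow_x = x$affine[1L, ], srow_y = x$affine[2L, ],
    srow_z = x$affine[3L, ]))
  img <- RNifti::asNifti(x$grid, reference = hdr,
                         datatype = if (int_valued) "int32" else "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an atlas parcellation and its label lookup table
#'
#' The volume holds non-negative integer labels (0 = background). The lookup
#' table is tab-separated with a header line `label<TAB>name` and must cover
#' every nonzero label present in the volume, with no duplicated labels;
#' labels listed in the table must occupy at least one voxel.
#'
#' @param volume_path NIfTI-1 file with the integer label volume.
#' @param lut_path Tab-separated lookup table path.
#' @return A `lesion_atlas` object: list with `grid` (3-D integer array),
#'   `roi_table` (data.frame with columns `label`, `name`), `voxel_dims`,
#'   `affine`.
#' @export
read_atlas <- function(volume_path, lut_path) {
  img <- RNifti::readNifti(volume_path)
  grid <- drop_trailing_units(img)
  if (length(dim(grid)) != 3L) {
    stop("atlas must be a 3-D volume, got ", length(dim(grid)), " dimensions")
  }
  vals <- as.vector(grid)
  if (anyNA(vals) || any(vals < 0) || any(abs(vals - round(vals)) > 1e-6)) {
    stop("atlas labels must be non-negative integers: ", volume_path)
  }
  lut <- utils::read.delim(lut_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("label", "name") %in% names(lut))) {
    stop("atlas lookup table must have columns 'label' and 'name': ", lut_path)
  }
  new_lesion_atlas(
    grid = array(as.integer(round(vals)), dim = dim(grid)),
    roi_table = data.frame(label = as.integer(lut$label),
                           name = as.character(lut$name),
                           stringsAsFactors = FALSE),
    voxel_dims = RNifti::pixdim(img)[seq_len(3L)],
    affine = unclass_affine(RNifti::xform(img))
  )
}

new_lesion_atlas <- function(grid, roi_table, voxel_dims, affine) {
  if (anyDuplicated(roi_table$label)) {
    stop("atlas lookup table contains duplicated labels: ",
         paste(unique(roi_table$label[duplicated(roi_table$label)]),
               collapse = ", "))
  }
  present <- sort(unique(as.vector(grid)))
  present <- present[present != 0L]
  missing_from_lut <- setdiff(present, roi_table$label)
  if (length(missing_from_lut) > 0L) {
    stop("atlas grid contains labels absent from the lookup table: ",
         paste(missing_from_lut, collapse = ", "))
  }
  empty <- setdiff(roi_table$label, present)
  if (length(empty) > 0L) {
    stop("lookup table lists labels with no voxels in the grid: ",
         paste(empty, collapse = ", "))
  }
  structure(
    list(grid = grid, roi_table = roi_table,
         voxel_dims = as.numeric(voxel_dims), affine = affine),
    class = "lesion_atlas"
  )
}

#' @export
print.lesion_atlas <- function(x, ...) {
  cat("Atlas parcellation:", nrow(x$roi_table), "ROIs on a",
      paste(dim(x$grid), collapse = " x "), "grid\n")
  cat("  labelled voxels:", sum(x$grid != 0L), "\n")
  invisible(x)
}

#' Write an atlas parcellation (volume + lookup table)
#'
#' @param atlas A `lesion_atlas`.
#' @param volume_path Destination NIfTI path.
#' @param lut_path Destination tab-separated lookup table path.
#' @return `volume_path`, invisibly.
#' @export
write_atlas <- function(atlas, volume_path, lut_path) {
  stopifnot(inherits(atlas, "lesion_atlas"))
  write_lesion_mask(atlas, volume_path)
  utils::write.table(atlas$roi_table, lut_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(volume_path)
}

# Grids must match in shape and (within tolerance) in affine; resampling is
# out of scope, so a mismatch is an error rather than silently handled.
check_same_grid <- function(a, b, what = "volumes", tol = 1e-4) {
  da <- dim(if (is.list(a)) a$grid else a)
  db <- dim(if (is.list(b)) b$grid else b)
  if (!identical(da, db)) {
    stop(what, " are on different grids: ", paste(da, collapse = "x"),
         " vs ", paste(db, collapse = "x"))
  }
  if (is.list(a) && is.list(b) && !is.null(a$affine) && !is.null(b$affine)) {
    if (max(abs(a$affine - b$affine)) > tol) {
      stop(what, " have different voxel-to-world transforms (max entry ",
           "difference > ", tol, ")")
    }
  }
  invisible(TRUE)
}

# NIfTI stores trailing singleton dimensions implicitly: a volume saved as
# 3 x 1 x 1 reads back 1-D. Drop spurious trailing units, then pad back up
# to 3-D; genuinely 4-D data stays 4-D and is refused by the callers.
drop_trailing_units <- function(img) {
  d <- dim(img)
  if (is.null(d)) d <- length(img)
  while (length(d) > 3L && d[length(d)] == 1L) d <- d[-length(d)]
  if (length(d) < 3L) d <- c(d, rep(1L, 3L - length(d)))
  array(as.vector(img)[seq_len(prod(d))], dim = d)
}

unclass_affine <- function(x) {
  m <- matrix(as.numeric(x), 4L, 4L)
  m
}
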