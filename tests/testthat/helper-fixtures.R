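# Small in-code fixtures shared across test files.

# A 6x6x6 atlas with two 3x3x6 ROIs filling the x <= 3 hemisphere.
toy_atlas <- function() {
  grid <- array(0L, dim = c(6, 6, 6))
  grid[1:3, 1:3, ] <- 1L
  grid[1:3, 4:6, ] <- 2L
  roilsm:::new_lesion_atlas(
    grid = grid,
    roi_table = data.frame(label = 1:2, name = c("front", "back"),
                           stringsAsFactors = FALSE),
    voxel_dims = c(1, 1, 1), affine = diag(4)
  )
}

toy_mask <- function(voxels, subject_id = "s1", dims = c(6, 6, 6)) {
  grid <- array(0L, dim = dims)
  grid[voxels] <- 1L
  roilsm:::new_lesion_mask(subject_id = subject_id, grid = grid,
                           voxel_dims = c(1, 1, 1), affine = diag(4))
}

# Cohort built directly from a damage matrix (no imaging involved).
matrix_cohort <- function(damage, scores, label = "toy", volumes = NULL,
                          atlas_voxels = 1000) {
  n <- nrow(damage)
  if (is.null(colnames(damage))) {
    colnames(damage) <- sprintf("ROI_%03d", seq_len(ncol(damage)))
  }
  rownames(damage) <- sprintf("s%03d", seq_len(n))
  if (is.null(volumes)) volumes <- rowSums(damage) * 10
  new_lsm_cohort(
    damage = damage, lesion_volumes = volumes,
    behaviour = data.frame(subject_id = rownames(damage), wab_aq = scores,
                           stringsAsFactors = FALSE),
    roi_table = data.frame(label = seq_len(ncol(damage)),
                           name = colnames(damage),
                           stringsAsFactors = FALSE),
    cohort_label = label, atlas_voxels = atlas_voxels
  )
}

# Small but non-trivial simulated cohort for module tests.
small_sim_config <- function(seed = 1, n_subjects = 30, noise_sd = 8,
                             critical_rois = NULL,
                             critical_weights = c(0.5, 0.3, 0.2)) {
  generative_config(grid_dims = c(20, 24, 20), n_rois = 12,
                    n_subjects = n_subjects,
                    critical_rois = critical_rois,
                    critical_weights = critical_weights,
                    noise_sd = noise_sd,
                    lesion_volume_log_mean = log(500),
                    lesion_volume_log_sd = 0.8, seed = seed)
}
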