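test_that("reading a mask binarizes non-binary values with a warning", {
  vals <- array(0, dim = c(3, 1, 1))
  vals[1] <- 0; vals[2] <- 0.5; vals[3] <- 2
  f <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(vals), f)
  expect_warning(mask <- read_lesion_mask(f), "not binary")
  expect_identical(as.vector(mask$grid), c(0L, 1L, 1L))
  expect_equal(lesion_volume(mask), 2)
})

test_that("strictly binary and empty masks read back unchanged", {
  grid <- array(0L, dim = c(4, 5, 6))
  grid[c(1, 10, 60)] <- 1L
  f <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(grid), f)
  expect_silent(mask <- read_lesion_mask(f, subject_id = "sub1"))
  expect_identical(mask$grid, grid)
  expect_identical(mask$subject_id, "sub1")

  empty <- array(0L, dim = c(4, 4, 4))
  f2 <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(empty), f2)
  expect_equal(lesion_volume(read_lesion_mask(f2)), 0)
})

test_that("non-3-D volumes are rejected", {
  f <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, dim = c(3, 3, 3, 2))), f)
  expect_error(read_lesion_mask(f), "3-D")
  expect_error(read_lesion_mask(file.path(tempdir(), "nope.nii")), "exist")
})

test_that("masks round-trip through write/read exactly", {
  set.seed(42)
  grid <- array(as.integer(stats::runif(4 * 5 * 6) > 0.5), dim = c(4, 5, 6))
  mask <- roilsm:::new_lesion_mask("rt", grid, c(2, 2, 2),
                                   diag(c(2, 2, 2, 1)))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_lesion_mask(mask, f)
  back <- read_lesion_mask(f)
  expect_identical(back$grid, grid)
  expect_equal(back$voxel_dims, c(2, 2, 2))
  expect_equal(back$affine, diag(c(2, 2, 2, 1)), tolerance = 1e-6)
})

test_that("atlas reading validates the lookup table against the grid", {
  atlas <- toy_atlas()
  vol <- withr::local_tempfile(fileext = ".nii.gz")
  lut <- withr::local_tempfile(fileext = ".tsv")
  write_atlas(atlas, vol, lut)
  back <- read_atlas(vol, lut)
  expect_identical(back$grid, atlas$grid)
  expect_equal(back$roi_table, atlas$roi_table)

  # label present in grid but missing from lookup
  lut2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("label\tname", "1\tfront"), lut2)
  expect_error(read_atlas(vol, lut2), "2")

  # duplicated label in lookup
  lut3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("label\tname", "1\tfront", "2\tback", "2\tagain"), lut3)
  expect_error(read_atlas(vol, lut3), "duplicated")

  # lookup lists a label with no voxels
  lut4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("label\tname", "1\tfront", "2\tback", "9\tghost"), lut4)
  expect_error(read_atlas(vol, lut4), "no voxels")
})

test_that("damage fractions follow the lesioned/total voxel ratio", {
  atlas <- toy_atlas()  # ROI 'front' = grid[1:3,1:3,], 54 voxels each

  full <- toy_mask(which(atlas$grid == 1L))
  dv <- compute_damage_vector(full, atlas)
  expect_equal(unname(dv$values), c(1, 0))

  none <- toy_mask(integer(0))
  dv0 <- compute_damage_vector(none, atlas)
  expect_equal(unname(dv0$values), c(0, 0))
  expect_equal(dv0$lesion_volume, 0)

  # half of ROI 2: 27 of its 54 voxels
  half <- toy_mask(which(atlas$grid == 2L)[1:27])
  expect_equal(unname(compute_damage_vector(half, atlas)$values), c(0, 0.5))

  bad <- toy_mask(1, dims = c(5, 5, 5))
  expect_error(compute_damage_vector(bad, atlas), "grids")
})

test_that("lesion voxels outside any label count to volume but no ROI", {
  atlas <- toy_atlas()
  outside <- which(atlas$grid == 0L)[1:10]
  mask <- toy_mask(c(which(atlas$grid == 1L)[1:5], outside))
  dv <- compute_damage_vector(mask, atlas)
  expect_equal(dv$lesion_volume, 15)
  expect_equal(sum(dv$values * c(54, 54)), 5)
})

test_that("damage is invariant under a consistent voxel-order permutation", {
  atlas <- toy_atlas()
  set.seed(7)
  mask <- toy_mask(sample(which(atlas$grid >= 0), 30))
  perm <- sample(length(atlas$grid))
  atlas2 <- atlas
  atlas2$grid <- array(atlas$grid[perm], dim = dim(atlas$grid))
  mask2 <- mask
  mask2$grid <- array(mask$grid[perm], dim = dim(mask$grid))
  expect_equal(compute_damage_vector(mask2, atlas2)$values,
               compute_damage_vector(mask, atlas)$values)
})

test_that("cohort assembly joins subjects by id and reports exclusions", {
  atlas <- toy_atlas()
  masks <- lapply(1:3, function(i) {
    toy_mask(which(atlas$grid == 1L)[seq_len(10 * i)],
             subject_id = paste0("s", i))
  })
  beh3 <- data.frame(subject_id = c("s1", "s2", "s3"),
                     wab_aq = c(90, 70, 50))
  cohort <- build_cohort(masks, atlas, beh3, "toy")
  expect_s3_class(cohort, "lsm_cohort")
  expect_equal(nrow(cohort$damage), 3)
  expect_equal(cohort$lesion_volumes, c(s1 = 10, s2 = 20, s3 = 30))

  beh2 <- beh3[1:2, ]
  expect_message(c2 <- build_cohort(masks, atlas, beh2, "toy"), "excluded 0")
  expect_equal(nrow(c2$damage), 2)

  dup <- rbind(beh3, beh3[1, ])
  expect_error(build_cohort(masks, atlas, dup, "toy"), "duplicated")

  beh_none <- data.frame(subject_id = c("x1", "x2"), wab_aq = c(1, 2))
  expect_error(build_cohort(masks, atlas, beh_none, "toy"), "no overlapping")
})

test_that("overlay maps sum binary masks voxelwise", {
  atlas <- toy_atlas()
  m1 <- toy_mask(1:10, "a")
  expect_identical(overlay_map(list(m1))$grid, m1$grid)

  m2 <- toy_mask(11:25, "b")
  ov <- overlay_map(list(m1, m2))
  expect_equal(max(ov$grid), 1)
  expect_equal(sum(ov$grid), 25)

  ov2 <- overlay_map(list(m1, m1))
  expect_equal(max(ov2$grid), 2)
  expect_equal(sum(ov2$grid), 2 * lesion_volume(m1))
  expect_equal(ov2$n_subjects, 2)

  expect_error(overlay_map(list(m1, toy_mask(1, dims = c(3, 3, 3)))),
               "grids")
})

test_that("damage matrices export with ROI names and lesion volume", {
  damage <- matrix(c(0.2, 0, 0.5, 1), 2, 2,
                   dimnames = list(NULL, c("front", "back")))
  cohort <- matrix_cohort(damage, c(80, 40))
  f <- withr::local_tempfile(fileext = ".csv")
  write_damage_matrix(cohort, f)
  back <- utils::read.csv(f, check.names = FALSE)
  expect_equal(names(back), c("subject_id", "front", "back", "lesion_volume"))
  expect_equal(back$front, c(0.2, 0))
})
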