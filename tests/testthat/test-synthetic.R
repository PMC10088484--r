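test_that("synthetic atlas tiles one hemisphere with contiguous ROIs", {
  cfg <- generative_config(grid_dims = c(8, 8, 8), n_rois = 2, n_subjects = 3)
  atlas <- make_synthetic_atlas(cfg)
  sizes <- table(atlas$grid[atlas$grid != 0])
  expect_equal(sort(as.integer(names(sizes))), 1:2)
  expect_true(all(sizes >= 8))
  # all labels confined to the x <= nx/2 half
  labelled_x <- which(atlas$grid != 0, arr.ind = TRUE)[, 1]
  expect_true(all(labelled_x <= 4))
  # each ROI is one connected component
  for (l in 1:2) {
    expect_equal(flood_fill_components(atlas$grid == l), 1)
  }
  # deterministic
  expect_identical(make_synthetic_atlas(cfg)$grid, atlas$grid)
})

test_that("atlas construction fails when ROIs cannot get 8 voxels", {
  cfg <- generative_config(grid_dims = c(4, 4, 4), n_rois = 2, n_subjects = 3)
  cfg$n_rois <- 100L  # bypass constructor to hit the atlas-stage validation
  expect_error(make_synthetic_atlas(cfg), "too small")
})

test_that("simulated lesions hit the target volume exactly and stay connected", {
  cfg <- small_sim_config()
  atlas <- make_synthetic_atlas(cfg)
  capacity <- sum(atlas$grid != 0)

  set.seed(1)
  tiny <- simulate_lesion(atlas, 1)
  expect_equal(lesion_volume(tiny), 1)
  expect_true(all(atlas$grid[tiny$grid == 1L] != 0))

  set.seed(2)
  full <- simulate_lesion(atlas, capacity)
  expect_identical(full$grid != 0L, atlas$grid != 0L)

  set.seed(3)
  for (target in c(7, 150, 2000)) {
    mask <- simulate_lesion(atlas, target)
    expect_equal(lesion_volume(mask), target)
    expect_true(all(atlas$grid[mask$grid == 1L] != 0))
    expect_equal(flood_fill_components(mask$grid), 1)
  }

  expect_error(simulate_lesion(atlas, 0), "target_volume")
  expect_error(simulate_lesion(atlas, capacity + 1), "target_volume")
})

test_that("the severity law is linear in weighted critical damage", {
  # intact brain
  expect_equal(simulate_behaviour(c(0, 0, 0), 1, 1), 100)
  # single critical ROI fully damaged, w = 1
  expect_equal(simulate_behaviour(c(1, 0, 0), 1, 1), 0)
  # w = (0.5, 0.5), damage (1.0, 0.5) -> 100 * (1 - 0.75) = 25
  expect_equal(simulate_behaviour(c(1, 0.5), c(1, 2), c(0.5, 0.5)), 25)
  expect_error(simulate_behaviour(c(0, 1), 5, 1), "exceeds")
})

test_that("severity is non-increasing in critical damage (noise-free)", {
  w <- c(0.4, 0.3)
  base <- c(0.2, 0.5, 0.7)
  for (d in seq(0.2, 1, by = 0.2)) {
    bumped <- base
    bumped[1] <- d
    expect_lte(simulate_behaviour(bumped, c(1, 2), w),
               simulate_behaviour(base, c(1, 2), w))
  }
})

test_that("cohort simulation is reproducible and volumes match the masks", {
  cfg <- small_sim_config(seed = 9, n_subjects = 8)
  a <- simulate_cohort(cfg, keep_masks = TRUE)
  b <- simulate_cohort(cfg)
  expect_identical(a$cohort$damage, b$cohort$damage)
  expect_identical(a$cohort$behaviour, b$cohort$behaviour)
  expect_identical(a$truth$noise, b$truth$noise)
  mask_vols <- vapply(a$masks, lesion_volume, numeric(1))
  expect_equal(unname(a$cohort$lesion_volumes), mask_vols)
})

test_that("noise-free severity is exactly reconstructable from damage", {
  cfg <- small_sim_config(seed = 4, n_subjects = 10, noise_sd = 0)
  sim <- simulate_cohort(cfg)
  manual <- 100 * (1 - drop(
    sim$cohort$damage[, sim$truth$critical_rois] %*%
      sim$truth$critical_weights))
  expect_equal(unname(sim$cohort$behaviour$wab_aq), unname(manual))
  expect_equal(unname(sim$truth$true_severity), unname(manual))
})

test_that("acute-like replicate cohorts hit the configured mean volume", {
  cfg0 <- cohort_preset("acute", voxel_mm = 4, seed = 0)
  configured_mean <- exp(cfg0$lesion_volume_log_mean +
                           cfg0$lesion_volume_log_sd^2 / 2)
  means <- vapply(1:20, function(s) {
    cfg <- cohort_preset("acute", voxel_mm = 4, seed = 500 + s)
    mean(simulate_cohort(cfg)$cohort$lesion_volumes)
  }, numeric(1))
  expect_lt(abs(mean(means) - configured_mean) / configured_mean, 0.25)
})

test_that("lesion volume correlates negatively with severity", {
  signs <- vapply(1:20, function(s) {
    sim <- simulate_cohort(small_sim_config(seed = 300 + s,
                                            n_subjects = 100))
    cor(sim$cohort$lesion_volumes, sim$cohort$behaviour$wab_aq)
  }, numeric(1))
  expect_true(all(signs < 0))
})

test_that("cohort directories round-trip through write and read", {
  cfg <- small_sim_config(seed = 12, n_subjects = 5)
  dir <- withr::local_tempdir()
  out <- file.path(dir, "cohort")
  sim <- simulate_cohort_dir(cfg, out)
  expect_length(list.files(file.path(out, "masks")), 5)
  expect_error(simulate_cohort_dir(cfg, out), "force")

  back <- read_cohort_dir(out)
  expect_equal(back$damage, sim$cohort$damage)
  expect_equal(unname(back$lesion_volumes),
               unname(sim$cohort$lesion_volumes))
  expect_equal(back$behaviour$wab_aq, sim$cohort$behaviour$wab_aq)
  expect_identical(back$cohort_label, "synthetic")

  truth <- jsonlite::read_json(file.path(out, "ground_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$critical_rois, sim$truth$critical_rois)
})

test_that("generative configuration is validated", {
  expect_error(generative_config(n_rois = 1, n_subjects = 5), "n_rois")
  expect_error(generative_config(critical_weights = c(0.9, 0.3),
                                 n_subjects = 5), "sum")
  expect_error(generative_config(critical_weights = -0.1, n_subjects = 5),
               "positive")
  expect_error(generative_config(noise_sd = -1, n_subjects = 5), "noise_sd")
  expect_error(generative_config(n_subjects = 2), "n_subjects")
  expect_error(generative_config(critical_rois = c(1, 1),
                                 critical_weights = c(0.2, 0.2),
                                 n_subjects = 5), "distinct")
})
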