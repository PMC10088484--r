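#' Configuration for the synthetic stroke-cohort generator
#'
#' The generator emulates a left-hemisphere stroke cohort: an atlas whose
#' ROIs tile one half ("hemisphere") of the grid, contiguous lesions grown
#' inside that hemisphere with log-normally distributed volumes, and severity
#' scores produced by a known linear damage-to-severity law,
#' `score = clip(100 * (1 - sum_k w_k * d_k) + noise, 0, 100)`,
#' where the sum runs over a designated set of critical ROIs.
#'
#' @param grid_dims Integer vector of length 3; volume dimensions.
#' @param n_rois Number of atlas regions (>= 2) tiling the hemisphere.
#' @param critical_rois Integer labels of the critical ROIs. `NULL` (default)
#'   selects the `length(critical_weights)` ROIs nearest the hemisphere
#'   centroid, a stand-in for the perisylvian core.
#' @param critical_weights Positive weights, one per critical ROI, summing to
#'   at most 1. Default `c(0.5, 0.3, 0.2)`.
#' @param noise_sd SD of the additive Gaussian score noise, in points of the
#'   0-100 severity scale. Default 8.
#' @param lesion_volume_log_mean,lesion_volume_log_sd Parameters of the
#'   log-normal lesion-volume distribution (log-voxel scale).
#' @param n_subjects Number of subjects (>= 3).
#' @param seed Integer seed making the whole cohort reproducible.
#' @param voxel_dims Physical voxel size in mm (length 3).
#' @param cohort_label Label attached to the generated cohort.
#' @param subscores If `TRUE`, also generate the four WAB-R subscores
#'   (same law rescaled to each subscore's range, independent noise).
#' @return A `generative_config` list.
#' @seealso [cohort_preset()] for acute-like and chronic-like presets,
#'   [simulate_cohort()] to draw a cohort.
#' @export
generative_config <- function(grid_dims = c(24, 32, 24),
                              n_rois = 12,
                              critical_rois = NULL,
                              critical_weights = c(0.5, 0.3, 0.2),
                              noise_sd = 8,
                              lesion_volume_log_mean = log(500),
                              lesion_volume_log_sd = 0.8,
                              n_subjects = 63,
                              seed = 1L,
                              voxel_dims = c(1, 1, 1),
                              cohort_label = "synthetic",
                              subscores = TRUE) {
  grid_dims <- as.integer(grid_dims)
  if (length(grid_dims) != 3L || any(grid_dims < 2L)) {
    stop("grid_dims must be three integers >= 2")
  }
  if (n_rois < 2L) stop("n_rois must be >= 2")
  if (any(critical_weights <= 0)) stop("critical weights must be positive")
  if (sum(critical_weights) > 1 + 1e-9) {
    stop("critical weights must sum to at most 1")
  }
  if (!is.null(critical_rois)) {
    critical_rois <- as.integer(critical_rois)
    if (length(critical_rois) != length(critical_weights)) {
      stop("critical_rois and critical_weights must have equal length")
    }
    if (any(critical_rois < 1L) || any(critical_rois > n_rois) ||
        anyDuplicated(critical_rois)) {
      stop("critical_rois must be distinct labels in 1..n_rois")
    }
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_subjects < 3L) stop("n_subjects must be >= 3")
  structure(
    list(grid_dims = grid_dims, n_rois = as.integer(n_rois),
         critical_rois = critical_rois,
         critical_weights = as.numeric(critical_weights),
         noise_sd = as.numeric(noise_sd),
         lesion_volume_log_mean = as.numeric(lesion_volume_log_mean),
         lesion_volume_log_sd = as.numeric(lesion_volume_log_sd),
         n_subjects = as.integer(n_subjects), seed = as.integer(seed),
         voxel_dims = as.numeric(voxel_dims),
         cohort_label = as.character(cohort_label),
         subscores = isTRUE(subscores)),
    class = "generative_config"
  )
}

#' Acute-like and chronic-like cohort presets
#'
#' Presets matching the published demographics of the two study stages:
#' 63 acute subjects with a mean lesion volume of 22 510.4 voxels
#' (SD 42 812.8) and 109 chronic subjects with a mean of 118 808.6 voxels
#' (SD 94 864.7), both modelled as log-normal via method of moments. The two
#' presets share one damage-to-severity law and differ only in sample size
#' and lesion-volume distribution, so cross-stage transfer is well-posed by
#' construction.
#'
#' The default geometry is a 1 mm grid of 96 x 128 x 96 voxels whose labelled
#' hemisphere holds ~590k voxels, comparable to a human hemisphere at 1 mm
#' resolution. `voxel_mm` coarsens the grid (dimensions divided by
#' `voxel_mm`, volumes by `voxel_mm^3`), preserving all volume-to-hemisphere
#' ratios; use e.g. `voxel_mm = 4` for fast simulation studies.
#'
#' @param stage `"acute"` or `"chronic"`.
#' @param voxel_mm Voxel edge length in mm (1 = full scale).
#' @param n_rois Number of atlas regions. Default 48.
#' @param noise_sd Score-noise SD (0-100 scale). Default 8.
#' @param seed Integer seed.
#' @return A `generative_config`.
#' @export
cohort_preset <- function(stage = c("acute", "chronic"), voxel_mm = 1,
                          n_rois = 48, noise_sd = 8, seed = 1L) {
  stage <- match.arg(stage)
  if (voxel_mm < 1) stop("voxel_mm must be >= 1")
  tab <- list(acute = list(n = 63L, mean = 22510.4, sd = 42812.8),
              chronic = list(n = 109L, mean = 118808.6, sd = 94864.7))[[stage]]
  scale <- voxel_mm^3
  m <- tab$mean / scale
  s <- tab$sd / scale
  sigma2 <- log(1 + (s / m)^2)
  mu <- log(m) - sigma2 / 2
  generative_config(
    grid_dims = pmax(8L, as.integer(round(c(96, 128, 96) / voxel_mm))),
    n_rois = n_rois,
    noise_sd = noise_sd,
    lesion_volume_log_mean = mu,
    lesion_volume_log_sd = sqrt(sigma2),
    n_subjects = tab$n,
    seed = seed,
    voxel_dims = rep(voxel_mm, 3),
    cohort_label = stage
  )
}

#' Build the deterministic synthetic atlas for a configuration
#'
#' ROIs are contiguous axis-aligned blocks tiling the "left hemisphere" half
#' of the grid (`x <= floor(nx / 2)`); the rest of the grid is background.
#' The construction is deterministic: no random numbers are consumed.
#'
#' @param config A `generative_config`.
#' @return A `lesion_atlas` with `n_rois` regions named `ROI_001`, ...
#' @export
make_synthetic_atlas <- function(config) {
  stopifnot(inherits(config, "generative_config"))
  d <- config$grid_dims
  hx <- d[1L] %/% 2L
  n_rois <- config$n_rois
  grid <- array(0L, dim = d)

  # Partition n_rois into z-slabs, each slab into y-rows, each row into
  # x-blocks, so every label is one contiguous box.
  nz_slabs <- max(1L, min(d[3L], round(n_rois^(1 / 3))))
  slab_counts <- distribute_evenly(n_rois, nz_slabs)
  z_edges <- split_axis(d[3L], nz_slabs)
  label <- 0L
  for (iz in seq_len(nz_slabs)) {
    m_i <- slab_counts[iz]
    ny_rows <- max(1L, min(d[2L], round(sqrt(m_i))))
    row_counts <- distribute_evenly(m_i, ny_rows)
    y_edges <- split_axis(d[2L], ny_rows)
    for (iy in seq_len(ny_rows)) {
      m_ij <- row_counts[iy]
      if (m_ij == 0L) next
      x_edges <- split_axis(hx, m_ij)
      for (ix in seq_len(m_ij)) {
        label <- label + 1L
        grid[x_edges[ix]:(x_edges[ix + 1L] - 1L),
             y_edges[iy]:(y_edges[iy + 1L] - 1L),
             z_edges[iz]:(z_edges[iz + 1L] - 1L)] <- label
      }
    }
  }
  sizes <- tabulate(grid[grid != 0L], nbins = n_rois)
  if (length(sizes) < n_rois || any(sizes < 8L)) {
    stop("grid too small: every ROI needs at least 8 voxels (smallest got ",
         min(sizes), ")")
  }
  new_lesion_atlas(
    grid = grid,
    roi_table = data.frame(label = seq_len(n_rois),
                           name = sprintf("ROI_%03d", seq_len(n_rois)),
                           stringsAsFactors = FALSE),
    voxel_dims = config$voxel_dims,
    affine = diag(c(config$voxel_dims, 1))
  )
}

# n items into k near-equal groups (sizes differ by <= 1)
distribute_evenly <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  c(rep(base + 1L, extra), rep(base, k - extra))
}

# 1-based start positions of k contiguous segments covering 1..len,
# returned as k+1 edges (segment i = edges[i] .. edges[i+1]-1)
split_axis <- function(len, k) {
  if (k > len) stop("grid too small: cannot split axis of length ", len,
                    " into ", k, " blocks")
  as.integer(round(seq(1, len + 1, length.out = k + 1)))
}

#' Grow one contiguous lesion inside the labelled hemisphere
#'
#' Starting from a uniformly drawn seed voxel inside the labelled hemisphere,
#' the lesion grows by repeatedly accepting a random subset of its 6-connected
#' boundary until it reaches exactly `target_volume` voxels. The result is a
#' single 6-connected component confined to labelled territory. Random draws
#' are consumed from R's global RNG stream; call `set.seed()` beforehand for
#' reproducibility.
#'
#' @param atlas A `lesion_atlas` (as built by [make_synthetic_atlas()]).
#' @param target_volume Number of lesion voxels, between 1 and the number of
#'   labelled voxels.
#' @param subject_id Identifier stored in the returned mask.
#' @param growth_prob Probability that a boundary voxel is absorbed per
#'   growth wave; lower values give more irregular lesion shapes. Default 0.7.
#' @return A `lesion_mask` with exactly `target_volume` voxels set.
#' @export
simulate_lesion <- function(atlas, target_volume, subject_id = "sim",
                            growth_prob = 0.7) {
  stopifnot(inherits(atlas, "lesion_atlas"))
  d <- dim(atlas$grid)
  inside <- atlas$grid != 0L
  capacity <- sum(inside)
  target_volume <- as.integer(round(target_volume))
  if (target_volume < 1L || target_volume > capacity) {
    stop("target_volume must be between 1 and the labelled-hemisphere ",
         "capacity (", capacity, "), got ", target_volume)
  }
  nx <- d[1L]; ny <- d[2L]; nz <- d[3L]
  sxy <- nx * ny
  inside_idx <- which(inside)
  in_lesion <- logical(length(inside))

  neighbours <- function(v) {
    i <- (v - 1L) %% nx + 1L
    j <- ((v - 1L) %/% nx) %% ny + 1L
    k <- (v - 1L) %/% sxy + 1L
    c(v[i > 1L] - 1L, v[i < nx] + 1L,
      v[j > 1L] - nx, v[j < ny] + nx,
      v[k > 1L] - sxy, v[k < nz] + sxy)
  }

  seed_voxel <- inside_idx[sample.int(length(inside_idx), 1L)]
  in_lesion[seed_voxel] <- TRUE
  vol <- 1L
  frontier <- neighbours(seed_voxel)
  frontier <- frontier[inside[frontier]]
  while (vol < target_volume) {
    frontier <- unique(frontier)
    frontier <- frontier[!in_lesion[frontier]]
    if (length(frontier) == 0L) {
      stop("lesion growth exhausted the reachable hemisphere before ",
           "reaching the target volume")  # unreachable for box hemispheres
    }
    need <- target_volume - vol
    k <- min(need, max(1L, stats::rbinom(1L, length(frontier), growth_prob)))
    acc <- if (k >= length(frontier)) frontier
           else frontier[sample.int(length(frontier), k)]
    in_lesion[acc] <- TRUE
    vol <- vol + length(acc)
    new_front <- neighbours(acc)
    new_front <- new_front[inside[new_front] & !in_lesion[new_front]]
    frontier <- c(frontier[!in_lesion[frontier]], new_front)
  }
  new_lesion_mask(
    subject_id = subject_id,
    grid = array(as.integer(in_lesion), dim = d),
    voxel_dims = atlas$voxel_dims,
    affine = atlas$affine
  )
}

#' Severity score from regional damage under the generative law
#'
#' Applies `score = clip(scale * (1 - sum_k w_k * d_k) + noise, 0, scale)`
#' where the weights cover the critical ROIs only. With `noise_sd = 0` the
#' score is a deterministic function of the damage. Noise draws (one per
#' subject, in row order) are consumed from R's global RNG stream.
#'
#' @param damage A `damage_vector`, a named damage-fraction vector, or a
#'   subjects-by-ROIs damage matrix.
#' @param critical_rois Integer labels of the critical ROIs (positions in
#'   the ROI ordering of `damage`).
#' @param critical_weights Positive weights, one per critical ROI.
#' @param noise_sd Gaussian noise SD on the score scale. Default 0.
#' @param scale Maximum of the score range. Default 100.
#' @return Numeric score(s) in `[0, scale]`.
#' @export
simulate_behaviour <- function(damage, critical_rois, critical_weights,
                               noise_sd = 0, scale = 100) {
  if (inherits(damage, "damage_vector")) damage <- damage$values
  if (!is.matrix(damage)) damage <- matrix(damage, nrow = 1L)
  if (max(critical_rois) > ncol(damage)) {
    stop("critical ROI label exceeds number of ROIs in damage input")
  }
  burden <- drop(damage[, critical_rois, drop = FALSE] %*% critical_weights)
  noise <- if (noise_sd > 0) stats::rnorm(nrow(damage), 0, noise_sd) else 0
  pmin(pmax(scale * (1 - burden) + noise, 0), scale)
}

#' Draw a full synthetic cohort with known ground truth
#'
#' Consumes one seeded RNG stream in a documented order: (1) the `n_subjects`
#' lesion-volume draws, (2) per-subject lesion growth in subject order,
#' (3) the AQ noise draws, (4) noise draws for each subscore in turn. Volumes
#' are drawn log-normal, rounded, and truncated to `[1, hemisphere capacity]`.
#'
#' @param config A `generative_config`.
#' @param mask_sink Optional `function(mask)` called with each subject's
#'   `lesion_mask` as it is generated (used to stream masks to disk without
#'   holding the whole cohort in memory).
#' @param keep_masks If `TRUE`, the returned object carries the lesion masks.
#' @return A list of class `synthetic_cohort` with elements `cohort`
#'   (an [new_lsm_cohort()] object), `atlas`, `truth` (critical ROI labels
#'   and weights, per-subject noise, noise-free true severity, seed) and,
#'   if requested, `masks`.
#' @export
simulate_cohort <- function(config, mask_sink = NULL, keep_masks = FALSE) {
  stopifnot(inherits(config, "generative_config"))
  atlas <- make_synthetic_atlas(config)
  crit <- config$critical_rois
  if (is.null(crit)) crit <- default_critical_rois(atlas, length(config$critical_weights))
  w <- config$critical_weights
  n <- config$n_subjects
  capacity <- sum(atlas$grid != 0L)

  set.seed(config$seed)
  volumes <- pmin(pmax(round(stats::rlnorm(n, config$lesion_volume_log_mean,
                                           config$lesion_volume_log_sd)), 1),
                  capacity)
  ids <- sprintf("%s_%03d", config$cohort_label, seq_len(n))
  damage <- matrix(0, n, config$n_rois,
                   dimnames = list(ids, atlas$roi_table$name))
  masks <- if (keep_masks) vector("list", n) else NULL
  for (i in seq_len(n)) {
    mask <- simulate_lesion(atlas, volumes[i], subject_id = ids[i])
    damage[i, ] <- compute_damage_vector(mask, atlas)$values
    if (!is.null(mask_sink)) mask_sink(mask)
    if (keep_masks) masks[[i]] <- mask
  }
  burden <- drop(damage[, crit, drop = FALSE] %*% w)
  true_severity <- 100 * (1 - burden)
  noise <- stats::rnorm(n, 0, config$noise_sd)
  wab_aq <- pmin(pmax(true_severity + noise, 0), 100)
  behaviour <- data.frame(subject_id = ids, wab_aq = wab_aq,
                          stringsAsFactors = FALSE)
  if (config$subscores) {
    ranges <- c(spontaneous_speech = 20, auditory_verbal_comprehension = 200,
                repetition = 100, naming = 100)
    for (nm in names(ranges)) {
      sc <- ranges[[nm]]
      sub_noise <- stats::rnorm(n, 0, config$noise_sd * sc / 100)
      behaviour[[nm]] <- pmin(pmax(sc * (1 - burden) + sub_noise, 0), sc)
    }
  }
  cohort <- new_lsm_cohort(damage = damage, lesion_volumes = volumes,
                           behaviour = behaviour,
                           roi_table = atlas$roi_table,
                           cohort_label = config$cohort_label,
                           atlas_voxels = capacity)
  structure(
    list(cohort = cohort, atlas = atlas,
         truth = list(critical_rois = crit, critical_weights = w,
                      critical_names = atlas$roi_table$name[crit],
                      noise = noise, true_severity = true_severity,
                      seed = config$seed),
         masks = masks, config = config),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort (seed ", x$truth$seed, ")\n", sep = "")
  print(x$cohort)
  cat("  critical ROIs:",
      paste(sprintf("%s (w=%.2f)", x$truth$critical_names,
                    x$truth$critical_weights), collapse = ", "), "\n")
  invisible(x)
}

# The labelled ROIs nearest the hemisphere centroid: a deterministic
# stand-in for the perisylvian regions that drive aphasia severity.
default_critical_rois <- function(atlas, k) {
  d <- dim(atlas$grid)
  idx <- which(atlas$grid != 0L)
  lab <- atlas$grid[idx]
  nx <- d[1L]; sxy <- nx * d[2L]
  ijk <- cbind((idx - 1L) %% nx + 1L,
               ((idx - 1L) %/% nx) %% d[2L] + 1L,
               (idx - 1L) %/% sxy + 1L)
  centre <- colSums(ijk) / nrow(ijk)
  n_rois <- nrow(atlas$roi_table)
  cent <- vapply(seq_len(n_rois), function(l) {
    sel <- lab == l
    sqrt(sum((colSums(ijk[sel, , drop = FALSE]) / sum(sel) - centre)^2))
  }, numeric(1))
  order(cent)[seq_len(k)]
}

#' Write a synthetic cohort to a directory
#'
#' Lays out a cohort directory readable by [read_cohort_dir()]:
#' `masks/<subject_id>.nii.gz`, `atlas.nii.gz`, `atlas_lut.tsv`,
#' `behaviour.csv`, `ground_truth.json` and `cohort.json` (label + seed).
#'
#' @param config A `generative_config`.
#' @param dir Output directory.
#' @param force Overwrite an existing non-empty directory. Default `FALSE`.
#' @return The `synthetic_cohort` object, invisibly.
#' @export
simulate_cohort_dir <- function(config, dir, force = FALSE) {
  if (dir.exists(dir) && length(dir(dir)) > 0L && !force) {
    stop("output directory exists and is not empty (use force = TRUE): ", dir)
  }
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  sink_fun <- function(mask) {
    write_lesion_mask(mask, file.path(dir, "masks",
                                      paste0(mask$subject_id, ".nii.gz")))
  }
  sim <- simulate_cohort(config, mask_sink = sink_fun)
  write_atlas(sim$atlas, file.path(dir, "atlas.nii.gz"),
              file.path(dir, "atlas_lut.tsv"))
  utils::write.csv(sim$cohort$behaviour, file.path(dir, "behaviour.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(critical_rois = sim$truth$critical_rois,
         critical_names = sim$truth$critical_names,
         critical_weights = sim$truth$critical_weights,
         true_severity = sim$truth$true_severity,
         noise = sim$truth$noise, seed = sim$truth$seed),
    file.path(dir, "ground_truth.json"), digits = NA)
  jsonlite::write_json(
    list(cohort_label = config$cohort_label, seed = config$seed,
         n_subjects = config$n_subjects),
    file.path(dir, "cohort.json"), auto_unbox = TRUE)
  invisible(sim)
}

#' Read a cohort directory written by [simulate_cohort_dir()]
#'
#' @param dir Directory containing `masks/`, `atlas.nii.gz`, `atlas_lut.tsv`
#'   and `behaviour.csv`.
#' @param cohort_label Label override; defaults to the one stored in
#'   `cohort.json`, falling back to the directory name.
#' @return An `lsm_cohort`.
#' @export
read_cohort_dir <- function(dir, cohort_label = NULL) {
  atlas <- read_atlas(file.path(dir, "atlas.nii.gz"),
                      file.path(dir, "atlas_lut.tsv"))
  mask_files <- list.files(file.path(dir, "masks"),
                           pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
  if (length(mask_files) == 0L) stop("no masks found under ", dir)
  masks <- lapply(mask_files, read_lesion_mask)
  if (is.null(cohort_label)) {
    meta_path <- file.path(dir, "cohort.json")
    cohort_label <- if (file.exists(meta_path)) {
      jsonlite::read_json(meta_path)$cohort_label
    } else {
      basename(dir)
    }
  }
  build_cohort(masks, atlas, file.path(dir, "behaviour.csv"),
               cohort_label = cohort_label)
}
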