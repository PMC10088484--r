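# Signed sentinel reported when a regression fits perfectly (zero residual):
# the t statistic is unbounded, so a documented large-magnitude value stands
# in and such ROIs land at the permutation p floor.
STAT_SENTINEL <- 1e6

#' Minimum-damage inclusion filter
#'
#' An ROI enters the mapping analysis only if it is damaged (fraction > 0)
#' in at least a given proportion of subjects; the threshold count is
#' `round(min_prop * n)` with half-away-from-zero rounding, so 10% of 109
#' subjects gives 11 and 10% of 63 gives 6. This guards against ROIs whose
#' apparent effect rests on one or two lesions.
#'
#' @param cohort An `lsm_cohort`.
#' @param min_prop Minimum proportion of damaged subjects, in `(0, 1]`.
#'   Default 0.10.
#' @return An `inclusion_filter` object: list with `included` (logical, named
#'   by ROI), `threshold_count`, `damaged_counts`, `min_prop`, `n_subjects`.
#' @export
inclusion_filter <- function(cohort, min_prop = 0.10) {
  stopifnot(inherits(cohort, "lsm_cohort"))
  if (!is.numeric(min_prop) || min_prop <= 0 || min_prop > 1) {
    stop("min_prop must lie in (0, 1]")
  }
  n <- nrow(cohort$damage)
  counts <- colSums(cohort$damage > 0)
  threshold <- round_half_away(min_prop * n)
  structure(
    list(included = counts >= threshold,
         threshold_count = threshold,
         damaged_counts = counts,
         min_prop = min_prop,
         n_subjects = n),
    class = "inclusion_filter"
  )
}

#' @export
print.inclusion_filter <- function(x, ...) {
  cat("Inclusion filter: damaged in >= ", x$threshold_count, " of ",
      x$n_subjects, " subjects (", 100 * x$min_prop, "%): ",
      sum(x$included), "/", length(x$included), " ROIs included\n", sep = "")
  invisible(x)
}

# round-half-away-from-zero (base round() is round-half-even)
round_half_away <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Per-ROI association statistic
#'
#' The t statistic of the slope from a simple linear regression of the
#' behavioural score on the damage fraction. Negative values mean damage
#' lowers the score. A perfect (zero-residual) fit with nonzero slope is
#' reported as `sign(slope) * 1e6`; a zero slope (e.g. constant scores)
#' gives 0.
#'
#' @param damage Numeric vector of damage fractions (not constant).
#' @param scores Numeric vector of behavioural scores, same length >= 3.
#' @return Signed scalar statistic.
#' @export
roi_statistic <- function(damage, scores) {
  n <- length(damage)
  if (length(scores) != n) stop("damage and scores must have equal length")
  if (n < 3L) stop("at least 3 subjects are required")
  if (stats::sd(damage) == 0) {
    stop("damage column is constant; exclude it via inclusion_filter()")
  }
  drop(column_statistics(matrix(damage, ncol = 1L), matrix(scores, ncol = 1L)))
}

# Vectorised slope-t: D is n x R damage, Y is n x B score columns; returns
# R x B matrix of t statistics. Uses t = r * sqrt((n-2) / (1-r^2)), identical
# to the slope t of lm(score ~ damage). Constant score columns give r = NA,
# reported as statistic 0; |r| = 1 maps to the signed sentinel.
column_statistics <- function(D, Y) {
  n <- nrow(D)
  R <- suppressWarnings(stats::cor(D, Y))
  T <- matrix(0, nrow(R), ncol(R), dimnames = dimnames(R))
  ok <- !is.na(R)
  denom <- 1 - R[ok]^2
  perfect <- denom < 1e-12
  tt <- numeric(sum(ok))
  tt[!perfect] <- R[ok][!perfect] *
    sqrt((n - 2) / denom[!perfect])
  tt[perfect] <- sign(R[ok][perfect]) * STAT_SENTINEL
  tt[abs(tt) > STAT_SENTINEL] <- sign(tt[abs(tt) > STAT_SENTINEL]) * STAT_SENTINEL
  T[ok] <- tt
  T
}

#' Region-based lesion-symptom mapping with permutation FWE correction
#'
#' Fits the per-ROI association statistic for every ROI passing the
#' inclusion filter, then builds a family-wise null by permuting the
#' behavioural scores across subjects (damage fixed), recomputing all ROI
#' statistics per permutation and recording each permutation's minimum (most
#' negative) statistic. The corrected p for ROI k is
#' `(1 + #\{permutation minima <= observed_k\}) / (n_permutations + 1)` -- a
#' one-tailed max-statistic correction in the damage-lowers-score direction.
#'
#' @param cohort An `lsm_cohort`.
#' @param behaviour Name of the behaviour column to map. Default `"wab_aq"`.
#' @param min_prop Inclusion threshold proportion. Default 0.10.
#' @param n_permutations Number of random permutations. Default 2000.
#' @param alpha Family-wise significance level. Default 0.05.
#' @param seed Integer seed for the permutation draws (ignored when
#'   `exact = TRUE`).
#' @param exact If `TRUE`, enumerate all `n!` score permutations instead of
#'   sampling (only feasible for small cohorts; capped at n = 8).
#' @return An object of class `rlsm` with fields `behaviour`, `statistic`
#'   (named, included ROIs only), `p_corrected`, `significant` (character
#'   vector of ROI names), `alpha`, `n_permutations`, `seed`, `exact`,
#'   `inclusion`, `null_min` (the permutation minima).
#' @seealso [inclusion_filter()], [roi_statistic()], [dice_similarity()]
#' @export
rlsm <- function(cohort, behaviour = "wab_aq", min_prop = 0.10,
                 n_permutations = 2000, alpha = 0.05, seed = 1L,
                 exact = FALSE) {
  stopifnot(inherits(cohort, "lsm_cohort"))
  if (!exact && (!is.numeric(n_permutations) || n_permutations < 1)) {
    stop("n_permutations must be >= 1")
  }
  scores <- cohort_scores(cohort, behaviour)
  incl <- inclusion_filter(cohort, min_prop)
  if (!any(incl$included)) {
    stop("no ROI survives the inclusion filter")
  }
  D <- cohort$damage[, incl$included, drop = FALSE]
  constant <- apply(D, 2L, stats::sd) == 0
  if (any(constant)) {
    warning("dropping ", sum(constant),
            " included ROI(s) with constant damage fractions")
    D <- D[, !constant, drop = FALSE]
    if (ncol(D) == 0L) stop("no usable ROI after dropping constant columns")
  }
  n <- nrow(D)
  observed <- drop(column_statistics(D, matrix(scores, ncol = 1L)))

  if (exact) {
    if (n > 8L) stop("exact enumeration is limited to n <= 8 subjects")
    perms <- all_permutations(n)
    B <- nrow(perms)
    Y <- matrix(scores[t(perms)], nrow = n)
  } else {
    B <- as.integer(n_permutations)
    set.seed(seed)
    Y <- vapply(seq_len(B), function(b) scores[sample.int(n)], numeric(n))
  }
  null_min <- apply(column_statistics(D, Y), 2L, min)
  p <- vapply(observed, function(s) (1 + sum(null_min <= s)) / (B + 1),
              numeric(1))
  sig <- names(observed)[p < alpha]
  structure(
    list(behaviour = behaviour, statistic = observed, p_corrected = p,
         significant = sig, alpha = alpha, n_permutations = B,
         seed = if (exact) NA_integer_ else as.integer(seed), exact = exact,
         inclusion = incl, null_min = null_min,
         n_subjects = n, cohort_label = cohort$cohort_label),
    class = "rlsm"
  )
}

#' @export
print.rlsm <- function(x, ...) {
  cat("RLSM of '", x$behaviour, "' in cohort '", x$cohort_label, "' (n = ",
      x$n_subjects, ")\n", sep = "")
  cat("  ", length(x$statistic), " ROIs tested (inclusion >= ",
      x$inclusion$threshold_count, " damaged subjects); ",
      if (x$exact) "exact enumeration of " else "", x$n_permutations,
      " permutations\n", sep = "")
  cat("  significant at corrected p < ", x$alpha, ": ",
      length(x$significant), " ROI(s)\n", sep = "")
  if (length(x$significant) > 0L) {
    cat("   ", paste(x$significant, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.rlsm <- function(object, ...) {
  as.data.frame(object)
}

#' @export
coef.rlsm <- function(object, ...) {
  object$statistic
}

#' @export
as.data.frame.rlsm <- function(x, ...) {
  nm <- names(x$statistic)
  data.frame(
    roi = nm,
    n_damaged = unname(x$inclusion$damaged_counts[nm]),
    statistic = unname(x$statistic),
    p_corrected = unname(x$p_corrected),
    significant = nm %in% x$significant,
    stringsAsFactors = FALSE
  )
}

#' Export RLSM results to CSV
#'
#' @param x An `rlsm` result.
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_rlsm <- function(x, path) {
  stopifnot(inherits(x, "rlsm"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Dice similarity of two ROI sets
#'
#' `2 |A intersect B| / (|A| + |B|)`, defined as 1 when both sets are empty.
#'
#' @param set_a,set_b Character (or atomic) vectors treated as sets.
#' @return Coefficient in `[0, 1]`.
#' @export
dice_similarity <- function(set_a, set_b) {
  a <- unique(set_a)
  b <- unique(set_b)
  if (length(a) == 0L && length(b) == 0L) return(1)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

# all n! permutations of 1..n as rows, deterministic order
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 0L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    block <- cbind(first, matrix(rest[sub], nrow(sub), n - 1L))
    out[row + seq_len(nrow(sub)), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Paint per-ROI values into atlas space
#'
#' Builds a volume in which each ROI's voxels carry a supplied value
#' (e.g. an SVR beta weight, or 1 for significant ROIs) -- the data behind a
#' results brain map.
#'
#' @param atlas A `lesion_atlas`.
#' @param values Named numeric vector; names must be ROI names from the
#'   atlas. Unnamed ROIs get `background`.
#' @param background Value for background and unlisted ROIs. Default 0.
#' @return An `overlay_volume`-like list with the painted `grid`.
#' @export
paint_roi_values <- function(atlas, values, background = 0) {
  stopifnot(inherits(atlas, "lesion_atlas"))
  unknown <- setdiff(names(values), atlas$roi_table$name)
  if (length(unknown) > 0L) {
    stop("unknown ROI name(s): ", paste(unknown, collapse = ", "))
  }
  lut <- rep(background, max(atlas$roi_table$label))
  idx <- atlas$roi_table$label[match(names(values), atlas$roi_table$name)]
  lut[idx] <- values
  grid <- array(background, dim = dim(atlas$grid))
  nz <- atlas$grid != 0L
  grid[nz] <- lut[atlas$grid[nz]]
  structure(
    list(grid = grid, n_subjects = NA_integer_,
         voxel_dims = atlas$voxel_dims, affine = atlas$affine),
    class = "overlay_volume"
  )
}
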