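#' Pearson prediction accuracy
#'
#' Sample Pearson correlation with its two-tailed t-based p-value, the
#' accuracy measure used for every prediction design.
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return List with `r`, `p_value`, `n`.
#' @export
pearson_accuracy <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("at least 3 pairs are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation is undefined for constant input")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Fisher r-to-z comparison of two independent correlations
#'
#' Tests whether two Pearson correlations observed in independent samples
#' differ: `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))` with a
#' two-tailed normal p-value. Swapping the two samples negates `z` and
#' leaves `p` unchanged. Note the test treats the two correlations as
#' independent; applying it to correlations computed on the same test
#' subjects (as is common when comparing prediction designs) ignores their
#' dependence.
#'
#' @param r1,r2 Correlations, strictly inside (-1, 1).
#' @param n1,n2 Sample sizes, each >= 4.
#' @return A `fisher_z` object: list with `r1`, `n1`, `r2`, `n2`, `z`,
#'   `p_two_tailed`.
#' @examples
#' fisher_z_compare(0.7221, 63, 0.5205, 109)  # z rounds to 2.07
#' @export
fisher_z_compare <- function(r1, n1, r2, n2) {
  for (r in c(r1, r2)) {
    if (!is.finite(r) || abs(r) >= 1) {
      stop("correlations must lie strictly inside (-1, 1)")
    }
  }
  if (n1 <= 3 || n2 <= 3) stop("each sample size must be at least 4")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  structure(
    list(r1 = r1, n1 = n1, r2 = r2, n2 = n2, z = z,
         p_two_tailed = 2 * stats::pnorm(-abs(z))),
    class = "fisher_z"
  )
}

#' @export
print.fisher_z <- function(x, ...) {
  cat(sprintf(
    "Fisher r-to-z: r1 = %.4f (n = %d) vs r2 = %.4f (n = %d)\n",
    x$r1, as.integer(x$n1), x$r2, as.integer(x$n2)))
  cat(sprintf("  z = %.2f (unrounded %.4f), two-tailed p = %.4f\n",
              x$z, x$z, x$p_two_tailed))
  invisible(x)
}

#' Welch two-sample comparison
#'
#' Welch's unequal-variance t-test with Welch-Satterthwaite degrees of
#' freedom, plus the group descriptives it was computed from.
#'
#' @param x,y Numeric vectors, each of length >= 2; at least one group must
#'   have positive variance.
#' @return A `welch_comparison`: list with `mean_x`, `mean_y`, `sd_x`,
#'   `sd_y`, `n_x`, `n_y`, `t`, `df`, `p_two_tailed`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs at least 2 observations")
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    stop("both groups have zero variance; the comparison is degenerate")
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  structure(
    list(mean_x = mean(x), mean_y = mean(y),
         sd_x = stats::sd(x), sd_y = stats::sd(y),
         n_x = length(x), n_y = length(y),
         t = unname(tt$statistic), df = unname(tt$parameter),
         p_two_tailed = tt$p.value),
    class = "welch_comparison"
  )
}

#' @export
print.welch_comparison <- function(x, ...) {
  cat(sprintf("Welch t-test: M1 = %.2f (SD %.2f, n %d) vs M2 = %.2f (SD %.2f, n %d)\n",
              x$mean_x, x$sd_x, x$n_x, x$mean_y, x$sd_y, x$n_y))
  cat(sprintf("  t(%.1f) = %.3f, two-tailed p = %.4f\n",
              x$df, x$t, x$p_two_tailed))
  invisible(x)
}
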