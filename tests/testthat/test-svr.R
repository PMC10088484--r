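test_that("score normalization maps 0-100 onto 0-1", {
  expect_equal(normalize_scores(c(0, 80, 100)), c(0, 0.8, 1))
  expect_error(normalize_scores(c(50, 101)), "0, 100")
  expect_error(normalize_scores(c(-1, 50)), "0, 100")
})

test_that("constant targets give an offset-only model", {
  set.seed(1)
  X <- matrix(stats::runif(30), 10, 3)
  fit <- train_svr(X, rep(0.7, 10), epsilon = 0.1)
  expect_lt(max(abs(fit$beta)), 1e-8)
  expect_true(all(abs(predict(fit, X) - 0.7) <= 0.1 + 1e-8))
})

test_that("a noise-free linear law is recovered from one feature", {
  set.seed(2)
  damage <- matrix(stats::runif(100), ncol = 1,
                   dimnames = list(NULL, "ROI_001"))
  scores <- 1 - damage[, 1]
  fit <- train_svr(damage, scores, cost = 100, epsilon = 0.01)
  expect_lt(abs(fit$beta[["ROI_001"]] - (-1)), 0.05)
  r_in <- pearson_accuracy(scores, predict(fit, damage))$r
  expect_gte(r_in, 0.999)
})

test_that("tiny-instance solutions match the quadratic-program oracle", {
  set.seed(13)
  for (trial in 1:5) {
    X <- matrix(stats::runif(8), 4, 2)
    y <- stats::runif(4)
    fit <- train_svr(X, y, cost = 1, epsilon = 0.05)
    orc <- svr_qp_oracle(X, y, C = 1, eps = 0.05)
    expect_lt(max(abs(unname(fit$beta) - orc$beta)), 1e-4)
    expect_lt(abs(fit$offset - orc$offset), 1e-4)
  }
})

test_that("leave-one-out produces n folds and never leaks the held-out score", {
  sim <- simulate_cohort(small_sim_config(seed = 17, n_subjects = 20))
  cohort <- sim$cohort
  res <- loo_evaluate(cohort)
  expect_equal(res$n_folds, 20)
  expect_length(res$predicted, 20)
  expect_equal(nrow(res$fold_betas), 20)
  expect_equal(res$design, "loo_synthetic")
  expect_equal(unname(res$averaged_beta),
               unname(colMeans(res$fold_betas)))

  # leakage probe: changing subject i's score leaves fold i's prediction
  # untouched
  for (i in c(1, 7)) {
    mutated <- cohort
    mutated$behaviour$wab_aq[i] <-
      (mutated$behaviour$wab_aq[i] + 41) %% 100
    res2 <- loo_evaluate(mutated)
    expect_equal(res2$predicted[i], res$predicted[i], tolerance = 1e-10)
  }
})

test_that("predictions are invariant to training-set subject order", {
  sim <- simulate_cohort(small_sim_config(seed = 23, n_subjects = 25))
  test_cohort <- simulate_cohort(small_sim_config(seed = 24,
                                                  n_subjects = 10))$cohort
  base <- cross_evaluate(sim$cohort, test_cohort)

  perm <- sample(25)
  shuffled <- sim$cohort
  shuffled$damage <- shuffled$damage[perm, ]
  shuffled$lesion_volumes <- shuffled$lesion_volumes[perm]
  shuffled$behaviour <- shuffled$behaviour[perm, ]
  re <- cross_evaluate(shuffled, test_cohort)
  expect_equal(re$predicted, base$predicted, tolerance = 1e-6)
})

test_that("cross-cohort features align by ROI name", {
  sim <- simulate_cohort(small_sim_config(seed = 3, n_subjects = 15))
  test_cohort <- simulate_cohort(small_sim_config(seed = 6,
                                                  n_subjects = 12))$cohort
  base <- cross_evaluate(sim$cohort, test_cohort)

  shuffled <- test_cohort
  col_perm <- sample(ncol(shuffled$damage))
  shuffled$damage <- shuffled$damage[, col_perm]
  re <- cross_evaluate(sim$cohort, shuffled)
  expect_equal(re$predicted, base$predicted)

  renamed <- test_cohort
  colnames(renamed$damage)[1] <- "NOT_AN_ROI"
  expect_error(cross_evaluate(sim$cohort, renamed), "feature names")
})

test_that("in-sample fit is at least as good as held-out LOO accuracy", {
  diffs <- vapply(1:11, function(s) {
    cohort <- simulate_cohort(small_sim_config(seed = 600 + s,
                                               n_subjects = 40))$cohort
    cross_evaluate(cohort, cohort)$pearson_r -
      loo_evaluate(cohort)$pearson_r
  }, numeric(1))
  expect_gte(stats::median(diffs), 0)
})

test_that("damage features predict at least as well as volume alone", {
  diffs <- vapply(1:9, function(s) {
    cohort <- simulate_cohort(small_sim_config(seed = 700 + s,
                                               n_subjects = 60))$cohort
    loo_evaluate(cohort, feature_mode = "roi_damage")$pearson_r -
      loo_evaluate(cohort, feature_mode = "volume_only")$pearson_r
  }, numeric(1))
  expect_gte(stats::median(diffs), 0)
})

test_that("volume-only mode uses one bounded feature", {
  cohort <- simulate_cohort(small_sim_config(seed = 2, n_subjects = 12))$cohort
  X <- roilsm:::cohort_features(cohort, "volume_only")
  expect_equal(colnames(X), "lesion_volume")
  expect_true(all(X >= 0 & X <= 1))
  res <- loo_evaluate(cohort, feature_mode = "volume_only")
  expect_length(res$averaged_beta, 1)
})

test_that("most negative betas sort ascending with stable ties", {
  expect_equal(top_negative_betas(c(a = -3, b = -1, c = 2), k = 2)$roi,
               c("a", "b"))
  expect_equal(top_negative_betas(c(a = -3, b = -1, c = 2), k = 10)$roi,
               c("a", "b", "c"))
  expect_equal(top_negative_betas(c(a = -1, b = -1, c = -2), k = 3)$roi,
               c("c", "a", "b"))
  expect_error(top_negative_betas(c(a = 1), k = 0), "k must be")
})

test_that("fitted models serialize to JSON and back", {
  set.seed(4)
  X <- matrix(stats::runif(40), 10, 4,
              dimnames = list(NULL, paste0("ROI_", 1:4)))
  y <- stats::runif(10)
  fit <- train_svr(X, y)
  f <- withr::local_tempfile(fileext = ".json")
  write_svr_model(fit, f)
  back <- read_svr_model(f)
  expect_equal(back$beta, fit$beta)
  expect_equal(back$offset, fit$offset)
  expect_equal(predict(back, X), predict(fit, X))
})

test_that("raw predictions may leave [0,1] unless clipping is requested", {
  X <- matrix(seq(0, 1, length.out = 10), ncol = 1,
              dimnames = list(NULL, "d"))
  y <- seq(1, 0, length.out = 10)
  fit <- train_svr(X, y, cost = 100, epsilon = 0.01)
  wide <- matrix(c(-0.5, 1.5), ncol = 1, dimnames = list(NULL, "d"))
  raw <- predict(fit, wide)
  expect_true(any(raw < 0 | raw > 1))
  clipped <- predict(fit, wide, clip = TRUE)
  expect_true(all(clipped >= 0 & clipped <= 1))
})
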