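#' Normalize raw 0-100 severity scores to 0-1
#'
#' @param raw Numeric vector of scores on the 0-100 scale.
#' @return `raw / 100`.
#' @export
normalize_scores <- function(raw) {
  if (anyNA(raw) || any(raw < 0) || any(raw > 100)) {
    stop("scores must lie in [0, 100] with no missing values")
  }
  raw / 100
}

#' Fit a linear epsilon-insensitive support-vector regression
#'
#' Trains a linear SVR predicting a normalized severity score from regional
#' damage fractions (or any feature matrix), returning one beta weight per
#' feature plus an offset, so that `prediction = features %*% beta + offset`.
#' Features are used as-is (no standardization); the solver is libsvm's
#' epsilon-regression via \pkg{e1071}. When all scores fit inside the
#' epsilon tube the model degenerates to an offset-only fit with near-zero
#' betas -- this is a legitimate solution, not an error.
#'
#' @param features Numeric matrix, subjects x features (>= 3 rows), finite.
#' @param scores Numeric response on the 0-1 scale (see
#'   [normalize_scores()]).
#' @param cost Regularization parameter C. Default 1.
#' @param epsilon Insensitivity-tube half-width on the score scale.
#'   Default 0.1.
#' @param feature_mode `"roi_damage"` or `"volume_only"`; a bookkeeping tag.
#' @param tolerance Termination tolerance of the underlying solver. The
#'   default 1e-6 is much tighter than libsvm's 1e-3 so that solutions are
#'   reproducible to the accuracy at which quadratic-programming cross-checks
#'   operate.
#' @return An object of class `lsm_svr`: list with `beta` (named), `offset`,
#'   `cost`, `epsilon`, `feature_mode`, `feature_names`, `n_train`.
#' @export
train_svr <- function(features, scores, cost = 1, epsilon = 0.1,
                      feature_mode = "roi_damage", tolerance = 1e-6) {
  features <- as.matrix(features)
  if (nrow(features) < 3L) stop("at least 3 training subjects are required")
  if (length(scores) != nrow(features)) {
    stop("scores and feature rows must match")
  }
  if (!all(is.finite(features))) stop("features must be finite")
  if (is.null(colnames(features))) {
    colnames(features) <- sprintf("f%03d", seq_len(ncol(features)))
  }
  fit <- e1071::svm(x = features, y = scores, type = "eps-regression",
                    kernel = "linear", cost = cost, epsilon = epsilon,
                    scale = FALSE, fitted = FALSE, tolerance = tolerance)
  # with every score inside the epsilon tube there are no support vectors
  # and the model is offset-only
  beta <- if (is.null(fit$coefs) || nrow(fit$SV) == 0L) {
    numeric(ncol(features))
  } else {
    drop(crossprod(fit$coefs, fit$SV))
  }
  beta <- stats::setNames(as.numeric(beta), colnames(features))
  structure(
    list(beta = beta, offset = -fit$rho, cost = cost, epsilon = epsilon,
         feature_mode = feature_mode, feature_names = colnames(features),
         n_train = nrow(features)),
    class = "lsm_svr"
  )
}

#' @export
print.lsm_svr <- function(x, ...) {
  cat("Linear SVR (", x$feature_mode, "): ", length(x$beta),
      " feature(s), trained on ", x$n_train, " subjects\n", sep = "")
  cat("  C = ", x$cost, ", epsilon = ", x$epsilon,
      ", offset = ", signif(x$offset, 4), "\n", sep = "")
  invisible(x)
}

#' @export
coef.lsm_svr <- function(object, ...) {
  c(object$beta, `(offset)` = object$offset)
}

#' Predict severity scores from a fitted linear SVR
#'
#' @param object An `lsm_svr`.
#' @param newdata Feature matrix or an `lsm_cohort` (features are then
#'   extracted according to the model's `feature_mode`). Columns are aligned
#'   to the model's features by name when names are available.
#' @param clip If `TRUE`, clip predictions into `[0, 1]`. Default `FALSE`:
#'   raw predictions may fall outside the score range.
#' @param ... Unused.
#' @return Numeric vector of predicted normalized scores.
#' @export
predict.lsm_svr <- function(object, newdata, clip = FALSE, ...) {
  if (inherits(newdata, "lsm_cohort")) {
    newdata <- cohort_features(newdata, object$feature_mode)
  }
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata))) {
    missing <- setdiff(object$feature_names, colnames(newdata))
    if (length(missing) > 0L) {
      stop("newdata lacks model feature(s): ",
           paste(utils::head(missing, 5L), collapse = ", "))
    }
    newdata <- newdata[, object$feature_names, drop = FALSE]
  } else if (ncol(newdata) != length(object$beta)) {
    stop("newdata has ", ncol(newdata), " columns but the model expects ",
         length(object$beta))
  }
  pred <- drop(newdata %*% object$beta + object$offset)
  if (clip) pred <- pmin(pmax(pred, 0), 1)
  pred
}

# Feature extraction shared by every design. volume_only rescales voxel
# counts by the labelled-atlas voxel count so the single feature lies in
# [0, 1], commensurate with damage fractions.
cohort_features <- function(cohort, feature_mode = c("roi_damage",
                                                     "volume_only")) {
  feature_mode <- match.arg(feature_mode)
  if (feature_mode == "roi_damage") {
    return(cohort$damage)
  }
  if (is.na(cohort$atlas_voxels)) {
    stop("cohort lacks the atlas voxel count needed to scale lesion volume")
  }
  matrix(cohort$lesion_volumes / cohort$atlas_voxels,
         ncol = 1L, dimnames = list(rownames(cohort$damage), "lesion_volume"))
}

#' Leave-one-out prediction of severity within a cohort
#'
#' Iteratively sets one subject aside, trains the SVR on the remaining
#' `n - 1` subjects and predicts the held-out subject, yielding `n` held-out
#' predictions from `n` fold models. Accuracy is the Pearson correlation
#' between actual and predicted normalized scores; reported beta weights are
#' the arithmetic mean of the fold betas.
#'
#' @param cohort An `lsm_cohort` with at least 4 subjects.
#' @param behaviour Behaviour column to predict (raw 0-100; normalized
#'   internally). Default `"wab_aq"`.
#' @param feature_mode `"roi_damage"` or `"volume_only"`.
#' @param cost,epsilon SVR hyperparameters. Defaults 1 and 0.1.
#' @param clip Clip predictions to `[0, 1]`? Default `FALSE`.
#' @return An `lsm_prediction` object: list with `design`, `subject_id`,
#'   `actual`, `predicted` (normalized scores), `pearson_r`, `p_value`,
#'   `averaged_beta`, `averaged_offset`, `fold_betas`, `feature_mode`,
#'   `n_folds`, `behaviour`.
#' @export
loo_evaluate <- function(cohort, behaviour = "wab_aq",
                         feature_mode = "roi_damage", cost = 1,
                         epsilon = 0.1, clip = FALSE) {
  stopifnot(inherits(cohort, "lsm_cohort"))
  X <- cohort_features(cohort, feature_mode)
  y <- normalize_scores(cohort_scores(cohort, behaviour))
  n <- nrow(X)
  if (n < 4L) stop("leave-one-out needs at least 4 subjects")
  predicted <- numeric(n)
  fold_betas <- matrix(NA_real_, n, ncol(X),
                       dimnames = list(rownames(X), colnames(X)))
  offsets <- numeric(n)
  for (i in seq_len(n)) {
    fit <- train_svr(X[-i, , drop = FALSE], y[-i], cost = cost,
                     epsilon = epsilon, feature_mode = feature_mode)
    predicted[i] <- predict(fit, X[i, , drop = FALSE], clip = clip)
    fold_betas[i, ] <- fit$beta
    offsets[i] <- fit$offset
  }
  acc <- pearson_accuracy(y, predicted)
  new_lsm_prediction(
    design = paste0("loo_", cohort$cohort_label),
    subject_id = rownames(X), actual = y, predicted = predicted,
    pearson_r = acc$r, p_value = acc$p_value,
    averaged_beta = colMeans(fold_betas), averaged_offset = mean(offsets),
    fold_betas = fold_betas, feature_mode = feature_mode, n_folds = n,
    behaviour = behaviour
  )
}

#' Train on one cohort, predict severity in another
#'
#' A single model is trained on the whole training cohort and applied to the
#' test cohort; features are aligned by ROI name. Reported beta weights are
#' those of the single training model.
#'
#' @param train,test `lsm_cohort` objects sharing the same ROI names.
#' @inheritParams loo_evaluate
#' @return An `lsm_prediction`; its `model` field holds the fitted
#'   `lsm_svr`.
#' @export
cross_evaluate <- function(train, test, behaviour = "wab_aq",
                           feature_mode = "roi_damage", cost = 1,
                           epsilon = 0.1, clip = FALSE) {
  stopifnot(inherits(train, "lsm_cohort"), inherits(test, "lsm_cohort"))
  Xtr <- cohort_features(train, feature_mode)
  Xte <- cohort_features(test, feature_mode)
  if (!setequal(colnames(Xtr), colnames(Xte))) {
    stop("train and test cohorts have different feature names")
  }
  ytr <- normalize_scores(cohort_scores(train, behaviour))
  yte <- normalize_scores(cohort_scores(test, behaviour))
  fit <- train_svr(Xtr, ytr, cost = cost, epsilon = epsilon,
                   feature_mode = feature_mode)
  predicted <- predict(fit, Xte, clip = clip)
  acc <- pearson_accuracy(yte, predicted)
  out <- new_lsm_prediction(
    design = paste0("train_", train$cohort_label, "_test_",
                    test$cohort_label),
    subject_id = rownames(Xte), actual = yte, predicted = predicted,
    pearson_r = acc$r, p_value = acc$p_value,
    averaged_beta = fit$beta, averaged_offset = fit$offset,
    fold_betas = NULL, feature_mode = feature_mode, n_folds = 1L,
    behaviour = behaviour
  )
  out$model <- fit
  out
}

new_lsm_prediction <- function(design, subject_id, actual, predicted,
                               pearson_r, p_value, averaged_beta,
                               averaged_offset, fold_betas, feature_mode,
                               n_folds, behaviour) {
  structure(
    list(design = design, subject_id = subject_id, actual = actual,
         predicted = predicted, pearson_r = pearson_r, p_value = p_value,
         averaged_beta = averaged_beta, averaged_offset = averaged_offset,
         fold_betas = fold_betas, feature_mode = feature_mode,
         n_folds = n_folds, behaviour = behaviour),
    class = "lsm_prediction"
  )
}

#' @export
print.lsm_prediction <- function(x, ...) {
  cat("Prediction (", x$design, ", ", x$feature_mode, ") of '", x$behaviour,
      "'\n", sep = "")
  cat("  n = ", length(x$predicted), ", Pearson r = ",
      sprintf("%.4f", x$pearson_r), " (p = ", format.pval(x$p_value),
      ")\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.lsm_prediction <- function(x, ...) {
  data.frame(subject_id = x$subject_id, actual = x$actual,
             predicted = x$predicted, design = x$design,
             feature_mode = x$feature_mode, stringsAsFactors = FALSE)
}

#' @export
plot.lsm_prediction <- function(x, ...) {
  graphics::plot(x$actual, x$predicted,
                 xlab = "Actual (normalized)", ylab = "Predicted",
                 main = sprintf("%s (r = %.3f)", x$design, x$pearson_r), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' The k most negative beta weights
#'
#' ROIs whose damage most lowers the predicted score: betas sorted
#' ascending, ties broken by original feature order, clamped to the number
#' of features.
#'
#' @param x An `lsm_svr`, an `lsm_prediction` (its averaged betas are used),
#'   or a named numeric vector of betas.
#' @param k Number of ROIs to return. Default 10.
#' @return Data frame with columns `roi` and `beta`, most negative first.
#' @export
top_negative_betas <- function(x, k = 10) {
  if (k < 1L) stop("k must be >= 1")
  beta <- if (inherits(x, "lsm_svr")) x$beta
          else if (inherits(x, "lsm_prediction")) x$averaged_beta
          else x
  if (is.null(names(beta))) names(beta) <- sprintf("f%03d", seq_along(beta))
  ord <- order(beta, seq_along(beta))
  take <- utils::head(ord, min(k, length(beta)))
  data.frame(roi = names(beta)[take], beta = unname(beta[take]),
             stringsAsFactors = FALSE)
}

#' Serialize a fitted SVR model to JSON
#'
#' @param model An `lsm_svr`.
#' @param path Destination JSON path.
#' @return `path`, invisibly.
#' @export
write_svr_model <- function(model, path) {
  stopifnot(inherits(model, "lsm_svr"))
  jsonlite::write_json(
    list(feature_names = model$feature_names, beta = unname(model$beta),
         offset = model$offset, cost = model$cost, epsilon = model$epsilon,
         feature_mode = model$feature_mode, n_train = model$n_train),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a serialized SVR model
#'
#' @param path JSON path written by [write_svr_model()].
#' @return An `lsm_svr`.
#' @export
read_svr_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(beta = stats::setNames(as.numeric(j$beta), j$feature_names),
         offset = j$offset, cost = j$cost, epsilon = j$epsilon,
         feature_mode = j$feature_mode, feature_names = j$feature_names,
         n_train = j$n_train),
    class = "lsm_svr"
  )
}
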