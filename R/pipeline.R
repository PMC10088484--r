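#' Assemble a configuration for the full analysis pipeline
#'
#' A run configuration names the two cohorts (each may be an `lsm_cohort`, a
#' cohort directory path, or a `generative_config` to simulate on the fly)
#' and the analysis settings. `run_config()` can also load these fields from
#' a YAML file.
#'
#' @param acute,chronic Cohort inputs (object, directory path or generative
#'   config).
#' @param rlsm_behaviours Behaviours to map with RLSM; `NULL` means every
#'   behaviour present in both cohorts.
#' @param svr_behaviour Behaviour predicted by the SVR designs.
#'   Default `"wab_aq"`.
#' @param min_prop,n_permutations,alpha RLSM settings (defaults 0.10, 2000,
#'   0.05).
#' @param cost,epsilon SVR hyperparameters (defaults 1, 0.1).
#' @param feature_modes Feature modes to run; default both `"roi_damage"`
#'   and `"volume_only"`.
#' @param designs Subset of the four designs `loo_acute`, `loo_chronic`,
#'   `train_acute_test_chronic`, `train_chronic_test_acute`.
#' @param seed Master seed; stage-level seeds are derived from it.
#' @param output_dir If non-`NULL`, [run_full_analysis()] writes its report
#'   and tables there.
#' @param yaml Path to a YAML file supplying any of the above fields
#'   (explicit arguments win).
#' @return A `run_config` list.
#' @export
run_config <- function(acute = NULL, chronic = NULL,
                       rlsm_behaviours = NULL, svr_behaviour = "wab_aq",
                       min_prop = 0.10, n_permutations = 2000, alpha = 0.05,
                       cost = 1, epsilon = 0.1,
                       feature_modes = c("roi_damage", "volume_only"),
                       designs = c("loo_acute", "loo_chronic",
                                   "train_acute_test_chronic",
                                   "train_chronic_test_acute"),
                       seed = 1L, output_dir = NULL, yaml = NULL) {
  cfg <- list(acute = acute, chronic = chronic,
              rlsm_behaviours = rlsm_behaviours,
              svr_behaviour = svr_behaviour, min_prop = min_prop,
              n_permutations = n_permutations, alpha = alpha, cost = cost,
              epsilon = epsilon, feature_modes = feature_modes,
              designs = designs, seed = as.integer(seed),
              output_dir = output_dir)
  if (!is.null(yaml)) {
    from_file <- yaml::read_yaml(yaml)
    for (nm in names(from_file)) {
      if (is.null(cfg[[nm]]) || nm %in% names(match.call()) == FALSE) {
        cfg[[nm]] <- from_file[[nm]]
      }
    }
  }
  all_designs <- c("loo_acute", "loo_chronic", "train_acute_test_chronic",
                   "train_chronic_test_acute")
  bad <- setdiff(cfg$designs, all_designs)
  if (length(bad) > 0L) {
    stop("unknown design(s): ", paste(bad, collapse = ", "))
  }
  structure(cfg, class = "run_config")
}

resolve_cohort <- function(x, what) {
  if (inherits(x, "lsm_cohort")) return(x)
  if (inherits(x, "generative_config")) return(simulate_cohort(x)$cohort)
  if (is.character(x) && length(x) == 1L) return(read_cohort_dir(x))
  stop("cannot interpret the '", what, "' cohort input; supply an ",
       "lsm_cohort, a generative_config or a cohort directory path")
}

#' Run the complete mapping-and-prediction analysis suite
#'
#' Executes, for an acute-stage and a chronic-stage cohort: RLSM with
#' permutation correction for every requested behaviour in each cohort; the
#' dice overlap of the two cohorts' significant ROI sets per behaviour; the
#' four prediction designs (leave-one-out within each cohort, and each
#' cohort predicting the other) for each feature mode; Fisher r-to-z
#' comparisons of the prediction accuracies (within- vs between-group
#' training for each predicted stage, and acute- vs chronic-prediction for
#' each training regime); and the ten most negative beta weights per design.
#' Stages that fail raise a warning, are recorded under `failed`, and do not
#' stop the remaining stages.
#'
#' @param config A `run_config`.
#' @return A `run_report` list with elements `rlsm`, `dice`, `predictions`,
#'   `fisher`, `top_betas`, `failed`, `settings`, `timestamp`. If
#'   `config$output_dir` is set the report and tables are also written there.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  acute <- resolve_cohort(config$acute, "acute")
  chronic <- resolve_cohort(config$chronic, "chronic")
  cohorts <- list(acute = acute, chronic = chronic)
  failed <- list()
  note_failure <- function(stage, err) {
    warning("stage '", stage, "' failed: ", conditionMessage(err),
            call. = FALSE)
    failed[[stage]] <<- conditionMessage(err)
  }

  behaviours <- config$rlsm_behaviours
  if (is.null(behaviours)) {
    behaviours <- intersect(behaviour_names(acute), behaviour_names(chronic))
  }

  # --- RLSM per behaviour per cohort, each with its own derived seed -----
  rlsm_results <- list()
  seed_counter <- 0L
  for (beh in behaviours) {
    for (stage in names(cohorts)) {
      seed_counter <- seed_counter + 1L
      key <- paste(stage, beh, sep = ".")
      res <- tryCatch(
        rlsm(cohorts[[stage]], behaviour = beh, min_prop = config$min_prop,
             n_permutations = config$n_permutations, alpha = config$alpha,
             seed = config$seed + seed_counter),
        error = function(e) { note_failure(paste0("rlsm.", key), e); NULL })
      if (!is.null(res)) rlsm_results[[key]] <- res
    }
  }

  dice <- list()
  for (beh in behaviours) {
    a <- rlsm_results[[paste0("acute.", beh)]]
    b <- rlsm_results[[paste0("chronic.", beh)]]
    if (!is.null(a) && !is.null(b)) {
      dice[[beh]] <- dice_similarity(a$significant, b$significant)
    }
  }

  # --- prediction designs x feature modes --------------------------------
  predictions <- list()
  for (mode in config$feature_modes) {
    for (design in config$designs) {
      key <- paste(design, mode, sep = ".")
      res <- tryCatch(
        switch(design,
          loo_acute = loo_evaluate(acute, config$svr_behaviour, mode,
                                   config$cost, config$epsilon),
          loo_chronic = loo_evaluate(chronic, config$svr_behaviour, mode,
                                     config$cost, config$epsilon),
          train_acute_test_chronic = cross_evaluate(
            acute, chronic, config$svr_behaviour, mode, config$cost,
            config$epsilon),
          train_chronic_test_acute = cross_evaluate(
            chronic, acute, config$svr_behaviour, mode, config$cost,
            config$epsilon)),
        error = function(e) { note_failure(paste0("svr.", key), e); NULL })
      if (!is.null(res)) predictions[[key]] <- res
    }
  }

  # --- Fisher comparisons of prediction accuracies -----------------------
  fisher <- list()
  pred_r <- function(design, mode) {
    p <- predictions[[paste(design, mode, sep = ".")]]
    if (is.null(p)) NULL else p$pearson_r
  }
  n_ac <- nrow(acute$damage); n_ch <- nrow(chronic$damage)
  comparisons <- list(
    predicting_acute = list(c("loo_acute", "train_chronic_test_acute"),
                            c(n_ac, n_ac)),
    predicting_chronic = list(c("loo_chronic", "train_acute_test_chronic"),
                              c(n_ch, n_ch)),
    within_group = list(c("loo_acute", "loo_chronic"), c(n_ac, n_ch)),
    between_group = list(c("train_chronic_test_acute",
                           "train_acute_test_chronic"), c(n_ac, n_ch))
  )
  for (mode in config$feature_modes) {
    for (nm in names(comparisons)) {
      designs2 <- comparisons[[nm]][[1L]]
      ns <- comparisons[[nm]][[2L]]
      r1 <- pred_r(designs2[1L], mode); r2 <- pred_r(designs2[2L], mode)
      key <- paste(nm, mode, sep = ".")
      if (is.null(r1) || is.null(r2)) {
        failed[[paste0("fisher.", key)]] <-
          "required prediction design(s) not run"
        message("skipping Fisher comparison '", key,
                "': required design(s) absent")
        next
      }
      fisher[[key]] <- fisher_z_compare(r1, ns[1L], r2, ns[2L])
    }
  }

  # --- most negative betas (damage-feature models only) ------------------
  top_betas <- list()
  for (design in config$designs) {
    p <- predictions[[paste(design, "roi_damage", sep = ".")]]
    if (!is.null(p)) top_betas[[design]] <- top_negative_betas(p, 10)
  }

  report <- structure(
    list(rlsm = rlsm_results, dice = dice, predictions = predictions,
         fisher = fisher, top_betas = top_betas, failed = failed,
         settings = config[setdiff(names(config), c("acute", "chronic"))],
         n_subjects = c(acute = n_ac, chronic = n_ch),
         version = as.character(utils::packageVersion("roilsm")),
         timestamp = format(Sys.time(), tz = "UTC")),
    class = "run_report"
  )
  if (!is.null(config$output_dir)) write_run_report(report, config$output_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Analysis report (roilsm ", x$version, ")\n", sep = "")
  cat("  cohorts: acute n = ", x$n_subjects[["acute"]], ", chronic n = ",
      x$n_subjects[["chronic"]], "\n", sep = "")
  cat("  RLSM analyses:", length(x$rlsm), " | prediction results:",
      length(x$predictions), " | Fisher comparisons:", length(x$fisher), "\n")
  for (nm in names(x$dice)) {
    cat(sprintf("  dice overlap of significant ROIs (%s): %.3f\n",
                nm, x$dice[[nm]]))
  }
  for (nm in names(x$predictions)) {
    cat(sprintf("  %-45s r = %.4f\n", nm, x$predictions[[nm]]$pearson_r))
  }
  if (length(x$failed) > 0L) {
    cat("  FAILED stages:", paste(names(x$failed), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize a run report to machine-readable form
#'
#' Writes `report.json` plus CSV tables: one RLSM table per cohort and
#' behaviour, a combined per-subject prediction table and the top-negative
#' beta lists.
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report$rlsm)) {
    write_rlsm(report$rlsm[[nm]],
               file.path(dir, paste0("rlsm_", nm, ".csv")))
  }
  if (length(report$predictions) > 0L) {
    pred_df <- do.call(rbind, lapply(report$predictions, as.data.frame))
    utils::write.csv(pred_df, file.path(dir, "predictions.csv"),
                     row.names = FALSE)
  }
  for (nm in names(report$top_betas)) {
    utils::write.csv(report$top_betas[[nm]],
                     file.path(dir, paste0("top_betas_", nm, ".csv")),
                     row.names = FALSE)
  }
  json <- list(
    version = report$version, timestamp = report$timestamp,
    n_subjects = as.list(report$n_subjects),
    settings = report$settings[c("svr_behaviour", "min_prop",
                                 "n_permutations", "alpha", "cost",
                                 "epsilon", "seed")],
    dice = report$dice,
    predictions = lapply(report$predictions, function(p) {
      list(design = p$design, feature_mode = p$feature_mode,
           n = length(p$predicted), pearson_r = p$pearson_r,
           p_value = p$p_value)
    }),
    fisher = lapply(report$fisher, function(f) {
      list(r1 = f$r1, n1 = f$n1, r2 = f$r2, n2 = f$n2, z = f$z,
           p_two_tailed = f$p_two_tailed)
    }),
    rlsm = lapply(report$rlsm, function(r) {
      list(behaviour = r$behaviour, n_tested = length(r$statistic),
           n_permutations = r$n_permutations,
           significant = r$significant)
    }),
    top_betas = report$top_betas,
    failed = report$failed
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
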