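#' Split connectivity features by hemisphere scope
#'
#' Partitions canonical connectivity feature names into hemisphere-specific
#' candidate sets: the `left` set holds features whose every scope tag is
#' `left`, `right` analogously, and the `both` set holds every feature
#' (mixed-scope features such as `inter|MotorI:both|MotorIV:left` appear
#' only there). Under the default registry each pure-hemisphere set has
#' 6 intra + 15 inter = 21 features.
#'
#' @param features Character vector of canonical feature names.
#' @return Named list with elements `left`, `right` and `both`.
#' @export
candidate_sets_by_hemisphere <- function(features) {
  parsed <- map(features, parse_feature_name)
  scopes <- map(parsed, "scopes")
  list(
    left = features[map_lgl(scopes, function(s) all(s == "left"))],
    right = features[map_lgl(scopes, function(s) all(s == "right"))],
    both = features
  )
}

#' @importFrom purrr map_lgl
NULL

#' Strictly bilateral candidate features
#'
#' Features whose every scope tag is `both` (6 intra + 15 inter under the
#' default registry); the stricter alternative to the all-features bilateral
#' candidate set.
#'
#' @param features Character vector of canonical feature names.
#' @return Character vector.
#' @export
both_scope_features <- function(features) {
  scopes <- map(map(features, parse_feature_name), "scopes")
  features[map_lgl(scopes, function(s) all(s == "both"))]
}

#' Run the seven-model severity suite
#'
#' Builds the full set of incremental regression models on a cohort table
#' and reports their metrics side by side, all cross-validated on one shared
#' fold partition:
#'
#' 1. `lesion_only` - lesion volume as sole predictor;
#' 2. `best_connectivity_only` - the single best connectivity feature;
#' 3. `best_without_lesion` - greedy selection over all connectivity
#'    features, up to `cap` predictors;
#' 4. `best_with_lesion` - lesion volume seeded first, connectivity
#'    features added greedily;
#' 5. `left_hemisphere` / 6. `right_hemisphere` - greedy selection
#'    restricted to pure left- / right-scope features;
#' 7. `both_hemispheres` - greedy selection over the bilateral candidate
#'    set (all features by default; strictly both-scope features via
#'    `bilateral_candidates = "both_scope_only"`).
#'
#' Three comparisons accompany the models: paired fold t-tests and AIC
#' differences for left vs right and left vs bilateral, and a
#' likelihood-ratio test of the single-feature motor baseline against its
#' left-lateralized greedy extension.
#'
#' @param cohort Cohort data frame (`subject_id`, `lesion_volume`,
#'   connectivity feature columns, outcome) or a [simulate_cohort()] result.
#' @param outcome Outcome column name.
#' @param cap Maximum predictors per model.
#' @param folds Number of CV folds.
#' @param seed Integer seed controlling the shared fold partition.
#' @param vif_limit Collinearity gate applied during selection.
#' @param lrt_baseline Feature used as the motor-only baseline of the
#'   likelihood-ratio test.
#' @param bilateral_candidates `"all"` (default) or `"both_scope_only"`.
#' @return An object of class `stroke_suite`: list with `models` (tibble of
#'   per-model metrics), `comparisons` (tibble), `lrt` (tibble), `fits`,
#'   `cvs`, `paths` and `manifest`. Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @export
run_model_suite <- function(cohort, outcome = "nihss", cap = 5, folds = 5,
                            seed = 1L, vif_limit = 2,
                            lrt_baseline = "intra|MotorI:left",
                            bilateral_candidates = c("all", "both_scope_only")) {
  if (inherits(cohort, "synthetic_cohort")) cohort <- cohort$cohort
  bilateral_candidates <- match.arg(bilateral_candidates)
  check_columns(cohort, c("lesion_volume", outcome))
  reserved <- c("subject_id", "lesion_volume", outcome)
  conn <- setdiff(names(cohort), reserved)
  if (length(conn) == 0) {
    abort("The cohort has no connectivity feature columns; run feature extraction first (build_feature_vector / connectivity_feature_matrix).")
  }
  sets <- candidate_sets_by_hemisphere(conn)
  if (length(sets$left) == 0 || length(sets$right) == 0) {
    abort("Hemisphere-restricted candidate sets are empty; the cohort must carry pure left- and right-scope features.")
  }
  bilateral <- if (bilateral_candidates == "all") {
    conn
  } else {
    both_scope_features(conn)
  }

  select_with <- function(candidates, seeds = character()) {
    greedy_forward_selection(
      cohort, candidates, cap = cap, seed_predictors = seeds,
      vif_limit = vif_limit, outcome = outcome,
      cv_folds = folds, cv_seed = seed
    )
  }

  paths <- list(
    best_connectivity_only = greedy_forward_selection(
      cohort, conn, cap = 1, vif_limit = vif_limit, outcome = outcome,
      cv_folds = folds, cv_seed = seed),
    best_without_lesion = select_with(conn),
    best_with_lesion = select_with(conn, seeds = "lesion_volume"),
    left_hemisphere = select_with(sets$left),
    right_hemisphere = select_with(sets$right),
    both_hemispheres = select_with(bilateral)
  )

  fits <- c(
    list(lesion_only = fit_linear_model(cohort, "lesion_volume", outcome)),
    map(paths, "fit")
  )
  cvs <- c(
    list(lesion_only = kfold_cv(cohort, "lesion_volume", k = folds,
                                seed = seed, outcome = outcome)),
    map(paths, "cv")
  )
  order_names <- c("lesion_only", "best_connectivity_only",
                   "best_without_lesion", "best_with_lesion",
                   "left_hemisphere", "right_hemisphere",
                   "both_hemispheres")
  fits <- fits[order_names]
  cvs <- cvs[order_names]

  models <- dplyr::bind_rows(map(order_names, function(nm) {
    f <- fits[[nm]]
    cv <- cvs[[nm]]
    tibble(
      model = nm,
      n_predictors = f$k,
      predictors = list(f$predictor_names),
      r_squared = f$r_squared,
      adj_r_squared = f$adj_r_squared,
      aic = f$aic,
      bic = f$bic,
      cv_r_squared = cv$cv_r_squared,
      cv_mse = cv$cv_mse
    )
  }))

  comparison_row <- function(label, a, b) {
    tt <- paired_fold_ttest(cvs[[a]], cvs[[b]])
    tibble(comparison = label, model_a = a, model_b = b,
           t_statistic = tt$t_statistic, df = tt$df, p_value = tt$p_value,
           delta_aic = delta_aic(fits[[a]], fits[[b]]))
  }
  comparisons <- dplyr::bind_rows(
    comparison_row("left_vs_right", "left_hemisphere", "right_hemisphere"),
    comparison_row("left_vs_bilateral", "left_hemisphere", "both_hemispheres")
  )

  # Motor-baseline LRT: single-feature baseline extended with
  # left-lateralized predictors chosen greedily up to the cap.
  lrt <- NULL
  if (lrt_baseline %in% conn) {
    base_fit <- fit_linear_model(cohort, lrt_baseline, outcome)
    ext <- greedy_forward_selection(
      cohort, setdiff(sets$left, lrt_baseline), cap = cap,
      seed_predictors = lrt_baseline, vif_limit = vif_limit,
      outcome = outcome
    )
    lrt <- dplyr::bind_cols(
      tibble(comparison = "motor_baseline_vs_left_extended",
             baseline = lrt_baseline),
      likelihood_ratio_test(base_fit, ext$fit)
    )
  }

  structure(
    list(models = models, comparisons = comparisons, lrt = lrt,
         fits = fits, cvs = cvs, paths = paths,
         manifest = list(
           seed = seed, folds = folds, cap = cap, vif_limit = vif_limit,
           outcome = outcome, n_subjects = nrow(cohort),
           n_features = length(conn),
           bilateral_candidates = bilateral_candidates,
           package_version = as.character(utils::packageVersion("strokeconn"))
         )),
    class = "stroke_suite"
  )
}

#' @export
print.stroke_suite <- function(x, ...) {
  cat("<stroke_suite>: ", nrow(x$models), " models, ",
      x$manifest$folds, "-fold CV (seed ", x$manifest$seed, "), n = ",
      x$manifest$n_subjects, "\n", sep = "")
  m <- x$models
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-24s R^2 %.3f  adjR^2 %.3f  AIC %8.2f  CV R^2 %7.3f  CV MSE %7.3f\n",
                m$model[i], m$r_squared[i], m$adj_r_squared[i], m$aic[i],
                m$cv_r_squared[i], m$cv_mse[i]))
  }
  invisible(x)
}

#' Write a model-suite report to CSV and Markdown
#'
#' @param suite A [run_model_suite()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_suite_report <- function(suite, dir) {
  stopifnot(inherits(suite, "stroke_suite"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- tidy(suite)
  csv <- file.path(dir, "model_suite.csv")
  readr::write_csv(dplyr::select(tab, -predictors), csv)
  md <- file.path(dir, "model_suite.md")
  hdr <- c("Model", "R-Squared", "Adjusted R-Squared", "AIC", "BIC",
           "Cross-Validated R-Squared", "Cross-Validated MSE")
  lines <- c(
    paste0("| ", paste(hdr, collapse = " | "), " |"),
    paste0("|", paste(rep("---", length(hdr)), collapse = "|"), "|"),
    map_chr(seq_len(nrow(tab)), function(i) {
      sprintf("| %s | %.2f | %.2f | %.2f | %.2f | %.2f | %.2f |",
              tab$model[i], tab$r_squared[i], tab$adj_r_squared[i],
              tab$aic[i], tab$bic[i], tab$cv_r_squared[i], tab$cv_mse[i])
    })
  )
  writeLines(lines, md)
  cmp <- file.path(dir, "comparisons.csv")
  readr::write_csv(suite$comparisons, cmp)
  invisible(c(csv = csv, md = md, comparisons = cmp))
}
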