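#' Fit an ordinary least squares severity model
#'
#' Multiple linear regression of the outcome (NIHSS by default) on a named
#' set of predictors, with intercept. Information criteria use the Gaussian
#' log-likelihood including constants, counting the error variance as a
#' parameter (`k + 2` parameters for `k` predictors).
#'
#' @param table Cohort data frame: one row per subject, named predictor
#'   columns plus the outcome column.
#' @param predictors Character vector of predictor column names.
#' @param outcome Outcome column name (default `"nihss"`).
#' @return An object of class `stroke_fit` with fields `predictor_names`,
#'   `coefficients`, `r_squared`, `adj_r_squared`, `aic`, `bic`,
#'   `log_likelihood`, `residuals`, `fitted`, `n`, `k`, and the underlying
#'   `lm` object. Supports [tidy()], [glance()] and [autoplot()].
#' @export
#' @examples
#' d <- tibble::tibble(x = 1:10, nihss = 2 + 3 * (1:10))
#' fit <- fit_linear_model(d, "x")
#' glance(fit)
fit_linear_model <- function(table, predictors, outcome = "nihss") {
  check_columns(table, c(predictors, outcome))
  n <- nrow(table)
  k <- length(predictors)
  if (n <= k + 1) {
    abort(sprintf("Need n > k + 1 observations (n = %d, k = %d).", n, k))
  }
  y <- table[[outcome]]
  if (anyNA(y)) abort("The outcome contains missing values.")
  X <- design_matrix(table, predictors)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    abort(paste0("Design is rank deficient; collinear column(s): ",
                 paste(dropped, collapse = ", ")))
  }
  dat <- as.data.frame(table[, c(outcome, predictors), drop = FALSE])
  fml <- stats::reformulate(
    if (k == 0) "1" else sprintf("`%s`", predictors),
    response = sprintf("`%s`", outcome)
  )
  model <- lm(fml, data = dat)
  smry <- summary(model)
  structure(
    list(model = model,
         predictor_names = predictors,
         outcome = outcome,
         coefficients = coef(model),
         r_squared = smry$r.squared,
         adj_r_squared = smry$adj.r.squared,
         aic = AIC(model),
         bic = BIC(model),
         log_likelihood = as.numeric(logLik(model)),
         residuals = resid(model),
         fitted = stats::fitted(model),
         rss = sum(resid(model)^2),
         n = n, k = k),
    class = "stroke_fit"
  )
}

#' @export
print.stroke_fit <- function(x, ...) {
  cat("<stroke_fit>: ", x$outcome, " ~ ",
      if (x$k == 0) "1" else paste(x$predictor_names, collapse = " + "),
      "\n  n = ", x$n, ", R^2 = ", signif(x$r_squared, 4),
      ", adj R^2 = ", signif(x$adj_r_squared, 4),
      ", AIC = ", signif(x$aic, 6), "\n", sep = "")
  invisible(x)
}

check_columns <- function(table, cols) {
  if (!is.data.frame(table)) abort("`table` must be a data frame.")
  missing <- setdiff(cols, names(table))
  if (length(missing) > 0) {
    abort(paste0("Column(s) not found in the table: ",
                 paste(missing, collapse = ", ")))
  }
}

design_matrix <- function(table, predictors) {
  X <- cbind(`(Intercept)` = 1,
             as.matrix(table[, predictors, drop = FALSE]))
  storage.mode(X) <- "double"
  X
}

# Residual sum of squares of an OLS fit, fast path used by selection and CV.
ols_rss <- function(X, y) {
  fit <- .lm.fit(X, y)
  sum(fit$residuals^2)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing predictor
#' `j` on the other predictors (with intercept). Perfectly collinear
#' predictors are reported as `Inf` rather than raising an error, so that
#' selection code can gate on the value.
#'
#' @param table Cohort data frame.
#' @param predictors At least two predictor column names.
#' @return A tibble with columns `predictor` and `vif`.
#' @export
#' @examples
#' d <- tibble::tibble(a = rnorm(20), b = rnorm(20))
#' compute_vif(d, c("a", "b"))
compute_vif <- function(table, predictors) {
  check_columns(table, predictors)
  if (length(predictors) < 2) {
    abort("VIF needs at least two predictors.")
  }
  X <- as.matrix(table[, predictors, drop = FALSE])
  vifs <- map_dbl(seq_along(predictors), function(j) {
    xj <- X[, j]
    others <- cbind(1, X[, -j, drop = FALSE])
    rss <- ols_rss(others, xj)
    tss <- sum((xj - mean(xj))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - rss / tss
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  })
  tibble(predictor = predictors, vif = vifs)
}

#' Greedy forward selection with a collinearity gate
#'
#' Builds a model incrementally: at each step every remaining candidate is
#' added in turn to the current predictor set, and the candidate yielding
#' the largest increase in training R-squared is kept, provided all VIF
#' values of the resulting set stay below `vif_limit`. Selection stops at
#' `cap` predictors or when no admissible candidate increases R-squared.
#' Ties are broken by candidate order (canonical feature order).
#'
#' @param table Cohort data frame.
#' @param candidates Candidate predictor names, in canonical order.
#' @param cap Maximum total number of predictors including seeds (default 5,
#'   about one predictor per nine subjects at n = 44).
#' @param seed_predictors Predictors forced into the model before selection
#'   starts (e.g. `"lesion_volume"`).
#' @param vif_limit Upper bound (exclusive) on every VIF (default 2).
#' @param outcome Outcome column name.
#' @param cv_folds,cv_seed When `cv_seed` is non-`NULL`, K-fold
#'   cross-validation is run after each step (shared partition across
#'   steps) and stored alongside the fit; selection itself always uses
#'   training R-squared.
#' @return An object of class `selection_path`: list with `steps` (one
#'   entry per selection step: `predictor`, `fit`, `cv`), `seed_fit` (the
#'   model before any selection, when seeds are present), `predictors`
#'   (final set) and `fit` (final model). Supports [tidy()].
#' @export
greedy_forward_selection <- function(table, candidates, cap = 5,
                                     seed_predictors = character(),
                                     vif_limit = 2, outcome = "nihss",
                                     cv_folds = 5, cv_seed = NULL) {
  check_columns(table, c(candidates, seed_predictors, outcome))
  if (length(intersect(candidates, seed_predictors)) > 0) {
    abort("`candidates` must be disjoint from `seed_predictors`.")
  }
  if (cap < length(seed_predictors)) {
    abort("`cap` must be at least the number of seed predictors.")
  }
  y <- table[[outcome]]
  tss <- sum((y - mean(y))^2)
  Xall <- as.matrix(table[, candidates, drop = FALSE])
  current <- seed_predictors
  Xcur <- design_matrix(table, current)
  r2_cur <- 1 - ols_rss(Xcur, y) / tss

  cv_for <- function(preds) {
    if (is.null(cv_seed) || length(preds) == 0) return(NULL)
    kfold_cv(table, preds, k = cv_folds, seed = cv_seed, outcome = outcome)
  }
  seed_fit <- if (length(current) > 0) {
    fit_linear_model(table, current, outcome)
  } else NULL

  steps <- list()
  remaining <- candidates
  while (length(current) < cap && length(remaining) > 0) {
    r2_add <- map_dbl(remaining, function(nm) {
      1 - ols_rss(cbind(Xcur, Xall[, nm]), y) / tss
    })
    ord <- order(-r2_add, seq_along(r2_add))  # ties keep canonical order
    chosen <- NULL
    for (j in ord) {
      if (r2_add[j] <= r2_cur + 1e-12) break  # no admissible improvement left
      trial <- c(current, remaining[j])
      if (length(trial) >= 2) {
        v <- compute_vif(table, trial)$vif
        if (any(v >= vif_limit)) next
      }
      chosen <- j
      break
    }
    if (is.null(chosen)) break
    nm <- remaining[chosen]
    current <- c(current, nm)
    Xcur <- cbind(Xcur, Xall[, nm])
    r2_cur <- r2_add[chosen]
    remaining <- setdiff(remaining, nm)
    fit <- fit_linear_model(table, current, outcome)
    steps[[length(steps) + 1L]] <- list(predictor = nm, fit = fit,
                                        cv = cv_for(current))
  }
  final_fit <- if (length(steps) > 0) {
    steps[[length(steps)]]$fit
  } else {
    seed_fit
  }
  structure(
    list(steps = steps, seed_predictors = seed_predictors,
         seed_fit = seed_fit, cap = cap, vif_limit = vif_limit,
         predictors = current, fit = final_fit,
         cv = if (length(steps) > 0) steps[[length(steps)]]$cv else cv_for(current)),
    class = "selection_path"
  )
}

#' @export
print.selection_path <- function(x, ...) {
  cat("<selection_path>: ",
      if (length(x$seed_predictors) > 0) {
        paste0("seeds {", paste(x$seed_predictors, collapse = ", "), "} + ")
      } else "",
      length(x$steps), " selected step(s), cap ", x$cap, "\n", sep = "")
  for (s in x$steps) {
    cat("  + ", s$predictor, " (R^2 = ", signif(s$fit$r_squared, 4), ")\n",
        sep = "")
  }
  invisible(x)
}

#' K-fold cross-validation of a fixed predictor set
#'
#' Subjects are randomly partitioned into `k` folds of near-equal size
#' (sizes differ by at most one). For each fold the model is fit on the
#' remaining folds and evaluated on the held-out fold:
#' `fold R^2 = 1 - SSE / SST` with SST taken about the held-out fold's own
#' outcome mean. Cross-validated R-squared and MSE are unweighted means over
#' folds; a pooled-prediction R-squared (all held-out residuals against the
#' overall mean) is reported alongside. The partition is a deterministic
#' function of `seed`, so several models evaluated with the same seed share
#' folds and can be compared pairwise.
#'
#' @param table Cohort data frame.
#' @param predictors Predictor column names.
#' @param k Number of folds (default 5).
#' @param seed Integer seed controlling the partition.
#' @param outcome Outcome column name.
#' @return An object of class `stroke_cv` with `fold_assignments`,
#'   `per_fold_r_squared`, `per_fold_mse`, `cv_r_squared`, `cv_mse`,
#'   `pooled_r_squared` and `seed`. Supports [tidy()] and [glance()].
#' @export
kfold_cv <- function(table, predictors, k = 5, seed, outcome = "nihss") {
  check_columns(table, c(predictors, outcome))
  n <- nrow(table)
  if (n < k) abort("Need at least as many subjects as folds.")
  if (missing(seed)) abort("`seed` is required (folds must be reproducible).")
  y <- table[[outcome]]
  folds <- withr::with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  X <- design_matrix(table, predictors)
  per_r2 <- numeric(k)
  per_mse <- numeric(k)
  pooled_sse <- 0
  for (f in seq_len(k)) {
    test <- folds == f
    fit <- .lm.fit(X[!test, , drop = FALSE], y[!test])
    pred <- X[test, , drop = FALSE] %*% fit$coefficients
    sse <- sum((y[test] - pred)^2)
    sst <- sum((y[test] - mean(y[test]))^2)
    if (sst == 0) {
      abort(sprintf(
        "Fold %d has zero outcome variance; its R^2 is undefined. Re-seed the partition.", f))
    }
    per_r2[f] <- 1 - sse / sst
    per_mse[f] <- sse / sum(test)
    pooled_sse <- pooled_sse + sse
  }
  structure(
    list(fold_assignments = setNames(folds,
           table[["subject_id"]] %||% seq_len(n)),
         per_fold_r_squared = per_r2,
         per_fold_mse = per_mse,
         cv_r_squared = mean(per_r2),
         cv_mse = mean(per_mse),
         pooled_r_squared = 1 - pooled_sse / sum((y - mean(y))^2),
         k = k, seed = seed, predictors = predictors, outcome = outcome),
    class = "stroke_cv"
  )
}

#' @export
print.stroke_cv <- function(x, ...) {
  cat("<stroke_cv>: ", x$k, "-fold, CV R^2 = ", signif(x$cv_r_squared, 4),
      ", CV MSE = ", signif(x$cv_mse, 4), " (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Shapiro-Wilk check of residual normality
#'
#' Tests the fitted model's residuals for approximate normality and returns
#' the data needed for a Q-Q plot.
#'
#' @param fit A [fit_linear_model()] result.
#' @return A list with `w_statistic`, `p_value` and `qq` (a tibble of
#'   `theoretical` and `sample` quantiles, theoretical strictly
#'   increasing).
#' @export
residual_normality_check <- function(fit) {
  stopifnot(inherits(fit, "stroke_fit"))
  r <- fit$residuals
  if (length(r) < 3) abort("Need at least 3 residuals.")
  if (sd(r) < 1e-10) {
    abort("Residuals are constant (perfect fit); normality is undefined.")
  }
  sw <- shapiro.test(r)
  list(
    w_statistic = unname(sw$statistic),
    p_value = sw$p.value,
    qq = tibble(theoretical = qnorm(ppoints(length(r))),
                sample = sort(r))
  )
}
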