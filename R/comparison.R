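#' Paired t-test across shared cross-validation folds
#'
#' Two-sided paired t-test on the per-fold R-squared differences of two
#' models evaluated on an identical fold partition (same CV seed). With K
#' folds the test has K - 1 degrees of freedom and the folds are not
#' independent, so p-values are optimistic; a Nadeau-Bengio-style corrected
#' variance is available via `correction = "nadeau_bengio"`.
#'
#' @param cv_a,cv_b [kfold_cv()] results computed with the same seed on the
#'   same subjects.
#' @param correction `"none"` (plain paired t-test, default) or
#'   `"nadeau_bengio"` (variance inflated by `1/K + n_test/n_train`).
#' @return One-row tibble with `t_statistic`, `df`, `p_value`,
#'   `mean_difference` (a minus b) and `correction`.
#' @export
paired_fold_ttest <- function(cv_a, cv_b,
                              correction = c("none", "nadeau_bengio")) {
  stopifnot(inherits(cv_a, "stroke_cv"), inherits(cv_b, "stroke_cv"))
  correction <- match.arg(correction)
  if (!identical(unname(cv_a$fold_assignments),
                 unname(cv_b$fold_assignments))) {
    abort("Fold assignments differ; rerun both cross-validations with the same seed so the pairing is meaningful.")
  }
  d <- cv_a$per_fold_r_squared - cv_b$per_fold_r_squared
  K <- length(d)
  if (all(d == 0)) {
    # identical per-fold scores: no evidence of any difference
    return(tibble(t_statistic = 0, df = K - 1, p_value = 1,
                  mean_difference = 0, correction = correction))
  }
  if (sd(d) == 0) {
    abort("Per-fold differences have zero variance; the paired t-test is degenerate.")
  }
  if (correction == "none") {
    ht <- t.test(cv_a$per_fold_r_squared, cv_b$per_fold_r_squared,
                 paired = TRUE)
    t_stat <- unname(ht$statistic)
    p <- ht$p.value
  } else {
    n <- length(cv_a$fold_assignments)
    n_test <- n / K
    n_train <- n - n_test
    se <- sqrt(var(d) * (1 / K + n_test / n_train))
    t_stat <- mean(d) / se
    p <- 2 * pt(-abs(t_stat), df = K - 1)
  }
  tibble(t_statistic = t_stat, df = K - 1, p_value = p,
         mean_difference = mean(d), correction = correction)
}

#' Likelihood-ratio test between nested OLS models
#'
#' `chi2 = 2 * (logL_full - logL_nested)` compared to a chi-square
#' distribution with `df = k_full - k_nested`. For Gaussian OLS this equals
#' `n * log(RSS_nested / RSS_full)`.
#'
#' @param fit_nested,fit_full [fit_linear_model()] results on the same
#'   subjects and outcome; the nested model's predictors must be a proper
#'   subset of the full model's.
#' @return One-row tibble with `chi_squared`, `df` and `p_value`.
#' @export
likelihood_ratio_test <- function(fit_nested, fit_full) {
  stopifnot(inherits(fit_nested, "stroke_fit"),
            inherits(fit_full, "stroke_fit"))
  if (fit_nested$n != fit_full$n ||
      !identical(fit_nested$outcome, fit_full$outcome)) {
    abort("Models must be fit to the same subjects and outcome.")
  }
  if (!all(fit_nested$predictor_names %in% fit_full$predictor_names)) {
    abort("Models are not nested: the first model's predictors must be a subset of the second's.")
  }
  chi2 <- 2 * (fit_full$log_likelihood - fit_nested$log_likelihood)
  if (chi2 < -1e-8) {
    abort("Likelihood ordering violated: the full model has lower likelihood than the nested model.")
  }
  chi2 <- max(chi2, 0)
  df <- fit_full$k - fit_nested$k
  p <- if (df == 0) 1 else pchisq(chi2, df, lower.tail = FALSE)
  tibble(chi_squared = chi2, df = df, p_value = p)
}

#' AIC difference between two models
#'
#' `AIC_a - AIC_b`; positive values favour model b (lower AIC is better).
#'
#' @param fit_a,fit_b [fit_linear_model()] results on the same subjects and
#'   outcome.
#' @return A single AIC difference.
#' @export
delta_aic <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "stroke_fit"), inherits(fit_b, "stroke_fit"))
  if (fit_a$n != fit_b$n || !identical(fit_a$outcome, fit_b$outcome)) {
    abort("Models must be fit to the same subjects and outcome.")
  }
  fit_a$aic - fit_b$aic
}
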