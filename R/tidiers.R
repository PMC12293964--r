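#' Tidiers for fitted severity models
#'
#' @param x A `stroke_fit`, `stroke_cv`, `selection_path` or `stroke_suite`
#'   object.
#' @param ... Unused, for generic consistency.
#' @return A tibble; see each method.
#' @name strokeconn-tidiers
NULL

#' @describeIn strokeconn-tidiers Coefficient table (term, estimate,
#'   std.error, statistic, p.value).
#' @method tidy stroke_fit
#' @export
tidy.stroke_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble(term = gsub("`", "", rownames(s), fixed = TRUE),
         estimate = s[, 1], std.error = s[, 2],
         statistic = s[, 3], p.value = s[, 4])
}

#' @describeIn strokeconn-tidiers One-row model summary (r.squared,
#'   adj.r.squared, AIC, BIC, logLik, n, k).
#' @method glance stroke_fit
#' @export
glance.stroke_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, adj.r.squared = x$adj_r_squared,
         AIC = x$aic, BIC = x$bic, logLik = x$log_likelihood,
         n = x$n, k = x$k)
}

#' @describeIn strokeconn-tidiers Per-fold metrics of a cross-validation.
#' @method tidy stroke_cv
#' @export
tidy.stroke_cv <- function(x, ...) {
  tibble(fold = seq_len(x$k),
         n_test = as.integer(table(x$fold_assignments)),
         r_squared = x$per_fold_r_squared,
         mse = x$per_fold_mse)
}

#' @describeIn strokeconn-tidiers One-row cross-validation summary.
#' @method glance stroke_cv
#' @export
glance.stroke_cv <- function(x, ...) {
  tibble(cv.r.squared = x$cv_r_squared, cv.mse = x$cv_mse,
         pooled.r.squared = x$pooled_r_squared, k = x$k, seed = x$seed)
}

#' @describeIn strokeconn-tidiers One row per selection step with training
#'   and cross-validated metrics.
#' @method tidy selection_path
#' @export
tidy.selection_path <- function(x, ...) {
  dplyr::bind_rows(map(seq_along(x$steps), function(i) {
    s <- x$steps[[i]]
    tibble(step = i, predictor = s$predictor,
           r_squared = s$fit$r_squared,
           adj_r_squared = s$fit$adj_r_squared,
           aic = s$fit$aic,
           cv_r_squared = if (is.null(s$cv)) NA_real_ else s$cv$cv_r_squared)
  }))
}

#' @describeIn strokeconn-tidiers The per-model metrics table of a suite.
#' @method tidy stroke_suite
#' @export
tidy.stroke_suite <- function(x, ...) x$models

#' @describeIn strokeconn-tidiers One-row suite summary: best model by
#'   cross-validated R-squared.
#' @method glance stroke_suite
#' @export
glance.stroke_suite <- function(x, ...) {
  best <- x$models[which.max(x$models$cv_r_squared), ]
  tibble(n_models = nrow(x$models),
         best_model = best$model,
         best_cv_r_squared = best$cv_r_squared,
         seed = x$manifest$seed)
}
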