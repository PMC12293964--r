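test_that("OLS fits match closed forms and the normal-equations oracle", {
  d <- tibble::tibble(x = 1:10, nihss = 2 + 3 * (1:10))
  fit <- fit_linear_model(d, "x")
  expect_equal(unname(fit$coefficients), c(2, 3), tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)

  d0 <- tibble::tibble(nihss = rnorm(15))
  fit0 <- fit_linear_model(d0, character(0))
  expect_equal(fit0$r_squared, 0)
  expect_equal(unname(fit0$coefficients), mean(d0$nihss))

  # 6 points, 2 predictors: direct matrix solve
  d6 <- withr::with_seed(8, tibble::tibble(
    a = rnorm(6), b = rnorm(6), nihss = rnorm(6)))
  fit6 <- fit_linear_model(d6, c("a", "b"))
  X <- cbind(1, d6$a, d6$b)
  beta <- solve(t(X) %*% X, t(X) %*% d6$nihss)
  expect_equal(unname(fit6$coefficients), as.vector(beta), tolerance = 1e-10)

  # AIC/BIC convention: Gaussian log-likelihood, k + 2 parameters
  rss <- sum(fit6$residuals^2)
  n <- 6
  ll <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  expect_equal(fit6$log_likelihood, ll)
  expect_equal(fit6$aic, -2 * ll + 2 * (2 + 2))
  expect_equal(fit6$bic, -2 * ll + log(n) * (2 + 2))

  d6$c <- d6$a + d6$b
  expect_error(fit_linear_model(d6, c("a", "b", "c")), "rank deficient.*c")
  expect_error(fit_linear_model(d6, c("a", "missing")), "missing")
  expect_error(fit_linear_model(d6[1:3, ], c("a", "b")), "n > k \\+ 1")
})

test_that("VIF matches its closed form and reports collinearity as Inf", {
  n <- 40
  # orthogonal by construction
  d <- tibble::tibble(a = rep(c(1, -1), n / 2), b = rep(c(1, 1, -1, -1), n / 4))
  v <- compute_vif(d, c("a", "b"))
  expect_equal(v$vif, c(1, 1))

  # correlation exactly 0.6 via fixed vectors
  x <- scale(rnorm(n))[, 1]
  e <- withr::with_seed(2, scale(resid(lm(rnorm(n) ~ x)))[, 1])
  y <- 0.6 * x + sqrt(1 - 0.36) * e
  d2 <- tibble::tibble(a = x, b = y)
  expect_equal(compute_vif(d2, c("a", "b"))$vif,
               rep(1 / (1 - 0.36), 2), tolerance = 1e-10)

  d3 <- tibble::tibble(a = rnorm(n))
  d3$b <- 2 * d3$a
  expect_identical(compute_vif(d3, c("a", "b"))$vif, c(Inf, Inf))
  expect_error(compute_vif(d3, "a"), "at least two")
})

test_that("greedy selection matches exhaustive scans and gates on VIF", {
  set.seed(31)
  n <- 44
  d <- tibble::tibble(
    x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n), x4 = rnorm(n)
  )
  d$nihss <- 1 + 2 * d$x2 + 0.8 * d$x4 + rnorm(n)

  # cap = 1 equals the exhaustive single-predictor argmax
  path1 <- greedy_forward_selection(d, paste0("x", 1:4), cap = 1)
  scan <- vapply(paste0("x", 1:4), function(p) {
    fit_linear_model(d, p)$r_squared
  }, numeric(1))
  expect_identical(path1$predictors, names(which.max(scan)))

  # orthogonalized candidates: greedy cap-3 equals best subset of size 3
  Q <- qr.Q(qr(matrix(rnorm(n * 8), n)))
  do <- tibble::as_tibble(as.data.frame(Q))
  names(do) <- paste0("q", 1:8)
  do$nihss <- 2 * Q[, 2] - 1.5 * Q[, 5] + Q[, 7] + rnorm(n, sd = 0.5)
  path3 <- greedy_forward_selection(do, paste0("q", 1:8), cap = 3)
  combos <- utils::combn(paste0("q", 1:8), 3, simplify = FALSE)
  best <- combos[[which.max(vapply(combos, function(cs) {
    fit_linear_model(do, cs)$r_squared
  }, numeric(1)))]]
  expect_setequal(path3$predictors, best)

  # a candidate perfectly collinear with a seed predictor is never selected
  d$dup <- 2 * d$x2
  path_gate <- greedy_forward_selection(
    d, c("dup", paste0("x", c(1, 3, 4))), cap = 3, seed_predictors = "x2")
  expect_false("dup" %in% path_gate$predictors)

  # monotone path: training R^2 never decreases
  r2s <- vapply(path3$steps, function(s) s$fit$r_squared, numeric(1))
  expect_true(all(diff(r2s) >= 0))
  expect_lte(length(path3$predictors), 3)

  expect_error(
    greedy_forward_selection(d, c("x1", "x2"), seed_predictors = "x1"),
    "disjoint"
  )
})

test_that("k-fold CV partitions correctly, is seed-stable and scores noiseless fits perfectly", {
  set.seed(4)
  d <- tibble::tibble(x = rnorm(44))
  d$nihss <- 1 + 2 * d$x
  cv <- kfold_cv(d, "x", k = 5, seed = 99)
  expect_equal(sort(as.integer(table(cv$fold_assignments))),
               c(8, 9, 9, 9, 9))
  expect_equal(cv$per_fold_r_squared, rep(1, 5))
  expect_equal(cv$cv_mse, 0, tolerance = 1e-20)

  cv2 <- kfold_cv(d, "x", k = 5, seed = 99)
  expect_identical(cv, cv2)
  cv3 <- kfold_cv(d, "x", k = 5, seed = 100)
  expect_false(identical(cv$fold_assignments, cv3$fold_assignments))

  dconst <- tibble::tibble(x = rnorm(20), nihss = rep(3, 20))
  expect_error(kfold_cv(dconst, "x", k = 5, seed = 1),
               "zero outcome variance")
  expect_error(kfold_cv(d, "x", k = 5), "required")
})

test_that("CV of an uninformative model is centred near zero (null-simulation oracle)", {
  cvs <- vapply(1:200, function(s) {
    d <- withr::with_seed(s, tibble::tibble(
      x1 = rnorm(44), x2 = rnorm(44), nihss = rnorm(44)))
    kfold_cv(d, c("x1", "x2"), k = 5, seed = s)$cv_r_squared
  }, numeric(1))
  expect_lt(mean(cvs), 0.05)
})

test_that("residual normality check is calibrated and detects heavy tails", {
  d <- withr::with_seed(1, tibble::tibble(x = rnorm(44),
                                          nihss = 1 + rnorm(44)))
  chk <- residual_normality_check(fit_linear_model(d, "x"))
  expect_true(all(diff(chk$qq$theoretical) > 0))
  expect_equal(chk$p_value,
               shapiro.test(resid(lm(nihss ~ x, data = d)))$p.value)

  # power against t_2 residuals at n = 44
  rej <- vapply(1:200, function(s) {
    dd <- withr::with_seed(s, tibble::tibble(
      x = rnorm(44), nihss = 1 + 0.5 * stats::rt(44, df = 2)))
    residual_normality_check(fit_linear_model(dd, "x"))$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.5)

  dflat <- tibble::tibble(x = 1:10, nihss = rep(5, 10))
  expect_error(residual_normality_check(fit_linear_model(dflat, "x")),
               "constant")
})

test_that("tidy and glance return the documented tibbles", {
  d <- withr::with_seed(3, tibble::tibble(a = rnorm(30), b = rnorm(30)))
  d$nihss <- 1 + d$a + rnorm(30)
  fit <- fit_linear_model(d, c("a", "b"))
  td <- tidy(fit)
  expect_identical(td$term, c("(Intercept)", "a", "b"))
  expect_named(glance(fit),
               c("r.squared", "adj.r.squared", "AIC", "BIC", "logLik",
                 "n", "k"))
  cv <- kfold_cv(d, "a", k = 5, seed = 2)
  expect_identical(nrow(tidy(cv)), 5L)
  expect_named(glance(cv), c("cv.r.squared", "cv.mse", "pooled.r.squared",
                             "k", "seed"))
})

test_that("greedy selection recovers distinct informative predictors (parameter recovery)", {
  # Identifiable conditions: connectivity uncoupled from lesion volume and
  # candidates restricted to the pure-hemisphere intra features, which carry
  # mutually independent subject-level signal. Recovery is counted only when
  # a feature's partial R^2 (given the other generating predictors) exceeds
  # 0.10, i.e. when it is actually informative in that cohort.
  sets <- candidate_sets_by_hemisphere(
    feature_names(default_network_registry()))
  pure_intra <- grep("^intra\\|", c(sets$left, sets$right), value = TRUE)
  res <- lapply(1:50, function(s) {
    co <- simulate_cohort(
      simulation_config(seed = s, connectivity_damping_slope = 0))
    truth <- setdiff(names(co$truth$coefficients), "(Intercept)")
    conn_truth <- setdiff(truth, "lesion_volume")
    full <- fit_linear_model(co$cohort, truth)
    partial <- vapply(conn_truth, function(p) {
      red <- fit_linear_model(co$cohort, setdiff(truth, p))
      (red$rss - full$rss) / red$rss
    }, numeric(1))
    path <- greedy_forward_selection(co$cohort, pure_intra, cap = 5,
                                     seed_predictors = "lesion_volume")
    cbind(partial, selected = conn_truth %in% path$predictors)
  })
  res <- do.call(rbind, res)
  informative <- res[res[, "partial"] > 0.10, , drop = FALSE]
  expect_gt(nrow(informative), 30)
  expect_gte(mean(informative[, "selected"]), 0.8)
})
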