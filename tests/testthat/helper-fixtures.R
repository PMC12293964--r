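# Small registries and cohorts used across tests.

# Two disjoint two-region networks: 8 lateralized regions, 18 features.
disjoint_registry <- function() {
  network_registry(list(NetA = c("R1", "R2"), NetB = c("R3", "R4")))
}

# Two networks sharing region S (4 base regions, 8 lateralized): exercises
# the inter-network self-pair exclusion.
overlapping_registry <- function() {
  network_registry(list(NetA = c("S", "P"), NetB = c("S", "Q", "W")))
}

# Fast simulation settings for tests that only need structure, not power.
quick_config <- function(...) {
  args <- utils::modifyList(list(n_subjects = 12, n_timepoints = 80),
                            rlang::list2(...), keep.null = TRUE)
  do.call(simulation_config, args)
}

# Deterministic toy time series with known correlations is easiest to build
# from a target covariance.
mvn_timeseries <- function(sigma, n_time, region_names, seed = 1,
                           sampling_interval = 1.78) {
  stopifnot(nrow(sigma) == length(region_names))
  L <- chol(sigma)
  z <- withr::with_seed(seed,
    matrix(rnorm(n_time * nrow(sigma)), n_time))
  roi_timeseries(z %*% L, region_names, sampling_interval)
}

# A minimal cross-validation object for comparison tests that need exact
# per-fold scores.
fake_cv <- function(per_fold, folds = rep(seq_along(per_fold), 4),
                    seed = 1) {
  structure(
    list(fold_assignments = folds,
         per_fold_r_squared = per_fold,
         per_fold_mse = rep(1, length(per_fold)),
         cv_r_squared = mean(per_fold),
         cv_mse = 1,
         pooled_r_squared = mean(per_fold),
         k = length(per_fold), seed = seed,
         predictors = "x", outcome = "nihss"),
    class = "stroke_cv"
  )
}

# Brute-force connectivity oracle: enumerate every qualifying region pair
# and average arctanh of the raw correlations, independently of the
# package's indexing machinery.
brute_force_feature <- function(ts, registry, feature) {
  r <- cor(ts$data)
  parsed <- parse_feature_name(feature)
  cfgs <- network_configurations(registry)
  labels <- vapply(cfgs, function(cf) cf$label, character(1))
  pick <- function(net, scope) cfgs[[which(labels == paste0(net, ":", scope))]]
  zclip <- function(v) atanh(pmin(pmax(v, -(1 - 1e-7)), 1 - 1e-7))
  if (parsed$type == "intra") {
    cf <- pick(parsed$networks[1], parsed$scopes[1])
    vals <- c()
    m <- cf$members
    for (i in seq_along(m)) {
      for (j in seq_along(m)) {
        if (i < j) vals <- c(vals, zclip(r[m[i], m[j]]))
      }
    }
    mean(vals)
  } else {
    ca <- pick(parsed$networks[1], parsed$scopes[1])
    cb <- pick(parsed$networks[2], parsed$scopes[2])
    vals <- c()
    for (a in ca$members) {
      for (b in cb$members) {
        if (a != b) vals <- c(vals, zclip(r[a, b]))
      }
    }
    mean(vals)
  }
}
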