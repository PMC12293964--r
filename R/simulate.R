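#' Configure a synthetic stroke cohort
#'
#' Defines the generative model for synthetic cohorts with the statistical
#' structure the downstream analysis assumes: block-structured network
#' covariance in the ROI time series, lesion volumes coupled to
#' within-network connectivity degradation, and an NIHSS outcome generated
#' by a linear model with Gaussian noise.
#'
#' The region covariance is realized through a latent factor model: a global
#' factor carries the between-network correlation, one factor per network
#' and hemisphere (left/right factors coupled at `homotopic_coupling`)
#' carries the within-network correlation, and region-specific noise makes
#' up the remaining unit variance. For networks that share no regions this
#' reproduces the configured block correlations exactly; regions belonging
#' to several networks split their loadings across memberships, which keeps
#' the covariance positive definite for any admissible configuration.
#'
#' Per-subject variation enters in two ways: within-network correlations of
#' the `affected_networks` are attenuated by
#' `lesion volume * connectivity_damping_slope`, and every network's
#' correlation per hemisphere receives a subject-specific Gaussian offset
#' with standard deviation `subject_r_sd` (individual differences in
#' connectivity, which give connectivity features predictive signal beyond
#' lesion volume).
#'
#' @param n_subjects Number of subjects (default 44).
#' @param n_timepoints BOLD volumes per subject (default 260).
#' @param sampling_interval Repetition time in seconds (default 1.78).
#' @param within_network_r Baseline within-network correlation; a single
#'   value or a named vector (one entry per registry network).
#' @param between_network_r Between-network correlation, in `[0, 1)`.
#' @param homotopic_coupling Correlation between the left and right factor
#'   of a network; controls how strongly interhemispheric homologue pairs
#'   correlate relative to within-hemisphere pairs.
#' @param subject_r_sd Standard deviation of per-subject, per-network,
#'   per-hemisphere correlation offsets (clipped at 2.5 sd).
#' @param lesion_volume_range Lesion volume interval in cubic millimeters;
#'   volumes are drawn uniformly and rounded to whole mm^3.
#' @param connectivity_damping_slope Per-mm^3 attenuation of within-network
#'   correlation in affected networks: the within-correlation is multiplied
#'   by `1 - slope * volume`.
#' @param affected_networks Networks whose connectivity is damped by the
#'   lesion. `NULL` (default) selects the primary sensorimotor and basal
#'   ganglia networks (`MotorI`, `MotorIV`) when the registry defines them,
#'   otherwise none.
#' @param outcome_coefficients Named numeric vector: `(Intercept)` plus one
#'   slope per predictor (`lesion_volume` or a connectivity feature name),
#'   in NIHSS points per unit.
#' @param noise_sd Outcome noise standard deviation in NIHSS points, or
#'   `NULL` to derive it from `target_design_r2`.
#' @param target_design_r2 Desired design R-squared
#'   `var(lp) / (var(lp) + noise_sd^2)` of the generating linear model;
#'   when set, `noise_sd` is calibrated per cohort from the realized linear
#'   predictor. Exactly one of `noise_sd` and `target_design_r2` must be
#'   given.
#' @param integer_outcome If `TRUE`, outcomes are rounded to integers and
#'   clipped to `[0, 14]` (mild-to-moderate NIHSS); continuous by default.
#' @param ar1_phi Optional AR(1) coefficient applied to all latent series,
#'   so that temporal filtering can be exercised on temporally structured
#'   input; 0 (white) by default. Series are rescaled to unit variance, so
#'   the configured correlations are unchanged.
#' @param registry A [network_registry()].
#' @param seed Master integer seed. Per-subject streams are derived from it
#'   in a way that is stable under changes of `n_subjects`.
#' @return An object of class `simulation_config`.
#' @export
#' @examples
#' cfg <- simulation_config(n_subjects = 8, n_timepoints = 80)
#' cohort <- simulate_cohort(cfg)
simulation_config <- function(n_subjects = 44,
                              n_timepoints = 260,
                              sampling_interval = 1.78,
                              within_network_r = 0.5,
                              between_network_r = 0.15,
                              homotopic_coupling = 0.9,
                              subject_r_sd = 0.06,
                              lesion_volume_range = c(100, 25000),
                              connectivity_damping_slope = 1.6e-5,
                              affected_networks = NULL,
                              outcome_coefficients = default_outcome_coefficients(),
                              noise_sd = NULL,
                              target_design_r2 = 0.70,
                              integer_outcome = FALSE,
                              ar1_phi = 0,
                              registry = default_network_registry(),
                              seed = 1L) {
  stopifnot(inherits(registry, "network_registry"))
  nets <- names(registry$networks)
  if (length(within_network_r) == 1 && is.null(names(within_network_r))) {
    within_network_r <- setNames(rep(within_network_r, length(nets)), nets)
  }
  if (!all(nets %in% names(within_network_r))) {
    abort("`within_network_r` must be a single value or named per network.")
  }
  within_network_r <- within_network_r[nets]
  if (any(abs(within_network_r) >= 1)) {
    abort("`within_network_r` must lie in (-1, 1).")
  }
  if (between_network_r < 0 || between_network_r >= 1) {
    abort("`between_network_r` must lie in [0, 1) (it is carried by a shared global factor).")
  }
  if (homotopic_coupling < 0 || homotopic_coupling > 1) {
    abort("`homotopic_coupling` must lie in [0, 1].")
  }
  if (subject_r_sd < 0) abort("`subject_r_sd` must be non-negative.")
  if (n_subjects < 2) abort("`n_subjects` must be at least 2.")
  if (n_timepoints < 3) abort("`n_timepoints` must be at least 3.")
  if (length(lesion_volume_range) != 2 || any(lesion_volume_range < 0) ||
      diff(lesion_volume_range) < 0) {
    abort("`lesion_volume_range` must be a non-negative, increasing mm^3 interval.")
  }
  if (connectivity_damping_slope < 0) {
    abort("`connectivity_damping_slope` must be non-negative.")
  }
  if (is.null(affected_networks)) {
    affected_networks <- intersect(c("MotorI", "MotorIV"), nets)
  }
  missing_net <- setdiff(affected_networks, nets)
  if (length(missing_net) > 0) {
    abort(paste0("Unknown affected network(s): ",
                 paste(missing_net, collapse = ", ")))
  }
  if (!is.null(noise_sd) && !is.null(target_design_r2)) {
    abort("Give either `noise_sd` or `target_design_r2`, not both.")
  }
  if (is.null(noise_sd) && is.null(target_design_r2)) {
    abort("One of `noise_sd` or `target_design_r2` is required.")
  }
  if (!is.null(noise_sd) && noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (!is.null(target_design_r2) &&
      (target_design_r2 <= 0 || target_design_r2 > 1)) {
    abort("`target_design_r2` must lie in (0, 1].")
  }
  if (is.null(names(outcome_coefficients)) ||
      !"(Intercept)" %in% names(outcome_coefficients)) {
    abort("`outcome_coefficients` must be named and include '(Intercept)'.")
  }
  if (abs(ar1_phi) >= 1) abort("`ar1_phi` must lie in (-1, 1).")

  cfg <- structure(
    list(n_subjects = as.integer(n_subjects),
         n_timepoints = as.integer(n_timepoints),
         sampling_interval = sampling_interval,
         within_network_r = within_network_r,
         between_network_r = between_network_r,
         homotopic_coupling = homotopic_coupling,
         subject_r_sd = subject_r_sd,
         lesion_volume_range = lesion_volume_range,
         connectivity_damping_slope = connectivity_damping_slope,
         affected_networks = affected_networks,
         outcome_coefficients = outcome_coefficients,
         noise_sd = noise_sd,
         target_design_r2 = target_design_r2,
         integer_outcome = integer_outcome,
         ar1_phi = ar1_phi,
         registry = registry,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
  validate_covariance_config(cfg)
  cfg
}

#' Default generating coefficients of the synthetic outcome model
#'
#' Lesion volume raises NIHSS (about 5.5 points over the default volume
#' range) and lower within-network connectivity in motor and frontoparietal
#' configurations raises it further; the intercept centres the outcome near
#' the mild-to-moderate range.
#'
#' @return Named numeric vector of generating coefficients.
#' @export
default_outcome_coefficients <- function() {
  c("(Intercept)" = 11,
    lesion_volume = 2.2e-4,
    "intra|MotorI:left" = -9,
    "intra|MotorIV:left" = -7,
    "intra|Frontoparietal:right" = -5)
}

#' A no-signal variant of the default configuration
#'
#' All slopes zero: NIHSS is pure Gaussian noise (sd 3.35 points, matching
#' an acute mild-to-moderate cohort) around a mean of 4.3, independent of
#' every predictor. Used for null calibration of the modelling pipeline.
#'
#' @param ... Overrides passed on to [simulation_config()].
#' @return A `simulation_config`.
#' @export
null_simulation_config <- function(...) {
  simulation_config(
    outcome_coefficients = c("(Intercept)" = 4.3),
    noise_sd = 3.35, target_design_r2 = NULL, ...
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>: ", x$n_subjects, " subjects, ",
      x$n_timepoints, " timepoints @ TR ", x$sampling_interval, " s\n",
      "  within r = ", paste(signif(unique(x$within_network_r), 3),
                             collapse = "/"),
      ", between r = ", x$between_network_r,
      ", damping = ", x$connectivity_damping_slope, " per mm^3\n", sep = "")
  invisible(x)
}

# ---- internal generative machinery -----------------------------------------

# Validation of the implied covariance: every region must retain positive
# unique variance at the most extreme admissible correlation targets, and
# damping must not push a within-network correlation below the
# between-network level (the factor loading would be imaginary).
validate_covariance_config <- function(cfg) {
  reg <- cfg$registry
  r_b <- cfg$between_network_r
  max_vol <- cfg$lesion_volume_range[2]
  max_delta <- 2.5 * cfg$subject_r_sd
  for (nm in names(reg$networks)) {
    damp <- if (nm %in% cfg$affected_networks) {
      cfg$connectivity_damping_slope * max_vol
    } else 0
    r_min <- cfg$within_network_r[[nm]] * (1 - damp) - max_delta
    if (r_min <= r_b) {
      abort(sprintf(
        "Network block '%s': damping and subject variation can drive its within-network correlation to %.3f, at or below the between-network level %.3f; the implied covariance degenerates. Reduce `connectivity_damping_slope`, `subject_r_sd` or `between_network_r`.",
        nm, r_min, r_b
      ))
    }
  }
  base <- base_regions(reg)
  membership <- map(setNames(base, base), function(rg) {
    names(keep(reg$networks, function(m) rg %in% m))
  })
  for (rg in base) {
    nets <- membership[[rg]]
    load_sum <- sum(map_dbl(nets, function(nm) {
      r_max <- cfg$within_network_r[[nm]] + max_delta
      (r_max - r_b) / length(nets)
    }))
    if (r_b + load_sum >= 0.99) {
      abort(sprintf(
        "Region '%s' (network block(s) %s): implied variance exceeds 1 (loadings %.3f + between %.3f); the covariance is not positive definite. Reduce `within_network_r` or `subject_r_sd`.",
        rg, paste(nets, collapse = " + "), load_sum, r_b
      ))
    }
  }
  invisible(cfg)
}

# Per-subject seeds derived from the master seed by a prefix-stable draw:
# the i-th subject's seed does not change when n_subjects grows.
derive_subject_seed <- function(seed, subject_index) {
  withr::with_seed(seed,
    sample.int(2147483646L, subject_index)[subject_index])
}

# Subject-level draws happen in a fixed order inside one seeded stream:
# lesion volume, connectivity offsets, latent time series, outcome noise.
# `sseed` lets simulate_cohort() pass a batch-derived seed (identical to the
# per-subject derivation, computed once).
subject_draws <- function(cfg, subject_index, sseed = NULL) {
  if (subject_index < 1 || subject_index > cfg$n_subjects) {
    abort("`subject_index` must lie in 1..n_subjects.")
  }
  reg <- cfg$registry
  nets <- names(reg$networks)
  if (is.null(sseed)) {
    sseed <- derive_subject_seed(cfg$seed, subject_index)
  }
  withr::with_seed(sseed, {
    volume <- round(runif(1, cfg$lesion_volume_range[1],
                          cfg$lesion_volume_range[2]))
    deltas <- matrix(rnorm(2 * length(nets), 0, cfg$subject_r_sd),
                     nrow = length(nets), ncol = 2,
                     dimnames = list(nets, c("left", "right")))
    deltas <- pmin(pmax(deltas, -2.5 * cfg$subject_r_sd),
                   2.5 * cfg$subject_r_sd)
    ts <- draw_timeseries(cfg, volume, deltas)
    outcome_z <- rnorm(1)
    mask_seed <- sample.int(2147483646L, 1)
  })
  list(volume = volume, deltas = deltas, ts = ts,
       outcome_z = outcome_z, mask_seed = mask_seed)
}

# Subject-specific within-network correlation targets per hemisphere.
correlation_targets <- function(cfg, volume, deltas) {
  nets <- names(cfg$registry$networks)
  t(vapply(nets, function(nm) {
    damp <- if (nm %in% cfg$affected_networks) {
      cfg$connectivity_damping_slope * volume
    } else 0
    cfg$within_network_r[[nm]] * (1 - damp) + deltas[nm, ]
  }, numeric(2)))
}

region_loadings <- function(cfg, targets) {
  reg <- cfg$registry
  base <- base_regions(reg)
  r_b <- cfg$between_network_r
  nets <- names(reg$networks)
  membership <- map(setNames(base, base), function(rg) {
    names(keep(reg$networks, function(m) rg %in% m))
  })
  regions <- lateralized_regions(reg)
  # loadings[region, network]: nonzero only for the region's own networks
  load <- matrix(0, nrow = length(regions), ncol = length(nets),
                 dimnames = list(regions, nets))
  hemi <- rep(c("left", "right"), times = length(base))
  base_of <- rep(base, each = 2)
  for (k in seq_along(regions)) {
    for (nm in membership[[base_of[k]]]) {
      m <- length(membership[[base_of[k]]])
      a2 <- (targets[nm, hemi[k]] - r_b) / m
      load[k, nm] <- sqrt(max(a2, 0))
    }
  }
  load
}

# Draw one subject's T x R series from the factor model.
draw_timeseries <- function(cfg, volume, deltas) {
  reg <- cfg$registry
  regions <- lateralized_regions(reg)
  nets <- names(reg$networks)
  R <- length(regions)
  T_ <- cfg$n_timepoints
  targets <- correlation_targets(cfg, volume, deltas)
  load <- region_loadings(cfg, targets)
  hemi <- rep(c("left", "right"), length.out = R)
  r_b <- cfg$between_network_r
  c_h <- cfg$homotopic_coupling

  latent <- function(n) {
    z <- matrix(rnorm(T_ * n), T_, n)
    if (cfg$ar1_phi != 0) {
      z <- apply(z, 2, function(col) {
        x <- as.numeric(stats::filter(col, cfg$ar1_phi, method = "recursive"))
        x * sqrt(1 - cfg$ar1_phi^2)
      })
    }
    z
  }
  g <- latent(1)                       # global (between-network) factor
  h <- latent(length(nets))            # shared network factors
  e <- list(left = latent(length(nets)), right = latent(length(nets)))
  eps <- latent(R)                     # region-specific noise

  f <- list(left = sqrt(c_h) * h + sqrt(1 - c_h) * e$left,
            right = sqrt(c_h) * h + sqrt(1 - c_h) * e$right)
  u <- pmax(1 - r_b - rowSums(load^2), 0)
  X <- matrix(sqrt(r_b) * g[, 1], T_, R, dimnames = list(NULL, regions))
  for (hh in c("left", "right")) {
    rows <- which(hemi == hh)
    X[, rows] <- X[, rows] + f[[hh]] %*% t(load[rows, , drop = FALSE])
  }
  X + sweep(eps, 2, sqrt(u), "*")
}

#' Model-implied region correlation matrix
#'
#' The population correlation matrix of one subject's ROI time series under
#' a [simulation_config()], against which empirical correlations converge as
#' the number of timepoints grows.
#'
#' @param cfg A [simulation_config()].
#' @param subject_index Subject whose lesion volume and connectivity offsets
#'   determine the matrix.
#' @return Symmetric correlation matrix over the lateralized regions.
#' @export
implied_correlation_matrix <- function(cfg, subject_index) {
  stopifnot(inherits(cfg, "simulation_config"))
  draws <- subject_draws(cfg, subject_index)
  targets <- correlation_targets(cfg, draws$volume, draws$deltas)
  load <- region_loadings(cfg, targets)
  regions <- rownames(load)
  hemi <- rep(c("left", "right"), length.out = nrow(load))
  c_h <- cfg$homotopic_coupling
  S <- matrix(cfg$between_network_r, nrow(load), nrow(load),
              dimnames = list(regions, regions))
  for (i in seq_len(nrow(load))) {
    for (j in seq_len(nrow(load))) {
      couple <- if (hemi[i] == hemi[j]) 1 else c_h
      S[i, j] <- S[i, j] + couple * sum(load[i, ] * load[j, ])
    }
  }
  diag(S) <- 1
  S
}

#' Simulate one subject's ROI time series
#'
#' Draws a `T x R` region time-series matrix from the configured
#' block-structured covariance, attenuated by the subject's lesion volume.
#' The result is a deterministic function of `(config$seed, subject_index)`
#' and does not change when `n_subjects` changes.
#'
#' @param cfg A [simulation_config()].
#' @param subject_index Subject number in `1..n_subjects`.
#' @return A [roi_timeseries()] over the registry's lateralized regions.
#' @export
simulate_roi_timeseries <- function(cfg, subject_index) {
  stopifnot(inherits(cfg, "simulation_config"))
  draws <- subject_draws(cfg, subject_index)
  roi_timeseries(draws$ts, lateralized_regions(cfg$registry),
                 cfg$sampling_interval)
}

#' Simulate a full synthetic cohort
#'
#' Generates every subject's ROI time series, extracts the full connectivity
#' feature vector through the same code path the analysis uses, draws lesion
#' volumes, and produces the NIHSS outcome from the configured linear model:
#' `NIHSS_i = intercept + sum_j coef_j * predictor_ij + eps_i` with
#' `eps ~ Normal(0, noise_sd^2)`.
#'
#' @param cfg A [simulation_config()].
#' @param masks If `TRUE`, also renders a binary lesion mask per subject
#'   (1 mm isotropic voxels) whose volume matches the subject's
#'   `lesion_volume`.
#' @param mask_grid Grid dimensions for rendered masks.
#' @return An object of class `synthetic_cohort`: a list with
#'   * `cohort`: tibble with `subject_id`, `lesion_volume`, one column per
#'     connectivity feature, and `nihss`;
#'   * `timeseries`: named list of [roi_timeseries()];
#'   * `lesion_masks`: named list of [lesion_mask()] or `NULL`;
#'   * `truth`: generating coefficients, the noise sd actually used, and
#'     the realized design R-squared.
#' @export
simulate_cohort <- function(cfg, masks = FALSE, mask_grid = c(64, 64, 64)) {
  stopifnot(inherits(cfg, "simulation_config"))
  n <- cfg$n_subjects
  ids <- sprintf("sub-%02d", seq_len(n))
  regions <- lateralized_regions(cfg$registry)

  sseeds <- withr::with_seed(cfg$seed, sample.int(2147483646L, n))
  draws <- map(seq_len(n), function(i) subject_draws(cfg, i, sseed = sseeds[i]))
  ts_list <- map(draws, function(d) {
    roi_timeseries(d$ts, regions, cfg$sampling_interval)
  })
  names(ts_list) <- ids

  features <- connectivity_feature_matrix(ts_list, cfg$registry)
  cohort <- dplyr::bind_cols(
    tibble(subject_id = ids,
           lesion_volume = map_dbl(draws, "volume")),
    features[, -1]
  )

  coefs <- cfg$outcome_coefficients
  slopes <- coefs[setdiff(names(coefs), "(Intercept)")]
  available <- c("lesion_volume", names(features)[-1])
  unknown <- setdiff(names(slopes), available)
  if (length(unknown) > 0) {
    abort(paste0(
      "Unknown predictor(s) in `outcome_coefficients`: ",
      paste(unknown, collapse = ", "),
      ". Available: lesion_volume plus the ", length(available) - 1,
      " connectivity feature names (see feature_names(registry))."
    ))
  }
  lp <- rep(coefs[["(Intercept)"]], n)
  for (nm in names(slopes)) {
    lp <- lp + slopes[[nm]] * cohort[[nm]]
  }

  noise_sd <- cfg$noise_sd
  if (is.null(noise_sd)) {
    if (length(slopes) == 0 || var(lp) == 0) {
      abort("`target_design_r2` needs a non-degenerate linear predictor; give `noise_sd` instead.")
    }
    r2 <- cfg$target_design_r2
    noise_sd <- sd(lp) * sqrt((1 - r2) / r2)
  }
  design_r2 <- if (var(lp) == 0 && noise_sd == 0) {
    1
  } else if (var(lp) == 0) {
    0
  } else {
    var(lp) / (var(lp) + noise_sd^2)
  }

  nihss <- lp + noise_sd * map_dbl(draws, "outcome_z")
  if (cfg$integer_outcome) {
    nihss <- pmin(pmax(round(nihss), 0), 14)
  }
  cohort$nihss <- as.numeric(nihss)

  lesion_masks <- NULL
  if (masks) {
    lesion_masks <- map(draws, function(d) {
      make_lesion_mask(d$volume, grid_shape = mask_grid,
                       voxel_dims = c(1, 1, 1), seed = d$mask_seed)
    })
    names(lesion_masks) <- ids
  }

  structure(
    list(cohort = cohort,
         timeseries = ts_list,
         lesion_masks = lesion_masks,
         truth = list(coefficients = coefs,
                      noise_sd = noise_sd,
                      design_r2 = design_r2,
                      linear_predictor = as.numeric(lp)),
         config = cfg),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>: ", nrow(x$cohort), " subjects, ",
      ncol(x$cohort) - 3, " connectivity features\n",
      "  design R^2 = ", signif(x$truth$design_r2, 3),
      ", noise sd = ", signif(x$truth$noise_sd, 3), " NIHSS points\n",
      sep = "")
  invisible(x)
}

#' Render a toy volumetric dataset from a synthetic cohort
#'
#' Writes each subject's region time series into a small 4D volume (every
#' voxel of a region carries the region's series plus optional i.i.d. voxel
#' noise) together with one integer label volume, so that ROI extraction can
#' be exercised end to end: with zero voxel noise, extraction recovers the
#' input series exactly.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param atlas_layout Named list mapping each region to an `n x 3` integer
#'   matrix of voxel coordinates; blocks must be disjoint. Defaults to
#'   [default_atlas_layout()].
#' @param voxel_noise_sd Standard deviation of independent voxel noise.
#' @param dir Optional directory; when given, 4D images and the label
#'   volume are written there as NIfTI-1.
#' @param seed Seed for the voxel noise.
#' @return A list with `images` (named list of 4D arrays), `labels` (3D
#'   integer array), `label_map` (named integer vector region -> label) and
#'   `paths` (when `dir` is given).
#' @export
render_toy_dataset <- function(cohort, atlas_layout = NULL,
                               voxel_noise_sd = 0, dir = NULL, seed = 1L) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  regions <- lateralized_regions(cohort$config$registry)
  if (is.null(atlas_layout)) {
    atlas_layout <- default_atlas_layout(regions)
  }
  missing <- setdiff(regions, names(atlas_layout))
  if (length(missing) > 0) {
    abort(paste0("Atlas layout lacks region(s): ",
                 paste(missing, collapse = ", ")))
  }
  all_vox <- do.call(rbind, atlas_layout[regions])
  keys <- paste(all_vox[, 1], all_vox[, 2], all_vox[, 3])
  if (anyDuplicated(keys)) {
    abort("Atlas layout voxel blocks overlap.")
  }
  shape <- apply(all_vox, 2, max)
  labels <- array(0L, dim = shape)
  label_map <- setNames(seq_along(regions), regions)
  for (rg in regions) {
    labels[atlas_layout[[rg]]] <- label_map[[rg]]
  }
  images <- withr::with_seed(seed, {
    map(cohort$timeseries, function(ts) {
      T_ <- nrow(ts$data)
      img <- array(0, dim = c(shape, T_))
      flat <- matrix(img, ncol = T_)
      for (rg in regions) {
        vox <- atlas_layout[[rg]]
        lin <- vox[, 1] + (vox[, 2] - 1) * shape[1] +
          (vox[, 3] - 1) * shape[1] * shape[2]
        block <- matrix(rep(ts$data[, rg], each = length(lin)),
                        nrow = length(lin))
        if (voxel_noise_sd > 0) {
          block <- block + rnorm(length(block), 0, voxel_noise_sd)
        }
        flat[lin, ] <- block
      }
      array(flat, dim = c(shape, T_))
    })
  })
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    label_path <- file.path(dir, "labels.nii.gz")
    RNifti::writeNifti(RNifti::asNifti(labels), label_path)
    img_paths <- map_chr(names(images), function(id) {
      p <- file.path(dir, paste0(id, "_bold.nii.gz"))
      RNifti::writeNifti(RNifti::asNifti(images[[id]]), p)
      p
    })
    paths <- list(labels = label_path, images = img_paths)
  }
  list(images = images, labels = labels, label_map = label_map,
       paths = paths)
}

#' Default disjoint atlas layout for toy volumes
#'
#' Assigns each region a vertical column of `voxels_per_region` voxels at a
#' distinct (x, y) position on a compact grid.
#'
#' @param regions Character vector of region names.
#' @param voxels_per_region Voxels per region block.
#' @return Named list of `n x 3` integer coordinate matrices.
#' @export
default_atlas_layout <- function(regions, voxels_per_region = 4) {
  nx <- ceiling(sqrt(length(regions)))
  map(setNames(seq_along(regions), regions), function(i) {
    x <- ((i - 1) %% nx) + 1
    y <- ((i - 1) %/% nx) + 1
    cbind(x = rep(x, voxels_per_region),
          y = rep(y, voxels_per_region),
          z = seq_len(voxels_per_region))
  })
}
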