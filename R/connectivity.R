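#' Pearson correlation matrix of an ROI time-series set
#'
#' @param ts A [roi_timeseries()].
#' @return Symmetric `R x R` correlation matrix with unit diagonal, rows and
#'   columns named by region. Regions with zero temporal variance are an
#'   error (their correlation is undefined).
#' @export
correlation_matrix <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  sds <- apply(ts$data, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("Zero-variance region(s): ",
                 paste(ts$region_names[sds == 0], collapse = ", ")))
  }
  r <- cor(ts$data)
  diag(r) <- 1
  r
}

#' Fisher z-transformation of a correlation
#'
#' `z = arctanh(r)`, the variance-stabilizing transform applied to
#' correlations before averaging. To keep aggregated features finite on
#' degenerate inputs, `|r|` is clipped to `1 - 1e-7` before transforming.
#'
#' @param r Correlation value(s) in `[-1, 1]`.
#' @return z-value(s), finite even at `|r| = 1`.
#' @export
#' @examples
#' fisher_z(0.5) # 0.5 * log(3)
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12)) {
    abort("Correlations must lie in [-1, 1].")
  }
  atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
}

config_pairs_intra <- function(config) {
  m <- config$members
  if (length(m) < 2) {
    abort(paste0("Configuration '", config$label,
                 "' has a single member; intra-network connectivity needs at least one region pair."))
  }
  t(utils::combn(m, 2))
}

config_pairs_inter <- function(config_a, config_b) {
  pairs <- expand.grid(a = config_a$members, b = config_b$members,
                       stringsAsFactors = FALSE)
  # Networks can share regions; a region paired with itself has r = 1
  # (infinite z) and is excluded. Distinct shared members are kept.
  pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
  if (nrow(pairs) == 0) {
    abort(paste0("No region pairs remain between '", config_a$label,
                 "' and '", config_b$label, "' after excluding self-pairs."))
  }
  as.matrix(pairs)
}

z_mean_over_pairs <- function(zmatrix, pairs) {
  mean(zmatrix[cbind(pairs[, 1], pairs[, 2])])
}

check_members_present <- function(zmatrix, members) {
  missing <- setdiff(members, rownames(zmatrix))
  if (length(missing) > 0) {
    abort(paste0("Region(s) missing from the matrix: ",
                 paste(missing, collapse = ", ")))
  }
}

#' Intra- and inter-network connectivity aggregates
#'
#' Intra-network connectivity is the unweighted mean Fisher z over all
#' unordered pairs of a configuration's member regions (diagonal excluded).
#' Inter-network connectivity is the mean z over all cross pairs between two
#' configurations, excluding pairs where both sides are the same lateralized
#' region (networks may share regions; the self-pair correlation of 1 has
#' infinite z).
#'
#' @param zmatrix Symmetric matrix of Fisher z values with region names on
#'   rows and columns, i.e. `fisher_z(correlation_matrix(ts))`.
#' @param config,config_a,config_b Network configurations from
#'   [network_configurations()].
#' @return A single z-value.
#' @export
intra_network_connectivity <- function(zmatrix, config) {
  check_members_present(zmatrix, config$members)
  z_mean_over_pairs(zmatrix, config_pairs_intra(config))
}

#' @rdname intra_network_connectivity
#' @export
inter_network_connectivity <- function(zmatrix, config_a, config_b) {
  if (identical(config_a$label, config_b$label)) {
    abort("Inter-network connectivity needs two distinct configurations.")
  }
  check_members_present(zmatrix, c(config_a$members, config_b$members))
  z_mean_over_pairs(zmatrix, config_pairs_inter(config_a, config_b))
}

# Precompute, per feature, the matrix-index pairs it averages over.
# Memoized: the index depends only on the registry and the region ordering,
# not on the data, and is reused across subjects.
.pair_cache <- new.env(parent = emptyenv())

feature_pair_index <- function(registry, region_names) {
  key <- paste(
    c(names(registry$networks), unlist(registry$networks),
      registry$scopes, registry$suffixes, "::", region_names),
    collapse = "\r"
  )
  cached <- .pair_cache[[key]]
  if (!is.null(cached)) return(cached)
  cfg <- network_configurations(registry)
  C <- length(cfg)
  idx <- function(members) match(members, region_names)
  out <- vector("list", C + C * (C - 1) / 2)
  nm <- character(length(out))
  k <- 0L
  for (i in seq_len(C)) {
    k <- k + 1L
    p <- config_pairs_intra(cfg[[i]])
    out[[k]] <- cbind(idx(p[, 1]), idx(p[, 2]))
    nm[k] <- paste0("intra|", cfg[[i]]$label)
  }
  if (C >= 2) {
    for (i in seq_len(C - 1)) {
      for (j in seq(i + 1, C)) {
        k <- k + 1L
        p <- config_pairs_inter(cfg[[i]], cfg[[j]])
        out[[k]] <- cbind(idx(p[, 1]), idx(p[, 2]))
        nm[k] <- paste0("inter|", cfg[[i]]$label, "|", cfg[[j]]$label)
      }
    }
  }
  names(out) <- nm
  .pair_cache[[key]] <- out
  out
}

#' Build the connectivity feature vector of one subject
#'
#' Computes the full ordered set of intra- and inter-network Fisher-z
#' connectivity features for an ROI time-series set: all intra features (one
#' per network configuration) followed by all inter features (one per
#' unordered configuration pair), in canonical registry order. Under the
#' default six-network registry with three hemisphere scopes this is
#' 18 + 153 = 171 features.
#'
#' @param ts A [roi_timeseries()] containing every lateralized region of the
#'   registry.
#' @param registry A [network_registry()].
#' @return A tibble with columns `feature` (canonical name) and `z`, one row
#'   per feature in canonical order.
#' @export
#' @examples
#' cfg <- simulation_config(n_subjects = 5, n_timepoints = 60)
#' ts <- simulate_roi_timeseries(cfg, 1)
#' feats <- build_feature_vector(ts, default_network_registry())
#' nrow(feats) # 171
build_feature_vector <- function(ts, registry = default_network_registry()) {
  stopifnot(inherits(ts, "roi_timeseries"))
  needed <- unique(unlist(map(network_configurations(registry), "members")))
  missing <- setdiff(needed, ts$region_names)
  if (length(missing) > 0) {
    abort(paste0("Region(s) required by the registry are missing from the time series: ",
                 paste(missing, collapse = ", ")))
  }
  z <- fisher_z(correlation_matrix(ts))
  pairs <- feature_pair_index(registry, rownames(z))
  tibble(
    feature = names(pairs),
    z = unname(map_dbl(pairs, function(p) mean(z[p])))
  )
}

# z[p] above indexes with a 2-column matrix; mean over the selected entries.

#' Connectivity feature matrix for a list of subjects
#'
#' @param ts_list Named list of [roi_timeseries()] (names become
#'   `subject_id`).
#' @param registry A [network_registry()].
#' @return A tibble with `subject_id` and one named column per connectivity
#'   feature, rows in input order.
#' @export
connectivity_feature_matrix <- function(ts_list,
                                        registry = default_network_registry()) {
  ids <- names(ts_list) %||% sprintf("sub-%02d", seq_along(ts_list))
  rows <- map(ts_list, function(ts) {
    f <- build_feature_vector(ts, registry)
    tibble::as_tibble_row(setNames(as.list(f$z), f$feature))
  })
  dplyr::bind_cols(tibble(subject_id = ids), dplyr::bind_rows(rows))
}
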