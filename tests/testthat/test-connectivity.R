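test_that("band-pass removes DC and keeps the passband (FFT amplitude oracle)", {
  tr <- 1.78
  n_time <- 1024
  t_axis <- (seq_len(n_time) - 1) * tr
  make_ts <- function(signal) {
    roi_timeseries(cbind(sig = signal, const = rep(2, n_time) + 0),
                   c("sig", "const"), tr)
  }
  amp_at <- function(x, f) {
    Mod(fft(x))[round(f * n_time * tr) + 1]
  }
  # constant series: DC is far below the 0.01 Hz edge
  filt <- bandpass_filter(make_ts(sin(2 * pi * 0.05 * t_axis)))
  expect_lt(max(abs(filt$data[, "const"])), 1e-8)
  # 0.05 Hz is inside the band
  ratio_in <- amp_at(filt$data[, "sig"], 0.05) /
    amp_at(sin(2 * pi * 0.05 * t_axis), 0.05)
  expect_gte(ratio_in, 0.9)
  # 0.25 Hz is in the stopband (Nyquist is ~0.281 Hz)
  filt_out <- bandpass_filter(make_ts(sin(2 * pi * 0.25 * t_axis)))
  ratio_out <- amp_at(filt_out$data[, "sig"], 0.25) /
    amp_at(sin(2 * pi * 0.25 * t_axis), 0.25)
  expect_lte(ratio_out, 0.1)
  expect_identical(dim(filt$data), dim(make_ts(t_axis)$data))
})

test_that("band edges outside the Nyquist range are rejected with the admissible band", {
  ts <- roi_timeseries(matrix(rnorm(300), 100, 3), c("a", "b", "c"), 1.78)
  expect_error(bandpass_filter(ts, high = 0.3), "Nyquist.*0.2809|0.2809.*Nyquist")
  expect_error(bandpass_filter(ts, low = 0.2, high = 0.1), "low < high")
  expect_error(bandpass_filter(ts, order = 3), "even")
})

test_that("ROI extraction averages voxels, flags absent labels and ignores unmapped ones", {
  labels <- array(0L, dim = c(2, 2, 1))
  labels[1, 1, 1] <- 1L
  labels[2, 1, 1] <- 2L
  labels[1, 2, 1] <- 2L
  labels[2, 2, 1] <- 9L  # present but unmapped
  img <- array(0, dim = c(2, 2, 1, 4))
  img[1, 1, 1, ] <- c(1, 2, 3, 4)    # single-voxel region: verbatim
  img[2, 1, 1, ] <- 2                # two-voxel region with constants 2 and 4
  img[1, 2, 1, ] <- 4
  expect_message(
    ts <- extract_roi_timeseries(img, labels, c(solo = 1L, pair = 2L), 1.78),
    "unmapped"
  )
  expect_equal(ts$data[, "solo"], c(1, 2, 3, 4))
  expect_equal(ts$data[, "pair"], rep(3, 4))
  expect_error(
    extract_roi_timeseries(img, labels, c(solo = 1L, ghost = 7L), 1.78),
    "ghost"
  )
  expect_error(
    extract_roi_timeseries(img, array(0L, c(3, 2, 1)), c(solo = 1L), 1.78),
    "Grid mismatch"
  )
})

test_that("correlation matrix is a unit-diagonal Pearson matrix with variance guard", {
  x <- rnorm(200)
  ts <- roi_timeseries(cbind(a = x, b = -x, c = rnorm(200)),
                       c("a", "b", "c"), 1.78)
  r <- correlation_matrix(ts)
  expect_equal(diag(r), c(a = 1, b = 1, c = 1))
  expect_equal(r["a", "b"], -1)
  expect_equal(r, t(r))
  # independent white noise decorrelates at large T
  big <- withr::with_seed(4, roi_timeseries(
    matrix(rnorm(2 * 10000), 10000, 2), c("u", "v"), 1.78))
  expect_lt(abs(correlation_matrix(big)["u", "v"]), 0.05)
  flat <- roi_timeseries(cbind(a = rnorm(50), dead = rep(1, 50)),
                         c("a", "dead"), 1.78)
  expect_error(correlation_matrix(flat), "dead")
})

test_that("fisher_z matches arctanh, clips at |r| = 1 and rejects |r| > 1", {
  expect_identical(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3))
  expect_equal(fisher_z(-0.5), -0.5 * log(3))
  expect_true(is.finite(fisher_z(1)))
  expect_equal(fisher_z(1), atanh(1 - 1e-7))
  expect_equal(fisher_z(-1), -atanh(1 - 1e-7))
  expect_error(fisher_z(1.001), "\\[-1, 1\\]")
})

test_that("intra/inter aggregates match closed forms and the exclusion contract", {
  # three regions with pairwise correlation exactly 0.4
  sigma <- matrix(0.4, 3, 3); diag(sigma) <- 1
  nm <- c("X_L", "Y_L", "Z_L")
  z <- fisher_z(sigma)
  rownames(z) <- colnames(z) <- nm
  cfg3 <- list(network = "N", scope = "left", label = "N:left", members = nm)
  expect_equal(intra_network_connectivity(z, cfg3), atanh(0.4))
  cfg2 <- list(network = "N", scope = "left", label = "N:left",
               members = nm[1:2])
  expect_equal(intra_network_connectivity(z, cfg2), z["X_L", "Y_L"])
  cfg1 <- list(network = "N", scope = "left", label = "N:left",
               members = nm[1])
  expect_error(intra_network_connectivity(z, cfg1), "single member")

  # one region each: inter value is the z of that single cross pair
  r2 <- matrix(c(1, 0.3, 0.3, 1), 2, 2,
               dimnames = list(c("A_L", "B_L"), c("A_L", "B_L")))
  z2 <- fisher_z(r2)
  ca <- list(network = "A", scope = "left", label = "A:left", members = "A_L")
  cb <- list(network = "B", scope = "left", label = "B:left", members = "B_L")
  expect_equal(inter_network_connectivity(z2, ca, cb), atanh(0.3))
  expect_error(inter_network_connectivity(z2, ca, ca), "distinct")

  # shared-region self-pair exclusion: A = {X, Y}, B = {X, Z}
  nm4 <- c("X", "Y", "Z")
  r4 <- matrix(c(1, 0.2, 0.5,
                 0.2, 1, 0.1,
                 0.5, 0.1, 1), 3, 3, dimnames = list(nm4, nm4))
  z4 <- fisher_z(r4)
  ca <- list(network = "A", scope = "left", label = "A:left",
             members = c("X", "Y"))
  cb <- list(network = "B", scope = "left", label = "B:left",
             members = c("X", "Z"))
  # pairs kept: (X,Z), (Y,X), (Y,Z); (X,X) excluded
  expect_equal(
    inter_network_connectivity(z4, ca, cb),
    mean(c(z4["X", "Z"], z4["Y", "X"], z4["Y", "Z"]))
  )

  # all-zero cross correlations average to zero
  z0 <- matrix(0, 3, 3, dimnames = list(nm4, nm4))
  expect_equal(inter_network_connectivity(z0, ca, cb), 0)
})

test_that("feature vector matches a brute-force arctanh-averaging oracle to 1e-10", {
  reg <- overlapping_registry()  # 4 base regions incl. one shared
  sigma <- withr::with_seed(2, {
    A <- matrix(rnorm(64), 8)
    cov2cor(crossprod(A) + 8 * diag(8))
  })
  ts <- mvn_timeseries(sigma, 400, lateralized_regions(reg), seed = 7)
  feats <- build_feature_vector(ts, reg)
  expect_length(feats$z, 6 + 15)
  for (i in seq_len(nrow(feats))) {
    expect_equal(feats$z[i],
                 brute_force_feature(ts, reg, feats$feature[i]),
                 tolerance = 1e-10)
  }
})

test_that("features are invariant to region column order and need every region", {
  reg <- disjoint_registry()
  sigma <- diag(8) * 0.5 + 0.5
  ts <- mvn_timeseries(sigma, 300, lateralized_regions(reg), seed = 3)
  feats <- build_feature_vector(ts, reg)
  perm <- withr::with_seed(1, sample(ncol(ts$data)))
  ts_perm <- roi_timeseries(ts$data[, perm], ts$region_names[perm],
                            ts$sampling_interval)
  expect_equal(build_feature_vector(ts_perm, reg), feats)
  ts_missing <- roi_timeseries(ts$data[, -1], ts$region_names[-1],
                               ts$sampling_interval)
  expect_error(build_feature_vector(ts_missing, reg), "R1_L")
})

test_that("stronger within-network coupling raises the intra feature (simulation)", {
  reg <- disjoint_registry()
  intra_at <- function(r_within, seed) {
    cfg <- simulation_config(
      n_subjects = 2, n_timepoints = 400, registry = reg,
      within_network_r = r_within, between_network_r = 0.05,
      subject_r_sd = 0, connectivity_damping_slope = 0,
      affected_networks = character(0),
      outcome_coefficients = c("(Intercept)" = 0), noise_sd = 1,
      target_design_r2 = NULL, seed = seed
    )
    f <- build_feature_vector(simulate_roi_timeseries(cfg, 1), reg)
    f$z[f$feature == "intra|NetA:left"]
  }
  lo <- vapply(1:20, function(s) intra_at(0.25, s), numeric(1))
  hi <- vapply(1:20, function(s) intra_at(0.65, s), numeric(1))
  expect_gt(mean(hi), mean(lo))
})

test_that("ROI time series round-trip through TSV", {
  ts <- withr::with_seed(10, roi_timeseries(
    matrix(rnorm(60), 20, 3), c("PreCG_L", "PreCG_R", "PCL_L"), 1.78))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_roi_tsv(ts, path)
  back <- read_roi_tsv(path, sampling_interval = 1.78)
  expect_identical(back$region_names, ts$region_names)
  expect_equal(back$data, ts$data, tolerance = 1e-12, ignore_attr = TRUE)
})
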