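#' ROI time-series set
#'
#' Container for one subject's region-averaged BOLD signals: a `T x R`
#' matrix (timepoints by regions) with unique region names and the sampling
#' interval (repetition time) in seconds.
#'
#' @param data Numeric matrix, timepoints in rows, regions in columns.
#' @param region_names Character vector of lateralized region names; taken
#'   from `colnames(data)` when omitted.
#' @param sampling_interval Sampling interval (TR) in seconds.
#' @return An object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(data, region_names = colnames(data),
                           sampling_interval) {
  data <- as.matrix(data)
  if (is.null(region_names)) abort("Region names are required.")
  if (length(region_names) != ncol(data)) {
    abort("`region_names` must have one entry per column of `data`.")
  }
  if (anyDuplicated(region_names)) abort("Region names must be unique.")
  if (nrow(data) < 3) abort("At least 3 timepoints are required.")
  if (anyNA(data)) abort("Time series must not contain missing values.")
  if (!is.numeric(sampling_interval) || sampling_interval <= 0) {
    abort("`sampling_interval` must be a positive number of seconds.")
  }
  colnames(data) <- region_names
  structure(
    list(data = data, region_names = region_names,
         sampling_interval = sampling_interval),
    class = "roi_timeseries"
  )
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat("<roi_timeseries>: ", nrow(x$data), " timepoints x ",
      ncol(x$data), " regions, TR = ", x$sampling_interval, " s\n", sep = "")
  invisible(x)
}

#' @export
dim.roi_timeseries <- function(x) dim(x$data)

#' Zero-phase band-pass filter for ROI time series
#'
#' Applies a Butterworth band-pass (default 0.01-0.1 Hz, the standard
#' resting-state fluctuation band) to every region's series. Filtering is
#' zero-phase (forward-backward), so correlations between regions are not
#' distorted by phase shifts. Each series is demeaned before filtering; the
#' DC component is therefore removed exactly.
#'
#' @param ts A [roi_timeseries()].
#' @param low,high Band edges in Hz. `high` must lie below the Nyquist
#'   frequency `1 / (2 * sampling_interval)`.
#' @param order Effective Butterworth order of the band-pass (even, default
#'   4); attenuation is doubled again by the forward-backward pass.
#' @return A [roi_timeseries()] with identical dimensions.
#' @export
#' @examples
#' ts <- roi_timeseries(matrix(rnorm(600), 200, 3),
#'                      c("A", "B", "C"), sampling_interval = 1.78)
#' filt <- bandpass_filter(ts)
bandpass_filter <- function(ts, low = 0.01, high = 0.1, order = 4) {
  stopifnot(inherits(ts, "roi_timeseries"))
  nyquist <- 1 / (2 * ts$sampling_interval)
  if (low <= 0 || high <= low) {
    abort("Band edges must satisfy 0 < low < high.")
  }
  if (high >= nyquist) {
    abort(sprintf(
      "Upper band edge %.4g Hz is at or above the Nyquist frequency %.4g Hz; admissible band is (0, %.4g) Hz.",
      high, nyquist, nyquist
    ))
  }
  if (order %% 2 != 0 || order < 2) abort("`order` must be a positive even number.")
  bf <- signal::butter(order / 2, c(low, high) / nyquist, type = "pass")
  centred <- sweep(ts$data, 2, colMeans(ts$data))
  filtered <- apply(centred, 2, function(col) signal::filtfilt(bf, col))
  roi_timeseries(filtered, ts$region_names, ts$sampling_interval)
}

#' Extract region-averaged time series from a 4D image
#'
#' Averages the voxel time series within each labelled region of interest:
#' each region's series is the unweighted mean over its voxels at every
#' timepoint.
#'
#' @param image4d 4D numeric array (x, y, z, time), e.g. read with
#'   [RNifti::readNifti()].
#' @param labels 3D integer array on the same grid assigning an atlas label
#'   to each voxel (0 = background).
#' @param region_map Named integer vector mapping region name to atlas
#'   label, e.g. `c(PreCG_L = 1, PreCG_R = 2)`.
#' @param sampling_interval Sampling interval (TR) in seconds.
#' @return A [roi_timeseries()] with one column per mapped region. Nonzero
#'   labels present in `labels` but absent from `region_map` are ignored
#'   with a message.
#' @export
extract_roi_timeseries <- function(image4d, labels, region_map,
                                   sampling_interval) {
  image4d <- unclass(image4d)
  labels <- unclass(labels)
  if (length(dim(image4d)) != 4) abort("`image4d` must be a 4D array.")
  if (!identical(dim(image4d)[1:3], dim(labels)[1:3]) ||
      length(dim(labels)) != 3) {
    abort(sprintf(
      "Grid mismatch: image grid is %s, label grid is %s.",
      paste(dim(image4d)[1:3], collapse = "x"),
      paste(dim(labels), collapse = "x")
    ))
  }
  if (is.null(names(region_map)) || anyDuplicated(names(region_map))) {
    abort("`region_map` must be a named vector with unique region names.")
  }
  present <- unique(as.vector(labels))
  missing <- region_map[!region_map %in% present]
  if (length(missing) > 0) {
    abort(paste0(
      "Mapped labels absent from the label volume: ",
      paste0(names(missing), " (", missing, ")", collapse = ", ")
    ))
  }
  unmapped <- setdiff(present, c(0, region_map))
  if (length(unmapped) > 0) {
    inform(paste0("Ignoring ", length(unmapped),
                  " unmapped nonzero label(s) in the label volume."))
  }
  tdim <- dim(image4d)[4]
  flat <- matrix(image4d, ncol = tdim)  # voxels x time
  series <- vapply(region_map, function(lab) {
    vox <- which(as.vector(labels) == lab)
    if (length(vox) == 1) flat[vox, ] else colMeans(flat[vox, , drop = FALSE])
  }, numeric(tdim))
  roi_timeseries(series, names(region_map), sampling_interval)
}

#' Read and write ROI time series as TSV
#'
#' The TSV layout is timepoints in rows, one named column per region.
#'
#' @param path File path.
#' @param sampling_interval Sampling interval (TR) in seconds.
#' @param ts A [roi_timeseries()].
#' @return `read_roi_tsv()` returns a [roi_timeseries()];
#'   `write_roi_tsv()` returns `path` invisibly.
#' @export
read_roi_tsv <- function(path, sampling_interval) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  roi_timeseries(as.matrix(tab), names(tab), sampling_interval)
}

#' @rdname read_roi_tsv
#' @export
write_roi_tsv <- function(ts, path) {
  stopifnot(inherits(ts, "roi_timeseries"))
  readr::write_tsv(as_tibble(as.data.frame(ts$data)), path)
  invisible(path)
}
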