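#' Binary lesion mask
#'
#' @param grid 3D array of 0/1 values (1 = lesioned voxel).
#' @param voxel_dims Voxel edge lengths in mm, length-3, strictly positive.
#' @param space Free-text label of the coordinate space (e.g. `"MNI"`).
#' @param binarize_at Optional threshold in `(0, 1)`. Masks that have been
#'   resampled can carry interpolation residue in `[0, 1]`; such grids are
#'   rejected unless a threshold is given explicitly, in which case voxels
#'   `>= binarize_at` become foreground.
#' @return An object of class `lesion_mask`.
#' @export
lesion_mask <- function(grid, voxel_dims = c(1, 1, 1), space = "unspecified",
                        binarize_at = NULL) {
  grid <- unclass(grid)
  if (length(dim(grid)) != 3) abort("`grid` must be a 3D array.")
  if (length(voxel_dims) != 3 || any(!is.finite(voxel_dims)) ||
      any(voxel_dims <= 0)) {
    abort("`voxel_dims` must be three strictly positive lengths in mm.")
  }
  vals <- unique(as.vector(grid))
  if (!all(vals %in% c(0, 1))) {
    if (is.null(binarize_at)) {
      abort(paste0(
        "Mask is not binary (values outside {0, 1} found). ",
        "Pass `binarize_at` (e.g. 0.5) to threshold interpolated masks explicitly."
      ))
    }
    if (binarize_at <= 0 || binarize_at >= 1) {
      abort("`binarize_at` must lie in (0, 1).")
    }
    grid <- (grid >= binarize_at) + 0
  }
  storage.mode(grid) <- "integer"
  structure(list(grid = grid, voxel_dims = as.numeric(voxel_dims),
                 space = space),
            class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  v <- compute_lesion_volume(x)
  cat("<lesion_mask>: grid ", paste(dim(x$grid), collapse = "x"),
      ", voxels ", paste(x$voxel_dims, collapse = "x"), " mm, ",
      v$voxel_count, " foreground voxels (", v$volume_mm3, " mm^3)\n",
      sep = "")
  invisible(x)
}

#' Lesion volume from a binary mask
#'
#' The number of foreground voxels multiplied by the voxel volume, expressed
#' in cubic millimeters.
#'
#' @param mask A [lesion_mask()].
#' @return A one-row tibble with `voxel_count` and `volume_mm3`.
#' @export
#' @examples
#' m <- make_lesion_mask(40, grid_shape = c(10, 10, 10),
#'                       voxel_dims = c(2, 2, 2))
#' compute_lesion_volume(m) # 5 voxels, 40 mm^3
compute_lesion_volume <- function(mask) {
  stopifnot(inherits(mask, "lesion_mask"))
  count <- sum(mask$grid)
  tibble(voxel_count = as.integer(count),
         volume_mm3 = count * prod(mask$voxel_dims))
}

#' Generate a synthetic lesion mask of a given volume
#'
#' Grows a single 6-connected component from the grid centre by repeatedly
#' adding a randomly chosen frontier voxel, until the target volume is
#' reached. The target must be an exact multiple of the voxel volume and fit
#' on the grid.
#'
#' @param target_volume Desired lesion volume in cubic millimeters.
#' @param grid_shape Integer length-3 grid dimensions.
#' @param voxel_dims Voxel edge lengths in mm.
#' @param seed Integer seed; the mask is a deterministic function of
#'   (`target_volume`, `grid_shape`, `voxel_dims`, `seed`).
#' @return A [lesion_mask()] whose foreground is one connected component of
#'   exactly `target_volume / prod(voxel_dims)` voxels (empty for target 0).
#' @export
make_lesion_mask <- function(target_volume, grid_shape = c(64, 64, 64),
                             voxel_dims = c(1, 1, 1), seed = 1L) {
  if (target_volume < 0) abort("`target_volume` must be non-negative.")
  vox_vol <- prod(voxel_dims)
  n_vox <- target_volume / vox_vol
  if (abs(n_vox - round(n_vox)) > 1e-8 || round(n_vox) > prod(grid_shape)) {
    nearest <- min(round(n_vox), prod(grid_shape)) * vox_vol
    abort(sprintf(
      "Target volume %g mm^3 is not achievable on this grid (voxel volume %g mm^3); nearest achievable volume is %g mm^3.",
      target_volume, vox_vol, nearest
    ))
  }
  n_vox <- as.integer(round(n_vox))
  grid <- array(0L, dim = grid_shape)
  if (n_vox > 0) {
    filled <- withr::with_seed(seed, grow_component(grid_shape, n_vox))
    grid[filled] <- 1L
  }
  lesion_mask(grid, voxel_dims, space = "synthetic")
}

# Randomized connected growth over linear voxel indices. The frontier is a
# multiset (stale entries are discarded on draw); removal is swap-with-last.
grow_component <- function(shape, n_vox) {
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  filled <- logical(prod(shape))
  frontier <- integer(2048)
  n_front <- 0L
  push <- function(v) {
    if (n_front == length(frontier)) {
      frontier <<- c(frontier, integer(length(frontier)))
    }
    n_front <<- n_front + 1L
    frontier[n_front] <<- v
  }
  neighbours <- function(v) {
    v0 <- v - 1L
    x <- v0 %% nx
    y <- (v0 %/% nx) %% ny
    z <- v0 %/% (nx * ny)
    out <- integer(0)
    if (x > 0L) out <- c(out, v - 1L)
    if (x < nx - 1L) out <- c(out, v + 1L)
    if (y > 0L) out <- c(out, v - nx)
    if (y < ny - 1L) out <- c(out, v + nx)
    if (z > 0L) out <- c(out, v - nx * ny)
    if (z < nz - 1L) out <- c(out, v + nx * ny)
    out
  }
  start <- ceiling(shape / 2)
  v0 <- as.integer((start[3] - 1) * nx * ny + (start[2] - 1) * nx + start[1])
  filled[v0] <- TRUE
  n_added <- 1L
  for (w in neighbours(v0)) push(w)
  while (n_added < n_vox) {
    if (n_front == 0L) {
      abort("Lesion growth exhausted the grid; enlarge `grid_shape`.")
    }
    i <- sample.int(n_front, 1L)
    v <- frontier[i]
    frontier[i] <- frontier[n_front]
    n_front <- n_front - 1L
    if (!filled[v]) {
      filled[v] <- TRUE
      n_added <- n_added + 1L
      for (w in neighbours(v)) if (!filled[w]) push(w)
    }
  }
  which(filled)
}

#' Read and write lesion masks as NIfTI-1
#'
#' Voxel dimensions are taken from the image header. If `voxel_dims` is also
#' supplied and disagrees with the header, reading is an error (a silent
#' mismatch would corrupt every downstream volume).
#'
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param voxel_dims Optional expected voxel dimensions in mm, checked
#'   against the header.
#' @param binarize_at Optional threshold for interpolated masks, see
#'   [lesion_mask()].
#' @param mask A [lesion_mask()].
#' @return `read_lesion_mask()` returns a [lesion_mask()];
#'   `write_lesion_mask()` returns `path` invisibly.
#' @export
read_lesion_mask <- function(path, voxel_dims = NULL, binarize_at = NULL) {
  img <- RNifti::readNifti(path)
  hdr_dims <- RNifti::pixdim(img)[1:3]
  if (!is.null(voxel_dims) &&
      any(abs(hdr_dims - voxel_dims) > 1e-5 * pmax(1, abs(voxel_dims)))) {
    abort(sprintf(
      "Header voxel dimensions (%s mm) disagree with the expected dimensions (%s mm).",
      paste(signif(hdr_dims, 6), collapse = "x"),
      paste(voxel_dims, collapse = "x")
    ))
  }
  lesion_mask(array(as.vector(img), dim = dim(img)[1:3]),
              voxel_dims = hdr_dims, space = "from-header",
              binarize_at = binarize_at)
}

#' @rdname read_lesion_mask
#' @export
write_lesion_mask <- function(mask, path) {
  stopifnot(inherits(mask, "lesion_mask"))
  img <- RNifti::asNifti(mask$grid)
  RNifti::pixdim(img) <- mask$voxel_dims
  RNifti::writeNifti(img, path)
  invisible(path)
}
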