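#' Construct a subject volume
#'
#' One subject's 3D white-matter intensity grid together with its voxel
#' geometry and outcome label.
#'
#' @param data 3D numeric array of WM intensities (finite; normally in
#'   \[0, 1\]).
#' @param voxel_size_mm length-3 voxel size in mm.
#' @param subject_id subject identifier string.
#' @param label outcome label, +1 (favorable) or -1 (non-favorable).
#' @param clip clip intensities into \[0, 1\] (default TRUE).
#' @return An object of class `subject_volume`.
#' @export
subject_volume <- function(data, voxel_size_mm = c(1, 1, 1),
                           subject_id = "S01", label = 1, clip = TRUE) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort_field("data", "must be a 3D array")
  }
  if (!all(is.finite(data))) abort_field("data", "must be finite")
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0)) {
    abort_field("voxel_size_mm", "must be a positive length triple")
  }
  if (!label %in% c(-1, 1)) abort_field("label", "must be +1 or -1")
  if (clip) data <- pmin(pmax(data, 0), 1)
  structure(
    list(data = data, voxel_size_mm = as.numeric(voxel_size_mm),
         subject_id = as.character(subject_id), label = as.numeric(label)),
    class = "subject_volume"
  )
}

# 1D truncated Gaussian kernel, sum-normalized; radius 4 sigma.
gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- ceiling(4 * sigma)
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Convolve a 3D array separably with per-axis kernels, zero padding.
convolve_separable <- function(a, kernels) {
  d <- dim(a)
  for (ax in 1:3) {
    k <- kernels[[ax]]
    if (length(k) == 1L) next
    n <- d[ax]
    r <- (length(k) - 1L) / 2L
    # banded convolution matrix: out[i] = sum_j k[i-j+r+1] a[j]
    K <- matrix(0, n, n)
    for (off in (-r:r)[abs(-r:r) < n]) {
      idx <- seq_len(n - abs(off))
      if (off >= 0) {
        K[cbind(idx + off, idx)] <- k[off + r + 1L]
      } else {
        K[cbind(idx, idx - off)] <- k[off + r + 1L]
      }
    }
    a <- apply(a, setdiff(1:3, ax), function(v) K %*% v)
    # apply returns the convolved axis first; rotate back into place
    perm <- order(c(ax, setdiff(1:3, ax)))
    a <- aperm(array(a, dim = c(d[ax], d[setdiff(1:3, ax)])), perm)
  }
  a
}

#' Gaussian-smooth a volume
#'
#' Isotropic-in-mm Gaussian smoothing with per-axis sigma
#' `fwhm_mm / voxel_size_mm / (2 sqrt(2 log 2))` voxels. The kernel is
#' truncated at 4 sigma and renormalized per output voxel, so a constant
#' volume is reproduced exactly, including at the edges.
#'
#' @param volume a [subject_volume()].
#' @param fwhm_mm full width at half maximum in mm (>= 0; 0 is the
#'   identity).
#' @return A smoothed `subject_volume` of the same shape.
#' @export
gaussian_smooth <- function(volume, fwhm_mm) {
  stopifnot(inherits(volume, "subject_volume"))
  if (length(fwhm_mm) != 1L || !is.finite(fwhm_mm) || fwhm_mm < 0) {
    abort_field("fwhm_mm", "must be a single value >= 0")
  }
  if (fwhm_mm == 0) return(volume)
  sigmas <- fwhm_to_sigma(fwhm_mm, volume$voxel_size_mm)
  kernels <- lapply(sigmas, gaussian_kernel_1d)
  num <- convolve_separable(volume$data, kernels)
  den <- convolve_separable(array(1, dim = dim(volume$data)), kernels)
  out <- volume
  out$data <- num / den
  out
}

#' Default analysis mask from cohort-mean intensity
#'
#' Voxels whose across-subject mean intensity exceeds `threshold` are kept;
#' this excludes empty background in tissue-probability volumes. The
#' threshold is a stand-in for an anatomically defined white-matter mask and
#' is configurable.
#'
#' @param volumes list of [subject_volume()] objects with a common shape.
#' @param threshold mean-intensity cutoff (default 0.05).
#' @return Logical 3D array.
#' @export
default_mask <- function(volumes, threshold = 0.05) {
  stopifnot(length(volumes) >= 1L)
  d <- dim(volumes[[1]]$data)
  acc <- array(0, dim = d)
  for (v in volumes) {
    if (!identical(dim(v$data), d)) {
      stop("all volumes must share the same grid shape", call. = FALSE)
    }
    acc <- acc + v$data
  }
  (acc / length(volumes)) > threshold
}

#' Morphologically dilate a voxel mask
#'
#' Box (Chebyshev) dilation: a voxel is in the dilated mask if any mask
#' voxel lies within `radius_voxels` along every axis. Used e.g. to define
#' the neighbourhood a smoothed planted effect may legitimately spill into
#' (radius the ceiling of twice the kernel sigma).
#'
#' @param mask logical 3D array.
#' @param radius_voxels non-negative integer dilation radius.
#' @return Logical 3D array.
#' @export
dilate_mask <- function(mask, radius_voxels) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L, radius_voxels >= 0)
  r <- as.integer(ceiling(radius_voxels))
  if (r == 0L) return(mask)
  d <- dim(mask)
  out <- array(FALSE, dim = d)
  idx <- which(mask, arr.ind = TRUE)
  for (row in seq_len(nrow(idx))) {
    lo <- pmax(idx[row, ] - r, 1L)
    hi <- pmin(idx[row, ] + r, d)
    out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  }
  out
}

#' Flatten a cohort of volumes into a feature matrix
#'
#' Builds the subjects-by-voxels analysis matrix: each subject's in-mask
#' voxel intensities form one row, in a fixed voxel order recorded in
#' `voxel_index_map` so any column can be mapped back to its voxel
#' coordinate.
#'
#' @param volumes list of [subject_volume()] objects (common shape).
#' @param mask logical 3D array; at least one voxel must be TRUE. Defaults
#'   to [default_mask()] of the volumes.
#' @param clinical optional clinical data frame with an `id` column covering
#'   every subject.
#' @return An object of class `cohort_dataset` with elements `X` (N x n
#'   matrix), `y` (labels), `mask`, `grid_shape`, `voxel_size_mm`,
#'   `voxel_index_map` (n x 3 matrix of 1-based voxel coordinates, row j =
#'   coordinate of column j), `subject_ids`, `clinical`.
#' @export
build_dataset <- function(volumes, mask = NULL, clinical = NULL) {
  stopifnot(length(volumes) >= 2L)
  d <- dim(volumes[[1]]$data)
  for (v in volumes) {
    if (!identical(dim(v$data), d)) {
      stop("volume shape mismatch across subjects", call. = FALSE)
    }
  }
  if (is.null(mask)) mask <- default_mask(volumes)
  if (!is.logical(mask) || !identical(dim(mask), d)) {
    stop("mask must be a logical array matching the volume shape",
         call. = FALSE)
  }
  if (!any(mask)) stop("mask selects no voxels", call. = FALSE)
  ids <- vapply(volumes, function(v) v$subject_id, character(1))
  y <- vapply(volumes, function(v) v$label, numeric(1))
  check_labels(y)
  if (!is.null(clinical)) {
    if (!all(ids %in% clinical$id)) {
      stop("every subject needs a clinical row (missing id)", call. = FALSE)
    }
    clinical <- clinical[match(ids, clinical$id), , drop = FALSE]
  }
  keep <- which(mask)
  X <- t(vapply(volumes, function(v) v$data[keep], numeric(length(keep))))
  rownames(X) <- ids
  structure(
    list(X = X, y = y, mask = mask, grid_shape = d,
         voxel_size_mm = volumes[[1]]$voxel_size_mm,
         voxel_index_map = which(mask, arr.ind = TRUE),
         subject_ids = ids, clinical = clinical),
    class = "cohort_dataset"
  )
}

#' Un-flatten one feature column back to its voxel coordinate
#'
#' @param dataset a [build_dataset()] result.
#' @param column in-mask column index.
#' @return Integer triple, the 1-based voxel coordinate of that column.
#' @export
column_to_voxel <- function(dataset, column) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  if (column < 1 || column > nrow(dataset$voxel_index_map)) {
    stop("column index out of range", call. = FALSE)
  }
  as.integer(dataset$voxel_index_map[column, ])
}
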