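# Phenotype preparation: smoothing of modulated gray-matter volumes and the
# mask/flatten step that turns per-subject 3D maps into the subjects x voxels
# matrix the fusion stage consumes.

FWHM_TO_SIGMA <- 1 / sqrt(8 * log(2))

#' Separable Gaussian smoothing of a 3D volume
#'
#' Smooths a volumetric image with an isotropic-in-mm Gaussian kernel
#' specified by its full width at half maximum, the convention used for
#' voxel-based morphometry maps.  The per-axis kernel standard deviation in
#' voxels is `fwhm_mm / (sqrt(8 log 2) * voxel_size_mm)`; the kernel is
#' truncated at 4 sigma and renormalised to unit mass.  Boundaries use
#' normalised convolution (zero-padding divided by the smoothed indicator
#' of the grid), so constant volumes are exactly invariant and compactly
#' supported interior signals keep their total intensity.
#'
#' @param volume 3D numeric array.
#' @param fwhm_mm Full width at half maximum in millimetres; 0 is identity.
#' @param voxel_size_mm Positive voxel edge lengths, length 1 or 3 (mm).
#' @return Smoothed array with the same dimensions.
#' @export
gaussian_smooth <- function(volume, fwhm_mm = 4, voxel_size_mm = c(1, 1, 1)) {
  if (length(dim(volume)) != 3L) {
    stop_pf("gaussian_smooth() expects a 3D array, got %s dimensions",
            length(dim(volume)) %||% 0L)
  }
  if (fwhm_mm < 0) stop_pf("fwhm_mm must be >= 0")
  voxel_size_mm <- rep_len(voxel_size_mm, 3L)
  if (any(voxel_size_mm <= 0)) stop_pf("voxel sizes must be positive")
  if (fwhm_mm == 0) return(volume)

  out <- volume
  norm <- array(1, dim(volume))       # local kernel mass inside the grid
  for (axis in 1:3) {
    k <- gaussian_kernel(fwhm_mm * FWHM_TO_SIGMA / voxel_size_mm[axis])
    out <- convolve_axis(out, k, axis)
    norm <- convolve_axis(norm, k, axis)
  }
  out / norm
}

gaussian_kernel <- function(sigma_vox) {
  if (sigma_vox == 0) return(1)
  half <- max(1L, ceiling(4 * sigma_vox))
  x <- (-half):half
  k <- exp(-0.5 * (x / sigma_vox)^2)
  k / sum(k)
}

# 1D convolution along one axis of a 3D array, zero-padded: the output is the
# sum over kernel taps of shifted copies of the input.
convolve_axis <- function(a, kernel, axis) {
  half <- (length(kernel) - 1L) %/% 2L
  if (half == 0L) return(a * kernel)
  d <- dim(a)
  out <- array(0, d)
  n <- d[axis]
  for (t in seq_along(kernel)) {
    off <- t - half - 1L             # source index = dest index + off
    src <- seq_len(n) + off
    keep <- src >= 1L & src <= n
    if (!any(keep)) next
    dst_idx <- which(keep)
    src_idx <- src[keep]
    idx_dst <- slice_index(d, axis, dst_idx)
    idx_src <- slice_index(d, axis, src_idx)
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] +
      kernel[t] * a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  }
  out
}

slice_index <- function(d, axis, idx) {
  full <- lapply(d, seq_len)
  full[[axis]] <- idx
  full
}

#' Mask and flatten per-subject volumes into a phenotype matrix
#'
#' Applies a binary 3D mask to each subject's volume and stacks the in-mask
#' voxels into a subjects x voxels matrix.  Voxel order is the fixed
#' lexicographic order over grid coordinates with the first axis fastest
#' (R's native array linearisation), recorded in `voxel_index_map` so maps
#' can be reconstructed bit-for-bit.
#'
#' @param volumes List of 3D arrays (one per subject), or a 4D array with
#'   subject as the 4th dimension.
#' @param mask Logical/0-1 3D array; `TRUE` voxels enter the matrix.
#' @param voxel_size_mm Voxel edge lengths carried as metadata.
#' @return An object of class `phenotype_matrix`: list with `values`
#'   (subjects x in-mask voxels), `mask`, `grid_dims`, `voxel_size_mm`,
#'   `voxel_index_map` (linear indices of in-mask voxels, ascending).
#' @export
mask_and_flatten <- function(volumes, mask, voxel_size_mm = c(1, 1, 1)) {
  if (is.array(volumes) && length(dim(volumes)) == 4L) {
    volumes <- lapply(seq_len(dim(volumes)[4]), function(s) volumes[, , , s])
  }
  mask <- array(as.logical(mask), dim(mask))
  dims <- dim(mask)
  idx_map <- which(mask)
  values <- matrix(NA_real_, nrow = length(volumes), ncol = length(idx_map))
  for (s in seq_along(volumes)) {
    v <- volumes[[s]]
    if (!identical(dim(v), dims)) {
      stop_pf("subject %d volume has dims %s, mask has %s",
              s, paste(dim(v), collapse = "x"), paste(dims, collapse = "x"))
    }
    values[s, ] <- v[idx_map]
  }
  rownames(values) <- names(volumes)
  structure(
    list(values = values, mask = mask, grid_dims = dims,
         voxel_size_mm = rep_len(voxel_size_mm, 3L),
         voxel_index_map = idx_map,
         ordering = "x-fastest lexicographic v1"),
    class = "phenotype_matrix")
}

#' Reconstruct a 3D map from a flattened in-mask vector
#'
#' Exact inverse of [mask_and_flatten()] for a single row: off-mask voxels
#' are zero.
#'
#' @param row_vector Numeric vector, one value per in-mask voxel.
#' @param mask Logical/0-1 3D array used to flatten.
#' @return 3D array with `dim(mask)`.
#' @export
unflatten_map <- function(row_vector, mask) {
  mask <- array(as.logical(mask), dim(mask))
  n_in <- sum(mask)
  if (length(row_vector) != n_in) {
    stop_pf("vector length %d does not match mask support %d",
            length(row_vector), n_in)
  }
  out <- array(0, dim(mask))
  out[which(mask)] <- row_vector
  out
}
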