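#' Convert Gaussian FWHM to standard deviation
#'
#' `sigma = fwhm / (2 * sqrt(2 * log(2)))`, the definitional relation for a
#' Gaussian kernel's full width at half maximum.
#'
#' @param fwhm_mm FWHM in mm (>= 0).
#' @return Standard deviation in mm.
#' @examples
#' fwhm_to_sigma(8) # ~3.397
#' @export
fwhm_to_sigma <- function(fwhm_mm) {
  if (!is.numeric(fwhm_mm) || any(fwhm_mm < 0)) stop("fwhm_mm must be >= 0")
  fwhm_mm / (2 * sqrt(2 * log(2)))
}

# n x n 1D convolution matrix for a unit-sum Gaussian kernel with reflection
# padding: row i holds the kernel centred at i with out-of-range taps folded
# back onto the reflected index, so a constant input is exactly preserved
# and the total sum is conserved.
gaussian_conv_matrix <- function(n, sigma_vox) {
  half <- max(1L, ceiling(4 * sigma_vox))
  taps <- (-half):half
  k <- exp(-taps^2 / (2 * sigma_vox^2))
  k <- k / sum(k)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + taps
    # half-sample reflection about the edges (0 -> 1, n+1 -> n), iterated
    # for kernels wider than the axis; with an even kernel this makes K
    # symmetric and doubly stochastic, so constants and the total in-grid
    # sum are both preserved exactly
    while (any(j < 1L | j > n)) {
      j <- ifelse(j < 1L, 1L - j, j)
      j <- ifelse(j > n, 2L * n + 1L - j, j)
    }
    for (t in seq_along(taps)) K[i, j[t]] <- K[i, j[t]] + k[t]
  }
  K
}

#' Gaussian smoothing of a volume
#'
#' Separable 3D Gaussian convolution with per-axis standard deviation
#' `fwhm_to_sigma(fwhm_mm) / voxel_size_mm` voxels, using reflection padding
#' at the grid boundary (so constants are preserved and no edge attenuation
#' leaks into the brain mask). `fwhm_mm = 0` is the identity.
#'
#' @param volume 3D numeric array on `grid`.
#' @param grid A [grid_spec()]; the voxel size must be isotropic (which
#'   [grid_spec()] enforces by construction).
#' @param fwhm_mm Kernel FWHM in mm, default 8.
#' @return Smoothed array of the same dimensions.
#' @export
smooth_volume <- function(volume, grid, fwhm_mm = 8) {
  check_volume_grid(volume, grid)
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || fwhm_mm < 0) {
    stop("fwhm_mm must be a single number >= 0")
  }
  if (fwhm_mm == 0) return(volume)
  sigma_vox <- fwhm_to_sigma(fwhm_mm) / grid$voxel_size_mm
  d <- dim(volume)
  out <- volume
  for (axis in 1:3) {
    K <- gaussian_conv_matrix(d[axis], sigma_vox)
    perm <- c(axis, setdiff(1:3, axis))
    m <- matrix(aperm(out, perm), nrow = d[axis])
    m <- K %*% m
    out <- aperm(array(m, dim = d[perm]), order(perm))
  }
  out
}

#' Proportional global intensity normalization
#'
#' Rescales a scan so its mean intensity inside the brain mask equals
#' `target_mean` (default 50): `out = volume * target_mean / mean(in-mask)`.
#' This removes per-subject global scaling (injected dose, uptake time,
#' scanner gain) so that the downstream statistics and decoder see only
#' regional contrast.
#'
#' @param volume 3D numeric array.
#' @param brain_mask Logical array of the same dimensions.
#' @param target_mean Target in-mask mean (> 0).
#' @return Rescaled array; its in-mask mean equals `target_mean` exactly.
#' @export
global_normalize <- function(volume, brain_mask, target_mean = 50) {
  stopifnot(identical(dim(volume), dim(brain_mask)))
  if (!is.numeric(target_mean) || target_mean <= 0) {
    stop("target_mean must be > 0")
  }
  m <- mean(volume[brain_mask])
  if (!is.finite(m) || m <= 0) {
    stop("degenerate scan: non-positive in-mask mean, cannot normalize")
  }
  volume * (target_mean / m)
}

#' Preprocess every scan of a cohort
#'
#' Applies, in order and identically to every subject: Gaussian smoothing
#' ([smooth_volume()]) and proportional global normalization
#' ([global_normalize()]). The order (smooth first, then normalize) and both
#' parameters are recorded in the returned cohort's `preprocess` field so a
#' testing cohort can be processed with exactly the training-time settings.
#'
#' @param cohort A `pet_cohort`.
#' @param fwhm_mm Smoothing kernel FWHM in mm (default 8).
#' @param target_mean Global normalization target (default 50).
#' @return The cohort with smoothed, normalized subject volumes and a
#'   `preprocess` parameter record.
#' @export
preprocess_cohort <- function(cohort, fwhm_mm = 8, target_mean = 50) {
  stopifnot(inherits(cohort, "pet_cohort"))
  for (i in seq_along(cohort$subjects)) {
    v <- smooth_volume(cohort$subjects[[i]]$volume, cohort$grid, fwhm_mm)
    v <- global_normalize(v, cohort$brain_mask, target_mean)
    cohort$subjects[[i]]$volume <- v
  }
  cohort$preprocess <- list(fwhm_mm = fwhm_mm, target_mean = target_mean,
                            order = c("smooth", "normalize"))
  cohort
}
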