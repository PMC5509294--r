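#' Voxel grid specification
#'
#' Describes the sampling lattice shared by every volume in a cohort: the
#' number of voxels per axis, the isotropic voxel edge length in mm, and the
#' template-space (mm) coordinate of voxel `(1,1,1)`. The affine mapping is
#' `mm = origin_mm + (ijk - 1) * voxel_size_mm` per axis, i.e. axis-aligned
#' scaling with no rotation, appropriate for volumes already resampled onto a
#' common template.
#'
#' @param shape Integer vector of length 3, voxel counts per axis (each >= 1).
#' @param voxel_size_mm Isotropic voxel edge length in mm (default 2, the
#'   template resolution the pipeline assumes).
#' @param origin_mm Numeric length-3 mm coordinate of the first voxel. The
#'   default centres the grid on the template origin.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(c(48, 56, 48))
#' voxel_to_mm(g, c(1, 1, 1))
#' @export
grid_spec <- function(shape, voxel_size_mm = 2, origin_mm = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L)
  if (any(shape < 1L)) stop("all grid shape entries must be >= 1")
  if (!is.numeric(voxel_size_mm) || length(voxel_size_mm) != 1L ||
      voxel_size_mm <= 0) {
    stop("voxel_size_mm must be a single positive number")
  }
  if (is.null(origin_mm)) {
    origin_mm <- -(shape - 1) / 2 * voxel_size_mm
  }
  stopifnot(length(origin_mm) == 3L, all(is.finite(origin_mm)))
  structure(
    list(shape = shape, voxel_size_mm = voxel_size_mm,
         origin_mm = as.numeric(origin_mm)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d x %d voxels, %.3g mm isotropic, origin (%s) mm\n",
              x$shape[1], x$shape[2], x$shape[3], x$voxel_size_mm,
              paste(signif(x$origin_mm, 4), collapse = ", ")))
  invisible(x)
}

#' Convert between voxel indices and template mm coordinates
#'
#' `voxel_to_mm()` maps 1-based voxel indices to mm coordinates;
#' `mm_to_voxel()` is its (real-valued) inverse. Rows of a matrix are
#' converted independently.
#'
#' @param grid A [grid_spec()].
#' @param ijk Numeric vector of length 3 or matrix with 3 columns of 1-based
#'   voxel indices.
#' @return Numeric vector or matrix of mm coordinates (or voxel indices for
#'   `mm_to_voxel`).
#' @export
voxel_to_mm <- function(grid, ijk) {
  stopifnot(inherits(grid, "grid_spec"))
  if (is.matrix(ijk)) {
    sweep(sweep(ijk - 1, 2, grid$voxel_size_mm, "*"), 2, grid$origin_mm, "+")
  } else {
    grid$origin_mm + (ijk - 1) * grid$voxel_size_mm
  }
}

#' @rdname voxel_to_mm
#' @param xyz_mm Numeric vector of length 3 or matrix with 3 columns of mm
#'   coordinates.
#' @export
mm_to_voxel <- function(grid, xyz_mm) {
  stopifnot(inherits(grid, "grid_spec"))
  if (is.matrix(xyz_mm)) {
    sweep(sweep(xyz_mm, 2, grid$origin_mm, "-"), 2, grid$voxel_size_mm, "/") + 1
  } else {
    (xyz_mm - grid$origin_mm) / grid$voxel_size_mm + 1
  }
}

#' mm coordinates of every voxel centre, one axis at a time
#' @noRd
axis_coords_mm <- function(grid) {
  lapply(1:3, function(a) {
    grid$origin_mm[a] + (seq_len(grid$shape[a]) - 1) * grid$voxel_size_mm
  })
}

#' NIfTI affine for a grid (RASish axis-aligned scaling)
#' @noRd
grid_affine <- function(grid) {
  aff <- diag(c(rep(grid$voxel_size_mm, 3), 1))
  aff[1:3, 4] <- grid$origin_mm
  aff
}

check_volume_grid <- function(volume, grid, what = "volume") {
  if (!identical(dim(volume), grid$shape)) {
    stop(sprintf("%s dimensions (%s) do not match grid shape (%s)",
                 what, paste(dim(volume), collapse = "x"),
                 paste(grid$shape, collapse = "x")))
  }
  invisible(TRUE)
}

#' Write / read a volume as NIfTI-1
#'
#' Thin wrappers around [RNifti::writeNifti()] / [RNifti::readNifti()] that
#' stamp the grid affine (isotropic voxel size plus origin) into the header,
#' so peak coordinates reported by the cluster stage line up with what any
#' NIfTI viewer displays.
#'
#' @param volume 3D numeric array matching `grid`.
#' @param grid A [grid_spec()].
#' @param path Output path; conventional extension `.nii.gz` or `.nii`.
#' @return `write_volume()` returns `path` invisibly; `read_volume()` returns
#'   a list with `volume` (plain array) and `grid`.
#' @export
write_volume <- function(volume, grid, path) {
  check_volume_grid(volume, grid)
  img <- RNifti::asNifti(volume)
  img <- RNifti::`pixdim<-`(img, rep(grid$voxel_size_mm, 3))
  aff <- structure(grid_affine(grid), code = 2L)
  img <- RNifti::`sform<-`(img, aff)
  img <- RNifti::`qform<-`(img, aff)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  vs <- aff[1, 1]
  grid <- grid_spec(dim(img), voxel_size_mm = vs, origin_mm = aff[1:3, 4])
  list(volume = array(as.numeric(img), dim = dim(img)), grid = grid)
}
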