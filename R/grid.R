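#' Define a regular sampling grid in world (MNI) coordinates
#'
#' The grid is axis-aligned: voxel `(i, j, k)` (1-based) has its center at
#' `origin_mm + (c(i, j, k) - 1) * vox_mm`. World coordinates follow the
#' RAS/MNI convention (x to the right, y anterior, z superior, millimeters).
#'
#' @param dims integer 3-vector, voxels per axis.
#' @param vox_mm numeric 3-vector, voxel size in mm (positive).
#' @param origin_mm numeric 3-vector, world coordinate of the center of
#'   voxel (1,1,1).
#' @return An object of class `bold_grid`.
#' @export
bold_grid <- function(dims, vox_mm, origin_mm) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L))
    stopf("grid dims must be three positive integers")
  if (length(vox_mm) != 3L || any(vox_mm <= 0))
    stopf("voxel size must be three positive numbers (mm)")
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stopf("origin must be a finite world coordinate (mm)")
  structure(list(dims = dims, vox_mm = as.numeric(vox_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = "bold_grid")
}

#' Default desk-scale grid
#'
#' A 20 x 24 x 20 grid of 5 mm isotropic voxels (9600 voxels) positioned so
#' that it covers the subcortical/cerebellar seed coordinates and a dorsal
#' "cortical" band, and so that voxel centers are symmetric about the x = 0
#' midline (left/right seeds resolve to mirror-image masks).
#'
#' @return A `bold_grid`.
#' @export
default_grid <- function() {
  bold_grid(c(20L, 24L, 20L), c(5, 5, 5), c(-47.5, -97.5, -62.5))
}

n_voxels <- function(grid) prod(grid$dims)

# n x 3 matrix of world coordinates of all voxel centers, in R array
# linear-index order (first axis fastest).
voxel_centers <- function(grid) {
  idx <- as.matrix(expand.grid(i = seq_len(grid$dims[1]),
                               j = seq_len(grid$dims[2]),
                               k = seq_len(grid$dims[3])))
  sweep(sweep(idx - 1, 2L, grid$vox_mm, `*`), 2L, grid$origin_mm, `+`)
}

# World-coordinate bounding box of voxel centers.
grid_extent <- function(grid) {
  lo <- grid$origin_mm
  hi <- grid$origin_mm + (grid$dims - 1L) * grid$vox_mm
  rbind(lo = lo, hi = hi)
}

# 4x4 voxel(0-based)->world affine, for NIfTI xforms.
grid_affine <- function(grid) {
  aff <- diag(4)
  aff[1:3, 1:3] <- diag(grid$vox_mm)
  aff[1:3, 4] <- grid$origin_mm
  aff
}

grid_from_affine <- function(aff, dims) {
  m <- aff[1:3, 1:3]
  if (any(abs(m[row(m) != col(m)]) > 1e-6))
    stopf("only axis-aligned NIfTI orientations are supported")
  bold_grid(dims, diag(m), aff[1:3, 4])
}

#' @export
print.bold_grid <- function(x, ...) {
  ext <- grid_extent(x)
  cat(sprintf("<bold_grid> %d x %d x %d voxels @ %g x %g x %g mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$vox_mm[1], x$vox_mm[2], x$vox_mm[3]))
  cat(sprintf("  centers span x [%g, %g]  y [%g, %g]  z [%g, %g] mm\n",
              ext[1, 1], ext[2, 1], ext[1, 2], ext[2, 2], ext[1, 3],
              ext[2, 3]))
  invisible(x)
}
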