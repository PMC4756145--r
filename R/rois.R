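#' Seed regions of the four subcortical-cerebellar systems
#'
#' Returns the default table of 16 spherical seed regions (6 mm radius), four
#' per system, in MNI millimeter coordinates:
#'
#' * striatum: left/right ventral striatum (+-12, 9, -9) and dorsal striatum
#'   (+-24, 12, 0);
#' * cerebellum: left/right Crus I (+-12, -80, -24) and Crus II
#'   (+-22, -86, -40);
#' * MTL: left/right hippocampus (+-24, -18, -18) and parahippocampus
#'   (+-26, -40, -12);
#' * amygdala: left/right basolateral and centromedial spheres. The amygdala
#'   subregions are *synthetic stand-ins* at literature-typical centers; in
#'   the original methodology they come from a probabilistic cytoarchitectonic
#'   atlas rather than printed coordinates.
#'
#' @param radius_mm sphere radius in mm (default 6).
#' @return A data.frame with columns `name`, `system`, `hemisphere`,
#'   `x`, `y`, `z`, `radius_mm`.
#' @export
default_roi_table <- function(radius_mm = 6) {
  mk <- function(base, system, x, y, z) {
    data.frame(
      name = paste(base, c("L", "R"), sep = "_"),
      system = system, hemisphere = c("left", "right"),
      x = c(-x, x), y = y, z = z, radius_mm = radius_mm,
      stringsAsFactors = FALSE)
  }
  rbind(
    mk("ventral_striatum", "striatum", 12, 9, -9),
    mk("dorsal_striatum", "striatum", 24, 12, 0),
    mk("crus1", "cerebellum", 12, -80, -24),
    mk("crus2", "cerebellum", 22, -86, -40),
    mk("hippocampus", "MTL", 24, -18, -18),
    mk("parahippocampus", "MTL", 26, -40, -12),
    mk("basolateral_amygdala", "amygdala", 28, -4, -22),
    mk("centromedial_amygdala", "amygdala", 22, -6, -12)
  )
}

#' The four subcortical-cerebellar systems under study
#' @return Character vector of system labels.
#' @export
roi_systems <- function() c("striatum", "cerebellum", "MTL", "amygdala")

#' Resolve spherical seed specifications to voxel masks
#'
#' A voxel belongs to a mask when its *center* lies within `radius_mm` of the
#' seed center in world coordinates (Euclidean distance, boundary inclusive).
#' Resolution is deterministic.
#'
#' @param roi_specs data.frame as returned by [default_roi_table()] (columns
#'   `name`, `system`, `hemisphere`, `x`, `y`, `z`, `radius_mm`).
#' @param grid a [bold_grid()].
#' @return A named list of `roi_mask` objects, each with fields `name`,
#'   `system`, `hemisphere`, `center`, `radius_mm` and `voxels` (linear voxel
#'   indices into the grid).
#' @export
make_roi_masks <- function(roi_specs, grid) {
  needed <- c("name", "system", "hemisphere", "x", "y", "z", "radius_mm")
  if (!all(needed %in% names(roi_specs)))
    stopf("roi_specs must have columns: %s", paste(needed, collapse = ", "))
  bad <- setdiff(unique(roi_specs$system), roi_systems())
  if (length(bad))
    stopf("unknown ROI system(s): %s", paste(bad, collapse = ", "))
  ext <- grid_extent(grid)
  ctr <- voxel_centers(grid)
  masks <- lapply(seq_len(nrow(roi_specs)), function(r) {
    spec <- roi_specs[r, ]
    cen <- c(spec$x, spec$y, spec$z)
    if (any(cen < ext["lo", ] - grid$vox_mm / 2) ||
        any(cen > ext["hi", ] + grid$vox_mm / 2))
      stopf("ROI '%s': center (%g, %g, %g) falls outside the grid",
            spec$name, cen[1], cen[2], cen[3])
    d2 <- (ctr[, 1] - cen[1])^2 + (ctr[, 2] - cen[2])^2 +
      (ctr[, 3] - cen[3])^2
    vox <- which(d2 <= spec$radius_mm^2 + 1e-9)
    if (!length(vox))
      stopf("ROI '%s': no voxel center within %g mm of (%g, %g, %g)",
            spec$name, spec$radius_mm, cen[1], cen[2], cen[3])
    structure(list(name = spec$name, system = spec$system,
                   hemisphere = spec$hemisphere, center = cen,
                   radius_mm = spec$radius_mm, voxels = vox),
              class = "roi_mask")
  })
  names(masks) <- roi_specs$name
  masks
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %s (%s, %s): %d voxels within %g mm of (%g, %g, %g)\n",
              x$name, x$system, x$hemisphere, length(x$voxels), x$radius_mm,
              x$center[1], x$center[2], x$center[3]))
  invisible(x)
}
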