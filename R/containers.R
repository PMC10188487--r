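#' Calibrated binary cell mask
#'
#' Lightweight container for a single-cell segmentation: a logical matrix
#' plus its pixel size. The mask must contain exactly one 8-connected
#' component of positive area.
#'
#' @param mask logical (or 0/1) matrix; rows are y, columns are x.
#' @param pixel_size_um pixel edge length in um.
#' @return object of class `cell_mask`.
#' @export
cell_mask <- function(mask, pixel_size_um) {
  .assert(is.matrix(mask), "mask must be a matrix")
  .assert(.is_num(pixel_size_um) && pixel_size_um > 0, "pixel_size_um must be > 0")
  mask <- mask != 0
  .assert(sum(mask) > 0, "mask is empty")
  .assert(.n_components(mask) == 1L, "mask must contain exactly one connected component")
  structure(list(mask = mask, pixel_size_um = pixel_size_um),
            class = "cell_mask")
}

#' @export
print.cell_mask <- function(x, ...) {
  cat(sprintf("<cell_mask> %d x %d px @ %.3g um/px, area %.3g um^2\n",
              nrow(x$mask), ncol(x$mask), x$pixel_size_um,
              sum(x$mask) * x$pixel_size_um^2))
  invisible(x)
}

#' Calibrated 3D intensity grid
#'
#' @param intensities 3D numeric array (x, y, z order of dimensions).
#' @param voxel_size_um voxel spacing `(dx, dy, dz)` in um; defaults to the
#'   confocal nuclear-imaging calibration 0.132 x 0.132 x 0.24 um.
#' @return object of class `voxel_grid`.
#' @export
voxel_grid <- function(intensities, voxel_size_um = c(0.132, 0.132, 0.24)) {
  .assert(is.array(intensities) && length(dim(intensities)) == 3,
          "intensities must be a 3D array")
  .assert(.is_num(voxel_size_um, 3L) && all(voxel_size_um > 0),
          "voxel_size_um must be 3 positive numbers")
  .assert(all(dim(intensities) >= 8), "grid needs >= 8 voxels per axis")
  structure(list(intensities = intensities, voxel_size_um = voxel_size_um),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %s voxels @ %s um\n",
              paste(dim(x$intensities), collapse = " x "),
              paste(signif(x$voxel_size_um, 3), collapse = " x ")))
  invisible(x)
}

#' Nuclei centroid field with optional region mask
#'
#' @param points two-column matrix or data.frame of `(x_um, y_um)` positions.
#' @param bounds field extent `(width_um, height_um)`.
#' @param pixel_size_um calibration used to interpret pixel-based rules
#'   (deduplication radius, border margin, region mask lookup).
#' @param region_mask optional logical matrix (same pixel grid) marking the
#'   "active" region.
#' @return object of class `centroid_field`.
#' @export
centroid_field <- function(points, bounds, pixel_size_um, region_mask = NULL) {
  pts <- as.matrix(points)
  if (nrow(pts)) {
    .assert(ncol(pts) >= 2, "points must have x and y columns")
    pts <- pts[, 1:2, drop = FALSE]
    .assert(all(is.finite(pts)), "points must be finite")
  } else {
    pts <- matrix(numeric(0), 0, 2)
  }
  colnames(pts) <- c("x_um", "y_um")
  .assert(.is_num(bounds, 2L) && all(bounds > 0), "bounds must be positive (w, h)")
  .assert(.is_num(pixel_size_um) && pixel_size_um > 0, "pixel_size_um must be > 0")
  .assert(all(pts[, 1] >= 0 & pts[, 1] <= bounds[1] &
                pts[, 2] >= 0 & pts[, 2] <= bounds[2]),
          "all points must lie within bounds")
  if (nrow(pts) > 1) {
    .assert(anyDuplicated(pts) == 0, "exact duplicate points are not allowed")
  }
  if (!is.null(region_mask)) .assert(is.matrix(region_mask), "region_mask must be a matrix")
  structure(list(points = pts, bounds = bounds, pixel_size_um = pixel_size_um,
                 region_mask = region_mask),
            class = "centroid_field")
}

#' @export
print.centroid_field <- function(x, ...) {
  cat(sprintf("<centroid_field> %d points in %.3g x %.3g um\n",
              nrow(x$points), x$bounds[1], x$bounds[2]))
  invisible(x)
}
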