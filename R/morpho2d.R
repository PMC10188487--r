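#' Cell compactness (isoperimetric ratio)
#'
#' Ratio of the cell area to the area of the circle having the same
#' perimeter: `C = A / (Per^2 / 4*pi) = 4*pi*A / Per^2`. Equals 1 for a
#' circle and decreases for rough or protrusive outlines. The perimeter is
#' estimated with a Crofton-style weighted boundary-pair count that is
#' asymptotically exact for disks and axis-aligned squares (naive pixel-edge
#' counting would overestimate circle perimeters by ~4/pi).
#'
#' @param mask a [cell_mask()].
#' @return compactness value (dimensionless, ~(0, 1] up to discretization).
#' @export
compactness <- function(mask) {
  d <- shape_descriptors(mask)
  d$compactness
}

#' Area, perimeter and compactness of a cell mask
#'
#' @param mask a [cell_mask()].
#' @return one-row data.frame with `area_um2`, `perimeter_um`,
#'   `compactness`.
#' @export
shape_descriptors <- function(mask) {
  .assert(inherits(mask, "cell_mask"), "mask must be a cell_mask")
  a <- sum(mask$mask) * mask$pixel_size_um^2
  per <- .perimeter_crofton_px(mask$mask) * mask$pixel_size_um
  data.frame(area_um2 = a, perimeter_um = per,
             compactness = 4 * pi * a / per^2)
}

#' Count filopodia by opening subtraction
#'
#' Protrusions are what a morphological opening with a disk of radius
#' 1.1 um removes from the cell: the protrusion mask is
#' `mask AND NOT opening(mask, disk)`, and the filopodia count is the
#' number of its 8-connected components with area above 0.077 um^2 (the
#' debris gate).
#'
#' @param mask a [cell_mask()].
#' @param disk_radius_um radius of the structuring disk (default 1.1 um).
#' @param min_area_um2 minimum component area counted (default 0.077 um^2).
#' @return integer count.
#' @export
count_filopodia <- function(mask, disk_radius_um = 1.1, min_area_um2 = 0.077) {
  .assert(inherits(mask, "cell_mask"), "mask must be a cell_mask")
  r_px <- disk_radius_um / mask$pixel_size_um
  .assert(r_px >= 1, "structuring disk is below 1 px at this calibration")
  # exact Euclidean disk of radius r_px (makeBrush's "disc" deviates from a
  # Euclidean ball and leaves spurious opening residues on smooth outlines)
  half <- ceiling(r_px)
  ax <- -half:half
  brush <- 1 * (outer(ax^2, ax^2, "+") <= r_px^2)
  m <- matrix(as.numeric(mask$mask), nrow(mask$mask), ncol(mask$mask))
  opened <- as.matrix(EBImage::opening(m, brush))
  protr <- m > 0 & !(opened > 0)
  if (!any(protr)) return(0L)
  lab <- .bwlabel8(protr)
  areas <- tabulate(lab[lab > 0]) * mask$pixel_size_um^2
  sum(areas > min_area_um2)
}

#' Total focal-adhesion length in a region of interest
#'
#' Skeletonizes the adhesion mask (optionally restricted to a square window,
#' the conventional window is 135 x 135 um^2) and sums the skeleton
#' length via [skeleton_length()].
#'
#' @param fa_mask binary matrix of segmented adhesion signal.
#' @param pixel_size_um pixel calibration.
#' @param roi_center_um optional `(x_um, y_um)` center of the square window.
#' @param roi_side_um side of the window (default 135 um); ignored when
#'   `roi_center_um` is NULL (the whole image is measured).
#' @return total length in um.
#' @export
total_fa_length <- function(fa_mask, pixel_size_um, roi_center_um = NULL,
                            roi_side_um = 135) {
  .assert(is.matrix(fa_mask), "fa_mask must be a matrix")
  m <- fa_mask != 0
  if (!is.null(roi_center_um)) {
    idx <- .roi_indices(dim(m), roi_center_um, roi_side_um^2, pixel_size_um)
    m <- m[idx$rows, idx$cols, drop = FALSE]
  }
  skeleton_length(m, pixel_size_um)
}

# Row/column index ranges of a square ROI of the requested physical area.
.roi_indices <- function(dims, center_um, area_um2, pixel_size_um) {
  side_px <- max(1L, round(sqrt(area_um2) / pixel_size_um))
  rc <- round(center_um[2] / pixel_size_um + 0.5)
  cc <- round(center_um[1] / pixel_size_um + 0.5)
  r0 <- rc - floor((side_px - 1) / 2); r1 <- r0 + side_px - 1L
  c0 <- cc - floor((side_px - 1) / 2); c1 <- c0 + side_px - 1L
  .assert(r0 >= 1 && c0 >= 1 && r1 <= dims[1] && c1 <= dims[2],
          "ROI exceeds the image")
  list(rows = r0:r1, cols = c0:c1)
}

#' Mean intensity in a square ROI of given physical area
#'
#' Arithmetic mean of the pixel values inside a square region centered on a
#' user point; the default is a 56 um^2 region (side
#' `sqrt(56) ~ 7.48` um) of maximum-projection images.
#'
#' @param image numeric matrix.
#' @param center_um `(x_um, y_um)` ROI center.
#' @param area_um2 ROI area (default 56 um^2).
#' @param pixel_size_um pixel calibration.
#' @return mean gray value.
#' @export
mean_intensity_roi <- function(image, center_um, area_um2 = 56,
                               pixel_size_um) {
  .assert(is.matrix(image), "image must be a matrix")
  .assert(.is_num(center_um, 2L), "center_um must be (x, y)")
  idx <- .roi_indices(dim(image), center_um, area_um2, pixel_size_um)
  mean(image[idx$rows, idx$cols])
}

#' Count nuclei in a 2D image with a debris gate
#'
#' Thresholds the nuclear channel (Otsu by default), labels connected
#' components and keeps only nuclei larger than `min_area_um2` (default
#' 7.1 um^2, excluding cellular debris). The density is reported per
#' 100 um^2 of field area.
#'
#' @param image numeric matrix (nuclear stain).
#' @param pixel_size_um pixel calibration.
#' @param min_area_um2 minimum nucleus area (default 7.1).
#' @param threshold intensity threshold; NULL uses Otsu. Blank images give
#'   a zero count.
#' @return list with `count`, `density_per_100um2`, `areas_um2`.
#' @export
count_nuclei_2d <- function(image, pixel_size_um, min_area_um2 = 7.1,
                            threshold = NULL) {
  .assert(is.matrix(image), "image must be a matrix")
  if (max(image) == min(image)) {
    return(list(count = 0L, density_per_100um2 = 0, areas_um2 = numeric(0)))
  }
  th <- threshold %||% .otsu_global(image)
  bin <- image > th
  if (!any(bin)) return(list(count = 0L, density_per_100um2 = 0,
                             areas_um2 = numeric(0)))
  lab <- .bwlabel8(bin)
  areas <- tabulate(lab[lab > 0]) * pixel_size_um^2
  keep <- areas > min_area_um2
  field_area <- prod(dim(image)) * pixel_size_um^2
  list(count = sum(keep),
       density_per_100um2 = sum(keep) / field_area * 100,
       areas_um2 = areas[keep])
}

#' Count stain-positive cells with a watershed split and area gate
#'
#' Thresholds the antibody channel, splits touching objects by a
#' distance-transform watershed, keeps regions of 6-200 um^2 that overlap a
#' nucleus in the co-registered nuclear channel, and reports the positive
#' fraction relative to the total nuclei count.
#'
#' @param stain_image,nuclei_image co-registered numeric matrices.
#' @param pixel_size_um pixel calibration.
#' @param area_range_um2 inclusive area gate (default `c(6, 200)`).
#' @param watershed_tolerance h-maxima depth of the watershed seeds, px.
#' @return list with `positive`, `total_nuclei`, `fraction`.
#' @export
count_positive_cells <- function(stain_image, nuclei_image, pixel_size_um,
                                 area_range_um2 = c(6, 200),
                                 watershed_tolerance = 2) {
  .assert(is.matrix(stain_image) && is.matrix(nuclei_image) &&
            all(dim(stain_image) == dim(nuclei_image)),
          "channels must be matrices of identical shape")
  nuc <- count_nuclei_2d(nuclei_image, pixel_size_um)
  if (max(stain_image) == min(stain_image)) {
    return(list(positive = 0L, total_nuclei = nuc$count, fraction = 0))
  }
  bin <- stain_image > .otsu_global(stain_image)
  if (!any(bin)) return(list(positive = 0L, total_nuclei = nuc$count, fraction = 0))
  dm <- EBImage::distmap(matrix(as.numeric(bin), nrow(bin), ncol(bin)))
  lab <- EBImage::watershed(dm, tolerance = watershed_tolerance)
  nuc_bin <- nuclei_image > .otsu_global(nuclei_image)
  areas <- tabulate(lab[lab > 0]) * pixel_size_um^2
  overlaps <- vapply(seq_along(areas), function(l) any(nuc_bin[lab == l]),
                     logical(1))
  pos <- sum(areas >= area_range_um2[1] & areas <= area_range_um2[2] & overlaps)
  list(positive = pos, total_nuclei = nuc$count,
       fraction = if (nuc$count > 0) pos / nuc$count else NA_real_)
}

#' Least-squares circle fit to boundary points
#'
#' Algebraic (Kasa) fit: solves the linear system
#' `x^2 + y^2 = 2*a*x + 2*b*y + c` in the least-squares sense. Used to
#' summarize embryo size as the area of the best-adjusted circle.
#'
#' @param points two-column matrix or data.frame of `(x_um, y_um)` boundary
#'   points; at least 3, not collinear.
#' @return list with `center` `(x, y)`, `radius`, `area_um2`.
#' @export
fit_embryo_circle <- function(points) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  .assert(nrow(pts) >= 3, "need at least 3 points")
  .assert(all(is.finite(pts)), "points must be finite")
  A <- cbind(2 * pts[, 1], 2 * pts[, 2], 1)
  .assert(qr(A)$rank == 3, "points are collinear; no unique circle")
  b <- pts[, 1]^2 + pts[, 2]^2
  sol <- qr.solve(A, b)
  ctr <- sol[1:2]
  r <- sqrt(sol[3] + sum(ctr^2))
  list(center = unname(ctr), radius = unname(r), area_um2 = unname(pi * r^2))
}
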