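#' 3D Gaussian blur of a voxel grid
#'
#' Isotropic-in-voxels separable Gaussian smoothing (sigma 2 voxels per axis
#' by default, the preprocessing used before nuclear segmentation) with
#' replicate boundary handling, which preserves the mean intensity.
#'
#' @param grid a [voxel_grid()].
#' @param sigma_px Gaussian sigma in voxels (scalar or per-axis length 3).
#' @return blurred [voxel_grid()].
#' @export
blur3d <- function(grid, sigma_px = 2) {
  .assert(inherits(grid, "voxel_grid"), "grid must be a voxel_grid")
  .assert(is.numeric(sigma_px) && all(sigma_px > 0), "sigma must be positive")
  voxel_grid(.gauss_blur_3d(grid$intensities, sigma_px), grid$voxel_size_um)
}

#' Segment nuclei in a blurred 3D stack
#'
#' Global Otsu threshold, 3D chamfer distance transform, h-dome extraction
#' of the distance map as deterministic watershed seeds (replacing an
#' interactive seeding step), and marker-based watershed flooding. Objects
#' below `min_voxels` are discarded.
#'
#' @param grid a [voxel_grid()], already blurred (see [blur3d()]).
#' @param threshold intensity threshold; NULL uses global Otsu.
#' @param h h-maxima depth of the seeds, in chamfer units of ~1 voxel
#'   (default 2).
#' @param min_voxels smallest object kept (default 30).
#' @return integer 3D array of labels (0 = background).
#' @export
segment_nuclei_3d <- function(grid, threshold = NULL, h = 2, min_voxels = 30) {
  .assert(inherits(grid, "voxel_grid"), "grid must be a voxel_grid")
  arr <- grid$intensities
  th <- threshold %||% .otsu_global(arr)
  mask <- arr > th
  .assert(any(mask), "empty foreground after thresholding")
  dist <- .chamfer_3d(mask)
  seeds <- .hdome_seeds_3d(dist, mask, h * 3)  # chamfer orthogonal step = 3
  if (max(seeds) == 0L) seeds <- .label_3d(mask)
  lab <- .watershed_3d(dist, seeds, mask)
  sizes <- tabulate(lab[lab > 0L])
  drop <- which(sizes < min_voxels)
  if (length(drop)) lab[lab %in% drop] <- 0L
  keep <- sort(unique(lab[lab > 0L]))
  if (length(keep)) {
    relab <- integer(max(keep)); relab[keep] <- seq_along(keep)
    pos <- lab > 0L
    lab[pos] <- relab[lab[pos]]
  }
  lab
}

#' 3D shape descriptors of segmented nuclei
#'
#' For each label: volume (voxel count times voxel volume), ellipsoid
#' semi-axes from the eigenvalues of the voxel-coordinate covariance matrix
#' in physical units (`s_i = sqrt(5 * lambda_i)`, the solid-ellipsoid moment
#' identity, with axes sorted `a >= b >= c`), flatness `F = b / c` (the
#' ratio between the second and third ellipsoid axes; 1 for a sphere,
#' larger for flatter nuclei), surface area from the coarea integral of the
#' smoothed indicator function, and sphericity
#' `Psi = 36 * pi * V^2 / S^3` (1 for a sphere).
#'
#' Because segmentation runs on a blurred copy of the stack, the labeled
#' regions carry a smoothing-dependent rind (thicker along z, where the
#' physical blur is wider); passing the raw `intensities` restricts each
#' region to voxels above `refine_threshold` (Otsu of the raw stack by
#' default), which removes that rind before the moments are computed.
#'
#' @param labels integer 3D label array from [segment_nuclei_3d()], or a
#'   logical array for a single region.
#' @param voxel_size_um voxel spacing `(dx, dy, dz)` in um.
#' @param min_voxels regions smaller than this are skipped (default 30).
#' @param intensities optional raw (unblurred) intensity array of the same
#'   shape, used to refine region boundaries.
#' @param refine_threshold threshold applied to `intensities`; NULL uses
#'   global Otsu.
#' @return data.frame with one row per label: `label`, `volume_voxels`,
#'   `volume_um3`, `surface_area_um2`, `a_um`, `b_um`, `c_um`, `flatness`,
#'   `sphericity`.
#' @export
nucleus_descriptors <- function(labels, voxel_size_um = c(0.132, 0.132, 0.24),
                                min_voxels = 30, intensities = NULL,
                                refine_threshold = NULL) {
  .assert(is.array(labels) && length(dim(labels)) == 3, "labels must be 3D")
  .assert(.is_num(voxel_size_um, 3L) && all(voxel_size_um > 0),
          "voxel_size_um must be positive")
  lab <- if (is.logical(labels)) array(as.integer(labels), dim(labels)) else labels
  if (!is.null(intensities)) {
    .assert(all(dim(intensities) == dim(lab)),
            "intensities must match the label array shape")
    th <- refine_threshold %||% .otsu_global(intensities)
    lab[intensities <= th] <- 0L
  }
  ids <- sort(unique(lab[lab > 0L]))
  vox_vol <- prod(voxel_size_um)
  rows <- lapply(ids, function(id) {
    idx <- which(lab == id, arr.ind = TRUE)
    n <- nrow(idx)
    if (n < min_voxels) return(NULL)
    pts <- sweep(idx, 2, voxel_size_um, "*")
    cv <- stats::cov(pts) * (n - 1) / n  # population covariance
    ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    .assert(ev[3] > 0, "degenerate region (coplanar voxels)")
    s <- sqrt(5 * ev)
    S <- .surface_area_coarea(lab == id, voxel_size_um)
    V <- n * vox_vol
    data.frame(label = id, volume_voxels = n, volume_um3 = V,
               surface_area_um2 = S, a_um = s[1], b_um = s[2], c_um = s[3],
               flatness = s[2] / s[3], sphericity = 36 * pi * V^2 / S^3)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(label = integer(0), volume_voxels = integer(0),
                      volume_um3 = numeric(0), surface_area_um2 = numeric(0),
                      a_um = numeric(0), b_um = numeric(0), c_um = numeric(0),
                      flatness = numeric(0), sphericity = numeric(0))
  }
  rownames(out) <- NULL
  out
}

# Surface area of a binary 3D region via the coarea formula: smooth the
# indicator with a small Gaussian (in voxel units) and integrate the
# gradient magnitude over physical space.
.surface_area_coarea <- function(mask, voxel_size_um, sigma_vox = 1.5) {
  d <- dim(mask)
  # pad so the gradient support does not touch the array faces
  pad <- ceiling(4 * sigma_vox) + 1L
  arr <- array(0, d + 2L * pad)
  arr[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <-
    as.numeric(mask)
  sm <- .gauss_blur_3d(arr, sigma_vox)
  dd <- dim(sm)
  cgrad <- function(a, ax, sp) {
    n <- dim(a)[ax]
    ip <- pmin(seq_len(n) + 1L, n); im <- pmax(seq_len(n) - 1L, 1L)
    (switch(ax, a[ip, , , drop = FALSE], a[, ip, , drop = FALSE], a[, , ip, drop = FALSE]) -
       switch(ax, a[im, , , drop = FALSE], a[, im, , drop = FALSE], a[, , im, drop = FALSE])) /
      ((ip - im) * sp)
  }
  gx <- cgrad(sm, 1, voxel_size_um[1])
  gy <- cgrad(sm, 2, voxel_size_um[2])
  gz <- cgrad(sm, 3, voxel_size_um[3])
  sum(sqrt(gx^2 + gy^2 + gz^2)) * prod(voxel_size_um)
}

#' Gate nuclei by volume
#'
#' Keeps nuclei with `min_vol <= volume <= max_vol` (both bounds inclusive;
#' the defaults 100-350 are in voxels, the unit the segmentation plugin
#' reports). Idempotent.
#'
#' @param shapes data.frame from [nucleus_descriptors()].
#' @param min_vol,max_vol volume gate bounds.
#' @param unit `"voxels"` (gates `volume_voxels`) or `"um3"` (gates
#'   `volume_um3`).
#' @return filtered data.frame.
#' @export
filter_nuclei_by_volume <- function(shapes, min_vol = 100, max_vol = 350,
                                    unit = c("voxels", "um3")) {
  unit <- match.arg(unit)
  .assert(min_vol <= max_vol, "min_vol must be <= max_vol")
  v <- if (unit == "voxels") shapes$volume_voxels else shapes$volume_um3
  shapes[v >= min_vol & v <= max_vol, , drop = FALSE]
}
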