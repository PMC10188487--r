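#' Generate a star-shaped cell mask with a known number of protrusions
#'
#' Builds a binary mask of a disk-shaped cell body with `n_spikes` thin
#' rectangular protrusions radiating outwards at random orientation, the
#' standard fixture for the opening-based filopodia counter: the spikes must
#' be narrower than the structuring disk (diameter 2.2 um) so that a
#' morphological opening removes them.
#'
#' @param base_radius_um radius of the cell body.
#' @param n_spikes number of protrusions (0 gives a pure disk).
#' @param spike_len_um length of each protrusion beyond the body edge.
#' @param spike_width_um width of each protrusion; must be < 2.2 um.
#' @param pixel_size_um raster calibration.
#' @param seed integer seed (controls the global rotation of the spikes).
#' @return A [cell_mask()] with attributes `n_spikes` (ground truth),
#'   `spike_area_um2` (nominal area of one protrusion) and
#'   `countable_above_gate` (`n_spikes` when the spike area exceeds the
#'   0.077 um^2 debris gate, else 0).
#' @export
make_star_cell <- function(base_radius_um = 8, n_spikes = 5,
                           spike_len_um = 2.5, spike_width_um = 0.4,
                           pixel_size_um = 0.1, seed = NULL) {
  .assert(.is_num(base_radius_um) && base_radius_um > 0, "base_radius_um must be > 0")
  .assert(.is_num(n_spikes) && n_spikes >= 0, "n_spikes must be >= 0")
  .assert(.is_num(spike_width_um) && spike_width_um > 0 &&
            spike_width_um < 2 * 1.1,
          "spike_width_um must be in (0, 2.2): wider spikes survive the opening")
  .assert(.is_num(spike_len_um) && spike_len_um > 0, "spike_len_um must be > 0")
  .assert(.is_num(pixel_size_um) && pixel_size_um > 0, "pixel_size_um must be > 0")
  n_spikes <- as.integer(n_spikes)
  if (n_spikes > 0) {
    # reject geometries in which neighboring spikes would merge at the body edge
    arc <- 2 * pi * base_radius_um / n_spikes
    .assert(arc > 2 * spike_width_um,
            "invalid fixture: spikes would overlap at the cell boundary")
  }

  .with_seed(seed, {
    rot <- stats::runif(1, 0, 2 * pi)
    half_px <- ceiling((base_radius_um + spike_len_um + 1) / pixel_size_um)
    n <- 2L * half_px + 1L
    ctr <- (half_px + 1L)
    xs <- (.px_to_um(seq_len(n), pixel_size_um)) - .px_to_um(ctr, pixel_size_um)
    X <- matrix(xs, n, n, byrow = TRUE)   # x along columns
    Y <- matrix(xs, n, n)                 # y along rows
    mask <- sqrt(X^2 + Y^2) <= base_radius_um
    if (n_spikes > 0) {
      angles <- rot + 2 * pi * (seq_len(n_spikes) - 1) / n_spikes
      # capsule-shaped spikes (semicircular tip of radius width/2): square
      # tips would leave corner slivers under an opening with a smaller
      # disk, which real rounded protrusions do not
      tip <- base_radius_um + spike_len_um - spike_width_um / 2
      for (a in angles) {
        u <- c(cos(a), sin(a))
        proj <- X * u[1] + Y * u[2]
        perp <- -X * u[2] + Y * u[1]
        t <- pmin(pmax(proj, 0), tip)
        dist2 <- (proj - t)^2 + perp^2
        mask <- mask | (dist2 <= (spike_width_um / 2)^2)
      }
    }
    out <- cell_mask(mask, pixel_size_um)
    attr(out, "n_spikes") <- n_spikes
    attr(out, "spike_area_um2") <- spike_len_um * spike_width_um
    # spikes below the debris gate exist in the mask but do not count
    attr(out, "countable_above_gate") <-
      if (spike_len_um * spike_width_um > 0.077) n_spikes else 0L
    out
  })
}

#' Render one solid ellipsoid into an anisotropic voxel grid
#'
#' Voxelizes a (possibly rotated) solid ellipsoid at the confocal calibration
#' used for nuclear imaging (0.132 x 0.132 um in plane, 0.24 um z step),
#' optionally adding Gaussian noise, and returns the grid with its analytic
#' ground truth (semi-axes, volume, flatness).
#'
#' @param semi_axes_um decreasing semi-axes `(a, b, c)` in um.
#' @param orientation length-3 numeric: rotation angles (radians) applied
#'   about the x, y and z axes in that order.
#' @param voxel_size_um `(dx, dy, dz)` voxel spacing in um.
#' @param pad_um clearance between the ellipsoid and the grid faces.
#' @param foreground,background intensities inside/outside the ellipsoid.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param seed integer seed for the noise.
#' @return list with `grid` (a [voxel_grid()]) and `truth`
#'   (`semi_axes_um`, `volume_um3`, `flatness`).
#' @export
make_ellipsoid_stack <- function(semi_axes_um, orientation = c(0, 0, 0),
                                 voxel_size_um = c(0.132, 0.132, 0.24),
                                 pad_um = 1.5, foreground = 1, background = 0,
                                 noise_sd = 0, seed = NULL) {
  .assert(.is_num(semi_axes_um, 3L) && all(diff(semi_axes_um) <= 0) &&
            all(semi_axes_um > 0), "semi_axes_um must be decreasing and positive")
  .assert(.is_num(orientation, 3L), "orientation must be 3 rotation angles")
  .assert(.is_num(voxel_size_um, 3L) && all(voxel_size_um > 0),
          "voxel_size_um must be positive")
  .assert(all(semi_axes_um > 2 * voxel_size_um),
          "each semi-axis must span more than 2 voxels")

  rx <- orientation[1]; ry <- orientation[2]; rz <- orientation[3]
  Rx <- rbind(c(1, 0, 0), c(0, cos(rx), -sin(rx)), c(0, sin(rx), cos(rx)))
  Ry <- rbind(c(cos(ry), 0, sin(ry)), c(0, 1, 0), c(-sin(ry), 0, cos(ry)))
  Rz <- rbind(c(cos(rz), -sin(rz), 0), c(sin(rz), cos(rz), 0), c(0, 0, 1))
  R <- Rz %*% Ry %*% Rx

  half <- max(semi_axes_um) + pad_um
  dims <- ceiling(2 * half / voxel_size_um)
  dims <- as.integer(dims + (dims %% 2 == 0))  # odd, so a voxel sits at center
  ctr <- (dims + 1) / 2
  # voxel centers in physical um, relative to the grid center
  cx <- (seq_len(dims[1]) - ctr[1]) * voxel_size_um[1]
  cy <- (seq_len(dims[2]) - ctr[2]) * voxel_size_um[2]
  cz <- (seq_len(dims[3]) - ctr[3]) * voxel_size_um[3]
  .assert(max(semi_axes_um) <= half, "ellipsoid exceeds the grid")

  # body-frame coordinates: p_body = R^T p_world
  arr <- array(background, dims)
  Rt <- t(R)
  for (z in seq_len(dims[3])) {
    bx <- Rt[1, 1] * outer(cx, rep(1, dims[2])) + Rt[1, 2] * outer(rep(1, dims[1]), cy) + Rt[1, 3] * cz[z]
    by <- Rt[2, 1] * outer(cx, rep(1, dims[2])) + Rt[2, 2] * outer(rep(1, dims[1]), cy) + Rt[2, 3] * cz[z]
    bz <- Rt[3, 1] * outer(cx, rep(1, dims[2])) + Rt[3, 2] * outer(rep(1, dims[1]), cy) + Rt[3, 3] * cz[z]
    inside <- (bx / semi_axes_um[1])^2 + (by / semi_axes_um[2])^2 +
      (bz / semi_axes_um[3])^2 <= 1
    sl <- arr[, , z]
    sl[inside] <- foreground
    arr[, , z] <- sl
  }
  arr <- .with_seed(seed, {
    if (noise_sd > 0) arr + array(stats::rnorm(length(arr), 0, noise_sd), dims) else arr
  })
  list(
    grid = voxel_grid(arr, voxel_size_um),
    truth = list(
      semi_axes_um = semi_axes_um,
      volume_um3 = 4 / 3 * pi * prod(semi_axes_um),
      flatness = semi_axes_um[2] / semi_axes_um[3]
    )
  )
}

# Shortest distance between two 2D segments (each a length-4 vector x0,y0,x1,y1).
.segment_distance <- function(s1, s2) {
  pt_seg <- function(p, a, b) {
    ab <- b - a
    t <- sum((p - a) * ab) / max(sum(ab^2), .Machine$double.eps)
    t <- min(max(t, 0), 1)
    sqrt(sum((a + t * ab - p)^2))
  }
  a1 <- s1[1:2]; b1 <- s1[3:4]; a2 <- s2[1:2]; b2 <- s2[3:4]
  # segments intersect?
  d <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  o1 <- d(a1, b1, a2); o2 <- d(a1, b1, b2); o3 <- d(a2, b2, a1); o4 <- d(a2, b2, b1)
  if (((o1 > 0) != (o2 > 0)) && ((o3 > 0) != (o4 > 0))) return(0)
  min(pt_seg(a2, a1, b1), pt_seg(b2, a1, b1), pt_seg(a1, a2, b2), pt_seg(b1, a2, b2))
}

#' Render a focal-adhesion-like pattern of bright line segments
#'
#' Draws anti-aliased bars of the given width on a dark background and
#' records the exact summed Euclidean length of the generating segments, the
#' ground truth for the skeleton-length estimator. Overlapping segments are
#' rejected because their skeleton would no longer decompose additively.
#'
#' @param segments numeric matrix with columns `x0, y0, x1, y1` (um), one
#'   segment per row; may have zero rows.
#' @param width_px bar width in pixels (default 2, ~0.6 um at the
#'   default calibration, the scale of mature adhesion stripes).
#' @param shape_px frame `(rows, cols)`.
#' @param pixel_size_um raster calibration.
#' @param amplitude,background_level intensities.
#' @return list with `image` (matrix), `mask` (binary matrix) and
#'   `truth_length_um`.
#' @export
make_fa_pattern <- function(segments, width_px = 2, shape_px = c(512, 512),
                            pixel_size_um = 0.3, amplitude = 1,
                            background_level = 0) {
  segments <- if (is.null(segments) || NROW(segments) == 0) {
    matrix(numeric(0), 0, 4)
  } else {
    m <- as.matrix(segments); .assert(ncol(m) == 4, "segments need x0,y0,x1,y1"); m
  }
  shape_px <- as.integer(shape_px)
  width_um <- width_px * pixel_size_um
  ext <- shape_px * pixel_size_um
  if (nrow(segments)) {
    .assert(all(segments[, c(1, 3)] > width_um &
                  segments[, c(1, 3)] < ext[2] - width_um) &&
              all(segments[, c(2, 4)] > width_um &
                    segments[, c(2, 4)] < ext[1] - width_um),
            "segments must lie inside the frame")
    if (nrow(segments) > 1) {
      for (i in seq_len(nrow(segments) - 1)) for (j in (i + 1):nrow(segments)) {
        .assert(.segment_distance(segments[i, ], segments[j, ]) > 2 * width_um,
                "segments overlap or run too close; rejected fixture")
      }
    }
  }
  img <- matrix(background_level, shape_px[1], shape_px[2])
  xs <- .px_to_um(seq_len(shape_px[2]), pixel_size_um)
  ys <- .px_to_um(seq_len(shape_px[1]), pixel_size_um)
  X <- matrix(xs, shape_px[1], shape_px[2], byrow = TRUE)
  Y <- matrix(ys, shape_px[1], shape_px[2])
  for (i in seq_len(nrow(segments))) {
    a <- segments[i, 1:2]; b <- segments[i, 3:4]
    ab <- b - a; len2 <- max(sum(ab^2), .Machine$double.eps)
    t <- ((X - a[1]) * ab[1] + (Y - a[2]) * ab[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    dx <- X - (a[1] + t * ab[1]); dy <- Y - (a[2] + t * ab[2])
    dist <- sqrt(dx^2 + dy^2)
    # soft 1-px anti-aliased edge
    prof <- pmin(pmax((width_um / 2 + pixel_size_um / 2 - dist) / pixel_size_um, 0), 1)
    img <- pmax(img, background_level + amplitude * prof)
  }
  truth <- if (nrow(segments)) {
    sum(sqrt((segments[, 3] - segments[, 1])^2 + (segments[, 4] - segments[, 2])^2))
  } else 0
  list(image = img, mask = img > background_level + amplitude / 2,
       truth_length_um = truth)
}
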