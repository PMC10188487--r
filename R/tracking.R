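#' Default detection and tracking parameters
#'
#' Bundles the calibrations and thresholds of the time-lapse tracking stage:
#' LoG blob diameter 7.9 px with quality threshold 0.23, pixel size
#' 0.189 um, 4-minute frame interval, and the 15-frame / midline exclusion
#' filters applied to tracks.
#'
#' @param blob_diameter_px expected nucleus diameter in pixels.
#' @param quality_threshold cutoff on the frame-normalized positive LoG
#'   response, in (0, 1).
#' @param pixel_size_um pixel size of the time-lapse frames.
#' @param frame_interval_min time between frames, minutes.
#' @param max_link_dist_um maximum frame-to-frame link distance.
#' @param min_frames minimum track length retained by [filter_tracks()].
#' @param midline_x_um x position of the embryo midline (NA disables
#'   midline-based classification/filtering).
#' @param midline_halfwidth_um half-width of the midline band in um.
#' @return named list of parameters.
#' @export
detection_params <- function(blob_diameter_px = 7.9, quality_threshold = 0.23,
                             pixel_size_um = 0.189, frame_interval_min = 4,
                             max_link_dist_um = 15, min_frames = 15,
                             midline_x_um = NA_real_,
                             midline_halfwidth_um = 50) {
  p <- list(blob_diameter_px = blob_diameter_px,
            quality_threshold = quality_threshold,
            pixel_size_um = pixel_size_um,
            frame_interval_min = frame_interval_min,
            max_link_dist_um = max_link_dist_um,
            min_frames = min_frames,
            midline_x_um = midline_x_um,
            midline_halfwidth_um = midline_halfwidth_um)
  for (nm in setdiff(names(p), "midline_x_um"))
    .assert(.is_num(p[[nm]]) && p[[nm]] > 0, paste(nm, "must be positive"))
  p
}

#' Preprocess a pair of confocal sections into one tracking frame
#'
#' Maximum-projects two co-registered z sections, applies an unsharp mask
#' (Gaussian sigma 15 px, mask weight 0.60, i.e.
#' `out = (in - w * blur) / (1 - w)`), clips at zero and finishes with a
#' median filter of radius 2 px.
#'
#' @param section_a,section_b numeric matrices of identical shape; pass
#'   `section_b = NULL` to process a single section.
#' @param unsharp_sigma_px,unsharp_weight unsharp-mask parameters.
#' @param median_radius_px median filter radius in pixels.
#' @return filtered matrix, same shape, non-negative.
#' @export
preprocess_frame <- function(section_a, section_b = NULL,
                             unsharp_sigma_px = 15, unsharp_weight = 0.60,
                             median_radius_px = 2) {
  .assert(is.matrix(section_a), "section_a must be a matrix")
  img <- if (is.null(section_b)) {
    section_a
  } else {
    .assert(is.matrix(section_b) && all(dim(section_a) == dim(section_b)),
            "sections must have identical shapes")
    pmax(section_a, section_b)
  }
  blur <- .gauss_blur_3d(array(img, c(dim(img), 1L)),
                         c(unsharp_sigma_px, unsharp_sigma_px, 0))[, , 1L]
  sharp <- pmax((img - unsharp_weight * blur) / (1 - unsharp_weight), 0)
  hi <- max(sharp)
  if (hi == 0) return(sharp)
  # EBImage's median filter operates on [0, 1] data
  out <- as.matrix(EBImage::medianFilter(sharp / hi, size = median_radius_px)) * hi
  matrix(out, nrow(img), ncol(img))
}

# Scale-normalized LoG response (bright blobs -> positive peaks).
.log_response <- function(image, sigma_px) {
  half <- ceiling(4 * sigma_px)
  ax <- -half:half
  g <- exp(-ax^2 / (2 * sigma_px^2))
  g <- g / sum(g)
  G <- outer(g, g)
  X2 <- outer(ax^2, ax^2, "+")
  log_k <- G * (X2 - 2 * sigma_px^2) / sigma_px^4
  log_k <- log_k - mean(log_k)               # zero response on constants
  resp <- as.matrix(EBImage::filter2(image, -sigma_px^2 * log_k,
                                     boundary = "replicate"))
  matrix(resp, nrow(image), ncol(image))
}

#' Detect nuclei as Laplacian-of-Gaussian blobs
#'
#' Computes the scale-normalized LoG response at
#' `sigma = blob_diameter_px / (2 * sqrt(2))`, normalizes the positive
#' (blob-like) response to `[0, 1]` per frame as the quality score (a
#' structureless region scores 0, the strongest blob 1), keeps 3x3 local
#' maxima with quality above the threshold, and refines each maximum by an
#' independent quadratic fit along x and y before converting to physical
#' coordinates.
#'
#' @param image 2D numeric matrix (one frame, already preprocessed).
#' @param params parameter list from [detection_params()].
#' @return data.frame with `x_um`, `y_um`, `quality`; zero rows on a blank
#'   frame.
#' @export
detect_spots <- function(image, params = detection_params()) {
  .assert(is.matrix(image), "image must be a matrix")
  sigma <- params$blob_diameter_px / (2 * sqrt(2))
  resp <- .log_response(image, sigma)
  hi <- max(resp)
  if (hi <= .Machine$double.eps) {
    return(data.frame(x_um = numeric(0), y_um = numeric(0), quality = numeric(0)))
  }
  # quality: positive (blob-like) response normalized to [0, 1] per frame,
  # so the baseline of a structureless region scores 0
  quality <- pmax(resp, 0) / hi
  nr <- nrow(resp); nc <- ncol(resp)
  is_max <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    sh <- matrix(-Inf, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    sh[rs, cs] <- resp[rs - dr, cs - dc]
    is_max <- is_max & (resp >= sh)
  }
  sel <- which(is_max & quality > params$quality_threshold &
                 row(resp) > 1 & row(resp) < nr &
                 col(resp) > 1 & col(resp) < nc)
  if (!length(sel)) {
    return(data.frame(x_um = numeric(0), y_um = numeric(0), quality = numeric(0)))
  }
  rr <- row(resp)[sel]; cc <- col(resp)[sel]
  sub <- function(r, c) resp[cbind(r, c)]
  denom_r <- sub(rr - 1, cc) - 2 * sub(rr, cc) + sub(rr + 1, cc)
  denom_c <- sub(rr, cc - 1) - 2 * sub(rr, cc) + sub(rr, cc + 1)
  dr <- ifelse(denom_r < 0, 0.5 * (sub(rr - 1, cc) - sub(rr + 1, cc)) / denom_r, 0)
  dc <- ifelse(denom_c < 0, 0.5 * (sub(rr, cc - 1) - sub(rr, cc + 1)) / denom_c, 0)
  dr <- pmin(pmax(dr, -0.5), 0.5); dc <- pmin(pmax(dc, -0.5), 0.5)
  data.frame(
    x_um = .px_to_um(cc + dc, params$pixel_size_um),
    y_um = .px_to_um(rr + dr, params$pixel_size_um),
    quality = quality[sel]
  )
}

#' Detect nuclei on every frame of a stack
#'
#' @param stack rows x cols x frames array.
#' @param params parameter list from [detection_params()].
#' @return data.frame with `frame` (0-based), `x_um`, `y_um`, `quality`.
#' @export
detect_stack <- function(stack, params = detection_params()) {
  .assert(is.array(stack) && length(dim(stack)) == 3, "stack must be 3D")
  out <- lapply(seq_len(dim(stack)[3]), function(f) {
    d <- detect_spots(stack[, , f], params)
    if (nrow(d)) d$frame <- f - 1L
    d
  })
  out <- do.call(rbind, out[vapply(out, nrow, 1L) > 0])
  if (is.null(out)) {
    out <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      quality = numeric(0), frame = integer(0))
  }
  out[, c("frame", "x_um", "y_um", "quality")]
}

#' Link per-frame detections into trajectories
#'
#' Frame-to-frame greedy mutual-nearest-neighbor assignment: a detection in
#' frame t is linked to one in frame t+1 only if each is the other's nearest
#' neighbor and their distance does not exceed `max_link_dist_um`. Unmatched
#' detections start new tracks; there is no gap closing, so a cell missing
#' for one frame yields two tracks.
#'
#' @param detections data.frame with `frame`, `x_um`, `y_um` (any other
#'   columns are carried along).
#' @param params parameter list from [detection_params()].
#' @return trajectory data.frame with `track_id`, `frame`, `t_min`, `x_um`,
#'   `y_um`, ordered by track then frame.
#' @export
link_tracks <- function(detections, params = detection_params()) {
  .assert(all(c("frame", "x_um", "y_um") %in% names(detections)),
          "detections need frame/x_um/y_um")
  .assert(params$max_link_dist_um > 0, "max_link_dist_um must be positive")
  det <- detections[order(detections$frame), , drop = FALSE]
  if (!nrow(det)) {
    return(data.frame(track_id = integer(0), frame = integer(0),
                      t_min = numeric(0), x_um = numeric(0), y_um = numeric(0)))
  }
  frames <- sort(unique(det$frame))
  by_frame <- split(seq_len(nrow(det)), det$frame)
  track_of <- integer(nrow(det))
  next_id <- 0L
  prev_idx <- by_frame[[1]]
  track_of[prev_idx] <- next_id + seq_along(prev_idx)
  next_id <- next_id + length(prev_idx)
  for (fi in seq_along(frames)[-1]) {
    cur_idx <- by_frame[[fi]]
    contiguous <- frames[fi] == frames[fi - 1] + 1
    if (length(prev_idx) && length(cur_idx) && contiguous) {
      dmat <- sqrt(outer(det$x_um[prev_idx], det$x_um[cur_idx], "-")^2 +
                     outer(det$y_um[prev_idx], det$y_um[cur_idx], "-")^2)
      nn_fwd <- apply(dmat, 1, which.min)   # for each prev, nearest cur
      nn_bwd <- apply(dmat, 2, which.min)   # for each cur, nearest prev
      for (i in seq_along(prev_idx)) {
        j <- nn_fwd[i]
        if (nn_bwd[j] == i && dmat[i, j] <= params$max_link_dist_um) {
          track_of[cur_idx[j]] <- track_of[prev_idx[i]]
        }
      }
    }
    new <- cur_idx[track_of[cur_idx] == 0L]
    track_of[new] <- next_id + seq_along(new)
    next_id <- next_id + length(new)
    prev_idx <- cur_idx
  }
  out <- data.frame(track_id = track_of, frame = det$frame,
                    t_min = det$frame * params$frame_interval_min,
                    x_um = det$x_um, y_um = det$y_um)
  out[order(out$track_id, out$frame), , drop = FALSE]
}

#' Per-track migration metrics
#'
#' For every trajectory computes the four migration statistics: displacement
#' `D` (start-to-end distance), path length `L` (summed step lengths),
#' persistence `P = D / L` (straightness; 0 for a degenerate track with
#' `L = 0`), and mean velocity `v` (mean of per-step speed). Also attaches
#' the displacement color bin and, when a midline is configured, the
#' lateral/midline position class.
#'
#' @param tracks trajectory data.frame (`track_id`, `frame`, `t_min`,
#'   `x_um`, `y_um`).
#' @param params parameter list from [detection_params()]; used for the
#'   midline definition only.
#' @return data.frame with one row per track: `track_id`, `n_frames`,
#'   `displacement_um`, `path_length_um`, `persistence`,
#'   `mean_velocity_um_min`, `displacement_bin`, `position_class`,
#'   `x_first_um`, `y_first_um`.
#' @export
track_metrics <- function(tracks, params = detection_params()) {
  .assert(all(c("track_id", "frame", "t_min", "x_um", "y_um") %in% names(tracks)),
          "tracks must have track_id/frame/t_min/x_um/y_um")
  .assert(all(is.finite(tracks$x_um)) && all(is.finite(tracks$y_um)),
          "coordinates must be finite")
  sp <- split(tracks[, c("frame", "t_min", "x_um", "y_um")], tracks$track_id)
  .assert(all(vapply(sp, nrow, 1L) >= 2), "every track needs >= 2 points")
  rows <- lapply(names(sp), function(id) {
    tr <- sp[[id]][order(sp[[id]]$frame), ]
    .assert(all(diff(tr$frame) > 0), "frame indices must be strictly increasing")
    dx <- diff(tr$x_um); dy <- diff(tr$y_um); dt <- diff(tr$t_min)
    step <- sqrt(dx^2 + dy^2)
    L <- sum(step)
    D <- sqrt((tr$x_um[nrow(tr)] - tr$x_um[1])^2 +
                (tr$y_um[nrow(tr)] - tr$y_um[1])^2)
    P <- if (L > 0) D / L else 0
    v <- mean(step / dt)
    pos <- if (is.na(params$midline_x_um)) NA_character_ else {
      if (mean(abs(tr$x_um - params$midline_x_um)) <= params$midline_halfwidth_um)
        "midline" else "lateral"
    }
    data.frame(track_id = id, n_frames = nrow(tr), displacement_um = D,
               path_length_um = L, persistence = P, mean_velocity_um_min = v,
               displacement_bin = classify_displacement_bin(D),
               position_class = pos,
               x_first_um = tr$x_um[1], y_first_um = tr$y_um[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify a displacement value into track-overlay color bins
#'
#' Bins follow the track-overlay color code (Blue 20-50, Green 50-80, Yellow
#' 80-130, Red above 130, in um): bins are closed below and open above,
#' except that 130 belongs to yellow because red is strictly "> 130";
#' displacements under 20 are labeled `sub`.
#'
#' @param d_um displacement(s) in um, non-negative.
#' @return character vector in `{sub, blue, green, yellow, red}`.
#' @export
classify_displacement_bin <- function(d_um) {
  .assert(is.numeric(d_um) && all(is.finite(d_um)) && all(d_um >= 0),
          "displacement must be finite and >= 0")
  ifelse(d_um < 20, "sub",
    ifelse(d_um < 50, "blue",
      ifelse(d_um < 80, "green",
        ifelse(d_um <= 130, "yellow", "red"))))
}

#' Apply the track exclusion rules
#'
#' Drops tracks observed in fewer than `min_frames` frames and tracks whose
#' first position lies within the midline band (start within
#' `midline_halfwidth_um` of `midline_x_um`). Idempotent. With
#' `midline_x_um = NA` only the frame-count rule applies.
#'
#' @param metrics data.frame from [track_metrics()].
#' @param params parameter list from [detection_params()].
#' @return filtered metrics data.frame.
#' @export
filter_tracks <- function(metrics, params = detection_params()) {
  keep <- metrics$n_frames >= params$min_frames
  if (!is.na(params$midline_x_um)) {
    keep <- keep & (abs(metrics$x_first_um - params$midline_x_um) >
                      params$midline_halfwidth_um)
  }
  metrics[keep, , drop = FALSE]
}

#' Compare a migration metric between two groups of embryos
#'
#' Statistics are computed on embryo-level means, not pooled cells: the
#' input vectors hold one mean per embryo. An F test for equal variances
#' gates the choice between the pooled and the Welch two-sided t test (see
#' [t_test_means()]).
#'
#' @param means_a,means_b numeric vectors of per-embryo metric means
#'   (>= 2 each).
#' @return a `two_sample_result` from [t_test_means()], which carries the
#'   variance test under `$f_test`.
#' @export
compare_groups <- function(means_a, means_b) {
  t_test_means(means_a, means_b)
}
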