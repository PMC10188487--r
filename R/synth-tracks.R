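#' Simulate persistent random-walk cell trajectories
#'
#' Generates correlated random walks emulating nuclei trajectories of cells
#' converging to the embryo midline during gastrulation. Each step keeps the
#' previous heading rotated by a zero-mean Gaussian angle whose standard
#' deviation shrinks linearly with the persistence parameter:
#' `sigma(p) = pi * (1 - p)`. A constant drift can be superimposed and tracks
#' are reflected at the arena walls so the track-length distribution is not
#' truncated by the field of view.
#'
#' @param n_tracks number of cells to simulate.
#' @param n_steps number of steps per track (each track has `n_steps + 1`
#'   points).
#' @param dt_min frame interval in minutes (default 4, the time-lapse
#'   acquisition interval).
#' @param speed_um_min cell speed in micrometers per minute.
#' @param persistence_p directional correlation in `[0, 1]`; 0 is an
#'   uncorrelated random walk, 1 a perfectly straight path.
#' @param drift length-2 numeric, constant drift velocity in um/min.
#' @param arena length-2 numeric `(width_um, height_um)` of the field.
#' @param seed integer seed; identical seeds give identical tracks.
#' @return A `data.frame` with columns `track_id`, `frame`, `t_min`, `x_um`,
#'   `y_um`, ordered by track then frame.
#' @examples
#' tr <- simulate_persistent_tracks(5, 20, speed_um_min = 1,
#'                                  persistence_p = 0.9, seed = 1)
#' head(tr)
#' @export
simulate_persistent_tracks <- function(n_tracks, n_steps, dt_min = 4,
                                       speed_um_min = 1, persistence_p = 0.8,
                                       drift = c(0, 0),
                                       arena = c(400, 400), seed = NULL) {
  .assert(.is_num(n_tracks) && n_tracks >= 1, "n_tracks must be a positive count")
  .assert(.is_num(n_steps) && n_steps >= 1, "n_steps must be >= 1")
  .assert(.is_num(dt_min) && dt_min > 0, "dt_min must be positive")
  .assert(.is_num(speed_um_min) && speed_um_min >= 0, "speed must be >= 0")
  .assert(.is_num(persistence_p) && persistence_p >= 0 && persistence_p <= 1,
          "persistence_p must lie in [0, 1]")
  .assert(.is_num(drift, 2L), "drift must be a finite 2-vector")
  .assert(.is_num(arena, 2L) && all(arena > 0), "arena must be positive (w, h)")
  n_tracks <- as.integer(n_tracks); n_steps <- as.integer(n_steps)

  .with_seed(seed, {
    sigma <- pi * (1 - persistence_p)
    step_len <- speed_um_min * dt_min
    x <- matrix(0, n_tracks, n_steps + 1L)
    y <- matrix(0, n_tracks, n_steps + 1L)
    x[, 1L] <- stats::runif(n_tracks, 0, arena[1])
    y[, 1L] <- stats::runif(n_tracks, 0, arena[2])
    theta <- stats::runif(n_tracks, -pi, pi)
    for (s in seq_len(n_steps)) {
      if (sigma > 0) theta <- theta + stats::rnorm(n_tracks, 0, sigma)
      nx <- x[, s] + step_len * cos(theta) + drift[1] * dt_min
      ny <- y[, s] + step_len * sin(theta) + drift[2] * dt_min
      # reflect at the walls, flipping the heading component accordingly
      ref_x <- nx < 0 | nx > arena[1]
      ref_y <- ny < 0 | ny > arena[2]
      nx <- ifelse(nx < 0, -nx, nx)
      nx <- ifelse(nx > arena[1], 2 * arena[1] - nx, nx)
      ny <- ifelse(ny < 0, -ny, ny)
      ny <- ifelse(ny > arena[2], 2 * arena[2] - ny, ny)
      theta <- ifelse(ref_x, pi - theta, theta)
      theta <- ifelse(ref_y, -theta, theta)
      x[, s + 1L] <- pmin(pmax(nx, 0), arena[1])
      y[, s + 1L] <- pmin(pmax(ny, 0), arena[2])
    }
    data.frame(
      track_id = rep(seq_len(n_tracks), each = n_steps + 1L),
      frame = rep(0:n_steps, times = n_tracks),
      t_min = rep(0:n_steps, times = n_tracks) * dt_min,
      x_um = as.vector(t(x)),
      y_um = as.vector(t(y))
    )
  })
}

#' Render a trajectory table as a synthetic time-lapse stack
#'
#' Draws every cell as an isotropic Gaussian spot on each frame, adds i.i.d.
#' Gaussian read-out noise, and returns the stack together with the
#' ground-truth centroid table used to score detection and linking.
#'
#' @param tracks trajectory `data.frame` as returned by
#'   [simulate_persistent_tracks()] (um coordinates).
#' @param shape_px `(rows, cols)` of each frame.
#' @param pixel_size_um pixel size (default 0.189 um, the time-lapse
#'   calibration).
#' @param blob_sigma_px Gaussian spot sigma in pixels.
#' @param amplitude peak intensity of each spot above background.
#' @param background_level constant background intensity.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param seed integer seed for the noise.
#' @return list with `stack` (rows x cols x frames array) and `truth`
#'   (the input table restricted to in-field points, with a `frame_index`
#'   column giving the 1-based slice).
#' @export
render_timelapse <- function(tracks, shape_px = c(256, 256),
                             pixel_size_um = 0.189, blob_sigma_px = 2.8,
                             amplitude = 1, background_level = 0.1,
                             noise_sd = 0, seed = NULL) {
  .assert(all(c("track_id", "frame", "x_um", "y_um") %in% names(tracks)),
          "tracks must have track_id/frame/x_um/y_um columns")
  .assert(.is_num(shape_px, 2L) && all(shape_px > 0), "shape_px must be positive")
  .assert(.is_num(pixel_size_um) && pixel_size_um > 0, "pixel_size_um must be > 0")
  .assert(.is_num(noise_sd) && noise_sd >= 0, "noise_sd must be >= 0")
  shape_px <- as.integer(shape_px)

  frames <- if (nrow(tracks)) sort(unique(tracks$frame)) else integer(0)
  n_frames <- max(1L, length(frames))
  .with_seed(seed, {
    stack <- array(background_level, c(shape_px[1], shape_px[2], n_frames))
    if (noise_sd > 0)
      stack <- stack + array(stats::rnorm(length(stack), 0, noise_sd), dim(stack))
    half <- ceiling(4 * blob_sigma_px)
    keep <- logical(nrow(tracks))
    fidx <- integer(nrow(tracks))
    for (i in seq_len(nrow(tracks))) {
      f <- match(tracks$frame[i], frames)
      fidx[i] <- f
      cc <- tracks$x_um[i] / pixel_size_um + 0.5  # pixel-center convention
      rr <- tracks$y_um[i] / pixel_size_um + 0.5
      if (cc < 1 || cc > shape_px[2] || rr < 1 || rr > shape_px[1]) next
      keep[i] <- TRUE
      r0 <- max(1L, floor(rr) - half); r1 <- min(shape_px[1], floor(rr) + half)
      c0 <- max(1L, floor(cc) - half); c1 <- min(shape_px[2], floor(cc) + half)
      rs <- r0:r1; cs <- c0:c1
      spot <- amplitude * exp(-(outer((rs - rr)^2, (cs - cc)^2, "+")) /
                                (2 * blob_sigma_px^2))
      stack[rs, cs, f] <- stack[rs, cs, f] + spot
    }
    truth <- tracks[keep, , drop = FALSE]
    truth$frame_index <- fidx[keep]
    list(stack = stack, truth = truth)
  })
}
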