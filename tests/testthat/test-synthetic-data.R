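test_that("perfectly persistent walks are collinear with D equal to L", {
  tr <- simulate_persistent_tracks(5, 30, speed_um_min = 1, persistence_p = 1,
                                   arena = c(5000, 5000), seed = 1)
  # huge arena so no wall reflection interrupts the straight paths
  mt <- track_metrics(tr)
  expect_equal(mt$persistence, rep(1, 5), tolerance = 1e-12)
  expect_equal(mt$displacement_um, mt$path_length_um, tolerance = 1e-12)
})

test_that("uncorrelated walks have low straightness at long times", {
  tr <- simulate_persistent_tracks(1000, 1000, speed_um_min = 0.25,
                                   persistence_p = 0,
                                   arena = c(4000, 4000), seed = 2)
  mt <- track_metrics(tr)
  expect_lt(mean(mt$persistence), 0.2)
})

test_that("the same seed reproduces tracks bit for bit", {
  a <- simulate_persistent_tracks(10, 50, persistence_p = 0.7, seed = 99)
  b <- simulate_persistent_tracks(10, 50, persistence_p = 0.7, seed = 99)
  expect_identical(a, b)
})

test_that("mean straightness increases with the persistence parameter", {
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  mp <- vapply(grid, function(p) {
    tr <- simulate_persistent_tracks(500, 100, speed_um_min = 0.5,
                                     persistence_p = p,
                                     arena = c(2000, 2000), seed = 11)
    mean(track_metrics(tr)$persistence)
  }, numeric(1))
  expect_true(all(diff(mp) >= 0))
})

test_that("generator rejects invalid parameters", {
  expect_error(simulate_persistent_tracks(0, 10), "n_tracks")
  expect_error(simulate_persistent_tracks(5, 10, persistence_p = 1.2), "persistence")
  expect_error(simulate_persistent_tracks(5, 10, speed_um_min = -1), "speed")
  expect_error(simulate_persistent_tracks(5, 10, drift = c(0, NA)), "drift")
})

test_that("rendering a static noise-free track puts the frame maximum at it", {
  tr <- data.frame(track_id = 1, frame = 0:4, t_min = (0:4) * 4,
                   x_um = 20, y_um = 30)
  rt <- render_timelapse(tr, shape_px = c(256, 256), noise_sd = 0)
  for (f in 1:5) {
    pk <- which(rt$stack[, , f] == max(rt$stack[, , f]), arr.ind = TRUE)
    expect_equal(unname(pk[1, "row"]), round(30 / 0.189 + 0.5))
    expect_equal(unname(pk[1, "col"]), round(20 / 0.189 + 0.5))
  }
})

test_that("an empty track list renders pure background", {
  tr <- data.frame(track_id = integer(0), frame = integer(0),
                   t_min = numeric(0), x_um = numeric(0), y_um = numeric(0))
  rt <- render_timelapse(tr, shape_px = c(64, 64), background_level = 0.2,
                         noise_sd = 0)
  expect_true(all(rt$stack == 0.2))
})

test_that("star cells carry their spike count as ground truth", {
  d <- make_star_cell(n_spikes = 0, seed = 1)
  expect_s3_class(d, "cell_mask")
  expect_identical(attr(d, "n_spikes"), 0L)
  s7 <- make_star_cell(n_spikes = 7, spike_len_um = 2.5, spike_width_um = 0.2,
                       seed = 2)
  expect_identical(attr(s7, "n_spikes"), 7L)
  expect_gt(attr(s7, "spike_area_um2"), 0.077)
})

test_that("star cells reject geometry with overlapping or too-wide spikes", {
  expect_error(make_star_cell(base_radius_um = 2, n_spikes = 40, seed = 1),
               "overlap")
  expect_error(make_star_cell(n_spikes = 3, spike_width_um = 2.5), "2.2")
})

test_that("ellipsoid stacks record exact analytic ground truth", {
  st <- make_ellipsoid_stack(c(4, 4, 4))
  expect_equal(st$truth$flatness, 1)
  st2 <- make_ellipsoid_stack(c(4, 3, 1.5))
  expect_equal(st2$truth$flatness, 2)
  expect_equal(st2$truth$volume_um3, 4 / 3 * pi * 18)
  rot <- make_ellipsoid_stack(c(4, 3, 1.5), orientation = c(0.4, 0.3, 0.2))
  expect_equal(rot$truth, st2$truth)
  expect_error(make_ellipsoid_stack(c(4, 3, 0.3)), "2 voxels")
})

test_that("point fields are reproducible and respect the region split", {
  f1 <- make_point_field(0.02, 0.02, seed = 5)
  f2 <- make_point_field(0.02, 0.02, seed = 5)
  expect_identical(f1$points, f2$points)
  f <- make_point_field(0.05, 0, region_split = 0.5, extent_um = c(100, 100),
                        seed = 6)
  expect_true(all(f$points[, 1] <= 50))
})

test_that("focal-adhesion patterns carry exact summed segment lengths", {
  p <- make_fa_pattern(matrix(c(20, 50, 70, 50), 1), shape_px = c(340, 340),
                       pixel_size_um = 0.3)
  expect_equal(p$truth_length_um, 50)
  p0 <- make_fa_pattern(NULL, shape_px = c(64, 64))
  expect_equal(p0$truth_length_um, 0)
  expect_true(all(!p0$mask))
  expect_error(
    make_fa_pattern(rbind(c(20, 50, 70, 50), c(20, 50.2, 70, 50.2)),
                    shape_px = c(340, 340), pixel_size_um = 0.3),
    "overlap")
})

test_that("genome fixtures give the requested enrichment by construction", {
  fx <- make_genome_fixture(1000, 100, 3, 150, seed = 7)
  expect_equal(fx$background_fraction, 0.1)
  expect_equal(fx$expected_deg_fraction, 0.3)
  fx1 <- make_genome_fixture(1000, 100, 1, 150, seed = 8)
  expect_equal(fx1$expected_deg_fraction, fx1$background_fraction,
               tolerance = 0.05)
  expect_error(make_genome_fixture(100, 50, 3, 10), "infeasible")
  a <- make_genome_fixture(200, 20, 2, 30, seed = 3)
  b <- make_genome_fixture(200, 20, 2, 30, seed = 3)
  expect_identical(a$degs, b$degs)
  expect_identical(as.data.frame(a$peaks), as.data.frame(b$peaks))
})
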