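test_that("3D blur preserves constants and unit mass", {
  g <- voxel_grid(array(3.7, c(16, 16, 16)))
  expect_equal(blur3d(g)$intensities, g$intensities, tolerance = 1e-12)
  imp <- array(0, c(33, 33, 33)); imp[17, 17, 17] <- 1
  sm <- blur3d(voxel_grid(imp), sigma_px = 2)$intensities
  expect_equal(sum(sm), 1, tolerance = 1e-3)
  expect_error(blur3d(g, sigma_px = -1), "positive")
})

test_that("3D blur matches a direct separable reference convolution", {
  set.seed(3)
  arr <- array(runif(14 * 12 * 10), c(14, 12, 10))
  got <- blur3d(voxel_grid(arr, c(1, 1, 1)), sigma_px = 1.5)$intensities
  # reference: direct triple loop with replicate padding
  half <- ceiling(4 * 1.5)
  k <- dnorm(-half:half, sd = 1.5); k <- k / sum(k)
  cl <- function(i, n) pmin(pmax(i, 1), n)
  ref <- array(0, dim(arr))
  tmp1 <- array(0, dim(arr)); tmp2 <- array(0, dim(arr))
  for (i in 1:14) for (j in 1:12) for (l in 1:10)
    tmp1[i, j, l] <- sum(k * arr[cl(i + (-half:half), 14), j, l])
  for (i in 1:14) for (j in 1:12) for (l in 1:10)
    tmp2[i, j, l] <- sum(k * tmp1[i, cl(j + (-half:half), 12), l])
  for (i in 1:14) for (j in 1:12) for (l in 1:10)
    ref[i, j, l] <- sum(k * tmp2[i, j, cl(l + (-half:half), 10)])
  expect_equal(got, ref, tolerance = 1e-6)
})

test_that("segmentation labels isolated and touching ellipsoids correctly", {
  vx <- c(0.132, 0.132, 0.24)
  one <- make_ellipsoid_stack(c(2.5, 2, 1.5), voxel_size_um = vx,
                              noise_sd = 0.05, seed = 31)
  lab <- segment_nuclei_3d(blur3d(one$grid))
  expect_equal(max(lab), 1L)
  truth_mask <- one$grid$intensities > 0.5
  overlap <- sum(lab == 1L & truth_mask) / sum(truth_mask)
  expect_gt(overlap, 0.95)
  # two ellipsoids far apart in one volume
  a1 <- make_ellipsoid_stack(c(2, 1.8, 1.5), voxel_size_um = vx,
                             pad_um = 0.8)$grid$intensities
  d1 <- dim(a1)
  arr <- array(0, c(90, 90, 40))
  arr[seq_len(d1[1]), seq_len(d1[2]), seq_len(d1[3])] <- a1
  ro <- 90 - d1[1] + seq_len(d1[1]); co <- 90 - d1[2] + seq_len(d1[2])
  zo <- 40 - d1[3] + seq_len(d1[3])
  arr[ro, co, zo] <- pmax(arr[ro, co, zo], a1)
  lab2 <- segment_nuclei_3d(blur3d(voxel_grid(arr, vx)))
  expect_equal(max(lab2), 2L)
  expect_error(segment_nuclei_3d(voxel_grid(array(0, c(10, 10, 10)), vx)))
})

test_that("watershed splits a touching dumbbell of two nuclei", {
  vx <- c(0.132, 0.132, 0.24)
  a1 <- make_ellipsoid_stack(c(2, 1.8, 1.5), voxel_size_um = vx,
                             pad_um = 0.6)$grid$intensities
  d1 <- dim(a1)
  # centers 3.96 um apart for 2-um x-semi-axes: the surfaces interpenetrate
  # slightly, leaving a clear neck between two bodies
  off <- 30L
  arr <- array(0, c(d1[1] + off, d1[2], d1[3]))
  arr[seq_len(d1[1]), , ] <- a1
  arr[off + seq_len(d1[1]), , ] <- pmax(arr[off + seq_len(d1[1]), , ], a1)
  lab <- segment_nuclei_3d(blur3d(voxel_grid(arr, vx)))
  expect_equal(max(lab), 2L)
})

test_that("descriptors recover sphere and ellipsoid shape parameters", {
  vx <- c(0.132, 0.132, 0.24)
  sph <- make_ellipsoid_stack(c(3, 3, 3), voxel_size_um = vx)
  d <- nucleus_descriptors(sph$grid$intensities > 0.5, vx)
  expect_gte(d$flatness, 1)
  expect_lt(d$flatness, 1.05)
  expect_gte(d$sphericity, 0.9)
  ell <- make_ellipsoid_stack(c(4, 3, 1.5), voxel_size_um = vx)
  de <- nucleus_descriptors(ell$grid$intensities > 0.5, vx)
  expect_equal(de$flatness, 2, tolerance = 0.05)
  expect_equal(de$volume_um3, ell$truth$volume_um3, tolerance = 0.02)
  expect_true(de$a_um >= de$b_um && de$b_um >= de$c_um)
})

test_that("descriptors are rotation invariant within 2 percent", {
  vx <- c(0.132, 0.132, 0.24)
  base <- make_ellipsoid_stack(c(4, 3, 1.5), voxel_size_um = vx)
  rot <- make_ellipsoid_stack(c(4, 3, 1.5),
                              orientation = c(pi / 6, pi / 6, pi / 6),
                              voxel_size_um = vx)
  d0 <- nucleus_descriptors(base$grid$intensities > 0.5, vx)
  d1 <- nucleus_descriptors(rot$grid$intensities > 0.5, vx)
  expect_equal(d1$flatness, d0$flatness, tolerance = 0.02)
  expect_equal(d1$sphericity, d0$sphericity, tolerance = 0.02)
  expect_equal(d1$volume_um3, d0$volume_um3, tolerance = 0.02)
})

test_that("anisotropy is handled: descriptors match an isotropic resampling", {
  # same physical ellipsoid voxelized at the anisotropic calibration and at
  # an isotropic grid must give the same flatness
  aniso <- make_ellipsoid_stack(c(4, 3, 1.5),
                                voxel_size_um = c(0.132, 0.132, 0.24))
  iso <- make_ellipsoid_stack(c(4, 3, 1.5),
                              voxel_size_um = c(0.15, 0.15, 0.15))
  da <- nucleus_descriptors(aniso$grid$intensities > 0.5, c(0.132, 0.132, 0.24))
  di <- nucleus_descriptors(iso$grid$intensities > 0.5, c(0.15, 0.15, 0.15))
  expect_equal(da$flatness, di$flatness, tolerance = 0.05)
  expect_equal(da$volume_um3, di$volume_um3, tolerance = 0.05)
})

test_that("volume gating keeps the inclusive 100-350 voxel band, idempotently", {
  sh <- data.frame(label = 1:5, volume_voxels = c(99, 100, 200, 350, 351),
                   volume_um3 = c(99, 100, 200, 350, 351) * 0.0042)
  kept <- filter_nuclei_by_volume(sh)
  expect_equal(kept$volume_voxels, c(100, 200, 350))
  expect_identical(filter_nuclei_by_volume(kept), kept)
  expect_error(filter_nuclei_by_volume(sh, min_vol = 400, max_vol = 100), "<=")
  k2 <- filter_nuclei_by_volume(sh, min_vol = 0.6, max_vol = 1, unit = "um3")
  expect_equal(k2$label, 3L)  # only 200 voxels x 0.0042 = 0.84 um^3 in band
})
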