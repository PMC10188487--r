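test_that("compactness recovers the circle and square identities", {
  dsk <- cell_mask(disk_mask(100), 1)
  expect_gt(compactness(dsk), 0.98)
  expect_lt(compactness(dsk), 1.02)
  sq <- cell_mask(square_mask(100), 1)
  expect_equal(compactness(sq), pi / 4, tolerance = 0.01)
})

test_that("compactness is scale invariant under re-rasterization", {
  # same continuous shape sampled at two pixel sizes (same seed keeps the
  # spike orientation identical)
  c1 <- compactness(make_star_cell(n_spikes = 5, pixel_size_um = 0.1, seed = 3))
  c2 <- compactness(make_star_cell(n_spikes = 5, pixel_size_um = 0.05, seed = 3))
  expect_equal(c2, c1, tolerance = 0.02)
})

test_that("a star cell is less compact than the spikeless body", {
  star <- make_star_cell(n_spikes = 8, seed = 9)
  body <- make_star_cell(n_spikes = 0, seed = 9)
  expect_lt(compactness(star), compactness(body))
})

test_that("cell_mask rejects empty or fragmented masks", {
  expect_error(cell_mask(matrix(FALSE, 5, 5), 1), "empty")
  frag <- matrix(FALSE, 10, 10); frag[2, 2] <- TRUE; frag[8, 8] <- TRUE
  expect_error(cell_mask(frag, 1), "one connected component")
})

test_that("filopodia counting recovers planted spikes and honors the area gate", {
  expect_equal(count_filopodia(make_star_cell(n_spikes = 0, seed = 1)), 0L)
  s7 <- make_star_cell(n_spikes = 7, spike_len_um = 2.5, spike_width_um = 0.2,
                       seed = 2)
  expect_equal(count_filopodia(s7), 7L)
  # spikes of ~0.05 um^2 fall under the 0.077 um^2 gate
  tiny <- make_star_cell(n_spikes = 5, spike_len_um = 0.25,
                         spike_width_um = 0.2, pixel_size_um = 0.05, seed = 3)
  expect_equal(count_filopodia(tiny, min_area_um2 = 0.077), 0L)
  expect_error(count_filopodia(s7, disk_radius_um = 0.01), "1 px")
})

test_that("filopodia counting is invariant under translation and rotation by 90", {
  s <- make_star_cell(n_spikes = 6, seed = 12)
  k <- count_filopodia(s)
  pad <- matrix(FALSE, nrow(s$mask) + 30, ncol(s$mask) + 30)
  pad[17:(16 + nrow(s$mask)), 9:(8 + ncol(s$mask))] <- s$mask
  expect_equal(count_filopodia(cell_mask(pad, s$pixel_size_um)), k)
  rot <- t(s$mask)[ncol(s$mask):1, ]  # 90-degree rotation
  expect_equal(count_filopodia(cell_mask(rot, s$pixel_size_um)), k)
})

test_that("skeleton length recovers bar patterns within 5 percent", {
  p50 <- make_fa_pattern(matrix(c(20, 50, 70, 50), 1), shape_px = c(340, 340),
                         pixel_size_um = 0.3)
  expect_equal(total_fa_length(p50$mask, 0.3), 50, tolerance = 0.05)
  segs <- t(vapply(1:10, function(i) {
    x0 <- 15 + ((i - 1) %% 5) * 27; y0 <- 25 + ((i - 1) %/% 5) * 75
    ang <- (i * 37) %% 180 * pi / 180
    c(x0, y0, x0 + 20 * cos(ang), y0 + 20 * sin(ang))
  }, numeric(4)))
  p200 <- make_fa_pattern(segs, shape_px = c(512, 512), pixel_size_um = 0.3)
  expect_equal(p200$truth_length_um, 200)
  expect_equal(total_fa_length(p200$mask, 0.3), 200, tolerance = 0.05)
  expect_equal(total_fa_length(matrix(FALSE, 50, 50), 0.3), 0)
})

test_that("skeleton length is additive over disjoint patterns", {
  s1 <- matrix(c(20, 40, 60, 40), 1)
  s2 <- matrix(c(20, 80, 55, 95), 1)
  pa <- make_fa_pattern(s1, shape_px = c(400, 400), pixel_size_um = 0.3)
  pb <- make_fa_pattern(s2, shape_px = c(400, 400), pixel_size_um = 0.3)
  pab <- make_fa_pattern(rbind(s1, s2), shape_px = c(400, 400),
                         pixel_size_um = 0.3)
  la <- total_fa_length(pa$mask, 0.3)
  lb <- total_fa_length(pb$mask, 0.3)
  expect_equal(total_fa_length(pab$mask, 0.3), la + lb, tolerance = 0.01)
})

test_that("ROI mean intensity matches direct summation", {
  expect_equal(mean_intensity_roi(matrix(7, 100, 100), c(25, 25),
                                  pixel_size_um = 0.5), 7)
  img <- matrix(0, 100, 100)
  img[, 51:100] <- 10
  # ROI centered on the step: half 0, half 10
  v <- mean_intensity_roi(img, c(25, 25), area_um2 = 64, pixel_size_um = 0.5)
  expect_equal(v, 5)
  set.seed(8)
  rnd <- matrix(runif(100 * 100), 100, 100)
  side <- round(sqrt(56) / 0.5)
  got <- mean_intensity_roi(rnd, c(20, 30), pixel_size_um = 0.5)
  rc <- round(30 / 0.5 + 0.5); cc <- round(20 / 0.5 + 0.5)
  rows <- (rc - floor((side - 1) / 2)):(rc - floor((side - 1) / 2) + side - 1)
  cols <- (cc - floor((side - 1) / 2)):(cc - floor((side - 1) / 2) + side - 1)
  expect_equal(got, sum(rnd[rows, cols]) / length(rnd[rows, cols]),
               tolerance = 1e-12)
  expect_error(mean_intensity_roi(rnd, c(1, 1), pixel_size_um = 0.5), "ROI")
})

test_that("nuclei counting applies the 7.1 um^2 debris gate", {
  img <- matrix(0, 200, 200)  # 100 x 100 um at 0.5 um/px
  for (k in 1:25) {
    r0 <- ((k - 1) %% 5) * 40 + 10; c0 <- ((k - 1) %/% 5) * 40 + 10
    img[r0:(r0 + 5), c0:(c0 + 5)] <- 1  # 6x6 px = 9 um^2
  }
  res <- count_nuclei_2d(img, 0.5)
  expect_equal(res$count, 25L)
  expect_equal(res$density_per_100um2, 0.25)
  small <- matrix(0, 200, 200)
  for (k in 1:25) {
    r0 <- ((k - 1) %% 5) * 40 + 10; c0 <- ((k - 1) %/% 5) * 40 + 10
    small[r0:(r0 + 3), c0:(c0 + 3)] <- 1  # 4x4 px = 4 um^2 < 7.1
  }
  expect_equal(count_nuclei_2d(small, 0.5)$count, 0L)
  expect_equal(count_nuclei_2d(matrix(0, 50, 50), 0.5)$count, 0L)
})

test_that("positive-cell counting gates areas and splits touching pairs", {
  # dumbbell of two 10-px-radius disks bridged by a neck
  img <- matrix(0, 120, 120)
  d1 <- sqrt(outer((1:120 - 50)^2, (1:120 - 55)^2, "+"))
  d2 <- sqrt(outer((1:120 - 50)^2, (1:120 - 72)^2, "+"))
  img[d1 <= 10 | d2 <= 10] <- 1
  img[44:56, 55:72] <- 1
  nuc <- matrix(0, 120, 120); nuc[d1 <= 5 | d2 <= 5] <- 1
  res <- count_positive_cells(img, nuc, pixel_size_um = 0.5)
  expect_equal(res$positive, 2L)
  # a 300 um^2 object fails the 6-200 um^2 gate
  big <- matrix(0, 120, 120); big[20:90, 20:37] <- 1  # 71x18 px ~ 320 um^2
  nb <- matrix(0, 120, 120); nb[50:55, 25:30] <- 1
  resb <- count_positive_cells(big, nb, pixel_size_um = 0.5)
  expect_equal(resb$positive, 0L)
  expect_error(count_positive_cells(big, matrix(0, 10, 10), 0.5), "shape")
})

test_that("circle fitting recovers exact and noisy circles", {
  f <- fit_embryo_circle(rbind(c(0, 0), c(2, 0), c(1, 1)))
  expect_equal(f$center, c(1, 0), tolerance = 1e-12)
  expect_equal(f$radius, 1, tolerance = 1e-12)
  expect_equal(f$area_um2, pi, tolerance = 1e-12)
  th <- seq(0, 2 * pi, length.out = 101)[-101]
  f2 <- fit_embryo_circle(cbind(5 * cos(th) + 3, 5 * sin(th) - 2))
  expect_equal(f2$radius, 5, tolerance = 1e-9)
  expect_equal(f2$center, c(3, -2), tolerance = 1e-9)
  set.seed(10)
  for (i in 1:100) {
    pts <- cbind(5 * cos(th) + rnorm(100, 0, 0.1),
                 5 * sin(th) + rnorm(100, 0, 0.1))
    r <- fit_embryo_circle(pts)$radius
    expect_gt(r, 4.9); expect_lt(r, 5.1)
  }
  expect_error(fit_embryo_circle(rbind(c(0, 0), c(1, 1), c(2, 2))), "collinear")
})
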