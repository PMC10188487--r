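#' Simulate a two-density nuclei centroid field with a region mask
#'
#' Draws homogeneous Poisson point patterns at two intensities: rate A inside
#' the "active" region (the left `region_split` fraction of the field,
#' mimicking the domain where the Yap readout is expressed) and rate B in the
#' remainder. Used as ground truth for the k-nearest-neighbor density
#' statistic, whose mean distance scales as `1/sqrt(rate)`.
#'
#' @param rate_per_um2_A,rate_per_um2_B point intensities (points per um^2).
#' @param region_split fraction of the field width assigned to region A.
#' @param extent_um field size `(width_um, height_um)`.
#' @param pixel_size_um calibration of the returned region mask
#'   (default 0.15 um, a typical 40x confocal pixel, so the 8-px
#'   deduplication radius spans ~1.2 um).
#' @param seed integer seed.
#' @return A `centroid_field` (see [centroid_field()]) whose `region_mask`
#'   is TRUE inside the active region.
#' @export
make_point_field <- function(rate_per_um2_A, rate_per_um2_B,
                             region_split = 0.5, extent_um = c(200, 200),
                             pixel_size_um = 0.15, seed = NULL) {
  .assert(.is_num(rate_per_um2_A) && rate_per_um2_A >= 0, "rate A must be >= 0")
  .assert(.is_num(rate_per_um2_B) && rate_per_um2_B >= 0, "rate B must be >= 0")
  .assert(.is_num(region_split) && region_split >= 0 && region_split <= 1,
          "region_split must be in [0, 1]")
  .assert(.is_num(extent_um, 2L) && all(extent_um > 0), "extent_um must be positive")

  .with_seed(seed, {
    w_a <- extent_um[1] * region_split
    area_a <- w_a * extent_um[2]
    area_b <- (extent_um[1] - w_a) * extent_um[2]
    n_a <- stats::rpois(1, rate_per_um2_A * area_a)
    n_b <- stats::rpois(1, rate_per_um2_B * area_b)
    pts <- rbind(
      cbind(stats::runif(n_a, 0, w_a), stats::runif(n_a, 0, extent_um[2])),
      cbind(stats::runif(n_b, w_a, extent_um[1]), stats::runif(n_b, 0, extent_um[2]))
    )
    colnames(pts) <- c("x_um", "y_um")
    nr <- ceiling(extent_um[2] / pixel_size_um)
    nc <- ceiling(extent_um[1] / pixel_size_um)
    mask <- matrix(FALSE, nr, nc)
    mask[, .px_to_um(seq_len(nc), pixel_size_um) < w_a] <- TRUE
    centroid_field(pts, bounds = extent_um, pixel_size_um = pixel_size_um,
                   region_mask = mask)
  })
}

#' Expected mean k-nearest-neighbor distance in a homogeneous Poisson field
#'
#' Closed form for the mean of the average distance to the `k` nearest
#' neighbors of a typical point of a 2D Poisson process of intensity
#' `lambda`: the j-th neighbor distance has expectation
#' `Gamma(j + 1/2) / Gamma(j) / sqrt(pi * lambda)`.
#'
#' @param lambda intensity (points per um^2).
#' @param k number of neighbors averaged (default 5).
#' @return expected mean distance in um.
#' @export
expected_knn_distance_poisson <- function(lambda, k = 5) {
  .assert(.is_num(lambda) && lambda > 0, "lambda must be > 0")
  j <- seq_len(k)
  mean(exp(lgamma(j + 0.5) - lgamma(j))) / sqrt(pi * lambda)
}
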