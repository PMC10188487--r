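#' Remove centroids closer than a pixel threshold
#'
#' Deletes every centroid that has at least one neighbor nearer than
#' `min_sep_px` pixels (symmetric removal of both members of a violating
#' pair, since a too-close pair usually reflects one oversegmented nucleus).
#' One pass is idempotent on the surviving set.
#'
#' @param field a [centroid_field()].
#' @param min_sep_px separation threshold in pixels (default 8).
#' @return filtered `centroid_field`.
#' @export
dedupe_centroids <- function(field, min_sep_px = 8) {
  .assert(inherits(field, "centroid_field"), "field must be a centroid_field")
  pts <- field$points
  if (nrow(pts) < 2) return(field)
  thr <- min_sep_px * field$pixel_size_um
  dm <- as.matrix(stats::dist(pts))
  diag(dm) <- Inf
  keep <- apply(dm, 1, min) >= thr
  centroid_field(pts[keep, , drop = FALSE], field$bounds, field$pixel_size_um,
                 field$region_mask)
}

#' Exclude centroids near the image border
#'
#' Drops points lying within `margin_px` pixels of any field edge, where
#' the k-nearest-neighbor distance would be biased by unobserved neighbors.
#'
#' @param field a [centroid_field()].
#' @param margin_px border margin in pixels (default 8).
#' @return filtered `centroid_field`; a warning is emitted if nothing
#'   survives.
#' @export
exclude_border <- function(field, margin_px = 8) {
  .assert(inherits(field, "centroid_field"), "field must be a centroid_field")
  .assert(.is_num(margin_px) && margin_px >= 0, "margin must be >= 0")
  m <- margin_px * field$pixel_size_um
  pts <- field$points
  keep <- pts[, 1] >= m & pts[, 1] <= field$bounds[1] - m &
    pts[, 2] >= m & pts[, 2] <= field$bounds[2] - m
  if (!any(keep)) warning("border exclusion removed every point")
  centroid_field(pts[keep, , drop = FALSE], field$bounds, field$pixel_size_um,
                 field$region_mask)
}

#' Mean distance to the k nearest neighbors
#'
#' For each centroid, the mean of the Euclidean distances to its `k`
#' closest other centroids (k = 5 by default): small
#' values mean dense neighborhoods. Exact all-pairs computation.
#'
#' @param field a [centroid_field()].
#' @param k number of neighbors (default 5); the field must contain more
#'   than `k` points.
#' @return data.frame with `x_um`, `y_um`, `mean_dist_knn_um`.
#' @export
mean_knn_distance <- function(field, k = 5) {
  .assert(inherits(field, "centroid_field"), "field must be a centroid_field")
  pts <- field$points
  .assert(nrow(pts) >= k + 1, sprintf("need at least %d points", k + 1))
  dm <- as.matrix(stats::dist(pts))
  diag(dm) <- Inf
  d_knn <- apply(dm, 1, function(r) mean(sort.int(r, partial = k)[seq_len(k)]))
  data.frame(x_um = pts[, 1], y_um = pts[, 2], mean_dist_knn_um = d_knn)
}

#' Assign each centroid to the active or inactive region
#'
#' Looks up the region-mask pixel containing each point (points on a pixel
#' follow that pixel's value) and labels it `active` (mask TRUE, i.e. the
#' marker-positive area) or `inactive`.
#'
#' @param records data.frame from [mean_knn_distance()] (or any table with
#'   `x_um`, `y_um`).
#' @param field a [centroid_field()] carrying the `region_mask`, or a
#'   logical matrix plus `pixel_size_um`.
#' @param pixel_size_um required when `field` is a bare matrix.
#' @return `records` with an added `region` factor.
#' @export
assign_region <- function(records, field, pixel_size_um = NULL) {
  if (inherits(field, "centroid_field")) {
    mask <- field$region_mask
    px <- field$pixel_size_um
  } else {
    mask <- field
    px <- pixel_size_um
  }
  .assert(is.matrix(mask), "no region mask available")
  .assert(.is_num(px) && px > 0, "pixel_size_um must be > 0")
  rr <- pmin(pmax(.um_to_px(records$y_um, px), 1L), nrow(mask))
  cc <- pmin(pmax(.um_to_px(records$x_um, px), 1L), ncol(mask))
  .assert(all(records$x_um >= 0 & records$x_um <= ncol(mask) * px &
                records$y_um >= 0 & records$y_um <= nrow(mask) * px),
          "point outside region mask bounds")
  records$region <- factor(ifelse(mask[cbind(rr, cc)], "active", "inactive"),
                           levels = c("active", "inactive"))
  records
}

#' Compare neighbor distances between regions across embryos
#'
#' Aggregates the per-nucleus mean k-NN distance to one mean per embryo and
#' region, then compares the two regions with a two-sided t test on embryo
#' means (the embryo, not the nucleus, is the statistical unit).
#'
#' @param records data.frame with `mean_dist_knn_um`, `region` and `embryo`
#'   columns.
#' @return list with `per_embryo` (embryo x region means) and `test`
#'   (a `two_sample_result`).
#' @export
compare_density <- function(records) {
  need <- c("mean_dist_knn_um", "region", "embryo")
  .assert(all(need %in% names(records)), "records need mean_dist_knn_um/region/embryo")
  agg <- stats::aggregate(mean_dist_knn_um ~ embryo + region, data = records,
                          FUN = mean)
  a <- agg$mean_dist_knn_um[agg$region == "active"]
  b <- agg$mean_dist_knn_um[agg$region == "inactive"]
  .assert(length(a) >= 2 && length(b) >= 2,
          "need >= 2 embryos with points in each region")
  list(per_embryo = agg, test = t_test_means(a, b))
}
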