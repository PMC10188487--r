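# Internal helpers shared across modules. Nothing here is exported.

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

.is_num <- function(x, n = 1L) is.numeric(x) && length(x) == n && all(is.finite(x))

# Run `expr` under `seed` (restoring RNG state afterwards); NULL seed means
# "use the current RNG stream".
.with_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# -- 2D geometry ------------------------------------------------------------

# Crofton-style perimeter of a binary matrix: count differing orthogonal and
# diagonal neighbor pairs and weight them so the continuum limit is exact for
# both a disk and an axis-aligned square.
.perimeter_crofton_px <- function(mask) {
  w_diag <- (4 - pi) / (8 - 4 * sqrt(2))
  w_orth <- 1 - 2 * w_diag
  m <- matrix(0, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- as.numeric(mask != 0)
  nr <- nrow(m); nc <- ncol(m)
  n_h  <- sum(abs(m[, -1L] - m[, -nc]))
  n_v  <- sum(abs(m[-1L, ] - m[-nr, ]))
  n_d1 <- sum(abs(m[-1L, -1L] - m[-nr, -nc]))
  n_d2 <- sum(abs(m[-1L, -nc] - m[-nr, -1L]))
  w_orth * (n_h + n_v) + w_diag * (n_d1 + n_d2)
}

# Pixel-center coordinate helpers: pixel (row r, col c) has its center at
# x = (c - 0.5) * px, y = (r - 0.5) * px, x along columns, y along rows.
.px_to_um <- function(idx, px) (idx - 0.5) * px
.um_to_px <- function(u, px) floor(u / px) + 1L

# 8-connected labeling of a binary matrix. EBImage::bwlabel uses
# 4-connectivity, so labels touching only diagonally are merged afterwards
# with a union-find pass.
.bwlabel8 <- function(mask) {
  lab <- EBImage::bwlabel(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n < 2L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1L, -1L])),   # SE diagonal
    cbind(as.vector(lab[-nr, -1L]), as.vector(lab[-1L, -nc]))    # SW diagonal
  )
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (!nrow(pairs)) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (r in seq_len(nrow(pairs))) {
    ri <- find(pairs[r, 1]); rj <- find(pairs[r, 2])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  pos <- lab > 0L
  lab[pos] <- relab[lab[pos]]
  lab
}

# Number of 8-connected components of a binary matrix.
.n_components <- function(mask) {
  if (!any(mask != 0)) return(0L)
  max(.bwlabel8(mask))
}

# -- 3D array primitives ----------------------------------------------------

# Separable Gaussian convolution of a 3D array, sigma in voxels per axis,
# replicate ("nearest") padding so a constant field is preserved exactly.
.gauss_blur_3d <- function(arr, sigma) {
  sigma <- rep_len(sigma, 3L)
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    half <- max(1L, ceiling(4 * s))
    k <- stats::dnorm(-half:half, sd = s)
    k <- k / sum(k)
    n <- d[ax]
    out <- array(0, d)
    for (j in seq_along(k)) {
      off <- j - half - 1L
      idx <- pmin(pmax(seq_len(n) + off, 1L), n)
      out <- out + k[j] * switch(ax,
        arr[idx, , , drop = FALSE],
        arr[, idx, , drop = FALSE],
        arr[, , idx, drop = FALSE])
    }
    arr <- out
  }
  arr
}

# Global Otsu threshold of a numeric array (256-bin histogram between the
# observed min and max), returned on the original intensity scale.
.otsu_global <- function(x) {
  v <- as.numeric(x)
  lo <- min(v); hi <- max(v)
  .assert(hi > lo, "cannot threshold a constant image")
  u <- (v - lo) / (hi - lo)
  th <- EBImage::otsu(EBImage::Image(matrix(u, ncol = 1L)), range = c(0, 1))
  lo + as.numeric(th)[1L] * (hi - lo)
}

# 26-connected labeling of a 3D logical array: 8-connected labeling of every
# z-slice, then union-find merges across adjacent slices.
.label_3d <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  offset <- 0L
  for (z in seq_len(d[3])) {
    sl <- as.integer(.bwlabel8(mask[, , z]))
    pos <- sl > 0L
    sl[pos] <- sl[pos] + offset
    offset <- offset + max(0L, max(sl))
    lab[, , z] <- sl
  }
  if (offset == 0L) return(lab)
  parent <- seq_len(offset)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union_ <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }
  for (z in seq_len(d[3] - 1L)) {
    a <- lab[, , z]; b <- lab[, , z + 1L]
    # 26-connectivity across slices: compare against the 9 in-plane shifts
    for (dr in -1:1) for (dc in -1:1) {
      rs <- seq_len(d[1]); cs <- seq_len(d[2])
      ra <- rs[rs + dr >= 1 & rs + dr <= d[1]]
      ca <- cs[cs + dc >= 1 & cs + dc <= d[2]]
      aa <- a[ra, ca, drop = FALSE]
      bb <- b[ra + dr, ca + dc, drop = FALSE]
      sel <- aa > 0L & bb > 0L & aa != bb
      if (any(sel)) {
        prs <- unique(cbind(aa[sel], bb[sel]))
        for (r in seq_len(nrow(prs))) union_(prs[r, 1L], prs[r, 2L])
      }
    }
  }
  roots <- vapply(seq_len(offset), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  pos <- lab > 0L
  lab[pos] <- relab[lab[pos]]
  lab
}

.shift_3d <- function(arr, dr, dc, dz, fill = 0) {
  d <- dim(arr)
  out <- array(fill, d)
  src_r <- seq_len(d[1]) - dr; src_c <- seq_len(d[2]) - dc; src_z <- seq_len(d[3]) - dz
  kr <- src_r >= 1 & src_r <= d[1]; kc <- src_c >= 1 & src_c <= d[2]; kz <- src_z >= 1 & src_z <= d[3]
  out[kr, kc, kz] <- arr[src_r[kr], src_c[kc], src_z[kz]]
  out
}

.OFFSETS_26 <- {
  g <- expand.grid(dr = -1:1, dc = -1:1, dz = -1:1)
  g[!(g$dr == 0 & g$dc == 0 & g$dz == 0), ]
}

# Chamfer (3-4-5) distance to background, iterated relaxation; returns
# distances in chamfer units (divide by 3 for approximate voxel units).
.chamfer_3d <- function(mask) {
  d <- dim(mask)
  big <- 3L * sum(d)
  dist <- array(0, d)
  dist[mask] <- big
  w <- with(.OFFSETS_26, 3 + (abs(dr) + abs(dc) + abs(dz) - 1))  # 3, 4, 5
  repeat {
    prev <- dist
    for (i in seq_len(nrow(.OFFSETS_26))) {
      o <- .OFFSETS_26[i, ]
      dist <- pmin(dist, .shift_3d(dist, o$dr, o$dc, o$dz, fill = big) + w[i])
    }
    dist[!mask] <- 0
    if (identical(dist, prev)) break
  }
  dist
}

.max_filter_26 <- function(arr, fill = -Inf) {
  out <- arr
  for (i in seq_len(nrow(.OFFSETS_26))) {
    o <- .OFFSETS_26[i, ]
    out <- pmax(out, .shift_3d(arr, o$dr, o$dc, o$dz, fill = fill))
  }
  out
}

# Grayscale reconstruction of `marker` under `maskimg` by iterated geodesic
# dilation (26-neighborhood).
.reconstruct_3d <- function(marker, maskimg) {
  repeat {
    nxt <- pmin(.max_filter_26(marker), maskimg)
    if (identical(nxt, marker)) return(marker)
    marker <- nxt
  }
}

# h-dome seeds of a 3D height map restricted to `mask`: connected components
# where the map exceeds its reconstruction from (map - h).
.hdome_seeds_3d <- function(height, mask, h) {
  rec <- .reconstruct_3d(pmax(height - h, 0), height)
  dome <- (height - rec) > 1e-9 & mask
  .label_3d(dome)
}

# Marker-based watershed on a 3D height map (flooding from high to low):
# voxels are labeled level by level by adopting the smallest positive label
# among their 26-neighbors.
.watershed_3d <- function(height, seeds, mask) {
  lab <- seeds
  levels <- sort(unique(height[mask & lab == 0L]), decreasing = TRUE)
  for (lv in levels) {
    repeat {
      cand <- mask & lab == 0L & height >= lv
      if (!any(cand)) break
      neigh <- array(Inf, dim(lab))
      labf <- lab
      labf[labf == 0L] <- .Machine$integer.max
      for (i in seq_len(nrow(.OFFSETS_26))) {
        o <- .OFFSETS_26[i, ]
        neigh <- pmin(neigh, .shift_3d(labf, o$dr, o$dc, o$dz, fill = .Machine$integer.max))
      }
      take <- cand & is.finite(neigh) & neigh < .Machine$integer.max
      if (!any(take)) break
      lab[take] <- as.integer(neigh[take])
    }
  }
  lab
}
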