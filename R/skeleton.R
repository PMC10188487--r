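# 2D topological thinning (Zhang & Suen 1984) and skeleton length.

# One Zhang-Suen subiteration, fully vectorized over the image.
.zs_subiter <- function(m, step) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  at <- function(dr, dc) pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  p2 <- at(-1, 0); p3 <- at(-1, 1); p4 <- at(0, 1); p5 <- at(1, 1)
  p6 <- at(1, 0); p7 <- at(1, -1); p8 <- at(0, -1); p9 <- at(-1, -1)
  bsum <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
  ring <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
  a <- matrix(0L, nr, nc)
  for (i in 1:8) a <- a + (ring[[i]] == 0L & ring[[i + 1L]] == 1L)
  cond <- m == 1L & bsum >= 2L & bsum <= 6L & a == 1L
  if (step == 1L) {
    cond <- cond & (p2 * p4 * p6 == 0L) & (p4 * p6 * p8 == 0L)
  } else {
    cond <- cond & (p2 * p4 * p8 == 0L) & (p2 * p6 * p8 == 0L)
  }
  m[cond] <- 0L
  m
}

#' Skeletonize a binary mask by topological thinning
#'
#' Iterative Zhang-Suen thinning: boundary pixels are peeled in two
#' alternating subiterations until stability, leaving an 8-connected,
#' one-pixel-wide medial line that preserves the topology of the input.
#'
#' @param mask logical or 0/1 matrix.
#' @return logical matrix of the skeleton.
#' @export
skeletonize <- function(mask) {
  .assert(is.matrix(mask), "mask must be a matrix")
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  repeat {
    before <- m
    m <- .zs_subiter(m, 1L)
    m <- .zs_subiter(m, 2L)
    if (identical(m, before)) break
  }
  .unit_width_pass(m) == 1L
}

# Zhang-Suen leaves two-pixel-wide staircases on lines near 45 degrees.
# Sequentially delete non-endpoint simple points (pixels whose foreground
# neighbors stay 8-connected without them) until the skeleton is strictly
# one pixel wide.
.unit_width_pass <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  # ring positions clockwise: N, NE, E, SE, S, SW, W, NW
  ring_dr <- c(-1, -1, 0, 1, 1, 1, 0, -1)
  ring_dc <- c(0, 1, 1, 1, 0, -1, -1, -1)
  adj8 <- outer(seq_len(8), seq_len(8), function(i, j) {
    pmax(abs(ring_dr[i] - ring_dr[j]), abs(ring_dc[i] - ring_dc[j])) <= 1 & i != j
  })
  # number of 8-connected components among the "on" ring positions,
  # connectivity through the (removed) center not counted
  ring_comp <- function(bits) {
    on <- which(bits)
    if (length(on) <= 1) return(length(on))
    comp <- 0L; seen <- logical(8)
    for (s in on) {
      if (seen[s]) next
      comp <- comp + 1L
      stack <- s
      while (length(stack)) {
        v <- stack[length(stack)]; stack <- stack[-length(stack)]
        if (seen[v]) next
        seen[v] <- TRUE
        for (w in on) if (!seen[w] && adj8[v, w]) stack <- c(stack, w)
      }
    }
    comp
  }
  repeat {
    changed <- FALSE
    idx <- which(m == 1L)
    for (p in idx) {
      r <- ((p - 1L) %% nr) + 1L
      c <- ((p - 1L) %/% nr) + 1L
      if (r < 2 || r > nr - 1 || c < 2 || c > nc - 1) next
      nb <- c(m[r - 1, c], m[r - 1, c + 1], m[r, c + 1], m[r + 1, c + 1],
              m[r + 1, c], m[r + 1, c - 1], m[r, c - 1], m[r - 1, c - 1]) == 1L
      ns <- sum(nb)
      if (ns < 2 || ns > 6) next
      if (ring_comp(nb) == 1L) {
        m[r, c] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# Order the pixels of a simple-path component by walking from an endpoint
# (or from an arbitrary pixel for a closed loop). `px` is a 2-column matrix
# of (row, col). Returns the ordered index vector, or NULL if branched.
.trace_path <- function(px) {
  n <- nrow(px)
  if (n == 1) return(1L)
  key <- px[, 1] * 1e6 + px[, 2]
  idx_of <- stats::setNames(seq_len(n), key)
  neigh <- vector("list", n)
  deg <- integer(n)
  for (i in seq_len(n)) {
    nb <- outer(px[i, 1] + (-1:1), rep(1, 3)) * 1e6 +
      outer(rep(1, 3), px[i, 2] + (-1:1))
    nb <- as.vector(nb)[-5]
    hit <- idx_of[as.character(nb)]
    hit <- hit[!is.na(hit)]
    neigh[[i]] <- unname(hit)
    deg[i] <- length(hit)
  }
  if (any(deg > 2)) return(NULL)  # branched skeleton
  start <- which(deg == 1)[1]
  if (is.na(start)) start <- 1L   # closed loop
  path <- integer(n)
  used <- logical(n)
  path[1] <- start; used[start] <- TRUE
  for (s in 2:n) {
    nxt <- neigh[[path[s - 1]]]
    nxt <- nxt[!used[nxt]]
    if (!length(nxt)) return(path[seq_len(s - 1)])
    path[s] <- nxt[1]; used[nxt[1]] <- TRUE
  }
  path
}

#' Total skeleton length of a binary mask
#'
#' Thins the mask with [skeletonize()] and measures each skeleton component.
#' Components that are simple paths (no branch point) are measured as a
#' polyline resampled every `resample_px` pixels, which removes the
#' staircase bias of naive chain-code counting on oblique lines; branched
#' components fall back to counting unique 8-adjacencies (1 per orthogonal
#' step, sqrt(2) per diagonal step).
#'
#' @param mask binary matrix (e.g. a thresholded adhesion image).
#' @param pixel_size_um pixel calibration.
#' @param resample_px polyline resampling step for straight-path components.
#' @return total length in um (0 for an empty mask).
#' @export
skeleton_length <- function(mask, pixel_size_um, resample_px = 4) {
  .assert(is.matrix(mask), "mask must be a matrix")
  .assert(.is_num(pixel_size_um) && pixel_size_um > 0, "pixel_size_um must be > 0")
  if (!any(mask != 0)) return(0)
  skel <- skeletonize(mask)
  if (!any(skel)) return(0)
  lab <- .bwlabel8(skel)
  total <- 0
  for (l in seq_len(max(lab))) {
    px <- which(lab == l, arr.ind = TRUE)
    if (nrow(px) < 2) next
    ord <- .trace_path(px)
    if (!is.null(ord)) {
      p <- px[ord, , drop = FALSE]
      take <- unique(c(seq(1, nrow(p), by = resample_px), nrow(p)))
      q <- p[take, , drop = FALSE]
      total <- total + sum(sqrt(rowSums((q[-1, , drop = FALSE] -
                                           q[-nrow(q), , drop = FALSE])^2)))
    } else {
      # branched: count unique adjacent pixel pairs
      key <- px[, 1] * 1e6 + px[, 2]
      kset <- new.env(hash = TRUE, size = nrow(px))
      for (k in key) assign(as.character(k), TRUE, envir = kset)
      steps <- rbind(c(0, 1, 1), c(1, 0, 1), c(1, 1, sqrt(2)), c(1, -1, sqrt(2)))
      for (s in seq_len(nrow(steps))) {
        nb <- (px[, 1] + steps[s, 1]) * 1e6 + (px[, 2] + steps[s, 2])
        hit <- vapply(as.character(nb), exists, logical(1), envir = kset,
                      inherits = FALSE)
        total <- total + sum(hit) * steps[s, 3]
      }
    }
  }
  total * pixel_size_um
}
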