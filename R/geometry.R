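# Planar geometry kernel for the local-convex-hull estimator.
# Polygons are two-column matrices (x, y) of ring vertices, not closed.

# convex hull vertices of a point matrix, counter-clockwise
convex_hull_ring <- function(pts) {
  idx <- grDevices::chull(pts[, 1], pts[, 2])
  ring <- pts[idx, , drop = FALSE]
  if (nrow(ring) >= 3 && signed_ring_area(ring) < 0) {
    ring <- ring[rev(seq_len(nrow(ring))), , drop = FALSE]
  }
  ring
}

signed_ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  j <- c(2:length(x), 1)
  sum(x * y[j] - x[j] * y) / 2
}

ring_area <- function(ring) {
  if (nrow(ring) < 3) return(0)
  abs(signed_ring_area(ring))
}

# which points lie in a convex ring; boundary points count as inside
points_in_convex <- function(px, py, ring, tol = 1e-9) {
  n <- nrow(ring)
  if (n == 1) return(abs(px - ring[1, 1]) < tol & abs(py - ring[1, 2]) < tol)
  if (n == 2) {
    return(point_on_segment(px, py, ring[1, ], ring[2, ], tol))
  }
  scale <- max(abs(ring)) + 1
  inside <- rep(TRUE, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cr <- (ring[j, 1] - ring[i, 1]) * (py - ring[i, 2]) -
      (ring[j, 2] - ring[i, 2]) * (px - ring[i, 1])
    inside <- inside & (cr >= -tol * scale^2)
  }
  inside
}

point_on_segment <- function(px, py, a, b, tol = 1e-9) {
  cr <- (b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1])
  within <- px >= min(a[1], b[1]) - tol & px <= max(a[1], b[1]) + tol &
    py >= min(a[2], b[2]) - tol & py <= max(a[2], b[2]) + tol
  abs(cr) < tol * (max(abs(a), abs(b)) + 1)^2 & within
}

# exact area of the union of convex rings by vertical slab decomposition:
# cut the plane at every vertex x and every pairwise edge-crossing x, so the
# union's vertical extent is linear within each slab and the trapezoid rule
# integrates it exactly
union_area_convex <- function(rings) {
  rings <- Filter(function(r) nrow(r) >= 3 && ring_area(r) > 0, rings)
  if (length(rings) == 0) return(0)
  edges <- do.call(rbind, lapply(rings, function(r) {
    j <- c(2:nrow(r), 1)
    cbind(r[, 1], r[, 2], r[j, 1], r[j, 2])
  }))
  xs <- c(edges[, 1], edges[, 3], edge_crossing_xs(edges))
  xs <- sort(unique(xs))
  if (length(xs) < 2) return(0)
  xrange <- t(vapply(rings, function(r) range(r[, 1]), numeric(2)))
  total <- 0
  for (s in seq_len(length(xs) - 1)) {
    x0 <- xs[s]; x1 <- xs[s + 1]
    active <- which(xrange[, 1] < x1 & xrange[, 2] > x0)
    if (length(active) == 0) next
    l0 <- union_interval_length(rings[active], x0)
    l1 <- union_interval_length(rings[active], x1)
    total <- total + (l0 + l1) / 2 * (x1 - x0)
  }
  total
}

# x-coordinates where two edges properly cross
edge_crossing_xs <- function(edges) {
  ne <- nrow(edges)
  if (ne < 2) return(numeric(0))
  pr <- utils::combn(ne, 2)
  a <- edges[pr[1, ], , drop = FALSE]
  b <- edges[pr[2, ], , drop = FALSE]
  d1x <- a[, 3] - a[, 1]; d1y <- a[, 4] - a[, 2]
  d2x <- b[, 3] - b[, 1]; d2y <- b[, 4] - b[, 2]
  den <- d1x * d2y - d1y * d2x
  ex <- b[, 1] - a[, 1]; ey <- b[, 2] - a[, 2]
  t1 <- (ex * d2y - ey * d2x) / den
  t2 <- (ex * d1y - ey * d1x) / den
  ok <- is.finite(t1) & is.finite(t2) &
    t1 >= 0 & t1 <= 1 & t2 >= 0 & t2 <= 1
  (a[, 1] + t1 * d1x)[ok]
}

# total length of the union of each ring's vertical extent at abscissa x
union_interval_length <- function(rings, x) {
  iv <- do.call(rbind, lapply(rings, ring_y_interval, x = x))
  iv <- iv[!is.na(iv[, 1]), , drop = FALSE]
  if (nrow(iv) == 0) return(0)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  tot <- 0; lo <- iv[1, 1]; hi <- iv[1, 2]
  if (nrow(iv) > 1) {
    for (i in 2:nrow(iv)) {
      if (iv[i, 1] > hi) {
        tot <- tot + hi - lo
        lo <- iv[i, 1]; hi <- iv[i, 2]
      } else hi <- max(hi, iv[i, 2])
    }
  }
  tot + hi - lo
}

# [ymin, ymax] of a convex ring at abscissa x, NA when x outside its range
ring_y_interval <- function(ring, x) {
  xr <- range(ring[, 1])
  if (x < xr[1] || x > xr[2]) return(c(NA_real_, NA_real_))
  x0 <- pmin(pmax(x, xr[1]), xr[2])
  n <- nrow(ring)
  ys <- numeric(0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ax <- ring[i, 1]; bx <- ring[j, 1]
    if (min(ax, bx) <= x0 && x0 <= max(ax, bx)) {
      if (ax == bx) {
        ys <- c(ys, ring[i, 2], ring[j, 2])
      } else {
        t <- (x0 - ax) / (bx - ax)
        ys <- c(ys, ring[i, 2] + t * (ring[j, 2] - ring[i, 2]))
      }
    }
  }
  range(ys)
}
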