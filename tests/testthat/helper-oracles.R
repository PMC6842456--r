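# Independent brute-force reference implementations used only by tests.
# They share no code with the package: plain loops, their own hull/area/
# containment routines.

# --- visit statistics ------------------------------------------------------

oracle_visits <- function(fixes, spec, ivg_hours) {
  cells <- list(); visits <- list()
  for (id in unique(fixes$individual_id)) {
    fi <- fixes[fixes$individual_id == id, ]
    col <- floor((fi$x - spec$origin_x) / spec$cell_size)
    row <- floor((fi$y - spec$origin_y) / spec$cell_size)
    key <- paste0(col, "_", row)
    for (kc in unique(key)) {
      ts <- sort(fi$t[key == kc])
      starts <- 1L
      if (length(ts) > 1) {
        for (i in 2:length(ts)) {
          gap <- as.numeric(difftime(ts[i], ts[i - 1], units = "hours"))
          if (gap > ivg_hours) starts <- c(starts, i)
        }
      }
      ends <- c(starts[-1] - 1L, length(ts))
      sizes <- ends - starts + 1L
      cells[[length(cells) + 1]] <- data.frame(
        individual_id = id, cell_id = kc, n_fixes = length(ts),
        nsv = length(starts), mlsv = mean(sizes),
        stringsAsFactors = FALSE)
      for (v in seq_along(starts)) {
        visits[[length(visits) + 1]] <- data.frame(
          individual_id = id, cell_id = kc, visit = v,
          first_t = ts[starts[v]], last_t = ts[ends[v]],
          n_locations = sizes[v], stringsAsFactors = FALSE)
      }
    }
  }
  list(cells = do.call(rbind, cells), visits = do.call(rbind, visits))
}

# --- k-LoCoH ---------------------------------------------------------------

# Andrew's monotone chain, counter-clockwise ring
oracle_hull <- function(x, y) {
  o <- order(x, y)
  x <- x[o]; y <- y[o]
  n <- length(x)
  if (n == 1) return(cbind(x, y))
  cross <- function(ox, oy, ax, ay, bx, by) {
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  }
  lower <- integer(0)
  for (i in seq_len(n)) {
    while (length(lower) >= 2 &&
           cross(x[lower[length(lower) - 1]], y[lower[length(lower) - 1]],
                 x[lower[length(lower)]], y[lower[length(lower)]],
                 x[i], y[i]) <= 0) {
      lower <- lower[-length(lower)]
    }
    lower <- c(lower, i)
  }
  upper <- integer(0)
  for (i in rev(seq_len(n))) {
    while (length(upper) >= 2 &&
           cross(x[upper[length(upper) - 1]], y[upper[length(upper) - 1]],
                 x[upper[length(upper)]], y[upper[length(upper)]],
                 x[i], y[i]) <= 0) {
      upper <- upper[-length(upper)]
    }
    upper <- c(upper, i)
  }
  idx <- c(lower[-length(lower)], upper[-length(upper)])
  ring <- cbind(x[idx], y[idx])
  if (nrow(ring) >= 3) {
    s <- 0
    for (i in seq_len(nrow(ring))) {
      j <- if (i == nrow(ring)) 1 else i + 1
      s <- s + ring[i, 1] * ring[j, 2] - ring[j, 1] * ring[i, 2]
    }
    if (s < 0) ring <- ring[rev(seq_len(nrow(ring))), , drop = FALSE]
  }
  ring
}

oracle_ring_area <- function(ring) {
  n <- nrow(ring)
  if (n < 3) return(0)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    s <- s + ring[i, 1] * ring[j, 2] - ring[j, 1] * ring[i, 2]
  }
  abs(s) / 2
}

oracle_in_convex <- function(px, py, ring, tol = 1e-9) {
  n <- nrow(ring)
  if (n < 3) {
    return(vapply(seq_along(px), function(i) {
      min(sqrt((ring[, 1] - px[i])^2 + (ring[, 2] - py[i])^2)) < tol
    }, logical(1)))
  }
  scale <- max(abs(ring)) + 1
  out <- rep(TRUE, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    cr <- (ring[j, 1] - ring[i, 1]) * (py - ring[i, 2]) -
      (ring[j, 2] - ring[i, 2]) * (px - ring[i, 1])
    out <- out & (cr >= -tol * scale^2)
  }
  out
}

# union area of convex rings: trapezoid over slabs cut at vertices and
# pairwise segment crossings (independent, loop-based)
oracle_union_area <- function(rings) {
  rings <- Filter(function(r) nrow(r) >= 3 && oracle_ring_area(r) > 0, rings)
  if (length(rings) == 0) return(0)
  segs <- list()
  for (r in rings) {
    for (i in seq_len(nrow(r))) {
      j <- if (i == nrow(r)) 1 else i + 1
      segs[[length(segs) + 1]] <- c(r[i, 1], r[i, 2], r[j, 1], r[j, 2])
    }
  }
  xs <- unlist(lapply(segs, function(s) c(s[1], s[3])))
  if (length(segs) > 1) {
    for (a in 1:(length(segs) - 1)) {
      for (b in (a + 1):length(segs)) {
        s1 <- segs[[a]]; s2 <- segs[[b]]
        d1x <- s1[3] - s1[1]; d1y <- s1[4] - s1[2]
        d2x <- s2[3] - s2[1]; d2y <- s2[4] - s2[2]
        den <- d1x * d2y - d1y * d2x
        if (den == 0) next
        t1 <- ((s2[1] - s1[1]) * d2y - (s2[2] - s1[2]) * d2x) / den
        t2 <- ((s2[1] - s1[1]) * d1y - (s2[2] - s1[2]) * d1x) / den
        if (t1 >= 0 && t1 <= 1 && t2 >= 0 && t2 <= 1) {
          xs <- c(xs, s1[1] + t1 * d1x)
        }
      }
    }
  }
  xs <- sort(unique(xs))
  interval_at <- function(r, x) {
    lo <- Inf; hi <- -Inf
    for (i in seq_len(nrow(r))) {
      j <- if (i == nrow(r)) 1 else i + 1
      ax <- r[i, 1]; bx <- r[j, 1]
      if (min(ax, bx) <= x && x <= max(ax, bx)) {
        if (ax == bx) {
          lo <- min(lo, r[i, 2], r[j, 2]); hi <- max(hi, r[i, 2], r[j, 2])
        } else {
          t <- (x - ax) / (bx - ax)
          yy <- r[i, 2] + t * (r[j, 2] - r[i, 2])
          lo <- min(lo, yy); hi <- max(hi, yy)
        }
      }
    }
    c(lo, hi)
  }
  union_len <- function(ivs) {
    if (nrow(ivs) == 0) return(0)
    ivs <- ivs[order(ivs[, 1]), , drop = FALSE]
    tot <- 0; lo <- ivs[1, 1]; hi <- ivs[1, 2]
    for (i in seq_len(nrow(ivs))[-1]) {
      if (ivs[i, 1] > hi) { tot <- tot + hi - lo; lo <- ivs[i, 1]; hi <- ivs[i, 2] }
      else hi <- max(hi, ivs[i, 2])
    }
    tot + hi - lo
  }
  total <- 0
  for (s in seq_len(length(xs) - 1)) {
    x0 <- xs[s]; x1 <- xs[s + 1]
    l <- c(0, 0)
    for (side in 1:2) {
      x <- c(x0, x1)[side]
      ivs <- matrix(numeric(0), ncol = 2)
      for (r in rings) {
        xr <- range(r[, 1])
        if (xr[1] < x1 && xr[2] > x0 && x >= xr[1] && x <= xr[2]) {
          ivs <- rbind(ivs, interval_at(r, x))
        }
      }
      l[side] <- union_len(ivs)
    }
    total <- total + (l[1] + l[2]) / 2 * (x1 - x0)
  }
  total
}

oracle_locoh <- function(fixes, k, level) {
  fixes <- fixes[order(fixes$t), ]
  n <- nrow(fixes); x <- fixes$x; y <- fixes$y
  hulls <- vector("list", n); area <- numeric(n); encl <- integer(n)
  for (i in seq_len(n)) {
    d <- sqrt((x - x[i])^2 + (y - y[i])^2)
    nb <- order(d, seq_len(n))[seq_len(k)]
    hulls[[i]] <- oracle_hull(x[nb], y[nb])
    area[i] <- oracle_ring_area(hulls[[i]])
    encl[i] <- sum(oracle_in_convex(x, y, hulls[[i]]))
  }
  ord <- order(area, -encl, seq_len(n))
  covered <- rep(FALSE, n); used <- integer(0)
  for (i in ord) {
    used <- c(used, i)
    covered <- covered | oracle_in_convex(x, y, hulls[[i]])
    if (sum(covered) >= level * n - 1e-9) break
  }
  list(covered = covered, n_covered = sum(covered),
       area = oracle_union_area(hulls[used]), n_hulls = length(used))
}
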