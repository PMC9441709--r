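# Planar geometry primitives on a local metric CRS.
#
# All layers live in one projected plane (units: meters), so Euclidean
# formulas are exact: segment-circle clipping for road length in buffers,
# point-segment distance for nearest-road variables, Liang-Barsky clipping
# for segment-rectangle tests. Buffers are closed disks: boundary features
# count as inside.

# Length of the chord of segment (x0,y0)-(x1,y1) inside the closed disk of
# radius r centered at (cx, cy). Vectorised over circles (cx, cy may be
# vectors); the segment is scalar.
seg_length_in_disk <- function(x0, y0, x1, y1, cx, cy, r) {
  dx <- x1 - x0
  dy <- y1 - y0
  a <- dx * dx + dy * dy
  if (a == 0) return(numeric(length(cx)))
  fx <- x0 - cx
  fy <- y0 - cy
  b <- 2 * (dx * fx + dy * fy)
  cc <- fx * fx + fy * fy - r * r
  disc <- b * b - 4 * a * cc
  out <- numeric(length(cx))
  ok <- disc > 0
  if (!any(ok)) return(out)
  sq <- sqrt(disc[ok])
  t1 <- pmax((-b[ok] - sq) / (2 * a), 0)
  t2 <- pmin((-b[ok] + sq) / (2 * a), 1)
  out[ok] <- pmax(t2 - t1, 0) * sqrt(a)
  out
}

# Distance from points (px, py) to segment (x0,y0)-(x1,y1); vectorised over
# points.
point_seg_dist <- function(px, py, x0, y0, x1, y1) {
  dx <- x1 - x0
  dy <- y1 - y0
  a <- dx * dx + dy * dy
  if (a == 0) return(sqrt((px - x0)^2 + (py - y0)^2))
  t <- pmin(pmax(((px - x0) * dx + (py - y0) * dy) / a, 0), 1)
  sqrt((px - x0 - t * dx)^2 + (py - y0 - t * dy)^2)
}

# Minimum distance from each point to any segment in `segs`
# (data frame with x0, y0, x1, y1). Inf when segs is empty.
min_dist_to_segments <- function(px, py, segs) {
  d <- rep(Inf, length(px))
  for (i in seq_len(nrow(segs))) {
    d <- pmin(d, point_seg_dist(px, py, segs$x0[i], segs$y0[i],
                                segs$x1[i], segs$y1[i]))
  }
  d
}

# Distance from points to an axis-aligned rectangle (0 inside).
point_rect_dist <- function(px, py, rect) {
  dx <- pmax(rect$xmin - px, 0, px - rect$xmax)
  dy <- pmax(rect$ymin - py, 0, py - rect$ymax)
  sqrt(dx * dx + dy * dy)
}

point_in_rect <- function(px, py, rect) {
  px >= rect$xmin & px <= rect$xmax & py >= rect$ymin & py <= rect$ymax
}

# TRUE for each rectangle (vectors xmin..ymax) that the segment touches.
# Liang-Barsky parametric clipping, vectorised over rectangles.
seg_intersects_rect <- function(x0, y0, x1, y1, xmin, xmax, ymin, ymax) {
  dx <- x1 - x0
  dy <- y1 - y0
  t0 <- rep(0, length(xmin))
  t1 <- rep(1, length(xmin))
  ok <- rep(TRUE, length(xmin))
  clip <- function(p, q) {
    # p * t <= q
    if (p == 0) {
      ok <<- ok & (q >= 0)
    } else if (p < 0) {
      t0 <<- pmax(t0, q / p)
    } else {
      t1 <<- pmin(t1, q / p)
    }
  }
  # p, q can be vectors over rectangles
  clip_vec <- function(p, q) {
    if (length(p) == 1) p <- rep(p, length(q))
    zero <- p == 0
    ok <<- ok & (!zero | q >= 0)
    neg <- p < 0
    pos <- p > 0
    if (any(neg)) t0[neg] <<- pmax(t0[neg], q[neg] / p[neg])
    if (any(pos)) t1[pos] <<- pmin(t1[pos], q[pos] / p[pos])
  }
  clip_vec(-dx, x0 - xmin)
  clip_vec(dx, xmax - x0)
  clip_vec(-dy, y0 - ymin)
  clip_vec(dy, ymax - y0)
  ok & (t0 <= t1)
}

# Clip an infinite line through (x, y) at angle `theta` to the extent
# rectangle; returns c(x0, y0, x1, y1) or NULL when outside.
clip_line_to_extent <- function(x, y, theta, extent) {
  dx <- cos(theta)
  dy <- sin(theta)
  big <- 2 * max(extent$xmax - extent$xmin, extent$ymax - extent$ymin) + 10
  x0 <- x - big * dx; y0 <- y - big * dy
  x1 <- x + big * dx; y1 <- y + big * dy
  # Liang-Barsky on the long segment
  t0 <- 0; t1 <- 1
  p <- c(-(x1 - x0), x1 - x0, -(y1 - y0), y1 - y0)
  q <- c(x0 - extent$xmin, extent$xmax - x0, y0 - extent$ymin, extent$ymax - y0)
  for (i in 1:4) {
    if (p[i] == 0) {
      if (q[i] < 0) return(NULL)
    } else {
      t <- q[i] / p[i]
      if (p[i] < 0) t0 <- max(t0, t) else t1 <- min(t1, t)
    }
  }
  if (t0 > t1) return(NULL)
  c(x0 + t0 * (x1 - x0), y0 + t0 * (y1 - y0),
    x0 + t1 * (x1 - x0), y0 + t1 * (y1 - y0))
}

## ---- in-memory single-band raster -------------------------------------

# Row 1 is the southernmost row; cell centers at origin + (index - 0.5) * res.
nl_raster <- function(values, origin, res) {
  stopifnot(is.matrix(values), res > 0)
  structure(
    list(values = values, origin = origin, res = res,
         nrow = nrow(values), ncol = ncol(values)),
    class = "nl_raster"
  )
}

raster_cell_centers <- function(r) {
  x <- r$origin[1] + (seq_len(r$ncol) - 0.5) * r$res
  y <- r$origin[2] + (seq_len(r$nrow) - 0.5) * r$res
  list(x = x, y = y)
}

# Nearest-cell lookup, clamped to the raster edge.
raster_value_at <- function(r, px, py) {
  j <- pmin(pmax(ceiling((px - r$origin[1]) / r$res), 1L), r$ncol)
  i <- pmin(pmax(ceiling((py - r$origin[2]) / r$res), 1L), r$nrow)
  r$values[cbind(i, j)]
}

# Values of cells whose centers fall within the closed disk of radius
# `radius` around (px, py). Scalar location.
raster_values_in_disk <- function(r, px, py, radius) {
  j0 <- max(1L, ceiling((px - radius - r$origin[1]) / r$res))
  j1 <- min(r$ncol, ceiling((px + radius - r$origin[1]) / r$res))
  i0 <- max(1L, ceiling((py - radius - r$origin[2]) / r$res))
  i1 <- min(r$nrow, ceiling((py + radius - r$origin[2]) / r$res))
  if (j0 > j1 || i0 > i1) return(r$values[0])
  jj <- j0:j1
  ii <- i0:i1
  cxs <- r$origin[1] + (jj - 0.5) * r$res
  cys <- r$origin[2] + (ii - 0.5) * r$res
  dx2 <- (cxs - px)^2
  dy2 <- (cys - py)^2
  inside <- outer(dy2, dx2, "+") <= radius^2
  r$values[ii, jj, drop = FALSE][inside]
}
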