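# Planar polygon primitives. A "ring" is a two-column matrix of (x, y)
# vertices in metres; rings need not repeat the first vertex. A "polygon"
# is list(exterior = ring, holes = list(ring, ...)).

.close_ring <- function(ring) {
  if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  ring
}

.open_ring <- function(ring) {
  if (nrow(ring) > 1 && all(ring[1, ] == ring[nrow(ring), ]))
    ring <- ring[-nrow(ring), , drop = FALSE]
  ring
}

# Signed shoelace area (positive = counter-clockwise)
ring_area_signed <- function(ring) {
  r <- .open_ring(ring)
  x <- r[, 1]; y <- r[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

ring_area <- function(ring) abs(ring_area_signed(ring))

polygon_area <- function(polygon) {
  a <- ring_area(polygon$exterior)
  for (h in polygon$holes) a <- a - ring_area(h)
  a
}

# Even-odd ray-crossing membership with a half-open tie rule: a point on a
# "left" boundary of a region is inside, on a "right" boundary outside, so a
# partition of the plane assigns every point to exactly one polygon.
# px, py: point vectors; returns logical vector.
points_in_ring <- function(px, py, ring) {
  r <- .open_ring(ring)
  n <- nrow(r)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- r[i, 1]; yi <- r[i, 2]; xj <- r[j, 1]; yj <- r[j, 2]
    crosses <- (yi > py) != (yj > py)
    if (any(crosses)) {
      xint <- xi + (py[crosses] - yi) * (xj - xi) / (yj - yi)
      idx <- which(crosses)[px[crosses] < xint]
      inside[idx] <- !inside[idx]
    }
    j <- i
  }
  inside
}

points_in_polygon <- function(px, py, polygon) {
  inside <- points_in_ring(px, py, polygon$exterior)
  for (h in polygon$holes) inside <- inside & !points_in_ring(px, py, h)
  inside
}

# Proper-intersection test between segments p1-p2 and p3-p4 (shared endpoints
# of adjacent edges are not flagged by the caller).
.segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
   ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

# TRUE when the ring is simple (no two non-adjacent edges cross)
ring_is_simple <- function(ring) {
  r <- .open_ring(ring)
  n <- nrow(r)
  if (n < 3) return(FALSE)
  edges <- lapply(seq_len(n), function(i) {
    list(r[i, ], r[if (i == n) 1 else i + 1, ])
  })
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (j == i + 1 || (i == 1 && j == n)) next  # adjacent edges share a vertex
      if (.segments_cross(edges[[i]][[1]], edges[[i]][[2]],
                          edges[[j]][[1]], edges[[j]][[2]]))
        return(FALSE)
    }
  }
  TRUE
}

# Sutherland-Hodgman clip of a ring to an axis-aligned rectangle
# rect = c(xmin, ymin, xmax, ymax). Returns a ring (possibly 0 rows).
clip_ring_to_rect <- function(ring, rect) {
  subject <- .open_ring(ring)
  clip_one <- function(pts, keep, intersect) {
    if (nrow(pts) == 0) return(pts)
    out <- matrix(numeric(0), ncol = 2)
    n <- nrow(pts)
    for (i in seq_len(n)) {
      cur <- pts[i, ]; prv <- pts[if (i == 1) n else i - 1, ]
      cur_in <- keep(cur); prv_in <- keep(prv)
      if (cur_in) {
        if (!prv_in) out <- rbind(out, intersect(prv, cur))
        out <- rbind(out, cur)
      } else if (prv_in) {
        out <- rbind(out, intersect(prv, cur))
      }
    }
    out
  }
  ix <- function(p, q, val, axis) {
    t <- (val - p[axis]) / (q[axis] - p[axis])
    p + t * (q - p)
  }
  s <- subject
  s <- clip_one(s, function(p) p[1] >= rect[1], function(p, q) ix(p, q, rect[1], 1))
  s <- clip_one(s, function(p) p[2] >= rect[2], function(p, q) ix(p, q, rect[2], 2))
  s <- clip_one(s, function(p) p[1] <= rect[3], function(p, q) ix(p, q, rect[3], 1))
  s <- clip_one(s, function(p) p[2] <= rect[4], function(p, q) ix(p, q, rect[4], 2))
  s
}

# Area of a polygon after clipping to a rectangle
clipped_polygon_area <- function(polygon, rect) {
  a <- 0
  ext <- clip_ring_to_rect(polygon$exterior, rect)
  if (nrow(ext) >= 3) a <- ring_area(ext)
  for (h in polygon$holes) {
    hc <- clip_ring_to_rect(h, rect)
    if (nrow(hc) >= 3) a <- a - ring_area(hc)
  }
  max(a, 0)
}

# Regular n-gon approximating a circle, counter-clockwise
circle_ring <- function(cx, cy, radius, n = 64L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(cx + radius * cos(th), cy + radius * sin(th))
}

rect_ring <- function(xmin, ymin, xmax, ymax) {
  cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
}
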