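# Internal planar-geometry helpers. Polygons are n x 2 matrices of vertices
# in order, without the first vertex repeated; edges wrap around.

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

.unit <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("cannot normalise a zero vector")
  v / nv
}

.rotate <- function(v, deg) {
  a <- .deg2rad(deg)
  c(cos(a) * v[1] - sin(a) * v[2], sin(a) * v[1] + cos(a) * v[2])
}

# signed angle from u to v, degrees in (-180, 180], positive counterclockwise
.signed_angle <- function(u, v) {
  ang <- .rad2deg(atan2(u[1] * v[2] - u[2] * v[1], sum(u * v)))
  if (ang <= -180) ang <- ang + 360
  ang
}

.as_points <- function(pts) {
  if (is.null(dim(pts))) matrix(pts, ncol = 2) else as.matrix(pts)
}

# Even-odd crossing test; points within 1e-9 of an edge count as inside.
# Hand-vectorised over edges because this sits in the simulator's per-frame
# loop; cross-checked against pracma::inpolygon in the test suite.
.pip_one <- function(x, y, xi, yi, xj, yj, ex, ey, len2) {
  crosses <- ((yi > y) != (yj > y)) &
    (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
  inside <- (sum(crosses, na.rm = TRUE) %% 2) == 1
  if (inside) return(TRUE)
  t <- pmin(pmax(((x - xi) * ex + (y - yi) * ey) / len2, 0), 1)
  d2 <- (x - (xi + t * ex))^2 + (y - (yi + t * ey))^2
  any(d2 <= 1e-18)
}

.point_in_poly <- function(pts, poly) {
  pts <- .as_points(pts)
  n <- nrow(poly)
  j <- c(2:n, 1L)
  xi <- poly[, 1]; yi <- poly[, 2]
  xj <- poly[j, 1]; yj <- poly[j, 2]
  ex <- xj - xi; ey <- yj - yi
  len2 <- pmax(ex^2 + ey^2, 1e-300)
  vapply(seq_len(nrow(pts)), function(i) {
    .pip_one(pts[i, 1], pts[i, 2], xi, yi, xj, yj, ex, ey, len2)
  }, logical(1))
}

# min Euclidean distance from each point to the polygon boundary (edges)
.dist_to_poly <- function(pts, poly) {
  pts <- .as_points(pts)
  n <- nrow(poly)
  d <- rep(Inf, nrow(pts))
  for (i in seq_len(n)) {
    a <- poly[i, ]
    b <- poly[if (i == n) 1L else i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      di <- sqrt((pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2)
    } else {
      t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
      t <- pmin(pmax(t, 0), 1)
      di <- sqrt((pts[, 1] - (a[1] + t * ab[1]))^2 +
                 (pts[, 2] - (a[2] + t * ab[2]))^2)
    }
    d <- pmin(d, di)
  }
  d
}

# do closed segments ab and cd intersect (including touching)?
.seg_intersect <- function(a, b, c, d) {
  o <- function(p, q, r) {
    v <- (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
    if (abs(v) < 1e-12) 0 else sign(v)
  }
  on_seg <- function(p, q, r) {
    min(p[1], q[1]) - 1e-12 <= r[1] && r[1] <= max(p[1], q[1]) + 1e-12 &&
    min(p[2], q[2]) - 1e-12 <= r[2] && r[2] <= max(p[2], q[2]) + 1e-12
  }
  o1 <- o(a, b, c); o2 <- o(a, b, d); o3 <- o(c, d, a); o4 <- o(c, d, b)
  if (o1 != o2 && o3 != o4) return(TRUE)
  (o1 == 0 && on_seg(a, b, c)) || (o2 == 0 && on_seg(a, b, d)) ||
  (o3 == 0 && on_seg(c, d, a)) || (o4 == 0 && on_seg(c, d, b))
}

# parameter t in [0,1] along ab of the crossing with cd, NA if none
.seg_intersect_param <- function(a, b, c, d) {
  r <- b - a
  s <- d - c
  denom <- r[1] * s[2] - r[2] * s[1]
  qp <- c - a
  if (abs(denom) < 1e-14) {
    # parallel: report touch at the nearest endpoint projection if collinear
    if (abs(qp[1] * r[2] - qp[2] * r[1]) > 1e-12) return(NA_real_)
    len2 <- sum(r^2)
    if (len2 == 0) return(NA_real_)
    t0 <- sum(qp * r) / len2
    t1 <- sum((d - a) * r) / len2
    lo <- max(min(t0, t1), 0)
    hi <- min(max(t0, t1), 1)
    if (lo > hi) return(NA_real_)
    return(lo)
  }
  t <- (qp[1] * s[2] - qp[2] * s[1]) / denom
  u <- (qp[1] * r[2] - qp[2] * r[1]) / denom
  if (t < -1e-12 || t > 1 + 1e-12 || u < -1e-12 || u > 1 + 1e-12) return(NA_real_)
  min(max(t, 0), 1)
}

.poly_is_simple <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  edges <- lapply(seq_len(n), function(i) {
    list(a = poly[i, ], b = poly[if (i == n) 1L else i + 1L, ])
  })
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      adjacent <- (j == i + 1) || (i == 1 && j == n)
      if (adjacent) next
      if (.seg_intersect(edges[[i]]$a, edges[[i]]$b, edges[[j]]$a, edges[[j]]$b)) {
        return(FALSE)
      }
    }
  }
  TRUE
}

.poly_centroid <- function(poly) colMeans(poly)

# outward unit normal of the polygon boundary at (or nearest to) a point
.outward_normal <- function(poly, point) {
  n <- nrow(poly)
  j <- c(2:n, 1L)
  ax <- poly[, 1]; ay <- poly[, 2]
  ex <- poly[j, 1] - ax; ey <- poly[j, 2] - ay
  len2 <- ex^2 + ey^2
  len2[len2 == 0] <- NA_real_
  t <- pmin(pmax(((point[1] - ax) * ex + (point[2] - ay) * ey) / len2, 0), 1)
  px <- ax + t * ex; py <- ay + t * ey
  d2 <- (point[1] - px)^2 + (point[2] - py)^2
  i <- which.min(d2)
  if (length(i) == 0) stop("cannot resolve a boundary normal at this point")
  e <- .unit(c(ex[i], ey[i]))
  normal <- c(e[2], -e[1])
  # orient outward: a short step along the normal must leave the polygon
  proj <- c(px[i], py[i])
  probe <- proj + normal * 1e-6 * max(1, sqrt(sum(proj^2)))
  if (.point_in_poly(probe, poly)) normal <- -normal
  normal
}

# first-contact parameter of directed segment ab with a convex band polygon:
# 0 if a is inside, else the smallest crossing parameter; NA if no contact
.seg_band_contact <- function(a, b, band) {
  if (.point_in_poly(a, band)) return(0)
  n <- nrow(band)
  tmin <- NA_real_
  for (i in seq_len(n)) {
    p <- band[i, ]
    q <- band[if (i == n) 1L else i + 1L, ]
    t <- .seg_intersect_param(a, b, p, q)
    if (!is.na(t) && (is.na(tmin) || t < tmin)) tmin <- t
  }
  tmin
}

# reflect a direction vector off a boundary with outward normal nrm
.reflect <- function(dir, nrm) {
  dir - 2 * sum(dir * nrm) * nrm
}

# crossing parameters of every path segment with one edge cd: returns
# s-values (segment index + fraction) of all crossings, vectorised
.crossing_s <- function(pts, c, d) {
  n <- nrow(pts)
  if (n < 2) return(numeric(0))
  ax <- pts[-n, 1]; ay <- pts[-n, 2]
  rx <- pts[-1, 1] - ax; ry <- pts[-1, 2] - ay
  sx <- d[1] - c[1]; sy <- d[2] - c[2]
  denom <- rx * sy - ry * sx
  qpx <- c[1] - ax; qpy <- c[2] - ay
  t <- (qpx * sy - qpy * sx) / denom
  u <- (qpx * ry - qpy * rx) / denom
  ok <- abs(denom) > 1e-14 &
    t >= -1e-12 & t <= 1 + 1e-12 & u >= -1e-12 & u <= 1 + 1e-12
  ok[is.na(ok)] <- FALSE
  which(ok) + pmin(pmax(t[ok], 0), 1)
}
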