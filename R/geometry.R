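# Polygon utilities. Polygons are n x 2 matrices of (x, y) vertices,
# implicitly closed. Point-in-polygon uses the even-odd rule with points on
# an edge counted inside.

#' Point-in-polygon test
#'
#' Even-odd (ray casting) rule; points lying exactly on a polygon edge are
#' counted as inside.
#'
#' @param px,py point coordinates (vectorized).
#' @param poly n x 2 matrix of polygon vertices, implicitly closed.
#' @return logical vector.
#' @examples
#' tri <- cbind(c(0, 4, 0), c(0, 0, 4))
#' pointInPolygon(c(1, 5, 0), c(1, 5, 2), tri)
#' @export
pointInPolygon <- function(px, py, poly) {
  stopifnot(length(px) == length(py))
  n <- nrow(poly)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- poly[c(2:n, 1), 1]; y2 <- poly[c(2:n, 1), 2]
  inside <- rep(FALSE, length(px))
  onedge <- rep(FALSE, length(px))
  scale <- max(abs(poly), 1)
  for (e in seq_len(n)) {
    ex1 <- x1[e]; ey1 <- y1[e]; ex2 <- x2[e]; ey2 <- y2[e]
    dx <- ex2 - ex1; dy <- ey2 - ey1
    len2 <- dx * dx + dy * dy
    if (len2 > 0) {
      cross <- (px - ex1) * dy - (py - ey1) * dx
      tt <- ((px - ex1) * dx + (py - ey1) * dy) / len2
      onedge <- onedge |
        (abs(cross) <= 1e-9 * sqrt(len2) * scale & tt >= 0 & tt <= 1)
      crosses <- ((ey1 > py) != (ey2 > py)) &
        (px < ex1 + (py - ey1) * dx / dy)
      crosses[is.na(crosses)] <- FALSE
      inside <- xor(inside, crosses)
    }
  }
  inside | onedge
}

# Shoelace area (absolute value).
.polyArea <- function(poly) {
  n <- nrow(poly)
  x <- poly[, 1]; y <- poly[, 2]
  xs <- poly[c(2:n, 1), 1]; ys <- poly[c(2:n, 1), 2]
  abs(sum(x * ys - xs * y)) / 2
}

# Simple-polygon check: no two non-adjacent edges intersect. O(n^2).
.polyIsSimple <- function(poly) {
  n <- nrow(poly)
  p1 <- poly
  p2 <- poly[c(2:n, 1), , drop = FALSE]
  segInt <- function(a1, a2, b1, b2) {
    d1 <- (b2[1] - b1[1]) * (a1[2] - b1[2]) - (b2[2] - b1[2]) * (a1[1] - b1[1])
    d2 <- (b2[1] - b1[1]) * (a2[2] - b1[2]) - (b2[2] - b1[2]) * (a2[1] - b1[1])
    d3 <- (a2[1] - a1[1]) * (b1[2] - a1[2]) - (a2[2] - a1[2]) * (b1[1] - a1[1])
    d4 <- (a2[1] - a1[1]) * (b2[2] - a1[2]) - (a2[2] - a1[2]) * (b2[1] - a1[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      if (segInt(p1[i, ], p2[i, ], p1[j, ], p2[j, ])) return(FALSE)
    }
  }
  TRUE
}

# All vertices of `inner` inside `outer` (sufficient for our convex-ish
# generated shapes, and what the outline-file validation needs).
.polyInside <- function(inner, outer) {
  all(pointInPolygon(inner[, 1], inner[, 2], outer))
}

# Uniform rejection sampling of n points inside `poly`, optionally excluding
# points inside `exclude`.
.sampleInPolygon <- function(n, poly, exclude = NULL, maxit = 200L) {
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  out <- matrix(NA_real_, 0, 2)
  for (it in seq_len(maxit)) {
    m <- max(2L * (n - nrow(out)), 8L)
    px <- runif(m, xr[1], xr[2]); py <- runif(m, yr[1], yr[2])
    ok <- pointInPolygon(px, py, poly)
    if (!is.null(exclude)) ok <- ok & !pointInPolygon(px, py, exclude)
    out <- rbind(out, cbind(px[ok], py[ok]))
    if (nrow(out) >= n) break
  }
  if (nrow(out) < n) stop("failed to sample points inside polygon")
  colnames(out) <- c("x", "y")
  out[seq_len(n), , drop = FALSE]
}

# Distance from point (px, py) to the polygon boundary (min over segments).
.distToBoundary <- function(px, py, poly) {
  n <- nrow(poly)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- poly[c(2:n, 1), 1]; y2 <- poly[c(2:n, 1), 2]
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- pmax(dx * dx + dy * dy, .Machine$double.eps)
  tt <- pmin(pmax(((px - x1) * dx + (py - y1) * dy) / len2, 0), 1)
  qx <- x1 + tt * dx; qy <- y1 + tt * dy
  min(sqrt((px - qx)^2 + (py - qy)^2))
}

# Distances from many points to the polygon boundary at once
# (points x segments).
.distToBoundaryMany <- function(px, py, poly) {
  n <- nrow(poly)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- poly[c(2:n, 1), 1]; y2 <- poly[c(2:n, 1), 2]
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- pmax(dx * dx + dy * dy, .Machine$double.eps)
  tt <- (outer(px, x1, "-") * rep(dx, each = length(px)) +
         outer(py, y1, "-") * rep(dy, each = length(px)))
  tt <- pmin(pmax(sweep(tt, 2, len2, "/"), 0), 1)
  qx <- rep(x1, each = length(px)) + tt * rep(dx, each = length(px))
  qy <- rep(y1, each = length(px)) + tt * rep(dy, each = length(px))
  dd <- (px - qx)^2 + (py - qy)^2
  sqrt(apply(dd, 1, min))
}

# Largest inscribed circle: coarse interior grid search refined with
# Nelder-Mead on the signed distance (negative outside).
.maxInscribedCircle <- function(poly, gridN = 17L) {
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  gx <- seq(xr[1], xr[2], length.out = gridN)
  gy <- seq(yr[1], yr[2], length.out = gridN)
  gg <- expand.grid(x = gx, y = gy)
  ok <- pointInPolygon(gg$x, gg$y, poly)
  gg <- gg[ok, , drop = FALSE]
  if (nrow(gg) == 0L) stop("degenerate polygon")
  d <- .distToBoundaryMany(gg$x, gg$y, poly)
  best <- which.max(d)
  sdist <- function(p) {
    s <- if (pointInPolygon(p[1], p[2], poly)) 1 else -1
    -s * .distToBoundary(p[1], p[2], poly)
  }
  opt <- stats::optim(c(gg$x[best], gg$y[best]), sdist,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-7, maxit = 250))
  list(center = opt$par, radius = -opt$value)
}
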