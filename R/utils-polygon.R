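# Polygon primitives shared by the synthetic tessellation generator and the
# label-image geometry extractor. Polygons are n x 2 matrices (x, y), implicitly
# closed (last vertex connects back to the first), in micron coordinates unless
# noted.

#' Area of a simple polygon
#'
#' Shoelace formula; vertex order may be clockwise or counterclockwise.
#'
#' @param poly Numeric matrix with two columns (x, y); implicitly closed.
#' @return Non-negative area in squared input units.
#' @export
polygon_area <- function(poly) {
  poly <- as.matrix(poly)
  if (nrow(poly) < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(2:nrow(poly), 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Perimeter of a closed polygon
#'
#' @inheritParams polygon_area
#' @return Total edge length.
#' @export
polygon_perimeter <- function(poly) {
  poly <- as.matrix(poly)
  if (nrow(poly) < 2) return(0)
  j <- c(2:nrow(poly), 1L)
  sum(sqrt(rowSums((poly[j, , drop = FALSE] - poly)^2)))
}

polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(2:nrow(poly), 1L)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(poly))
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * a)
}

#' Vertices of a regular polygon
#'
#' @param n Number of sides (>= 3).
#' @param side Side length.
#' @param center Numeric length-2 center.
#' @return `n` x 2 vertex matrix.
#' @export
regular_polygon <- function(n, side = 1, center = c(0, 0)) {
  stopifnot(n >= 3, side > 0)
  r <- side / (2 * sin(pi / n))
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

# Sutherland-Hodgman clip of a convex polygon by the half-plane
# a*x + b*y <= c. Returns possibly empty matrix.
clip_halfplane <- function(poly, a, b, c) {
  n <- nrow(poly)
  f <- a * poly[, 1] + b * poly[, 2] - c
  out <- vector("list", 2L * n)
  k <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (f[i] <= 0) { k <- k + 1L; out[[k]] <- poly[i, ] }
    if (f[i] * f[j] < 0) {
      t <- f[i] / (f[i] - f[j])
      k <- k + 1L; out[[k]] <- poly[i, ] + t * (poly[j, ] - poly[i, ])
    }
  }
  if (k == 0L) return(matrix(numeric(0), ncol = 2))
  do.call(rbind, out[seq_len(k)])
}

#' Voronoi cells of a point set, clipped to a rectangle
#'
#' Computes each cell as the intersection of perpendicular-bisector
#' half-planes, clipped to the bounding box. Exact to floating point, so the
#' result doubles as a ground-truth polygon oracle for rasterized
#' tessellations.
#'
#' @param seeds n x 2 matrix of generating points.
#' @param xlim,ylim Length-2 ranges of the bounding rectangle.
#' @return List of polygon matrices, one per seed (possibly with 0 rows if a
#'   seed lies outside the box).
#' @export
voronoi_polygons <- function(seeds, xlim, ylim) {
  seeds <- as.matrix(seeds)
  n <- nrow(seeds)
  box <- cbind(c(xlim[1], xlim[2], xlim[2], xlim[1]),
               c(ylim[1], ylim[1], ylim[2], ylim[2]))
  lapply(seq_len(n), function(i) {
    poly <- box
    for (j in seq_len(n)[-i]) {
      d <- seeds[j, ] - seeds[i, ]
      m <- (seeds[i, ] + seeds[j, ]) / 2
      poly <- clip_halfplane(poly, d[1], d[2], sum(d * m))
      if (nrow(poly) < 3) break
    }
    poly
  })
}

# Chaikin corner cutting on a closed polygon; each pass replaces every vertex
# by the 1/4 and 3/4 points of its outgoing edge.
chaikin_smooth <- function(poly, passes = 2) {
  for (p in seq_len(passes)) {
    n <- nrow(poly)
    j <- c(2:n, 1L)
    q <- 0.75 * poly + 0.25 * poly[j, , drop = FALSE]
    r <- 0.25 * poly + 0.75 * poly[j, , drop = FALSE]
    out <- matrix(0, 2L * n, 2L)
    out[seq(1, 2L * n, 2), ] <- q
    out[seq(2, 2L * n, 2), ] <- r
    poly <- out
  }
  poly
}

# Douglas-Peucker simplification of a closed polygon (tolerance eps in the
# polygon's units). Used to recover straight cell edges from the pixel-level
# marching-squares staircase before measuring perimeter.
dp_simplify_closed <- function(poly, eps) {
  n <- nrow(poly)
  if (n <= 4) return(poly)
  # anchor at the two most distant vertices to avoid degenerate closure
  a <- 1L
  b <- which.max(rowSums((poly - matrix(poly[a, ], n, 2, byrow = TRUE))^2))
  keep <- rep(FALSE, n)
  keep[c(a, b)] <- TRUE
  simplify_range <- function(i, j) {
    # vertices strictly between i and j walking forward (cyclic)
    idx <- if (i < j) seq(i + 1L, j - 1L) else c(seq(i + 1L, n), seq_len(j - 1L))
    if (length(idx) == 0) return(invisible())
    p0 <- poly[i, ]; p1 <- poly[j, ]
    ab <- p1 - p0; L <- sqrt(sum(ab^2))
    d <- if (L < 1e-12) {
      sqrt(rowSums((poly[idx, , drop = FALSE] -
                      matrix(p0, length(idx), 2, byrow = TRUE))^2))
    } else {
      abs(ab[2] * (poly[idx, 1] - p0[1]) - ab[1] * (poly[idx, 2] - p0[2])) / L
    }
    k <- which.max(d)
    if (d[k] > eps) {
      m <- idx[k]
      keep[m] <<- TRUE
      simplify_range(i, m)
      simplify_range(m, j)
    }
    invisible()
  }
  simplify_range(a, b)
  simplify_range(b, a)
  poly[keep, , drop = FALSE]
}
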