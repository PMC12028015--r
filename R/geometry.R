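# Small 2-D polygon utilities shared by the atlas, simulator and
# registration modules. All coordinates are in micrometres, origin at the
# top-left corner of the image frame, y increasing downward. Polygons are
# two-column matrices of vertices (closed implicitly; the last vertex is
# joined back to the first).

#' Polygon area by the shoelace formula
#'
#' @param poly two-column numeric matrix of vertices (x, y) in µm.
#' @return Absolute enclosed area in µm².
#' @export
polygon_area <- function(poly) {
  poly <- as.matrix(poly)
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Even-odd point-in-polygon test
#'
#' Ray-crossing (even-odd) rule, vectorized over points. Points exactly on
#' an edge are resolved by the half-open convention of the crossing test;
#' region assignment gets its determinism from atlas ordering, not from
#' this function.
#'
#' @param x,y numeric vectors of point coordinates (µm).
#' @param poly two-column vertex matrix.
#' @return Logical vector, `TRUE` for points inside.
#' @export
points_in_polygon <- function(x, y, poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  inside <- logical(length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Subdivide polygon edges to a maximum segment length
#'
#' Inserts evenly spaced vertices along each edge so that no segment exceeds
#' `max_seg_um`. Used before applying a nonlinear warp so curved
#' deformations of straight atlas edges are preserved.
#'
#' @param poly two-column vertex matrix.
#' @param max_seg_um maximum segment length in µm (> 0).
#' @return Densified vertex matrix.
#' @export
densify_polygon <- function(poly, max_seg_um) {
  stopifnot(max_seg_um > 0)
  poly <- as.matrix(poly)
  n <- nrow(poly)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    a <- poly[i, ]
    b <- poly[if (i == n) 1L else i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    k <- max(1L, ceiling(len / max_seg_um))
    t <- seq(0, 1, length.out = k + 1L)[-(k + 1L)]
    out[[i]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }
  do.call(rbind, out)
}

# Proper intersection test between segments p1-p2 and p3-p4 (shared
# endpoints do not count). Used to flag self-intersecting warped polygons.
.segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

#' Test whether a polygon is simple (non-self-intersecting)
#'
#' Quadratic sweep over non-adjacent edge pairs; adequate for atlas-sized
#' polygons (hundreds of vertices).
#'
#' @param poly two-column vertex matrix.
#' @return `TRUE` if no two non-adjacent edges properly intersect.
#' @export
polygon_is_simple <- function(poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  if (n < 4) return(TRUE)
  nxt <- function(i) if (i == n) 1L else i + 1L
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      # skip adjacent edges (sharing a vertex)
      if (j == i || nxt(i) == j || nxt(j) == i) next
      if (.segments_cross(poly[i, ], poly[nxt(i), ],
                          poly[j, ], poly[nxt(j), ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

# Uniform rejection sampling of n points inside a polygon. Uses the
# polygon's bounding box as the proposal; draws in batches.
.sample_points_in_polygon <- function(n, poly) {
  if (n == 0L) {
    return(cbind(x = numeric(0), y = numeric(0)))
  }
  poly <- as.matrix(poly)
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  got_x <- numeric(0); got_y <- numeric(0)
  while (length(got_x) < n) {
    m <- max(2L * (n - length(got_x)), 32L)
    px <- stats::runif(m, xr[1], xr[2])
    py <- stats::runif(m, yr[1], yr[2])
    keep <- points_in_polygon(px, py, poly)
    got_x <- c(got_x, px[keep]); got_y <- c(got_y, py[keep])
  }
  cbind(x = got_x[seq_len(n)], y = got_y[seq_len(n)])
}
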