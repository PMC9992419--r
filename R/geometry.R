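# Planar geometry helpers shared by the generator and the measurement stages.
# All coordinates are physical micrometres, 0-based, y-down; pixel (i, j)
# (1-based indices, x first) has its centre at ((i - 0.5) * s, (j - 0.5) * s)
# for pixel size s.

#' Signed/absolute area of a simple polygon (shoelace formula)
#'
#' @param poly data.frame or matrix with columns x, y (um); the polygon is
#'   closed implicitly (last vertex joins the first).
#' @return area in um^2 (non-negative)
#' @export
polygon_area <- function(poly) {
  p <- as.matrix(poly[, c("x", "y")])
  n <- nrow(p)
  if (n < 3L) stopf("polygon needs at least 3 vertices")
  i2 <- c(2:n, 1L)
  abs(sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2])) / 2
}

#' Test whether a polygon is simple (no self-intersections)
#'
#' Quadratic sweep over all non-adjacent edge pairs; polygons here have tens
#' of vertices, so this is cheap.
#'
#' @param poly data.frame with columns x, y
#' @return logical
#' @export
polygon_is_simple <- function(poly) {
  p <- as.matrix(poly[, c("x", "y")])
  n <- nrow(p)
  if (n < 3L) return(FALSE)
  seg_a <- p
  seg_b <- p[c(2:n, 1L), , drop = FALSE]
  cross2 <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      # skip adjacent edges (they share an endpoint)
      if (j == i + 1L || (i == 1L && j == n)) next
      d1 <- cross2(seg_a[i, 1], seg_a[i, 2], seg_b[i, 1], seg_b[i, 2], seg_a[j, 1], seg_a[j, 2])
      d2 <- cross2(seg_a[i, 1], seg_a[i, 2], seg_b[i, 1], seg_b[i, 2], seg_b[j, 1], seg_b[j, 2])
      d3 <- cross2(seg_a[j, 1], seg_a[j, 2], seg_b[j, 1], seg_b[j, 2], seg_a[i, 1], seg_a[i, 2])
      d4 <- cross2(seg_a[j, 1], seg_a[j, 2], seg_b[j, 1], seg_b[j, 2], seg_b[i, 1], seg_b[i, 2])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return(FALSE)
    }
  }
  TRUE
}

#' Point-in-polygon test
#'
#' Thin wrapper around `mgcv::in.out` (even-odd rule). Points exactly on the
#' boundary are implementation-defined, as usual for raster work.
#'
#' @param x,y numeric vectors of point coordinates (um)
#' @param poly data.frame with columns x, y
#' @return logical vector
#' @export
points_in_polygon <- function(x, y, poly) {
  if (length(x) == 0L) return(logical(0))
  bnd <- as.matrix(rbind(poly[, c("x", "y")], poly[1L, c("x", "y")]))
  mgcv::in.out(bnd, cbind(as.numeric(x), as.numeric(y)))
}

#' Minimum distance from points to a polyline
#'
#' Exact point-to-segment distance, minimized over all segments of the
#' polyline (not only its vertices).
#'
#' @param x,y point coordinates (um)
#' @param line data.frame with columns x, y (>= 2 vertices)
#' @return numeric vector of distances (um)
#' @export
dist_to_polyline <- function(x, y, line) {
  p <- as.matrix(line[, c("x", "y")])
  if (nrow(p) < 2L) stopf("polyline needs at least 2 vertices")
  n <- length(x)
  best <- rep(Inf, n)
  for (k in seq_len(nrow(p) - 1L)) {
    ax <- p[k, 1]; ay <- p[k, 2]
    bx <- p[k + 1L, 1]; by <- p[k + 1L, 2]
    dx <- bx - ax; dy <- by - ay
    L2 <- dx * dx + dy * dy
    t <- if (L2 == 0) rep(0, n) else pmin(1, pmax(0, ((x - ax) * dx + (y - ay) * dy) / L2))
    d <- sqrt((x - (ax + t * dx))^2 + (y - (ay + t * dy))^2)
    best <- pmin(best, d)
  }
  best
}

#' Coordinates of pixel centres
#' @param nx,ny raster dimensions (x first)
#' @param pixel_size_um pixel size
#' @return list with vectors x (length nx) and y (length ny), um
#' @keywords internal
pixel_centers <- function(nx, ny, pixel_size_um) {
  list(
    x = (seq_len(nx) - 0.5) * pixel_size_um,
    y = (seq_len(ny) - 0.5) * pixel_size_um
  )
}

#' Rasterize a polygon interior to a logical mask
#' @param nx,ny raster dims; @param poly polygon (um); @param pixel_size_um pixel size
#' @return logical matrix dim c(nx, ny)
#' @keywords internal
polygon_mask <- function(nx, ny, poly, pixel_size_um) {
  pc <- pixel_centers(nx, ny, pixel_size_um)
  xs <- rep(pc$x, times = ny)
  ys <- rep(pc$y, each = nx)
  matrix(points_in_polygon(xs, ys, poly), nx, ny)
}
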