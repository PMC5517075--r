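#' Region-of-interest constructors
#'
#' ROIs stand in for the manual tracings of a microscopy workflow: polylines
#' for traced paths (tube centerlines, junction segments, intensity bands),
#' polygons for closed regions (cell contours, vesicle outlines) and landmark
#' sets for anchor points. Coordinates are 0-based pixel-center `(x, y)` with
#' `y` increasing downwards.
#'
#' @param points,vertices Two-column numeric matrix or data frame of `(x, y)`
#'   coordinates. Polylines need at least 2 points with distinct consecutive
#'   points; polygons need at least 3 vertices of a simple (non self
#'   intersecting) ring, given unclosed (the closing edge is implicit).
#' @param name Label carried through measurement tables.
#' @param width_px Band width in pixels for polyline ROIs (1 = pure path).
#' @return An object of class `roi_polyline`, `roi_polygon` or
#'   `roi_landmarks` (all also class `roi`).
#' @examples
#' roi_polyline(cbind(c(0, 3), c(0, 4)), name = "path")
#' roi_polygon(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)), name = "cell")
#' @export
roi_polyline <- function(points, name = "polyline", width_px = 1) {
  pts <- as_xy_matrix(points)
  if (nrow(pts) < 2) stop("a polyline needs at least 2 points", call. = FALSE)
  d <- diff(pts)
  if (any(rowSums(d^2) == 0)) {
    stop("consecutive polyline points must be distinct", call. = FALSE)
  }
  if (!is.numeric(width_px) || width_px < 1) {
    stop("`width_px` must be >= 1", call. = FALSE)
  }
  structure(list(points = pts, name = name, width_px = width_px),
            class = c("roi_polyline", "roi"))
}

#' @rdname roi_polyline
#' @export
roi_polygon <- function(vertices, name = "polygon") {
  v <- as_xy_matrix(vertices)
  # drop an explicitly repeated closing vertex
  if (nrow(v) > 1 && all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  if (nrow(v) < 3) stop("a polygon needs at least 3 vertices", call. = FALSE)
  if (!polygon_is_simple(v)) {
    stop("polygon must be simple (non self-intersecting)", call. = FALSE)
  }
  structure(list(vertices = v, name = name), class = c("roi_polygon", "roi"))
}

#' @rdname roi_polyline
#' @export
roi_landmarks <- function(points, name = "landmarks") {
  pts <- as_xy_matrix(points)
  if (nrow(pts) < 1) stop("landmark set must not be empty", call. = FALSE)
  structure(list(points = pts, name = name), class = c("roi_landmarks", "roi"))
}

#' @export
print.roi <- function(x, ...) {
  n <- nrow(if (!is.null(x$points)) x$points else x$vertices)
  cat(sprintf("<%s> '%s', %d point(s)\n", class(x)[1], x$name, n))
  invisible(x)
}

as_xy_matrix <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points[, 1:2])
  if (is.null(dim(points))) points <- matrix(points, ncol = 2, byrow = TRUE)
  storage.mode(points) <- "double"
  if (ncol(points) != 2) stop("coordinates must have two columns (x, y)", call. = FALSE)
  colnames(points) <- c("x", "y")
  points
}

# --- geometry helpers (pixel units unless noted) -------------------------

# TRUE iff no two non-adjacent edges of the ring intersect.
polygon_is_simple <- function(v) {
  n <- nrow(v)
  a <- v
  b <- v[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      adjacent <- (j == i + 1) || (i == 1 && j == n)
      if (adjacent) next
      if (segments_intersect(a[i, ], b[i, ], a[j, ], b[j, ])) return(FALSE)
    }
  }
  TRUE
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

# Even-odd point-in-polygon test, vectorised over query points.
points_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Minimum distance from points (px, py) to the segment a-b.
point_segment_distance <- function(px, py, a, b) {
  abx <- b[1] - a[1]; aby <- b[2] - a[2]
  len2 <- abx^2 + aby^2
  if (len2 == 0) return(sqrt((px - a[1])^2 + (py - a[2])^2))
  t <- pmin(1, pmax(0, ((px - a[1]) * abx + (py - a[2]) * aby) / len2))
  sqrt((px - (a[1] + t * abx))^2 + (py - (a[2] + t * aby))^2)
}

# Minimum distance from points to a polyline (matrix of vertices).
point_polyline_distance <- function(px, py, pts) {
  d <- rep(Inf, length(px))
  for (i in seq_len(nrow(pts) - 1)) {
    d <- pmin(d, point_segment_distance(px, py, pts[i, ], pts[i + 1, ]))
  }
  d
}

# Logical [y, x] mask of pixels whose centers lie inside the polygon ROI.
polygon_mask <- function(roi, nrow_px, ncol_px) {
  v <- roi$vertices
  mask <- matrix(FALSE, nrow_px, ncol_px)
  xr <- range(v[, 1]); yr <- range(v[, 2])
  cols <- max(1, floor(xr[1]) + 1):min(ncol_px, ceiling(xr[2]) + 1)
  rows <- max(1, floor(yr[1]) + 1):min(nrow_px, ceiling(yr[2]) + 1)
  if (!length(cols) || !length(rows)) return(mask)
  grid <- expand.grid(y = rows, x = cols)
  inside <- points_in_polygon(grid$x - 1, grid$y - 1, v)
  mask[cbind(grid$y, grid$x)] <- inside
  mask
}

# Logical [y, x] mask of pixels within dist_px of the polygon boundary ring.
polygon_ring_mask <- function(roi, nrow_px, ncol_px, dist_px) {
  v <- roi$vertices
  ring <- rbind(v, v[1, , drop = FALSE])
  band_mask_around(ring, nrow_px, ncol_px, dist_px)
}

# Logical [y, x] mask of pixels within dist_px of a polyline (open path).
band_mask_around <- function(pts, nrow_px, ncol_px, dist_px) {
  mask <- matrix(FALSE, nrow_px, ncol_px)
  xr <- range(pts[, 1]) + c(-1, 1) * (dist_px + 1)
  yr <- range(pts[, 2]) + c(-1, 1) * (dist_px + 1)
  cols <- max(1, floor(xr[1]) + 1):min(ncol_px, ceiling(xr[2]) + 1)
  rows <- max(1, floor(yr[1]) + 1):min(nrow_px, ceiling(yr[2]) + 1)
  if (!length(cols) || !length(rows)) return(mask)
  grid <- expand.grid(y = rows, x = cols)
  d <- point_polyline_distance(grid$x - 1, grid$y - 1, pts)
  mask[cbind(grid$y, grid$x)] <- d <= dist_px
  mask
}
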