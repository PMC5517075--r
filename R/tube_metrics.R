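#' Arc length of a traced path
#'
#' Sum of Euclidean segment lengths of a polyline, converted to micrometres.
#'
#' @param path A [roi_polyline()] or a two-column coordinate matrix.
#' @param pixel_size_um Micrometres per pixel.
#' @return Arc length in micrometres.
#' @examples
#' arc_length(roi_polyline(cbind(c(0, 3), c(0, 4))), pixel_size_um = 1) # 5
#' @export
arc_length <- function(path, pixel_size_um) {
  pts <- path_points(path)
  polyline_length_px(pts) * pixel_size_um
}

#' Tube tortuosity: arc-to-chord ratio of a traced path
#'
#' The tube-length statistic: the length of the traced path divided by the
#' straight-line distance between its two endpoints (the anchor landmarks at
#' either end of the measured tube region). A ratio of 1 means a perfectly
#' straight tube; a curved, overelongated tube gives a ratio above 1. The
#' ratio is dimensionless and invariant under rotation, translation and
#' uniform scaling of the path.
#'
#' @param path A [roi_polyline()] or a two-column coordinate matrix with
#'   distinct endpoints.
#' @param pixel_size_um Micrometres per pixel.
#' @return A one-row tibble: `arc_length_um`, `chord_length_um`, `ratio`.
#' @examples
#' dt_ratio(roi_polyline(cbind(c(0, 1, 2), c(0, 1, 0))), 1) # ratio sqrt(2)
#' @export
dt_ratio <- function(path, pixel_size_um = 1) {
  pts <- path_points(path)
  chord_px <- sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2))
  if (chord_px == 0) {
    stop("degenerate path: endpoints coincide, chord is zero", call. = FALSE)
  }
  arc_um <- polyline_length_px(pts) * pixel_size_um
  chord_um <- chord_px * pixel_size_um
  tibble::tibble(arc_length_um = arc_um, chord_length_um = chord_um,
                 ratio = arc_um / chord_um)
}

path_points <- function(path) {
  if (inherits(path, "roi_polyline")) return(path$points)
  as_xy_matrix(path)
}

#' Automatic centerline tracing between two anchors
#'
#' Automates the manual freehand tracing of a tube path: the lumen channel is
#' thresholded (Otsu), morphologically closed, and the centerline is
#' extracted as the minimum-cost 8-connected path between the mask pixels
#' nearest each anchor, where step costs grow towards the mask boundary
#' (inverse distance-transform weighting) so the path follows the medial
#' ridge of the tube. The raw pixel chain is then smoothed (endpoint-anchored
#' moving average over about one tube radius) to suppress pixelation bias in
#' the arc length.
#'
#' @param img An [mc_image()] containing the lumen channel.
#' @param channel Channel name or index (default first).
#' @param anchors A [roi_landmarks()] (or 2x2 matrix) with the two endpoints
#'   of the tube region, in pixel coordinates.
#' @param threshold Binarization threshold; `NULL` uses Otsu's method.
#' @param smooth_window_px Moving-average half-window; `NULL` picks half the
#'   median mask half-width (about the tube radius).
#' @return A [roi_polyline()] of the traced centerline.
#' @examples
#' ph <- tube_phantom(length_um = 15, diameter_um = 2, tortuosity = 1.05,
#'                    imaging = imaging_params(seed = 6))
#' tr <- trace_centerline(ph$image, anchors = ph$truth$anchors_px)
#' dt_ratio(tr, ph$image$pixel_size_um)$ratio
#' @export
trace_centerline <- function(img, channel = 1, anchors, threshold = NULL,
                             smooth_window_px = NULL) {
  mat <- get_channel(img, channel)
  apts <- if (inherits(anchors, "roi_landmarks")) anchors$points else as_xy_matrix(anchors)
  if (nrow(apts) != 2) stop("exactly two anchor landmarks required", call. = FALSE)
  rng <- range(mat)
  if (diff(rng) == 0) stop("blank image: no tube to trace", call. = FALSE)
  norm <- (mat - rng[1]) / diff(rng)
  thr <- if (is.null(threshold)) EBImage::otsu(EBImage::Image(norm), range = c(0, 1)) else
    (threshold - rng[1]) / diff(rng)
  mask <- norm > thr
  mask <- EBImage::closing(mask, EBImage::makeBrush(5, "disc")) > 0
  if (!any(mask)) stop("thresholding produced an empty tube mask", call. = FALSE)
  dt <- as.matrix(EBImage::distmap(EBImage::Image(mask * 1)))

  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)  # column-major linear indices
  node_of <- integer(nr * nc)
  node_of[idx] <- seq_along(idx)
  ry <- ((idx - 1) %% nr) + 1
  cx <- ((idx - 1) %/% nr) + 1

  # 8-neighbour edges (4 forward directions to avoid duplicates)
  steps <- rbind(c(1, 0), c(0, 1), c(1, 1), c(-1, 1))  # (dy, dx)
  efrom <- integer(0); eto <- integer(0); ew <- numeric(0)
  inv <- 1 / pmax(dt[idx], 0.5)
  for (s in seq_len(nrow(steps))) {
    ny <- ry + steps[s, 1]; nx <- cx + steps[s, 2]
    ok <- ny >= 1 & ny <= nr & nx >= 1 & nx <= nc
    lin <- (nx - 1) * nr + ny
    ok[ok] <- mask[lin[ok]]
    if (!any(ok)) next
    a <- node_of[idx[ok]]
    b <- node_of[lin[ok]]
    len <- sqrt(sum(steps[s, ]^2))
    efrom <- c(efrom, a); eto <- c(eto, b)
    ew <- c(ew, len * (inv[a] + inv[b]) / 2)
  }
  g <- igraph::graph_from_edgelist(cbind(efrom, eto), directed = FALSE)
  if (igraph::vcount(g) < length(idx)) {
    g <- igraph::add_vertices(g, length(idx) - igraph::vcount(g))
  }
  igraph::E(g)$weight <- ew

  snap <- function(p) {
    d2 <- (cx - 1 - p[1])^2 + (ry - 1 - p[2])^2
    which.min(d2)
  }
  v1 <- snap(apts[1, ]); v2 <- snap(apts[2, ])
  sp <- suppressWarnings(igraph::shortest_paths(g, v1, v2, output = "vpath"))
  vp <- as.integer(sp$vpath[[1]])
  if (length(vp) < 2) {
    stop("anchors are not connected within the tube mask", call. = FALSE)
  }
  pts <- cbind(x = cx[vp] - 1, y = ry[vp] - 1)
  pts[1, ] <- apts[1, ]
  pts[nrow(pts), ] <- apts[2, ]

  if (is.null(smooth_window_px)) {
    smooth_window_px <- max(3, round(stats::median(dt[idx[vp]])))
  }
  pts <- smooth_path(pts, smooth_window_px)
  roi_polyline(dedupe_points(pts), name = "traced_centerline")
}

# Endpoint-anchored moving-average smoothing of an ordered pixel chain.
smooth_path <- function(pts, half_window) {
  n <- nrow(pts)
  if (n < 5 || half_window < 1) return(pts)
  out <- pts
  for (i in seq_len(n)) {
    w <- min(half_window, i - 1, n - i)
    if (w >= 1) out[i, ] <- colMeans(pts[(i - w):(i + w), , drop = FALSE])
  }
  out
}

dedupe_points <- function(pts) {
  if (nrow(pts) < 2) return(pts)
  keep <- c(TRUE, rowSums(diff(pts)^2) > 1e-12)
  pts[keep, , drop = FALSE]
}

#' Tube diameter at a point
#'
#' Measures the above-threshold run length through `at` along the
#' perpendicular to the tube axis direction, in micrometres.
#'
#' @param img An [mc_image()] with the lumen channel.
#' @param channel Channel name or index.
#' @param at `(x, y)` point inside the tube mask.
#' @param axis_deg Local tube-axis direction in degrees (the profile is taken
#'   perpendicular to it).
#' @param threshold Binarization threshold; `NULL` uses Otsu.
#' @return A one-row tibble: `diameter_um`, `x`, `y`.
#' @export
tube_diameter <- function(img, channel = 1, at, axis_deg = 0, threshold = NULL) {
  mat <- get_channel(img, channel)
  rng <- range(mat)
  if (diff(rng) == 0) stop("blank image", call. = FALSE)
  norm <- (mat - rng[1]) / diff(rng)
  thr <- if (is.null(threshold)) EBImage::otsu(EBImage::Image(norm), range = c(0, 1)) else
    (threshold - rng[1]) / diff(rng)
  mask <- norm > thr
  at <- as.numeric(at)
  r0 <- round(at[2]) + 1; c0 <- round(at[1]) + 1
  if (r0 < 1 || r0 > nrow(mask) || c0 < 1 || c0 > ncol(mask) || !mask[r0, c0]) {
    stop("measurement point lies outside the tube mask", call. = FALSE)
  }
  th <- (axis_deg + 90) * pi / 180
  dir <- c(cos(th), sin(th))
  run <- function(sgn) {
    s <- 0
    repeat {
      s2 <- s + 0.25
      x <- at[1] + sgn * s2 * dir[1]
      y <- at[2] + sgn * s2 * dir[2]
      r <- round(y) + 1; cc <- round(x) + 1
      if (r < 1 || r > nrow(mask) || cc < 1 || cc > ncol(mask) || !mask[r, cc]) break
      s <- s2
    }
    s
  }
  d_px <- run(1) + run(-1) + 1  # +1: the pixel under the point itself
  tibble::tibble(diameter_um = d_px * img$pixel_size_um, x = at[1], y = at[2])
}
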