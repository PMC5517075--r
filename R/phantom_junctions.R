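#' Synthetic junction-lattice phantom (cell-outline channel)
#'
#' Renders a rectangular lattice of bright cell-junction segments, emulating
#' an unrolled tube surface stained for an adherens-junction marker. Edges
#' parallel to the tube axis ("axial", mean length `axial_length_um`) and
#' edges perpendicular to it ("circumferential", mean length
#' `circumferential_length_um`) are jittered in orientation by a normal
#' deviate of s.d. `orientation_jitter_deg` about their midpoints, then the
#' whole lattice is rotated to `tube_axis_deg`. Ground truth lists every
#' segment with its planted endpoints, length and true angle relative to the
#' tube axis folded into [0, 90] degrees.
#'
#' @param n_cells Approximate number of lattice cells (arranged on a near
#'   square grid); must be >= 1.
#' @param axial_length_um,circumferential_length_um Mean edge lengths, um.
#' @param orientation_jitter_deg S.d. of the per-segment rotation, degrees.
#' @param tube_axis_deg Direction of the tube axis in the image frame
#'   (degrees; 0 = along +x).
#' @param junction_intensity,background_intensity Planted intensities.
#' @param line_width_px Rendered segment width in pixels.
#' @param imaging An [imaging_params()] object.
#' @return A list with `image` (channel `"junctions"`) and `truth` holding a
#'   `segments` tibble: `segment_id, x1, y1, x2, y2, angle_deg, length_um,
#'   orientation` ("axial"/"circumferential" by construction).
#' @examples
#' ph <- junction_phantom(n_cells = 9, imaging = imaging_params(seed = 2))
#' head(ph$truth$segments)
#' @export
junction_phantom <- function(n_cells = 25, axial_length_um = 2,
                             circumferential_length_um = 2,
                             orientation_jitter_deg = 5, tube_axis_deg = 0,
                             junction_intensity = 2500,
                             background_intensity = 100, line_width_px = 2,
                             imaging = imaging_params()) {
  stopifnot(inherits(imaging, "imaging_params"))
  if (n_cells < 1) stop("`n_cells` must be >= 1", call. = FALSE)
  if (axial_length_um <= 0 || circumferential_length_um <= 0) {
    stop("edge lengths must be positive", call. = FALSE)
  }
  if (orientation_jitter_deg < 0) stop("jitter must be >= 0", call. = FALSE)
  psz <- imaging$pixel_size_um
  ncol_cells <- ceiling(sqrt(n_cells))
  nrow_cells <- ceiling(n_cells / ncol_cells)
  ax_px <- axial_length_um / psz
  ci_px <- circumferential_length_um / psz

  segs <- with_local_seed(derive_seed(imaging$seed, "lattice"), {
    out <- list()
    # axial (horizontal) edges
    for (j in 0:nrow_cells) {
      for (i in seq_len(ncol_cells)) {
        out[[length(out) + 1L]] <- c((i - 1) * ax_px, j * ci_px, i * ax_px,
                                     j * ci_px, 0)
      }
    }
    # circumferential (vertical) edges
    for (j in seq_len(nrow_cells)) {
      for (i in 0:ncol_cells) {
        out[[length(out) + 1L]] <- c(i * ax_px, (j - 1) * ci_px, i * ax_px,
                                     j * ci_px, 90)
      }
    }
    m <- do.call(rbind, out)
    jit <- if (orientation_jitter_deg > 0) {
      stats::rnorm(nrow(m), 0, orientation_jitter_deg)
    } else rep(0, nrow(m))
    cbind(m, jit)
  })

  # rotate each segment by its jitter about the midpoint, then the whole
  # lattice by tube_axis_deg about the origin
  rot <- function(x, y, deg, cx = 0, cy = 0) {
    th <- deg * pi / 180
    cbind(cx + (x - cx) * cos(th) - (y - cy) * sin(th),
          cy + (x - cx) * sin(th) + (y - cy) * cos(th))
  }
  p1 <- cbind(segs[, 1], segs[, 2])
  p2 <- cbind(segs[, 3], segs[, 4])
  mid <- (p1 + p2) / 2
  a1 <- a2 <- matrix(0, nrow(segs), 2)
  for (k in seq_len(nrow(segs))) {
    a1[k, ] <- rot(p1[k, 1], p1[k, 2], segs[k, 6], mid[k, 1], mid[k, 2])
    a2[k, ] <- rot(p2[k, 1], p2[k, 2], segs[k, 6], mid[k, 1], mid[k, 2])
  }
  b1 <- rot(a1[, 1], a1[, 2], tube_axis_deg)
  b2 <- rot(a2[, 1], a2[, 2], tube_axis_deg)

  margin <- 6
  shift_x <- margin - min(b1[, 1], b2[, 1])
  shift_y <- margin - min(b1[, 2], b2[, 2])
  b1 <- b1 + cbind(rep(shift_x, nrow(b1)), rep(shift_y, nrow(b1)))
  b2 <- b2 + cbind(rep(shift_x, nrow(b2)), rep(shift_y, nrow(b2)))
  width_px <- ceiling(max(b1[, 1], b2[, 1]) + margin)
  height_px <- ceiling(max(b1[, 2], b2[, 2]) + margin)

  seg_len_um <- sqrt(rowSums((b2 - b1)^2)) * psz
  raw_angle <- atan2(b2[, 2] - b1[, 2], b2[, 1] - b1[, 1]) * 180 / pi
  true_angle <- fold_angle(raw_angle - tube_axis_deg)

  mat <- blank_canvas(width_px, height_px, background_intensity)
  for (k in seq_len(nrow(b1))) {
    mat <- paint_polyline(mat, rbind(b1[k, ], b2[k, ]), line_width_px,
                          junction_intensity)
  }
  mat <- with_local_seed(derive_seed(imaging$seed, "noise"),
                         apply_imaging(mat, imaging))

  segments <- tibble::tibble(
    segment_id = seq_len(nrow(b1)),
    x1 = b1[, 1], y1 = b1[, 2], x2 = b2[, 1], y2 = b2[, 2],
    angle_deg = true_angle,
    length_um = seg_len_um,
    orientation = ifelse(segs[, 5] == 0, "axial", "circumferential")
  )
  truth <- new_ground_truth("junction_lattice", segments = segments,
                            tube_axis_deg = tube_axis_deg,
                            total_length_um = sum(seg_len_um))
  list(image = mc_image(mat, "junctions", psz), truth = truth)
}

# Fold an undirected orientation into [0, 90] degrees.
fold_angle <- function(deg) {
  a <- abs(deg %% 180)
  ifelse(a > 90, 180 - a, a)
}
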