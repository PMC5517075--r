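#' Orientation of a junction segment relative to the tube axis
#'
#' The angle between the endpoint-to-endpoint chord of the traced junction
#' and the tube axis, folded into [0, 90] degrees (junction orientation is
#' undirected). The chord convention matches how a freehand-traced junction's
#' overall orientation is read; a total-least-squares direction over all
#' points is available via `method = "tls"`.
#'
#' @param polyline A [roi_polyline()] or coordinate matrix (>= 2 points,
#'   distinct endpoints).
#' @param tube_axis_deg Tube-axis direction in the image frame, degrees.
#' @param method `"chord"` (default) or `"tls"` (principal direction of all
#'   points).
#' @return Angle in degrees in [0, 90].
#' @examples
#' segment_angle(cbind(c(0, 1), c(0, 1)), 0) # 45
#' @export
segment_angle <- function(polyline, tube_axis_deg = 0,
                          method = c("chord", "tls")) {
  method <- match.arg(method)
  pts <- path_points(polyline)
  if (method == "chord") {
    d <- pts[nrow(pts), ] - pts[1, ]
    if (all(d == 0)) stop("degenerate segment: endpoints coincide", call. = FALSE)
    raw <- as.numeric(atan2(d[2], d[1])) * 180 / pi
  } else {
    cc <- scale(pts, scale = FALSE)
    sv <- svd(cc)
    raw <- atan2(sv$v[2, 1], sv$v[1, 1]) * 180 / pi
  }
  as.numeric(fold_angle(raw - tube_axis_deg))
}

#' Classify a junction by orientation band
#'
#' Junctions within 30 degrees of the tube axis are axial; within 30 degrees
#' of the perpendicular, circumferential; the bands are closed at their
#' printed boundaries (30 is axial, 60 is circumferential) and angles in
#' between are unclassified and excluded from the two-class comparison.
#'
#' @param angle_deg Angle(s) in degrees, each in [0, 90].
#' @return Character vector: `"axial"`, `"circumferential"` or
#'   `"unclassified"`.
#' @examples
#' classify_junction(c(0, 30, 45, 60, 90))
#' @export
classify_junction <- function(angle_deg) {
  if (any(angle_deg < 0 | angle_deg > 90)) {
    stop("angles must lie in [0, 90] degrees", call. = FALSE)
  }
  ifelse(angle_deg <= 30, "axial",
         ifelse(angle_deg >= 60, "circumferential", "unclassified"))
}

#' Junction length
#'
#' Polyline arc length in micrometres; a convenience alias of [arc_length()]
#' named for its use on traced cell junctions.
#'
#' @inheritParams arc_length
#' @return Length in micrometres.
#' @export
junction_length <- function(path, pixel_size_um) arc_length(path, pixel_size_um)

#' Measure and classify a table of junction segments
#'
#' Takes a tidy table of junction segments (one row per segment with endpoint
#' columns `x1, y1, x2, y2`, or a `segments` ground-truth tibble) and returns
#' it with `angle_deg`, `length_um` and `class` columns filled in.
#'
#' @param segments A data frame with columns `x1, y1, x2, y2` (pixel coords)
#'   and optionally a `group` column carried through.
#' @param tube_axis_deg Tube-axis direction, degrees.
#' @param pixel_size_um Micrometres per pixel.
#' @return The input as a tibble with `angle_deg`, `length_um`, `class`.
#' @export
measure_junctions <- function(segments, tube_axis_deg = 0, pixel_size_um = 0.1) {
  segments <- tibble::as_tibble(segments)
  stopifnot(all(c("x1", "y1", "x2", "y2") %in% names(segments)))
  ang <- fold_angle(atan2(segments$y2 - segments$y1,
                          segments$x2 - segments$x1) * 180 / pi - tube_axis_deg)
  len <- sqrt((segments$x2 - segments$x1)^2 +
                (segments$y2 - segments$y1)^2) * pixel_size_um
  dplyr::mutate(segments, angle_deg = ang, length_um = len,
                class = classify_junction(ang))
}

#' Per-class junction length summary and group comparison
#'
#' Summarizes classified junction segments per orientation class (and group,
#' when a grouping column is present): n, mean length, s.d. and s.e.
#' Unclassified segments are reported but excluded from any axial versus
#' circumferential comparison. With exactly two groups, a pooled-variance
#' Student's t comparison of lengths is run per class via [group_compare()].
#'
#' @param segments A tibble with `length_um` and `class` columns (see
#'   [measure_junctions()]).
#' @param group Optional name of a grouping column.
#' @return A list of class `junction_summary` with tibbles `summary` and
#'   (when two groups are present) `comparisons`.
#' @export
summarize_junctions <- function(segments, group = NULL) {
  segments <- tibble::as_tibble(segments)
  stopifnot(all(c("length_um", "class") %in% names(segments)))
  keys <- c(if (!is.null(group)) group, "class")
  summary <- segments |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_length_um = mean(.data$length_um),
                     sd_length_um = stats::sd(.data$length_um),
                     se_length_um = stats::sd(.data$length_um) / sqrt(dplyr::n()),
                     .groups = "drop")
  comparisons <- NULL
  if (!is.null(group)) {
    gl <- unique(segments[[group]])
    if (length(gl) == 2) {
      comparisons <- purrr::map_dfr(c("axial", "circumferential"), function(cl) {
        sub <- segments[segments$class == cl, ]
        a <- sub$length_um[sub[[group]] == gl[1]]
        b <- sub$length_um[sub[[group]] == gl[2]]
        if (length(a) < 2 || length(b) < 2) {
          return(tibble::tibble(class = cl, n_a = length(a), n_b = length(b)))
        }
        dplyr::mutate(glance(group_compare(a, b, labels = as.character(gl))),
                      class = cl, .before = 1)
      })
    }
  }
  structure(list(summary = summary, comparisons = comparisons),
            class = "junction_summary")
}

#' @export
print.junction_summary <- function(x, ...) {
  cat("<junction_summary>\n")
  print(x$summary)
  if (!is.null(x$comparisons)) {
    cat("comparisons:\n")
    print(x$comparisons)
  }
  invisible(x)
}
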