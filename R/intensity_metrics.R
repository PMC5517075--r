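#' Pixels of a polyline band
#'
#' The set of pixels whose centers lie within perpendicular distance
#' `width_px / 2` of the polyline — the raster equivalent of a wide line
#' selection. Bands reaching beyond the image are clipped with a warning.
#'
#' @param polyline A [roi_polyline()] or coordinate matrix.
#' @param width_px Total band width in pixels (>= 1); defaults to the ROI's
#'   own `width_px`.
#' @param dim_px Image dimensions `c(nrow, ncol)` in pixels.
#' @return A tibble with 0-based `x`, `y` pixel coordinates of the band.
#' @examples
#' nrow(band_pixels(cbind(c(0, 9), c(2, 2)), width_px = 1, dim_px = c(5, 10)))
#' @export
band_pixels <- function(polyline, width_px = NULL, dim_px) {
  pts <- path_points(polyline)
  if (is.null(width_px)) {
    width_px <- if (inherits(polyline, "roi_polyline")) polyline$width_px else 1
  }
  if (width_px < 1) stop("`width_px` must be >= 1", call. = FALSE)
  half <- width_px / 2
  xr <- range(pts[, 1]); yr <- range(pts[, 2])
  if (xr[1] - half < -0.5 || yr[1] - half < -0.5 ||
      xr[2] + half > dim_px[2] - 0.5 || yr[2] + half > dim_px[1] - 0.5) {
    warning("band extends beyond the image and was clipped")
  }
  m <- band_mask_around(pts, dim_px[1], dim_px[2], half)
  w <- which(m, arr.ind = TRUE)
  tibble::tibble(x = w[, 2] - 1, y = w[, 1] - 1)
}

band_mask <- function(polyline, width_px, nrow_px, ncol_px) {
  pts <- path_points(polyline)
  band_mask_around(pts, nrow_px, ncol_px, width_px / 2)
}

#' Normalized tube intensity: tube band over reference band
#'
#' Mean fluorescence over a wide band traced along the tube of interest,
#' normalized to the mean over a band traced along an internal reference
#' structure in the same image — cancelling embryo-to-embryo staining and
#' illumination differences. Band means (not sums) are used so the ratio does
#' not depend on the traced lengths; the conventional band widths are 60 px
#' for the tube and 10 px for the reference.
#'
#' @param img An [mc_image()].
#' @param channel Channel name or index.
#' @param dt_roi [roi_polyline()] along the tube (band width taken from the
#'   ROI, conventionally 60 px).
#' @param mt_roi [roi_polyline()] along the reference structure
#'   (conventionally 10 px wide).
#' @return A one-row tibble: `dt_mean`, `mt_mean`, `ratio`.
#' @export
dt_mt_ratio <- function(img, channel = 1, dt_roi, mt_roi) {
  mat <- get_channel(img, channel)
  dm <- band_mask(dt_roi, dt_roi$width_px %||% 60, nrow(mat), ncol(mat))
  mm <- band_mask(mt_roi, mt_roi$width_px %||% 10, nrow(mat), ncol(mat))
  if (!any(dm) || !any(mm)) stop("empty intensity band", call. = FALSE)
  dt_mean <- mean(mat[dm])
  mt_mean <- mean(mat[mm])
  if (mt_mean <= 0) {
    stop("reference band mean is zero: normalized ratio undefined", call. = FALSE)
  }
  tibble::tibble(dt_mean = dt_mean, mt_mean = mt_mean, ratio = dt_mean / mt_mean)
}

#' Subcellular accumulation ratio: contour band over interior region
#'
#' Quantifies apical enrichment of a protein at cell-cell contacts: the sum
#' fluorescence intensity over a band of `band_width_px` centered on the cell
#' contour (the subapical region, SAR) divided by the sum over an interior
#' region (the apical free region, AFR). The two pixel sets must be disjoint;
#' pixels falling in both after banding are assigned to the band and removed
#' from the interior, and an interior polygon touching the contour band
#' everywhere is an error.
#'
#' @param img An [mc_image()].
#' @param channel Channel name or index.
#' @param contour [roi_polygon()] outlining the cell.
#' @param inner [roi_polygon()] strictly inside the contour marking the
#'   interior region; `NULL` uses everything inside the contour that is not
#'   in the band.
#' @param band_width_px Width of the contour band, pixels (default 3).
#' @return A one-row tibble: `sar_sum`, `afr_sum`, `ratio`, `sar_n_px`,
#'   `afr_n_px`.
#' @export
sar_afr_ratio <- function(img, channel = 1, contour, inner = NULL,
                          band_width_px = 3) {
  stopifnot(inherits(contour, "roi_polygon"))
  mat <- get_channel(img, channel)
  sar <- polygon_ring_mask(contour, nrow(mat), ncol(mat), band_width_px / 2)
  afr <- if (is.null(inner)) {
    polygon_mask(contour, nrow(mat), ncol(mat)) & !sar
  } else {
    stopifnot(inherits(inner, "roi_polygon"))
    inside_contour <- points_in_polygon(inner$vertices[, 1], inner$vertices[, 2],
                                        contour$vertices)
    if (!all(inside_contour)) {
      stop("inner region must lie strictly inside the contour", call. = FALSE)
    }
    polygon_mask(inner, nrow(mat), ncol(mat)) & !sar
  }
  if (!any(afr)) {
    stop("interior region is empty after removing the contour band",
         call. = FALSE)
  }
  sar_sum <- sum(mat[sar])
  afr_sum <- sum(mat[afr])
  if (afr_sum <= 0) {
    stop("interior sum intensity is zero: ratio undefined", call. = FALSE)
  }
  tibble::tibble(sar_sum = sar_sum, afr_sum = afr_sum,
                 ratio = sar_sum / afr_sum,
                 sar_n_px = sum(sar), afr_n_px = sum(afr))
}
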