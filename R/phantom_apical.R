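#' Synthetic apical-cell phantom (subapical band vs apical free region)
#'
#' Renders a single apical cell surface: a bright band of width
#' `sar_band_width_um` along the cell-contour polygon (the subapical region,
#' SAR, where junctional enrichment accumulates) and a distinct interior
#' intensity (the apical free region, AFR, facing the lumen). Ground truth
#' stores the generating sum-intensity ratio SAR/AFR computed analytically by
#' exhaustive pixel enumeration of the two planted, disjoint regions — never
#' from rendered pixels.
#'
#' @param contour_polygon A [roi_polygon()] cell contour in pixel coords.
#' @param sar_band_width_um Width of the contour band, um (> 0; must not
#'   exceed the polygon inradius).
#' @param sar_intensity,afr_intensity Planted intensities of band / interior.
#' @param background_intensity Planted background level.
#' @param imaging An [imaging_params()] object.
#' @param field_width_px,field_height_px Canvas size; defaults fit the
#'   polygon with a margin.
#' @return A list with `image` (channel `"apical"`) and `truth` with
#'   `sar_afr_true_ratio` (NA with `ratio_defined = FALSE` when
#'   `afr_intensity` is 0), planted pixel counts and intensities.
#' @examples
#' sq <- roi_polygon(cbind(c(10, 60, 60, 10), c(10, 10, 60, 60)))
#' ph <- apical_cell_phantom(sq, imaging = imaging_params(seed = 4))
#' ph$truth$sar_afr_true_ratio
#' @export
apical_cell_phantom <- function(contour_polygon, sar_band_width_um = 0.3,
                                sar_intensity = 2000, afr_intensity = 1000,
                                background_intensity = 50,
                                imaging = imaging_params(),
                                field_width_px = NULL, field_height_px = NULL) {
  stopifnot(inherits(imaging, "imaging_params"),
            inherits(contour_polygon, "roi_polygon"))
  if (sar_band_width_um <= 0) stop("band width must be > 0", call. = FALSE)
  psz <- imaging$pixel_size_um
  band_px <- sar_band_width_um / psz
  v <- contour_polygon$vertices
  margin <- ceiling(band_px) + 4
  width_px <- field_width_px %||% ceiling(max(v[, 1]) + margin)
  height_px <- field_height_px %||% ceiling(max(v[, 2]) + margin)
  if (any(v[, 1] < 0) || any(v[, 2] < 0) ||
      any(v[, 1] > width_px - 1) || any(v[, 2] > height_px - 1)) {
    stop("contour polygon must lie inside the field of view", call. = FALSE)
  }

  inside <- polygon_mask(contour_polygon, height_px, width_px)
  ring <- polygon_ring_mask(contour_polygon, height_px, width_px, band_px / 2)
  sar <- ring
  afr <- inside & !ring
  if (!any(afr)) {
    stop("band wider than the polygon inradius: no interior left", call. = FALSE)
  }

  mat <- blank_canvas(width_px, height_px, background_intensity)
  mat[afr] <- afr_intensity
  mat[sar] <- sar_intensity
  sar_sum <- sar_intensity * sum(sar)
  afr_sum <- afr_intensity * sum(afr)
  ratio_defined <- afr_sum > 0
  mat <- with_local_seed(imaging$seed, apply_imaging(mat, imaging))

  truth <- new_ground_truth(
    "apical_cell",
    sar_afr_true_ratio = if (ratio_defined) sar_sum / afr_sum else NA_real_,
    ratio_defined = ratio_defined,
    sar_pixels = sum(sar), afr_pixels = sum(afr),
    sar_intensity = sar_intensity, afr_intensity = afr_intensity,
    sar_band_width_um = sar_band_width_um
  )
  list(image = mc_image(mat, "apical", psz), truth = truth)
}

#' Synthetic nuclei-field phantom (nuclear stain channel)
#'
#' Plants `n_nuclei` non-overlapping bright discs emulating a nuclear
#' counterstain, for validating nuclei counting. Ground truth lists the
#' planted centroids.
#'
#' @param n_nuclei Number of nuclei (>= 0).
#' @param nucleus_diameter_um Disc diameter, um.
#' @param min_separation_um Minimum center-to-center distance, um; must be at
#'   least the diameter so nuclei never overlap.
#' @param nucleus_intensity,background_intensity Planted intensities.
#' @param field_um Side of the square field, um; `NULL` sizes automatically.
#' @param imaging An [imaging_params()] object.
#' @return A list with `image` (channel `"nuclei"`) and `truth` holding a
#'   `nuclei` tibble of planted centroids.
#' @examples
#' ph <- nuclei_phantom(n_nuclei = 5, imaging = imaging_params(seed = 5))
#' nrow(ph$truth$nuclei)
#' @export
nuclei_phantom <- function(n_nuclei = 25, nucleus_diameter_um = 3,
                           min_separation_um = 4.5, nucleus_intensity = 3000,
                           background_intensity = 50, field_um = NULL,
                           imaging = imaging_params()) {
  stopifnot(inherits(imaging, "imaging_params"))
  if (n_nuclei < 0) stop("`n_nuclei` must be >= 0", call. = FALSE)
  if (min_separation_um < nucleus_diameter_um) {
    stop("`min_separation_um` must be at least the nucleus diameter",
         call. = FALSE)
  }
  psz <- imaging$pixel_size_um
  if (is.null(field_um)) {
    field_um <- max(10, ceiling(sqrt(max(n_nuclei, 1)) * min_separation_um * 1.8))
  }
  side_px <- ceiling(field_um / psz)
  r_px <- nucleus_diameter_um / 2 / psz
  mat <- blank_canvas(side_px, side_px, background_intensity)
  if (n_nuclei > 0) {
    pos <- with_local_seed(derive_seed(imaging$seed, "nuclei"),
                           place_points(n_nuclei, side_px, side_px,
                                        min_separation_um / psz, r_px + 3))
    for (k in seq_len(n_nuclei)) {
      mat <- paint_disc(mat, pos[k, 1], pos[k, 2], r_px, nucleus_intensity)
    }
    nuclei <- tibble::tibble(nucleus_id = seq_len(n_nuclei),
                             x = pos[, 1], y = pos[, 2])
  } else {
    nuclei <- tibble::tibble(nucleus_id = integer(), x = double(), y = double())
  }
  mat <- with_local_seed(derive_seed(imaging$seed, "noise"),
                         apply_imaging(mat, imaging))
  truth <- new_ground_truth("nuclei_field", nuclei = nuclei,
                            nucleus_diameter_um = nucleus_diameter_um)
  list(image = mc_image(mat, "nuclei", psz), truth = truth)
}
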