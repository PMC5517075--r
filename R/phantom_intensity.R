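#' Synthetic two-band intensity phantom (tube vs reference structure)
#'
#' Renders two horizontal band structures in one channel: a wide "tube" band
#' (measured with the conventional 60-px line) and a narrow internal
#' "reference" band (measured with the 10-px line), for validating the
#' normalized band-mean intensity ratio. Ground truth records
#' `dt_mt_true_ratio`, the generating band-mean ratio under the acquisition
#' model: with a Gaussian PSF the mean over a band of width W centered on a
#' structure of the same width falls short of the painted intensity by an
#' edge-coverage factor, so the truth is computed from the analytic 1-d
#' blurred-band profile (Gaussian-cdf coverage integral) — from the planted
#' geometry and optics, never from rendered pixels.
#'
#' @param dt_intensity,mt_intensity Painted band intensities.
#' @param dt_width_px,mt_width_px Band widths in pixels (defaults 60 and 10,
#'   the conventional line widths).
#' @param background_intensity Painted background level.
#' @param length_px Band length in pixels.
#' @param imaging An [imaging_params()] object.
#' @return A list with `image` (channel `"stain"`), `truth` (with
#'   `dt_mt_true_ratio` and the nominal painted ratio), and the two
#'   measurement ROIs `dt_roi`, `mt_roi` ([roi_polyline()]s of the band
#'   widths).
#' @examples
#' ph <- intensity_band_phantom(imaging = imaging_params(seed = 9))
#' ph$truth$dt_mt_true_ratio
#' @export
intensity_band_phantom <- function(dt_intensity = 1500, mt_intensity = 1000,
                                   dt_width_px = 60, mt_width_px = 10,
                                   background_intensity = 20, length_px = 190,
                                   imaging = imaging_params()) {
  stopifnot(inherits(imaging, "imaging_params"))
  if (mt_intensity <= 0) stop("reference intensity must be positive", call. = FALSE)
  sigma_px <- imaging$psf_sigma_um / imaging$pixel_size_um
  gap <- max(dt_width_px, 8 * sigma_px)
  y_dt <- dt_width_px / 2 + 4 * sigma_px + 4
  y_mt <- y_dt + dt_width_px / 2 + gap + mt_width_px / 2
  height <- ceiling(y_mt + mt_width_px / 2 + 4 * sigma_px + 4)
  width <- length_px + 10

  mat <- blank_canvas(width, height, background_intensity)
  dt_line <- cbind(c(5, 5 + length_px - 1), c(y_dt, y_dt))
  mt_line <- cbind(c(5, 5 + length_px - 1), c(y_mt, y_mt))
  mat <- paint_polyline(mat, dt_line, dt_width_px, dt_intensity)
  mat <- paint_polyline(mat, mt_line, mt_width_px, mt_intensity)
  mat <- with_local_seed(imaging$seed, apply_imaging(mat, imaging))

  dt_mean_true <- blurred_band_mean(dt_intensity, background_intensity,
                                    dt_width_px, sigma_px)
  mt_mean_true <- blurred_band_mean(mt_intensity, background_intensity,
                                    mt_width_px, sigma_px)
  truth <- new_ground_truth(
    "intensity_bands",
    dt_mt_true_ratio = dt_mean_true / mt_mean_true,
    nominal_ratio = dt_intensity / mt_intensity,
    dt_mean_true = dt_mean_true, mt_mean_true = mt_mean_true)
  list(image = mc_image(mat, "stain", imaging$pixel_size_um), truth = truth,
       dt_roi = roi_polyline(dt_line, name = "dt", width_px = dt_width_px),
       mt_roi = roi_polyline(mt_line, name = "mt", width_px = mt_width_px))
}

# Expected mean intensity over a width-W band centered on a painted band of
# the same width and intensity i on background bg, after Gaussian blur of
# s.d. sigma (1-d model across the band; the along-band direction is
# translation invariant away from the ends).
blurred_band_mean <- function(i, bg, W, sigma) {
  if (sigma <= 0) return(i)
  x <- seq(-W / 2, W / 2, length.out = 513)
  cov <- stats::pnorm((W / 2 - x) / sigma) + stats::pnorm((W / 2 + x) / sigma) - 1
  bg + (i - bg) * mean(cov)
}
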