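#' Synthetic curved-tube phantom (lumen channel)
#'
#' Renders a bright tube of constant diameter on a dark background whose
#' centerline is a single-period sinusoid between two anchor landmarks. The
#' sinusoid amplitude is solved numerically (bisection, tolerance 1e-4 on the
#' ratio) so that the planted centerline's arc-to-chord ratio equals the
#' requested `tortuosity`; a tortuosity of exactly 1 plants a straight line.
#' Ground truth carries the exact centerline, the two anchors and the true
#' ratio, all computed from the planted geometry, never from rendered pixels.
#'
#' @param length_um Chord length of the tube (straight anchor-to-anchor
#'   distance), micrometres.
#' @param diameter_um Tube diameter, micrometres (must be smaller than
#'   `length_um`).
#' @param tortuosity Target arc-to-chord ratio, >= 1.
#' @param waviness_wavelength_um Wavelength of the sinusoidal centerline;
#'   defaults to one full period over the chord.
#' @param lumen_intensity,background_intensity Planted intensities.
#' @param imaging An [imaging_params()] object.
#' @param field_width_um,field_height_um Optional fixed field of view; errors
#'   if the tube (with a one-diameter margin) does not fit. By default the
#'   field is sized to fit the tube.
#' @return A list with `image` (an [mc_image()] with channel `"lumen"`) and
#'   `truth` (a `ground_truth` with `centerline` in pixel coordinates,
#'   `anchors_px`, `arc_chord_ratio`, `diameter_um`).
#' @examples
#' ph <- tube_phantom(length_um = 20, diameter_um = 2, tortuosity = 1.1,
#'                    imaging = imaging_params(seed = 1))
#' ph$truth$arc_chord_ratio
#' @export
tube_phantom <- function(length_um = 40, diameter_um = 3, tortuosity = 1.0,
                         waviness_wavelength_um = length_um,
                         lumen_intensity = 3000, background_intensity = 100,
                         imaging = imaging_params(),
                         field_width_um = NULL, field_height_um = NULL) {
  stopifnot(inherits(imaging, "imaging_params"))
  if (tortuosity < 1) stop("`tortuosity` must be >= 1", call. = FALSE)
  if (diameter_um >= length_um) {
    stop("`diameter_um` must be smaller than `length_um`", call. = FALSE)
  }
  psz <- imaging$pixel_size_um
  chord_px <- length_um / psz
  lambda_px <- waviness_wavelength_um / psz
  r_px <- diameter_um / 2 / psz

  amp_px <- solve_sine_amplitude(tortuosity, chord_px, lambda_px)
  margin_px <- diameter_um / psz + 4
  width_px <- ceiling(chord_px + 2 * margin_px)
  height_px <- ceiling(2 * amp_px + 2 * margin_px)
  if (!is.null(field_width_um)) {
    fw <- field_width_um / psz
    fh <- (field_height_um %||% field_width_um) / psz
    if (fw < width_px || fh < height_px) {
      stop("tube does not fit the requested field of view", call. = FALSE)
    }
    width_px <- ceiling(fw); height_px <- ceiling(fh)
  }

  y0 <- (height_px - 1) / 2
  x0 <- margin_px
  cl <- sine_centerline(chord_px, lambda_px, amp_px)
  cl[, 1] <- cl[, 1] + x0
  cl[, 2] <- cl[, 2] + y0
  true_ratio <- polyline_length_px(cl) /
    sqrt(sum((cl[nrow(cl), ] - cl[1, ])^2))

  mat <- blank_canvas(width_px, height_px, background_intensity)
  dense <- densify_polyline(cl, step = 0.25)
  for (i in seq_len(nrow(dense))) {
    mat <- paint_disc(mat, dense[i, 1], dense[i, 2], r_px, lumen_intensity)
  }
  mat <- with_local_seed(imaging$seed, apply_imaging(mat, imaging))

  truth <- new_ground_truth(
    "tube",
    centerline = cl,
    anchors_px = rbind(cl[1, ], cl[nrow(cl), ]),
    arc_chord_ratio = true_ratio,
    tortuosity_requested = tortuosity,
    diameter_um = diameter_um,
    length_um = length_um,
    lumen_intensity = lumen_intensity,
    background_intensity = background_intensity
  )
  list(image = mc_image(mat, "lumen", psz), truth = truth)
}

# Centerline samples of y = A sin(2*pi*x/lambda) over x in [0, chord].
sine_centerline <- function(chord_px, lambda_px, amp_px, n = 2001) {
  x <- seq(0, chord_px, length.out = n)
  cbind(x = x, y = amp_px * sin(2 * pi * x / lambda_px))
}

# Arc/chord ratio of the sine centerline for a given amplitude.
sine_ratio <- function(amp_px, chord_px, lambda_px) {
  cl <- sine_centerline(chord_px, lambda_px, amp_px)
  polyline_length_px(cl) / chord_px
}

# Bisection on the amplitude to hit a target arc/chord ratio (tol 1e-4).
solve_sine_amplitude <- function(target, chord_px, lambda_px, tol = 1e-4) {
  if (target <= 1 + 1e-12) return(0)
  hi <- lambda_px / 4
  while (sine_ratio(hi, chord_px, lambda_px) < target) hi <- hi * 2
  lo <- 0
  repeat {
    mid <- (lo + hi) / 2
    r <- sine_ratio(mid, chord_px, lambda_px)
    if (abs(r - target) < tol || (hi - lo) < 1e-9) return(mid)
    if (r < target) lo <- mid else hi <- mid
  }
}
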