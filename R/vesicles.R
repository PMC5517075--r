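#' Detect vesicles/endosomes in a multi-channel image
#'
#' Blob detection on the per-pixel maximum of the listed channels: a
#' difference-of-Gaussians band-pass tuned to the requested size window
#' enhances blob-like structure, the enhanced image is thresholded (Otsu by
#' default), touching blobs are split by a watershed on the distance
#' transform, and segments outside the equivalent-diameter window are
#' discarded. Each detection is measured on its segmented pixel mask and
#' classified by cargo presence (see [classify_cargo()]).
#'
#' @param img An [mc_image()].
#' @param channels Channel names or indices used for detection (default all).
#' @param min_diameter_um,max_diameter_um Size window for accepted blobs.
#' @param detect_threshold Threshold on the smoothed detection image; `NULL`
#'   uses Otsu.
#' @param presence_factor A channel counts as "present" in a vesicle when its
#'   mean intensity inside the mask exceeds `presence_factor` times the
#'   channel's background median (default 2).
#' @param psf_sigma_um When the imaging PSF sigma is known, measured
#'   half-max diameters are corrected for blur by inverting the forward
#'   model of a uniform disc convolved with an isotropic Gaussian (whose
#'   radial profile has a closed form in the modified Bessel function I0):
#'   the half-max radius is tabulated over true radii and the table is
#'   inverted by interpolation. For objects much larger than the PSF the
#'   correction vanishes (the half-max contour of a blurred sharp edge sits
#'   on the edge); near the resolution limit it removes most of the blur
#'   inflation. `NULL` reports uncorrected half-max diameters.
#' @return A tibble of class `vesicle_detections`, one row per detection:
#'   `vesicle_id, x, y, area_px, diameter_um`, per-channel
#'   `mean_<ch>` / `integrated_<ch>`, and `cargo_class` (when two detection
#'   channels are used).
#' @examples
#' ph <- vesicle_phantom(n_vesicles = 8, imaging = imaging_params(seed = 7))
#' det <- detect_vesicles(ph$image)
#' nrow(det)
#' @export
detect_vesicles <- function(img, channels = NULL,
                            min_diameter_um = 0.25, max_diameter_um = 2.5,
                            detect_threshold = NULL, presence_factor = 2,
                            psf_sigma_um = NULL) {
  stopifnot(inherits(img, "mc_image"))
  if (min_diameter_um <= 0 || max_diameter_um <= min_diameter_um) {
    stop("invalid diameter window", call. = FALSE)
  }
  if (is.null(channels)) channels <- img$channel_names
  psz <- img$pixel_size_um
  mats <- lapply(channels, function(ch) get_channel(img, ch))
  det <- Reduce(pmax, mats)

  # DoG band-pass at the geometric center of the size window
  r_px <- sqrt(min_diameter_um * max_diameter_um) / 2 / psz
  s1 <- max(0.8, r_px / 2)
  enh <- as.matrix(EBImage::gblur(det, sigma = s1)) -
    as.matrix(EBImage::gblur(det, sigma = 2.5 * s1))
  enh[enh < 0] <- 0
  if (max(enh) == 0) return(empty_detections(channels))
  thr <- if (is.null(detect_threshold)) otsu_threshold(enh) else detect_threshold
  mask <- enh > thr
  if (!any(mask)) return(empty_detections(channels))
  dmap <- EBImage::distmap(EBImage::Image(mask * 1))
  labels <- EBImage::watershed(dmap, tolerance = 0.5)
  labels <- as.matrix(EBImage::imageData(labels))

  amin <- pi * (min_diameter_um / 2 / psz)^2
  amax <- pi * (max_diameter_um / 2 / psz)^2
  ids <- sort(unique(labels[labels > 0]))
  bg_med <- vapply(seq_along(channels), function(i) {
    stats::median(mats[[i]][labels == 0])
  }, numeric(1))

  det_bg <- stats::median(det[labels == 0])
  correct <- if (is.null(psf_sigma_um) || psf_sigma_um <= 0) identity else
    psf_diameter_corrector(psf_sigma_um / psz,
                           max_radius_px = max_diameter_um / 2 / psz)
  rows <- list()
  for (lab in ids) {
    sel0 <- labels == lab
    if (sum(sel0) < 2) next
    # re-segment at the local half-max: the DoG/watershed footprint locates
    # the blob, the half-max footprint sizes it
    sel <- halfmax_segment(det, sel0, det_bg)
    a <- sum(sel)
    if (a < amin / 2) next
    w <- which(sel, arr.ind = TRUE)
    cx <- mean(w[, 2]) - 1
    cy <- mean(w[, 1]) - 1
    dia_px <- correct(2 * sqrt(a / pi))
    dia <- dia_px * psz
    if (dia < min_diameter_um || dia > max_diameter_um) next
    means <- vapply(mats, function(m) mean(m[sel]), numeric(1))
    sums <- vapply(mats, function(m) sum(m[sel]), numeric(1))
    rows[[length(rows) + 1L]] <- c(cx, cy, a, dia, means, sums)
  }
  if (!length(rows)) return(empty_detections(channels))
  m <- do.call(rbind, rows)
  out <- tibble::tibble(
    vesicle_id = seq_len(nrow(m)), x = m[, 1], y = m[, 2],
    area_px = m[, 3], diameter_um = m[, 4])
  for (i in seq_along(channels)) {
    out[[paste0("mean_", channels[i])]] <- m[, 4 + i]
    out[[paste0("integrated_", channels[i])]] <- m[, 4 + length(channels) + i]
  }
  if (length(channels) == 2) {
    out$cargo_class <- classify_cargo(out, channels, bg_med, presence_factor)
    out <- out[!is.na(out$cargo_class), , drop = FALSE]
    out$vesicle_id <- seq_len(nrow(out))
  }
  class(out) <- c("vesicle_detections", class(out))
  attr(out, "background_median") <- stats::setNames(bg_med, channels)
  out
}

# Radial intensity profile of a unit uniform disc of radius R convolved with
# an isotropic Gaussian of s.d. sigma:
#   I(r) = int_0^R (rho/sigma^2) exp(-(rho - r)^2 / (2 sigma^2))
#          [I0(r rho / sigma^2) e^{-r rho / sigma^2}] d rho
# (exponentially-scaled Bessel form, overflow-safe). Used to map a true disc
# radius to its half-max footprint radius under the PSF.
disc_halfmax_radius <- function(R, sigma) {
  prof <- function(r) {
    rho <- seq(0, R, length.out = 256)
    x <- r * rho / sigma^2
    f <- (rho / sigma^2) * exp(-(rho - r)^2 / (2 * sigma^2)) *
      besselI(x, 0, expon.scaled = TRUE)
    sum((f[-1] + f[-length(f)]) / 2) * (rho[2] - rho[1])
  }
  peak <- prof(0)
  stats::uniroot(function(r) prof(r) - peak / 2, c(0, R + 5 * sigma),
                 tol = 1e-4)$root
}

# Returns a function mapping measured half-max diameters (px) to true disc
# diameters (px) by inverting the tabulated forward model. Below the
# resolution floor (a point source's half-max radius) measured sizes clamp
# to the smallest tabulated disc.
psf_diameter_corrector <- function(sigma_px, max_radius_px) {
  R_grid <- seq(0.2, max(max_radius_px * 1.5, 3 * sigma_px), length.out = 48)
  r_half <- vapply(R_grid, disc_halfmax_radius, numeric(1), sigma = sigma_px)
  function(d_half_px) {
    r <- d_half_px / 2
    R <- stats::approx(r_half, R_grid, xout = r, rule = 2)$y
    2 * R
  }
}

# Half-max re-segmentation of one detected blob: threshold the detection
# image at background + half the peak prominence inside a window around the
# blob, and keep the connected component containing the peak (pixels already
# claimed by a neighbouring blob are excluded).
halfmax_segment <- function(det, sel0, bg) {
  w <- which(sel0, arr.ind = TRUE)
  nr <- nrow(det); nc <- ncol(det)
  margin <- max(3, ceiling(sqrt(nrow(w))))
  r1 <- max(1, min(w[, 1]) - margin); r2 <- min(nr, max(w[, 1]) + margin)
  c1 <- max(1, min(w[, 2]) - margin); c2 <- min(nc, max(w[, 2]) + margin)
  win <- det[r1:r2, c1:c2]
  sel_win <- sel0[r1:r2, c1:c2]
  peak <- max(win[sel_win])
  thr <- bg + 0.5 * (peak - bg)
  m <- win > thr
  if (!any(m & sel_win)) return(sel0)
  comp <- as.matrix(EBImage::imageData(EBImage::bwlabel(m * 1)))
  pk <- which(sel_win & win == peak, arr.ind = TRUE)[1, , drop = FALSE]
  keep <- comp == comp[pk]
  out <- matrix(FALSE, nr, nc)
  out[r1:r2, c1:c2] <- keep
  out
}

empty_detections <- function(channels) {
  out <- tibble::tibble(vesicle_id = integer(), x = double(), y = double(),
                        area_px = double(), diameter_um = double())
  for (ch in channels) {
    out[[paste0("mean_", ch)]] <- double()
    out[[paste0("integrated_", ch)]] <- double()
  }
  if (length(channels) == 2) out$cargo_class <- character()
  class(out) <- c("vesicle_detections", class(out))
  out
}

#' Classify vesicle cargo composition
#'
#' A cargo channel is "present" in a vesicle when the vesicle's mean
#' intensity in that channel exceeds `presence_factor` times the channel's
#' background median. Vesicles with both channels present are `"both"`, one
#' channel `"ch1_only"` / `"ch2_only"`; a detection with neither present is
#' flagged `NA` (and dropped from the census as a spurious detection). The
#' rule is invariant under a common positive rescaling of both channels
#' (means and background medians scale together).
#'
#' @param detections A detection tibble with `mean_<ch>` columns.
#' @param channels The two channel names.
#' @param background_median Numeric length-2 background medians per channel.
#' @param presence_factor Presence multiplier (default 2).
#' @return Character vector: `"both"`, `"ch1_only"`, `"ch2_only"` or `NA`.
#' @export
classify_cargo <- function(detections, channels, background_median,
                           presence_factor = 2) {
  stopifnot(length(channels) == 2)
  m1 <- detections[[paste0("mean_", channels[1])]]
  m2 <- detections[[paste0("mean_", channels[2])]]
  p1 <- m1 > presence_factor * background_median[1]
  p2 <- m2 > presence_factor * background_median[2]
  out <- rep(NA_character_, length(m1))
  out[p1 & p2] <- "both"
  out[p1 & !p2] <- "ch1_only"
  out[!p1 & p2] <- "ch2_only"
  out
}

#' Cargo census of detected vesicles
#'
#' Counts and proportions of dual-cargo, channel-1-only and channel-2-only
#' vesicles among classified detections.
#'
#' @param detections A tibble with a `cargo_class` column, or a character
#'   vector of classes.
#' @return A one-row tibble of class `vesicle_census`: `n_total, n_both,
#'   n_ch1_only, n_ch2_only, p_both, p_ch1_only, p_ch2_only`. With no
#'   detections the proportions are `NA` (flagged empty census).
#' @examples
#' vesicle_census(c(rep("both", 10), rep("ch1_only", 5), rep("ch2_only", 5)))
#' @export
vesicle_census <- function(detections) {
  cls <- if (is.data.frame(detections)) detections$cargo_class else detections
  cls <- cls[!is.na(cls)]
  n <- length(cls)
  nb <- sum(cls == "both")
  n1 <- sum(cls == "ch1_only")
  n2 <- sum(cls == "ch2_only")
  out <- tibble::tibble(
    n_total = n, n_both = nb, n_ch1_only = n1, n_ch2_only = n2,
    p_both = if (n) nb / n else NA_real_,
    p_ch1_only = if (n) n1 / n else NA_real_,
    p_ch2_only = if (n) n2 / n else NA_real_)
  class(out) <- c("vesicle_census", class(out))
  out
}

#' Count nuclei in a nuclear-stain channel
#'
#' Blob detection (threshold, distance-transform watershed to split touching
#' discs) restricted to blobs at least `min_diameter_um` across.
#'
#' @param img An [mc_image()].
#' @param channel Channel name or index.
#' @param min_diameter_um Smallest accepted nucleus diameter, um.
#' @param threshold Intensity threshold; `NULL` uses Otsu.
#' @return Integer count of detected nuclei.
#' @examples
#' ph <- nuclei_phantom(n_nuclei = 6, imaging = imaging_params(seed = 8))
#' count_nuclei(ph$image)
#' @export
count_nuclei <- function(img, channel = 1, min_diameter_um = 1.5,
                         threshold = NULL) {
  mat <- get_channel(img, channel)
  if (diff(range(mat)) == 0) return(0L)
  thr <- if (is.null(threshold)) otsu_threshold(mat) else threshold
  mask <- mat > thr
  if (!any(mask)) return(0L)
  dmap <- EBImage::distmap(EBImage::Image(mask * 1))
  labels <- as.matrix(EBImage::imageData(EBImage::watershed(dmap, tolerance = 1)))
  amin <- pi * (min_diameter_um / 2 / img$pixel_size_um)^2
  ids <- tabulate(labels[labels > 0])
  sum(ids >= amin)
}
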