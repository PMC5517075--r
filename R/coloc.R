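#' Parameters for thresholded-ratio colocalization
#'
#' A pixel counts as colocalized when both channels exceed their intensity
#' thresholds and the ratio of the two intensities passes `ratio_cutoff`
#' (default 0.5, the conventional criterion). The symmetric form
#' `min(i1, i2) / max(i1, i2) >= cutoff` is the default so the criterion does
#' not depend on channel order; `directional = TRUE` applies
#' `i2 / i1 >= cutoff` instead.
#'
#' @param threshold_ch1,threshold_ch2 Per-channel intensity thresholds;
#'   `NULL` means Otsu's threshold computed per channel.
#' @param ratio_cutoff Ratio criterion in (0, 1], default 0.5.
#' @param directional Use the directional ch2/ch1 ratio instead of the
#'   symmetric min/max form.
#' @return An object of class `coloc_params`.
#' @export
coloc_params <- function(threshold_ch1 = NULL, threshold_ch2 = NULL,
                         ratio_cutoff = 0.5, directional = FALSE) {
  if (ratio_cutoff <= 0 || ratio_cutoff > 1) {
    stop("`ratio_cutoff` must be in (0, 1]", call. = FALSE)
  }
  for (thr in list(threshold_ch1, threshold_ch2)) {
    if (!is.null(thr) && thr < 0) stop("thresholds must be >= 0", call. = FALSE)
  }
  structure(list(threshold_ch1 = threshold_ch1, threshold_ch2 = threshold_ch2,
                 ratio_cutoff = ratio_cutoff, directional = isTRUE(directional)),
            class = "coloc_params")
}

otsu_threshold <- function(mat) {
  rng <- range(mat)
  if (diff(rng) == 0) return(rng[1])
  norm <- (mat - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  thr * diff(rng) + rng[1]
}

resolve_coloc <- function(img, ch1, ch2, params) {
  m1 <- get_channel(img, ch1)
  m2 <- get_channel(img, ch2)
  if (!all(dim(m1) == dim(m2))) stop("channel shapes differ", call. = FALSE)
  t1 <- params$threshold_ch1 %||% otsu_threshold(m1)
  t2 <- params$threshold_ch2 %||% otsu_threshold(m2)
  list(m1 = m1, m2 = m2, t1 = t1, t2 = t2)
}

#' Thresholded-ratio colocalization mask
#'
#' Binary mask of colocalized pixels: both channels above their thresholds
#' and the intensity ratio at or above the cutoff (see [coloc_params()]).
#' Raising the cutoff can only shrink the mask.
#'
#' @param img An [mc_image()].
#' @param ch1,ch2 Channel names or indices.
#' @param params A [coloc_params()].
#' @return A logical `[y, x]` matrix with attributes `threshold_ch1`,
#'   `threshold_ch2` (the thresholds actually used).
#' @examples
#' px <- array(c(100, 40, 0, 80, 90, 100, 50, 30), c(1, 4, 2))
#' m <- coloc_mask(mc_image(px), 1, 2, coloc_params(20, 20, 0.5))
#' as.vector(m) # TRUE FALSE FALSE FALSE
#' @export
coloc_mask <- function(img, ch1 = 1, ch2 = 2, params = coloc_params()) {
  r <- resolve_coloc(img, ch1, ch2, params)
  lo <- pmin(r$m1, r$m2)
  hi <- pmax(r$m1, r$m2)
  ratio_ok <- if (params$directional) {
    r$m1 > 0 & (r$m2 / pmax(r$m1, .Machine$double.eps)) >= params$ratio_cutoff
  } else {
    hi > 0 & (lo / pmax(hi, .Machine$double.eps)) >= params$ratio_cutoff
  }
  mask <- (r$m1 > r$t1) & (r$m2 > r$t2) & ratio_ok
  attr(mask, "threshold_ch1") <- r$t1
  attr(mask, "threshold_ch2") <- r$t2
  mask
}

#' Colocalized-signal fractions per channel
#'
#' For each channel: the integrated density (sum of intensities) over the
#' colocalization mask divided by the integrated density over that channel's
#' above-threshold pixels. A pixel-count variant (number of mask pixels over
#' number of above-threshold pixels) is reported alongside. A channel with no
#' above-threshold signal has undefined fractions (NA).
#'
#' @inheritParams coloc_mask
#' @param mask Optional precomputed mask from [coloc_mask()] on the same
#'   image and parameters; recomputed when missing.
#' @return A one-row tibble: `fraction_ch1`, `fraction_ch2` (integrated
#'   density), `fraction_ch1_px`, `fraction_ch2_px` (pixel count),
#'   `n_coloc_pixels`.
#' @export
coloc_fractions <- function(img, ch1 = 1, ch2 = 2, params = coloc_params(),
                            mask = NULL) {
  if (is.null(mask)) mask <- coloc_mask(img, ch1, ch2, params)
  r <- resolve_coloc(img, ch1, ch2, params)
  above1 <- r$m1 > r$t1
  above2 <- r$m2 > r$t2
  frac <- function(m, above) {
    tot <- sum(m[above])
    if (tot <= 0) return(c(NA_real_, NA_real_))
    c(sum(m[mask]) / tot, sum(mask) / sum(above))
  }
  f1 <- frac(r$m1, above1)
  f2 <- frac(r$m2, above2)
  tibble::tibble(fraction_ch1 = f1[1], fraction_ch2 = f2[1],
                 fraction_ch1_px = f1[2], fraction_ch2_px = f2[2],
                 n_coloc_pixels = sum(mask))
}

#' Per-object colocalized-signal fractions
#'
#' Restricts the colocalized-fraction computation to each object's pixel set
#' — a selected vesicle outline ([roi_polygon()]) or a detection row from
#' [detect_vesicles()] (a disc of its measured equivalent diameter around the
#' centroid). Each object's fraction is the mean of its two per-channel
#' integrated-density fractions; objects with no above-threshold pixels are
#' flagged and excluded from the summary mean.
#'
#' @inheritParams coloc_mask
#' @param objects A list of [roi_polygon()]s or a detection tibble with
#'   `x`, `y`, `diameter_um` columns.
#' @param mask Optional precomputed [coloc_mask()].
#' @return A list with `per_object` (tibble: object, per-channel and mean
#'   fractions, `flagged`) and `mean_fraction` (mean over unflagged objects).
#' @export
per_object_coloc <- function(img, ch1 = 1, ch2 = 2, objects,
                             params = coloc_params(), mask = NULL) {
  if (is.null(mask)) mask <- coloc_mask(img, ch1, ch2, params)
  r <- resolve_coloc(img, ch1, ch2, params)
  above1 <- r$m1 > r$t1
  above2 <- r$m2 > r$t2
  nr <- nrow(r$m1); nc <- ncol(r$m1)
  obj_masks <- object_pixel_masks(objects, nr, nc, img$pixel_size_um)

  rows <- purrr::imap_dfr(obj_masks, function(om, i) {
    a1 <- om & above1
    a2 <- om & above2
    t1 <- sum(r$m1[a1]); t2 <- sum(r$m2[a2])
    if (t1 <= 0 || t2 <= 0) {
      return(tibble::tibble(object = i, fraction_ch1 = NA_real_,
                            fraction_ch2 = NA_real_, fraction = NA_real_,
                            flagged = TRUE))
    }
    cm <- om & mask
    f1 <- sum(r$m1[cm]) / t1
    f2 <- sum(r$m2[cm]) / t2
    tibble::tibble(object = i, fraction_ch1 = f1, fraction_ch2 = f2,
                   fraction = (f1 + f2) / 2, flagged = FALSE)
  })
  ok <- rows$fraction[!rows$flagged]
  list(per_object = rows,
       mean_fraction = if (length(ok)) mean(ok) else NA_real_)
}

# Build logical pixel masks for a list of polygon ROIs or a detection table.
object_pixel_masks <- function(objects, nrow_px, ncol_px, pixel_size_um) {
  if (is.data.frame(objects)) {
    stopifnot(all(c("x", "y", "diameter_um") %in% names(objects)))
    return(lapply(seq_len(nrow(objects)), function(k) {
      r_px <- objects$diameter_um[k] / 2 / pixel_size_um + 1
      m <- matrix(FALSE, nrow_px, ncol_px)
      mm <- paint_disc(m * 0, objects$x[k], objects$y[k], r_px, 1)
      mm > 0
    }))
  }
  lapply(objects, function(o) {
    stopifnot(inherits(o, "roi_polygon"))
    polygon_mask(o, nrow_px, ncol_px)
  })
}
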