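# Internal rasterization helpers for the phantom generators. All painters
# operate on plain [y, x] matrices in pixel units and set values by pixel
# center membership; acquisition effects (PSF, noise, quantization) are
# applied once per channel by apply_imaging().

blank_canvas <- function(width_px, height_px, background = 0) {
  matrix(background, nrow = height_px, ncol = width_px)
}

# Paint a filled disc centred at continuous (cx, cy), radius r (px).
# mode "max" keeps the brighter of existing and new value; "set" overwrites.
paint_disc <- function(mat, cx, cy, r, value, mode = c("max", "set")) {
  mode <- match.arg(mode)
  nr <- nrow(mat); nc <- ncol(mat)
  cols <- max(1, floor(cx - r) + 1):min(nc, ceiling(cx + r) + 1)
  rows <- max(1, floor(cy - r) + 1):min(nr, ceiling(cy + r) + 1)
  if (!length(cols) || !length(rows)) return(mat)
  gx <- rep(cols - 1, each = length(rows))
  gy <- rep(rows - 1, times = length(cols))
  inside <- (gx - cx)^2 + (gy - cy)^2 <= r^2
  idx <- cbind(gy[inside] + 1, gx[inside] + 1)
  if (nrow(idx)) {
    mat[idx] <- if (mode == "max") pmax(mat[idx], value) else value
  }
  mat
}

# Paint a polyline band of total width width_px at a constant value.
paint_polyline <- function(mat, pts, width_px, value) {
  m <- band_mask_around(pts, nrow(mat), ncol(mat), width_px / 2)
  mat[m] <- pmax(mat[m], value)
  mat
}

# Resample a polyline at (approximately) uniform arc-length spacing step.
densify_polyline <- function(pts, step = 0.25) {
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total == 0) return(pts)
  t_out <- seq(0, total, by = step)
  if (t_out[length(t_out)] < total) t_out <- c(t_out, total)
  x <- stats::approx(s, pts[, 1], xout = t_out)$y
  y <- stats::approx(s, pts[, 2], xout = t_out)$y
  cbind(x = x, y = y)
}

polyline_length_px <- function(pts) {
  if (nrow(pts) < 2) return(0)
  sum(sqrt(rowSums(diff(pts)^2)))
}

# Apply the acquisition model to a [y, x] intensity matrix: Gaussian PSF,
# Poisson shot noise on the blurred signal, additive Gaussian read noise,
# then clipping and rounding to the detector bit depth. Callers are expected
# to have seeded the RNG (generators do this once per phantom).
apply_imaging <- function(mat, imaging) {
  sigma_px <- imaging$psf_sigma_um / imaging$pixel_size_um
  if (sigma_px > 0) {
    mat <- as.matrix(EBImage::gblur(mat, sigma = sigma_px))
    mat[mat < 0] <- 0
  }
  if (imaging$poisson_noise) {
    mat <- matrix(stats::rpois(length(mat), lambda = mat),
                  nrow = nrow(mat), ncol = ncol(mat))
  }
  if (imaging$read_noise_sigma > 0) {
    mat <- mat + matrix(stats::rnorm(length(mat), sd = imaging$read_noise_sigma),
                        nrow = nrow(mat), ncol = ncol(mat))
  }
  top <- 2^imaging$bit_depth - 1
  mat <- round(mat)
  mat[mat < 0] <- 0
  mat[mat > top] <- top
  mat
}

# Rejection-sample n points in [margin, w-margin] x [margin, h-margin] (px)
# with pairwise distance >= min_sep_px. Errors after bounded retries.
place_points <- function(n, width_px, height_px, min_sep_px, margin_px,
                         max_tries = 200 * max(n, 1)) {
  if (n == 0) return(cbind(x = numeric(0), y = numeric(0)))
  lo_x <- margin_px; hi_x <- width_px - 1 - margin_px
  lo_y <- margin_px; hi_y <- height_px - 1 - margin_px
  if (hi_x <= lo_x || hi_y <= lo_y) {
    stop("field of view too small for the requested margins", call. = FALSE)
  }
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0
  while (length(xs) < n) {
    tries <- tries + 1
    if (tries > max_tries) {
      stop(sprintf(
        "could not place %d objects at min separation %.1f px after %d tries; field too crowded",
        n, min_sep_px, max_tries), call. = FALSE)
    }
    cx <- stats::runif(1, lo_x, hi_x)
    cy <- stats::runif(1, lo_y, hi_y)
    if (length(xs) == 0 || all((xs - cx)^2 + (ys - cy)^2 >= min_sep_px^2)) {
      xs <- c(xs, cx); ys <- c(ys, cy)
    }
  }
  cbind(x = xs, y = ys)
}
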