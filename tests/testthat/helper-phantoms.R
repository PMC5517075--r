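# Shared helpers for building small fixtures in code.

# Acquisition with all stochastic/optical effects off: rendered pixels equal
# planted intensities exactly.
ideal_imaging <- function(seed = 1, pixel_size_um = 0.1) {
  imaging_params(pixel_size_um = pixel_size_um, psf_sigma_um = 0,
                 poisson_noise = FALSE, read_noise_sigma = 0, seed = seed)
}

# Densely sampled half circle of radius r starting at (cx + r, cy).
half_circle <- function(r = 10, n = 1000, cx = 0, cy = 0) {
  th <- seq(0, pi, length.out = n)
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# Rotate + scale + translate a point matrix.
transform_points <- function(pts, deg = 0, scale = 1, dx = 0, dy = 0) {
  th <- deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  t(R %*% t(pts * scale)) + matrix(c(dx, dy), nrow(pts), 2, byrow = TRUE)
}

# One-channel image from a plain [y, x] matrix.
as_img <- function(mat, pixel_size_um = 0.1, name = "ch1") {
  mc_image(array(mat, c(dim(mat), 1)), name, pixel_size_um)
}
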