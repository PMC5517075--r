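test_that("band pixels match a brute-force distance oracle", {
  line <- cbind(c(0, 9), c(2, 2))
  expect_equal(nrow(band_pixels(line, 1, dim_px = c(5, 10))), 10)

  oracle_count <- function(pts, half, nr, nc) {
    n <- 0
    for (r in seq_len(nr)) for (cc in seq_len(nc)) {
      x <- cc - 1; y <- r - 1
      d <- Inf
      for (k in seq_len(nrow(pts) - 1)) {
        a <- pts[k, ]; b <- pts[k + 1, ]
        t <- max(0, min(1, sum((c(x, y) - a) * (b - a)) / sum((b - a)^2)))
        p <- a + t * (b - a)
        d <- min(d, sqrt(sum((c(x, y) - p)^2)))
      }
      if (d <= half) n <- n + 1
    }
    n
  }
  expect_equal(nrow(suppressWarnings(band_pixels(line, 3, dim_px = c(7, 10)))),
               oracle_count(line, 1.5, 7, 10))
  bent <- cbind(c(1, 5, 8), c(1, 4, 1))
  expect_equal(nrow(suppressWarnings(band_pixels(bent, 4, dim_px = c(8, 10)))),
               oracle_count(bent, 2, 8, 10))
  # band larger than the image: clipped, counts match the in-bounds oracle
  expect_warning(clipped <- band_pixels(line, 30, dim_px = c(6, 10)), "clipped")
  expect_equal(nrow(clipped), oracle_count(line, 15, 6, 10))
})

test_that("normalized band ratio behaves on painted fixtures", {
  uniform <- as_img(matrix(500, 60, 120))
  r <- dt_mt_ratio(uniform, 1,
                   roi_polyline(cbind(c(5, 100), c(15, 15)), width_px = 20),
                   roi_polyline(cbind(c(5, 100), c(45, 45)), width_px = 6))
  expect_equal(r$ratio, 1)

  mat <- matrix(0, 80, 120)
  dt_line <- cbind(c(5, 110), c(20, 20))
  mt_line <- cbind(c(5, 110), c(60, 60))
  mat <- paint_polyline(mat, dt_line, 20, 200)
  mat <- paint_polyline(mat, mt_line, 6, 100)
  painted <- as_img(mat)
  r2 <- dt_mt_ratio(painted, 1, roi_polyline(dt_line, width_px = 20),
                    roi_polyline(mt_line, width_px = 6))
  expect_equal(r2$ratio, 2)
  expect_equal(r2$dt_mean, 200)

  # illumination invariance and monotonicity in the tube band
  bright <- as_img(mat * 3.7)
  expect_equal(dt_mt_ratio(bright, 1, roi_polyline(dt_line, width_px = 20),
                           roi_polyline(mt_line, width_px = 6))$ratio, 2)
  mat_hi <- paint_polyline(matrix(0, 80, 120), dt_line, 20, 300)
  mat_hi <- paint_polyline(mat_hi, mt_line, 6, 100)
  expect_gt(dt_mt_ratio(as_img(mat_hi), 1,
                        roi_polyline(dt_line, width_px = 20),
                        roi_polyline(mt_line, width_px = 6))$ratio, r2$ratio)

  dark <- as_img(matrix(0, 40, 60))
  expect_error(dt_mt_ratio(dark, 1, roi_polyline(cbind(c(2, 50), c(10, 10))),
                           roi_polyline(cbind(c(2, 50), c(30, 30)))),
               "zero")
})

test_that("band ratios recover the generating truth across planted ratios", {
  for (planted in c(0.5, 1, 2, 4)) {
    ratios <- truths <- numeric(4)
    for (i in 1:4) {
      ph <- intensity_band_phantom(dt_intensity = 1000 * planted,
                                   mt_intensity = 1000,
                                   imaging = imaging_params(seed = 50 * planted + i))
      ratios[i] <- dt_mt_ratio(ph$image, 1, ph$dt_roi, ph$mt_roi)$ratio
      truths[i] <- ph$truth$dt_mt_true_ratio
    }
    expect_lt(abs(mean(ratios) - mean(truths)) / mean(truths), 0.05)
  }
})

test_that("SAR/AFR sum-intensity ratio matches the pixel-enumeration truth", {
  square <- roi_polygon(cbind(c(10, 60, 60, 10), c(10, 10, 60, 60)))
  ph <- apical_cell_phantom(square, sar_band_width_um = 0.3,
                            sar_intensity = 200, afr_intensity = 100,
                            background_intensity = 0,
                            imaging = ideal_imaging(seed = 3))
  r <- sar_afr_ratio(ph$image, 1, square, band_width_px = 3)
  expect_lt(abs(r$ratio - ph$truth$sar_afr_true_ratio) /
              ph$truth$sar_afr_true_ratio, 0.03)

  # equal planted totals in the two regions: ratio 1 by construction
  eq_sar <- 100 * ph$truth$afr_pixels / ph$truth$sar_pixels
  ph_eq <- apical_cell_phantom(square, sar_band_width_um = 0.3,
                               sar_intensity = eq_sar, afr_intensity = 100,
                               background_intensity = 0,
                               imaging = ideal_imaging(seed = 3))
  r_eq <- sar_afr_ratio(ph_eq$image, 1, square, band_width_px = 3)
  expect_equal(r_eq$ratio, 1, tolerance = 0.02)

  # illumination invariance
  bright <- mc_image(ph$image$pixels * 2.5, "apical", 0.1)
  expect_equal(sar_afr_ratio(bright, 1, square, band_width_px = 3)$ratio,
               r$ratio, tolerance = 1e-9)

  # inner region must stay inside the contour
  outer_inner <- roi_polygon(cbind(c(5, 70, 70, 5), c(5, 5, 70, 70)))
  expect_error(sar_afr_ratio(ph$image, 1, square, inner = outer_inner),
               "inside")
})
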