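test_that("tube phantom plants the requested tortuosity", {
  straight <- tube_phantom(length_um = 10, diameter_um = 2, tortuosity = 1,
                           imaging = ideal_imaging())
  expect_identical(straight$truth$arc_chord_ratio, 1)

  curved <- tube_phantom(length_um = 20, diameter_um = 2, tortuosity = 1.226,
                         imaging = imaging_params(seed = 0))
  expect_gte(curved$truth$arc_chord_ratio, 1.214)
  expect_lte(curved$truth$arc_chord_ratio, 1.238)
  # amplitude solved to 1e-4 on the ratio
  expect_lt(abs(curved$truth$arc_chord_ratio - 1.226), 2e-4)

  expect_error(tube_phantom(tortuosity = 0.9), ">= 1")
  expect_error(tube_phantom(length_um = 5, diameter_um = 6), "smaller")
  expect_error(tube_phantom(length_um = 40, tortuosity = 1.5,
                            field_width_um = 30), "field of view")
})

test_that("ground-truth geometry comes from planted geometry, not pixels", {
  # heavy noise changes pixels but not the recorded truth
  a <- tube_phantom(length_um = 15, diameter_um = 2, tortuosity = 1.15,
                    imaging = imaging_params(seed = 1, read_noise_sigma = 200))
  b <- tube_phantom(length_um = 15, diameter_um = 2, tortuosity = 1.15,
                    imaging = imaging_params(seed = 9, read_noise_sigma = 0))
  expect_false(identical(a$image$pixels, b$image$pixels))
  expect_identical(a$truth$centerline, b$truth$centerline)
  expect_identical(a$truth$arc_chord_ratio, b$truth$arc_chord_ratio)
})

test_that("junction lattice records exact per-segment truth", {
  ph <- junction_phantom(n_cells = 9, orientation_jitter_deg = 0,
                         axial_length_um = 2, circumferential_length_um = 1,
                         imaging = ideal_imaging(seed = 4))
  segs <- ph$truth$segments
  expect_true(all(segs$angle_deg[segs$orientation == "axial"] == 0))
  expect_true(all(segs$angle_deg[segs$orientation == "circumferential"] == 90))
  # length conservation: recorded total equals the planted lattice total
  expect_equal(sum(segs$length_um), ph$truth$total_length_um)
  n_ax <- sum(segs$orientation == "axial")
  n_ci <- sum(segs$orientation == "circumferential")
  expect_equal(sum(segs$length_um), n_ax * 2 + n_ci * 1, tolerance = 1e-9)

  # jittered angles: empirical s.d. close to the requested 10 degrees
  big <- junction_phantom(n_cells = 110, orientation_jitter_deg = 10,
                          imaging = imaging_params(seed = 7))
  planted <- big$truth$segments
  expect_gt(nrow(planted), 200)
  dev <- ifelse(planted$orientation == "axial", planted$angle_deg,
                90 - planted$angle_deg)
  # folded angles are half-normal; the RMS deviation estimates the jitter s.d.
  expect_lt(abs(sqrt(mean(dev^2)) - 10), 3)
  expect_error(junction_phantom(n_cells = 0), ">= 1")
})

test_that("vesicle phantom draws classes and renders overlap as specified", {
  expect_error(vesicle_phantom(n_vesicles = 2, p_both = 0.5, p_ch1_only = 0.2,
                               p_ch2_only = 0.2), "sum to 1")
  expect_error(vesicle_phantom(n_vesicles = 2, within_vesicle_overlap = 1.2),
               "\\[0, 1\\]")

  # full dual cargo with full overlap: the two channels are identical
  ph <- vesicle_phantom(n_vesicles = 6, p_both = 1, p_ch1_only = 0,
                        p_ch2_only = 0, within_vesicle_overlap = 1,
                        imaging = ideal_imaging(seed = 5))
  expect_identical(ph$image$pixels[, , 1], ph$image$pixels[, , 2])

  # empty field
  ph0 <- vesicle_phantom(n_vesicles = 0, background_intensity = 0,
                         imaging = ideal_imaging(seed = 5))
  expect_equal(nrow(ph0$truth$vesicles), 0)
  expect_true(all(ph0$image$pixels == 0))

  # class draw recorded in ground truth matches its own tally, and the
  # pairwise separation constraint holds
  ph2 <- vesicle_phantom(n_vesicles = 60, min_separation_um = 1.5,
                         imaging = imaging_params(seed = 0))
  v <- ph2$truth$vesicles
  expect_equal(nrow(v), 60)
  expect_setequal(unique(v$cargo_class),
                  c("both", "ch1_only", "ch2_only"))
  dmat <- as.matrix(stats::dist(cbind(v$x, v$y))) * 0.1
  expect_true(all(dmat[upper.tri(dmat)] >= 1.5 - 1e-9))

  # overcrowding errors after bounded retries
  expect_error(vesicle_phantom(n_vesicles = 400, field_um = 8,
                               imaging = imaging_params(seed = 1)),
               "crowded|too small")
})

test_that("apical cell phantom matches an exhaustive pixel-count oracle", {
  square <- roi_polygon(cbind(c(10, 60, 60, 10), c(10, 10, 60, 60)))
  ph <- apical_cell_phantom(square, sar_band_width_um = 0.3,
                            sar_intensity = 200, afr_intensity = 100,
                            imaging = ideal_imaging(seed = 6))
  # independent oracle: brute-force distance of every pixel center to the
  # four edges of the square, and even-odd interior test
  v <- rbind(square$vertices, square$vertices[1, ])
  nr <- nrow(ph$image$pixels); nc <- ncol(ph$image$pixels)
  band <- interior <- 0
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      x <- cc - 1; y <- r - 1
      d <- Inf
      for (k in 1:4) {
        a <- v[k, ]; b <- v[k + 1, ]
        t <- max(0, min(1, sum((c(x, y) - a) * (b - a)) / sum((b - a)^2)))
        p <- a + t * (b - a)
        d <- min(d, sqrt(sum((c(x, y) - p)^2)))
      }
      in_band <- d <= 1.5  # 0.3 um at 0.1 um/px, half-width 1.5 px
      inside <- x > 10 && x < 60 && y > 10 && y < 60
      if (in_band) band <- band + 1
      else if (inside) interior <- interior + 1
    }
  }
  expect_equal(ph$truth$sar_pixels, band)
  expect_equal(ph$truth$afr_pixels, interior)
  expect_equal(ph$truth$sar_afr_true_ratio, (200 * band) / (100 * interior))

  # degenerate interior intensity: flagged, not a number
  dark <- apical_cell_phantom(square, afr_intensity = 0,
                              imaging = ideal_imaging(seed = 6))
  expect_false(dark$truth$ratio_defined)
  expect_true(is.na(dark$truth$sar_afr_true_ratio))

  expect_error(apical_cell_phantom(square, sar_band_width_um = 6,
                                   imaging = ideal_imaging()),
               "inradius")
})

test_that("nuclei phantom plants the requested count, seed moves positions", {
  ph <- nuclei_phantom(n_nuclei = 26, imaging = imaging_params(seed = 1))
  expect_equal(nrow(ph$truth$nuclei), 26)
  ph0 <- nuclei_phantom(n_nuclei = 0, background_intensity = 0,
                        imaging = ideal_imaging())
  expect_true(all(ph0$image$pixels == 0))
  a <- nuclei_phantom(n_nuclei = 25, imaging = imaging_params(seed = 1))
  b <- nuclei_phantom(n_nuclei = 25, imaging = imaging_params(seed = 2))
  expect_equal(nrow(a$truth$nuclei), nrow(b$truth$nuclei))
  expect_false(identical(a$truth$nuclei$x, b$truth$nuclei$x))
  expect_error(nuclei_phantom(n_nuclei = 5, min_separation_um = 2,
                              nucleus_diameter_um = 3), "at least")
})

test_that("intensity band phantom records the analytic generating ratio", {
  # without optics the generating ratio is the painted ratio
  ph0 <- intensity_band_phantom(dt_intensity = 300, mt_intensity = 100,
                                background_intensity = 0,
                                imaging = ideal_imaging(seed = 2))
  expect_equal(ph0$truth$dt_mt_true_ratio, 3)
  # with a PSF the narrow band loses proportionally more to its edges,
  # raising the band-mean ratio above the nominal painted value
  ph1 <- intensity_band_phantom(dt_intensity = 300, mt_intensity = 100,
                                imaging = imaging_params(seed = 2))
  expect_gt(ph1$truth$dt_mt_true_ratio, ph1$truth$nominal_ratio)
})
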