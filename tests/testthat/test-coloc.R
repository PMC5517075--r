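make_two_channel <- function(m1, m2, pixel_size_um = 0.1) {
  mc_image(array(c(m1, m2), c(dim(m1), 2)), c("ch1", "ch2"), pixel_size_um)
}

test_that("the four-pixel worked example matches hand enumeration", {
  img <- make_two_channel(matrix(c(100, 40, 0, 80), 1, 4),
                          matrix(c(90, 100, 50, 30), 1, 4))
  pars <- coloc_params(20, 20, 0.5)
  mask <- coloc_mask(img, "ch1", "ch2", pars)
  # ratios 0.9, 0.4, (below threshold), 0.375 -> only the first colocalizes
  expect_equal(as.vector(mask), c(TRUE, FALSE, FALSE, FALSE))
  fr <- coloc_fractions(img, "ch1", "ch2", pars, mask)
  expect_equal(fr$fraction_ch1, 100 / (100 + 40 + 80))
  expect_equal(fr$fraction_ch2, 90 / (90 + 100 + 50 + 30))
  expect_equal(fr$n_coloc_pixels, 1)
  # pixel-count variant: 1 of 3 and 1 of 4 above-threshold pixels
  expect_equal(fr$fraction_ch1_px, 1 / 3)
  expect_equal(fr$fraction_ch2_px, 1 / 4)
})

test_that("degenerate channel patterns give the expected masks", {
  m <- matrix(c(0, 5, 9, 0), 2, 2)
  same <- make_two_channel(m, m)
  mask <- coloc_mask(same, 1, 2, coloc_params(0, 0, 0.5))
  expect_equal(as.vector(mask), as.vector(m > 0))
  fr <- coloc_fractions(same, 1, 2, coloc_params(0, 0, 0.5), mask)
  expect_equal(fr$fraction_ch1, 1)
  expect_equal(fr$fraction_ch2, 1)

  disjoint <- make_two_channel(matrix(c(9, 0, 0, 0), 2, 2),
                               matrix(c(0, 0, 0, 9), 2, 2))
  mask_d <- coloc_mask(disjoint, 1, 2, coloc_params(0, 0, 0.5))
  expect_false(any(mask_d))
  fr_d <- coloc_fractions(disjoint, 1, 2, coloc_params(0, 0, 0.5), mask_d)
  expect_equal(fr_d$fraction_ch1, 0)
  expect_equal(fr_d$fraction_ch2, 0)

  expect_error(coloc_mask(mc_image(array(0, c(2, 2, 1))), 1, 2), "unknown")
  expect_error(coloc_params(ratio_cutoff = 0), "\\(0, 1\\]")
})

test_that("mask is channel-symmetric, scale-invariant, monotone in cutoff", {
  set.seed(41)
  m1 <- matrix(rpois(64, 40), 8, 8)
  m2 <- matrix(rpois(64, 40), 8, 8)
  img <- make_two_channel(m1, m2)
  rev <- make_two_channel(m2, m1)
  pars <- coloc_params(30, 30, 0.5)
  expect_equal(as.vector(coloc_mask(img, 1, 2, pars)),
               as.vector(coloc_mask(rev, 1, 2, pars)))

  scaled <- make_two_channel(m1 * 3, m2 * 3)
  pars_s <- coloc_params(90, 90, 0.5)
  expect_equal(as.vector(coloc_mask(scaled, 1, 2, pars_s)),
               as.vector(coloc_mask(img, 1, 2, pars)))
  fr <- coloc_fractions(img, 1, 2, pars)
  fr_s <- coloc_fractions(scaled, 1, 2, pars_s)
  expect_equal(fr_s$fraction_ch1, fr$fraction_ch1)
  expect_equal(fr_s$fraction_ch2, fr$fraction_ch2)

  masks <- lapply(c(0.3, 0.5, 0.7, 0.9), function(ct) {
    coloc_mask(img, 1, 2, coloc_params(30, 30, ct))
  })
  for (k in 2:4) expect_true(all(masks[[k]] <= masks[[k - 1]]))
})

test_that("vectorized rule agrees with a literal per-pixel oracle", {
  oracle <- function(m1, m2, t1, t2, cut) {
    out <- matrix(FALSE, nrow(m1), ncol(m1))
    for (r in seq_len(nrow(m1))) for (cc in seq_len(ncol(m1))) {
      a <- m1[r, cc]; b <- m2[r, cc]
      if (a > t1 && b > t2 && min(a, b) / max(a, b) >= cut) out[r, cc] <- TRUE
    }
    out
  }
  set.seed(42)
  for (i in 1:10) {
    m1 <- matrix(sample(0:120, 48, TRUE), 6, 8)
    m2 <- matrix(sample(0:120, 48, TRUE), 6, 8)
    t1 <- sample(0:50, 1); t2 <- sample(0:50, 1)
    cut <- runif(1, 0.2, 0.9)
    got <- coloc_mask(make_two_channel(m1, m2), 1, 2,
                      coloc_params(t1, t2, cut))
    expect_equal(as.vector(got), as.vector(oracle(m1, m2, t1, t2, cut)))
  }
})

test_that("per-object fractions recover planted overlap and flag blanks", {
  # one vesicle with full overlap: fraction exactly 1
  ph1 <- vesicle_phantom(n_vesicles = 1, p_both = 1, p_ch1_only = 0,
                         p_ch2_only = 0, within_vesicle_overlap = 1,
                         background_intensity = 0,
                         imaging = ideal_imaging(seed = 2))
  po1 <- per_object_coloc(ph1$image, "ch1", "ch2", ph1$truth$vesicles,
                          coloc_params(0, 0, 0.5))
  expect_equal(po1$mean_fraction, 1)

  # an object over a blank region is flagged and excluded from the mean
  blank_obj <- tibble::tibble(x = 5, y = 5, diameter_um = 0.5)
  both <- dplyr::bind_rows(ph1$truth$vesicles[, c("x", "y", "diameter_um")],
                           blank_obj)
  po2 <- per_object_coloc(ph1$image, "ch1", "ch2", both, coloc_params(0, 0, 0.5))
  expect_true(po2$per_object$flagged[2])
  expect_equal(po2$mean_fraction, 1)

  # planted overlap 0.6 recovered within 0.05 at modest n, low noise
  ph <- vesicle_phantom(n_vesicles = 40, p_both = 1, p_ch1_only = 0,
                        p_ch2_only = 0, within_vesicle_overlap = 0.6,
                        imaging = imaging_params(seed = 6, psf_sigma_um = 0.085,
                                                 poisson_noise = FALSE,
                                                 read_noise_sigma = 2))
  det <- detect_vesicles(ph$image)
  po <- per_object_coloc(ph$image, "ch1", "ch2", det)
  expect_lt(abs(po$mean_fraction - 0.6), 0.05)
})
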