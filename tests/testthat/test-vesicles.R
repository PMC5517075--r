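test_that("detection finds planted vesicles with no spurious hits", {
  ph <- vesicle_phantom(n_vesicles = 50,
                        imaging = imaging_params(seed = 10, poisson_noise = FALSE,
                                                 read_noise_sigma = 2))
  det <- detect_vesicles(ph$image)
  expect_gte(nrow(det), 48)
  # every detection sits within 2 px of a planted centroid (no spurious)
  truth <- ph$truth$vesicles
  for (k in seq_len(nrow(det))) {
    d <- sqrt((truth$x - det$x[k])^2 + (truth$y - det$y[k])^2)
    expect_lte(min(d), 2)
  }

  blank <- mc_image(array(50, c(80, 80, 2)), c("ch1", "ch2"), 0.1)
  expect_equal(nrow(detect_vesicles(blank)), 0)

  # recall and precision >= 95% on the default phantom at default noise
  ph2 <- vesicle_phantom(n_vesicles = 100, imaging = imaging_params(seed = 11))
  det2 <- detect_vesicles(ph2$image)
  tr <- ph2$truth$vesicles
  matched <- vapply(seq_len(nrow(det2)), function(k) {
    min(sqrt((tr$x - det2$x[k])^2 + (tr$y - det2$y[k])^2)) <= 2
  }, logical(1))
  recall <- vapply(seq_len(nrow(tr)), function(k) {
    min(sqrt((det2$x - tr$x[k])^2 + (det2$y - tr$y[k])^2)) <= 2
  }, logical(1))
  expect_gte(mean(matched), 0.95)  # precision
  expect_gte(mean(recall), 0.95)   # recall
})

test_that("two vesicles at minimum separation stay distinct", {
  ph <- vesicle_phantom(n_vesicles = 25, min_separation_um = 1.5,
                        field_um = 12,
                        imaging = imaging_params(seed = 12, poisson_noise = FALSE,
                                                 read_noise_sigma = 2))
  d <- as.matrix(stats::dist(cbind(ph$truth$vesicles$x, ph$truth$vesicles$y)))
  diag(d) <- Inf
  expect_lt(min(d) * 0.1, 1.8)  # the field really is crowded
  det <- detect_vesicles(ph$image)
  expect_equal(nrow(det), 25)
})

test_that("equivalent diameters follow area and undo PSF inflation", {
  # a perfect disc of radius 5 px at 0.1 um/px, no optics: exactly pi r^2
  mat <- paint_disc(matrix(0, 40, 40), 20, 20, 5, 1000)
  img <- mc_image(array(c(mat, mat), c(40, 40, 2)), c("ch1", "ch2"), 0.1)
  det <- detect_vesicles(img, detect_threshold = 1)
  expect_equal(nrow(det), 1)
  area <- sum(mat > 0)
  expect_equal(det$diameter_um, 2 * sqrt(area / pi) * 0.1, tolerance = 0.05)
  expect_equal(det$diameter_um, 1.0, tolerance = 0.06)

  # 1.3 um endosomes under the default PSF: mean within 10%
  big <- vesicle_phantom(n_vesicles = 15, p_both = 1, p_ch1_only = 0,
                         p_ch2_only = 0, within_vesicle_overlap = 1,
                         diameter_um_mean = 1.3, diameter_um_sd = 0.1,
                         min_separation_um = 3.5,
                         imaging = imaging_params(seed = 13))
  db <- detect_vesicles(big$image, min_diameter_um = 0.5, max_diameter_um = 4,
                        psf_sigma_um = 0.2)
  expect_lt(abs(mean(db$diameter_um) - 1.3) / 1.3, 0.10)

  # 0.28 um endosomes at 0.05 um/px near the resolution limit: within 20%
  small <- vesicle_phantom(n_vesicles = 20, p_both = 1, p_ch1_only = 0,
                           p_ch2_only = 0, within_vesicle_overlap = 1,
                           diameter_um_mean = 0.28, diameter_um_sd = 0.02,
                           min_separation_um = 1.2, field_um = 10,
                           imaging = imaging_params(seed = 14,
                                                    pixel_size_um = 0.05,
                                                    psf_sigma_um = 0.085))
  ds <- detect_vesicles(small$image, min_diameter_um = 0.1,
                        max_diameter_um = 0.9, psf_sigma_um = 0.085)
  expect_lt(abs(mean(ds$diameter_um) - 0.28) / 0.28, 0.20)
})

test_that("cargo classification follows presence and is scale invariant", {
  ph <- vesicle_phantom(n_vesicles = 30, imaging = imaging_params(seed = 15))
  det <- detect_vesicles(ph$image)
  truth <- ph$truth$vesicles
  # classified classes agree with the planted class of the nearest vesicle
  for (k in seq_len(nrow(det))) {
    j <- which.min((truth$x - det$x[k])^2 + (truth$y - det$y[k])^2)
    expect_equal(det$cargo_class[k], truth$cargo_class[j])
  }
  # invariance under common positive rescaling of both channels
  scaled <- mc_image(ph$image$pixels * 2.5, c("ch1", "ch2"), 0.1)
  det_s <- detect_vesicles(scaled)
  expect_equal(det_s$cargo_class, det$cargo_class)
})

test_that("census tallies classes and flags the empty case", {
  cen <- vesicle_census(c(rep("both", 10), rep("ch1_only", 5),
                          rep("ch2_only", 5)))
  expect_equal(cen$n_total, 20)
  expect_equal(c(cen$p_both, cen$p_ch1_only, cen$p_ch2_only),
               c(0.5, 0.25, 0.25))
  expect_equal(cen$p_both + cen$p_ch1_only + cen$p_ch2_only, 1)

  empty <- vesicle_census(character(0))
  expect_equal(empty$n_total, 0)
  expect_true(is.na(empty$p_both))

  # equals a brute-force tally over a random class list
  set.seed(16)
  cls <- sample(c("both", "ch1_only", "ch2_only"), 57, TRUE)
  cen2 <- vesicle_census(cls)
  expect_equal(cen2$n_both, sum(cls == "both"))
  expect_equal(cen2$n_ch1_only, sum(cls == "ch1_only"))
  expect_equal(cen2$n_ch2_only, sum(cls == "ch2_only"))
})

test_that("nuclei counting is exact on planted fields", {
  ph <- nuclei_phantom(n_nuclei = 26, imaging = imaging_params(seed = 17))
  expect_equal(count_nuclei(ph$image), 26)
  blank <- mc_image(array(0, c(60, 60, 1)), "nuclei", 0.1)
  expect_equal(count_nuclei(blank), 0)
  # planted counts 20-30: exact recovery in at least 95% of fields
  set.seed(18)
  planted <- sample(20:30, 40, TRUE)
  exact <- 0
  for (i in seq_along(planted)) {
    phi <- nuclei_phantom(n_nuclei = planted[i],
                          imaging = imaging_params(seed = 1000 + i))
    if (count_nuclei(phi$image) == planted[i]) exact <- exact + 1
  }
  expect_gte(exact, ceiling(0.95 * length(planted)))
})
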