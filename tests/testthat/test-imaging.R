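test_that("binarisation separates a two-level image exactly and guards degenerate ones", {
  img <- matrix(10, 60, 60)
  img[20:40, 25:35] <- 200
  mask <- binarise(img)
  expect_identical(c(mask), c(img > 100))
  # all-zero image
  expect_warning(m0 <- binarise(matrix(0, 20, 20)), "constant")
  expect_false(any(m0))
  # pure-noise image: almost nothing should survive the default method
  set.seed(12)
  noise <- matrix(rnorm(100 * 100, 50, 4), 100, 100)
  expect_warning(mn <- binarise(noise), "separable")
  expect_lt(mean(mn), 0.01)
  # manual threshold bypasses the guard
  mm <- binarise(img, method = "manual", manual_threshold = 100)
  expect_identical(c(mm), c(img > 100))
})

test_that("connected labelling finds 8-connected components", {
  m <- matrix(FALSE, 10, 10)
  m[2:3, 2:3] <- TRUE          # blob 1
  m[5, 5] <- TRUE; m[6, 6] <- TRUE # diagonal pair: one 8-connected blob
  m[9, 1:4] <- TRUE            # blob 3
  lab <- label_components(m)
  expect_equal(max(lab), 3)
  expect_equal(lab[5, 5], lab[6, 6])
  expect_true(all(lab[!m] == 0))
})

test_that("moment ellipses recover discs, rectangles and rotated rods", {
  # filled disc radius 50
  nr <- 120
  cc <- outer(1:nr, 1:nr, function(r, c) (r - 60)^2 + (c - 60)^2 <= 50^2)
  d <- fit_ellipses(cc)
  expect_equal(nrow(d), 1)
  expect_equal(d$major_axis_px, 100, tolerance = 0.01)
  expect_equal(d$minor_axis_px, 100, tolerance = 0.01)
  expect_lt(d$eccentricity, 0.1)

  # axis-aligned rectangle 60 x 12: axis ratio is exactly a/b under the
  # unit-pixel-corrected moments
  rect <- matrix(FALSE, 80, 100)
  rect[30:41, 20:79] <- TRUE
  r <- fit_ellipses(rect)
  expect_equal(r$major_axis_px / r$minor_axis_px, 60 / 12, tolerance = 1e-9)
  expect_equal(r$major_axis_px, 60 * 2 / sqrt(3), tolerance = 1e-9)

  # rotated synthetic rod vs the continuous stadium-moment oracle
  cells <- data.frame(length_um = 4, width_um = 1.2, orientation_deg = 30)
  img <- render_image(cells, canvas_px = c(120, 120), pixel_size_um = 0.1,
                      psf_sigma_px = 0, noise_sd = 0, seed = 1)
  reg <- fit_ellipses(img$truth_labels > 0)
  oracle <- stadium_moment_axes(40, 12)
  expect_equal(reg$major_axis_px, oracle["major"], tolerance = 0.03,
               ignore_attr = TRUE)
  expect_equal(reg$minor_axis_px, oracle["minor"], tolerance = 0.05,
               ignore_attr = TRUE)
})

test_that("axis lengths are invariant under 90-degree rotation and translation", {
  cells <- data.frame(length_um = 3.6, width_um = 1.1, orientation_deg = 20)
  img <- render_image(cells, canvas_px = c(100, 100), pixel_size_um = 0.1,
                      psf_sigma_px = 0, noise_sd = 0, seed = 4)
  m <- img$truth_labels > 0
  base <- fit_ellipses(m)
  rot <- fit_ellipses(t(m)[ncol(m):1, ]) # 90-degree rotation
  expect_equal(rot$major_axis_px, base$major_axis_px, tolerance = 1e-12)
  expect_equal(rot$minor_axis_px, base$minor_axis_px, tolerance = 1e-12)
  # translation by padding
  shifted <- matrix(FALSE, 130, 130)
  shifted[31:130, 16:115] <- m
  tr <- fit_ellipses(shifted)
  expect_equal(tr$major_axis_px, base$major_axis_px, tolerance = 1e-12)
  # arbitrary-angle stability: <= 3% drift across orientations
  majors <- vapply(seq(0, 165, by = 15), function(th) {
    ii <- render_image(data.frame(length_um = 3.6, width_um = 1.1,
                                  orientation_deg = th),
                       canvas_px = c(100, 100), pixel_size_um = 0.1,
                       psf_sigma_px = 0, noise_sd = 0, seed = 4)
    fit_ellipses(ii$truth_labels > 0)$major_axis_px
  }, 0)
  expect_lt((max(majors) - min(majors)) / mean(majors), 0.03)
})

test_that("QC filters reject merged, round and border regions with a complete log", {
  # deliberately overlapping pair -> merged blob, too thick
  pair <- data.frame(length_um = c(3.5, 3.5), width_um = c(1.2, 1.2),
                     orientation_deg = c(0, 90))
  img <- render_image(pair, canvas_px = c(90, 90), pixel_size_um = 0.1,
                      psf_sigma_px = 0, noise_sd = 0,
                      min_separation_um = 0.4, allow_overlap = TRUE,
                      max_retries = 500, seed = 42)
  # force a genuine overlap: draw both rods crossing at the centre
  m <- matrix(FALSE, 90, 90)
  m[43:54, 10:80] <- TRUE
  m[10:80, 43:54] <- TRUE
  regs <- fit_ellipses(m)
  qc <- qc_filter(regs, qc_config(max_minor_axis_um = 2), pixel_size_um = 0.1)
  expect_equal(nrow(qc$kept), 0)
  expect_true(all(qc$rejections$rule_failed %in%
                    c("max_minor_axis_um", "min_eccentricity")))

  # near-circular out-of-focus blob
  blob <- matrix(FALSE, 60, 60)
  blob[outer(1:60, 1:60, function(r, c) (r - 30)^2 + (c - 30)^2 <= 12^2)] <- TRUE
  qb <- qc_filter(fit_ellipses(blob), qc_config(), pixel_size_um = 0.1)
  expect_equal(nrow(qb$kept), 0)
  expect_equal(qb$rejections$rule_failed, "min_eccentricity")

  # clean rod passes
  rod <- render_image(data.frame(length_um = 3.7, width_um = 1.2,
                                 orientation_deg = 25),
                      canvas_px = c(90, 90), pixel_size_um = 0.1,
                      psf_sigma_px = 0, noise_sd = 0, seed = 2)
  qr <- qc_filter(fit_ellipses(rod$truth_labels > 0), qc_config(),
                  pixel_size_um = 0.1)
  expect_equal(nrow(qr$kept), 1)
  expect_equal(nrow(qr$rejections), 0)

  # filter never increases counts; log partitions the removals
  all_regs <- rbind(regs, fit_ellipses(blob))
  all_regs$region_id <- seq_len(nrow(all_regs))
  qa <- qc_filter(all_regs, qc_config(), pixel_size_um = 0.1)
  expect_lte(nrow(qa$kept), nrow(all_regs))
  expect_equal(nrow(qa$kept) + nrow(qa$rejections), nrow(all_regs))
  expect_setequal(c(qa$kept$region_id, qa$rejections$region_id),
                  all_regs$region_id)
})

test_that("pixel-to-micron conversion scales axes", {
  cells <- data.frame(length_um = 4, width_um = 1, orientation_deg = 0)
  img <- render_image(cells, canvas_px = c(80, 80), pixel_size_um = 0.1,
                      psf_sigma_px = 0, noise_sd = 0, seed = 3)
  regs <- fit_ellipses(img$truth_labels > 0)
  d1 <- to_microns(regs, 0.1)
  expect_equal(d1$length_um, regs$major_axis_px * 0.1)
  dI <- to_microns(regs, 1)
  expect_equal(dI$length_um, regs$major_axis_px)
  expect_error(to_microns(regs, 0), "positive")
})

test_that("weighted population statistics follow the counts", {
  # equal counts -> ordinary mean
  s <- weighted_population_stats(c(3, 4, 5), c(10, 10, 10))
  expect_equal(s$mean, 4)
  # dominating image pulls the mean toward itself
  s2 <- weighted_population_stats(c(10, rep(2, 10)), c(1000, rep(10, 10)))
  expect_lt(abs(s2$mean - 10) / 10, 0.1)
  # single image is degenerate
  s3 <- weighted_population_stats(3.7, 100)
  expect_true(s3$degenerate)
  expect_equal(s3$sd, 0)
  expect_equal(s3$sem, 0)
  expect_error(weighted_population_stats(numeric(0), numeric(0)), "empty")
  expect_error(weighted_population_stats(c(1, 2), c(1)), "equal length")
})

test_that("pooled Student's t matches the textbook case and degenerate inputs", {
  out <- compare_lengths(c(1, 2, 3), c(2, 3, 4))
  expect_equal(out$t, -1.224745, tolerance = 1e-6)
  expect_equal(out$df, 4)
  same <- compare_lengths(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # Welch option runs
  w <- compare_lengths(c(1, 2, 3), c(2, 3, 4), var_equal = FALSE)
  expect_equal(w$t, -1.224745, tolerance = 1e-6)
  expect_error(compare_lengths(1, c(1, 2)), "n >= 2")
})

test_that("type-I error of the pooled t test is close to the nominal 5%", {
  set.seed(123)
  rejections <- vapply(1:1000, function(i) {
    compare_lengths(rnorm(50), rnorm(50))$p < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.035)
  expect_lt(mean(rejections), 0.065)
})
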