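test_that("generators are pure functions of their seed", {
  g <- tiny_geometry(16)
  a <- simulate_point_source(c(0, 20), g, seed = 9)
  b <- simulate_point_source(c(0, 20), g, seed = 9)
  expect_identical(a$samples, b$samples)
  d1 <- simulate_diffuse_target(c(0, 20), geometry = g, seed = 9)
  d2 <- simulate_diffuse_target(c(0, 20), geometry = g, seed = 9)
  expect_identical(d1$samples, d2$samples)
  o1 <- simulate_out_of_plane(g, seed = 9)
  o2 <- simulate_out_of_plane(g, seed = 9)
  expect_identical(o1$samples, o2$samples)
  s1 <- simulate_bone_scene(geometry = g, seed = 9)
  s2 <- simulate_bone_scene(geometry = g, seed = 9)
  expect_identical(s1$data$samples, s2$data$samples)
  # and the caller's RNG stream is untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulate_point_source(c(0, 20), g, seed = 5))
  expect_identical(runif(1), before)
})

test_that("point-source channel delays match the analytic delay table", {
  g <- tiny_geometry(24)
  src <- c(0.5, 18)
  d <- simulate_point_source(src, g, fs = 32, depth_mm = 25,
                             noise_level = 0, seed = 1)
  c_mm_us <- g$sound_speed / 1000
  for (i in c(1, 12, 24)) {
    dist <- sqrt(sum((g$element_positions[i, ] - src)^2))
    t_pk <- (which.max(abs(d$samples[, i, 1])) - 1) / 32
    expect_lt(abs(t_pk - dist / c_mm_us), 1.5 / 32)
  }
})

test_that("source positions outside the field of view are rejected", {
  g <- tiny_geometry(16)
  expect_error(simulate_point_source(c(50, 20), g), "field of view")
  expect_error(simulate_point_source(c(0, -5), g), "field of view")
})

test_that("diffuse target converges to the compact limit as radius -> 0", {
  g <- tiny_geometry(32)
  grid <- image_grid(seq(-4.4, 4.4, by = 0.1), seq(15, 25, by = 0.1))
  pt <- simulate_point_source(c(0, 20), g, noise_level = 0, seed = 3)
  # with no spatial spread and no reverberant delay jitter the sub-sources
  # collapse onto one coherent point
  df0 <- simulate_diffuse_target(c(0, 20), radius = 0, jitter_us = 0,
                                 geometry = g, noise_level = 0, seed = 3)
  img_pt <- beamform_frame(pt, grid, "das")
  img_d0 <- beamform_frame(df0, grid, "das")
  expect_lt(sqrt(sum((brightest_pixel(img_pt) - brightest_pixel(img_d0))^2)),
            g$wavelength)
  # same seed, nonzero radius: reproducible but spatially spread
  dfr <- simulate_diffuse_target(c(0, 20), radius = 2, geometry = g,
                                 noise_level = 0, seed = 3)
  img_dr <- beamform_frame(dfr, grid, "das")
  a0 <- contour_area_6db(img_d0, center = c(0, 20), roi_size_mm = 4)
  ar <- contour_area_6db(img_dr, center = brightest_pixel(img_dr),
                         roi_size_mm = 4)
  expect_gt(ar, a0)
})

test_that("bone scene: truth band matches the polyline and shadow is dark", {
  g <- tiny_geometry(48)
  xmax <- max(abs(g$element_positions[, "x"]))
  flat <- data.frame(x = seq(-xmax, xmax, by = 0.1), z = 22)
  sc <- simulate_bone_scene(surface = flat, geometry = g, depth_mm = 32,
                            seed = 4)
  # ground-truth band: one band of ~2*band_mm/dz rows per lateral position
  per_col <- colSums(sc$truth_mask$pixels)
  band_rows <- 2 * (g$wavelength / 2) / sc$grid$dz
  expect_true(all(abs(per_col - band_rows) <= 1.5))
  cfg <- run_config(M = 2, n_lags = 6, axial_kernel_wavelengths = 1,
                    kernel_lateral_mm = 2.0, kernel_axial_mm = 3.1,
                    overlap = 0.6, alpha = 1)
  foc <- focus_frame(sc$data, sc$grid)
  st <- frame_coherence(sc$data, foc, cfg)
  das <- beamform_frame(sc$data, sc$grid, "das", cfg, focused = foc, stack = st)
  slsc <- beamform_frame(sc$data, sc$grid, "slsc", cfg, focused = foc, stack = st)
  bright <- roi(c(-4, 4), c(21.4, 22.6))
  shadow <- roi(c(-4, 4), c(26, 30))
  expect_gte(gcnr(das, bright, shadow), 0.5)
  expect_gte(gcnr(slsc, bright, shadow), gcnr(das, bright, shadow))
})

test_that("out-of-plane frames fail the in-plane SNR test", {
  g <- tiny_geometry(32)
  grid <- image_grid(seq(-4, 4, by = 0.2), seq(5, 42, by = 0.2))
  d <- simulate_out_of_plane(g, n_frames = 20, seed = 5)
  snrs <- vapply(1:20, function(f) {
    img <- beamform_frame(d, grid, "das", frame = f)
    t_roi <- roi_square(c(0, 35), 7)
    b_roi <- roi_square(c(0, 10), 7)
    snr(img, t_roi, b_roi)
  }, 0)
  expect_gte(sum(snrs <= 3), 19)
  # and its short-lag coherence is low beyond the first lags
  foc <- focus_frame(d, grid, 1)
  st <- coherence_stack(foc, n_lags = 6, kernel_length = 16)
  for (m in 3:6) expect_lt(abs(mean(st$values[, , m])), 0.1)
})

test_that("vertebra phantom supports exact registration round trips", {
  ph <- synth_vertebra_phantom(seed = 6)
  expect_true(all(ph$volume %in% c(0L, 1L)))
  ph2 <- synth_vertebra_phantom(seed = 6)
  expect_identical(ph$volume, ph2$volume)
  expect_equal(ph$landmarks_posed$points$x, ph2$landmarks_posed$points$x)
  est <- rigid_landmark_transform(ph$landmarks, ph$landmarks_posed)
  expect_equal(est$rotation, ph$rotation, tolerance = 1e-9)
  expect_equal(est$translation, ph$translation, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_lt(est$fre_rms, 1e-6)
  # NIfTI round trip of the volume
  p <- tempfile(fileext = ".nii.gz")
  on.exit(unlink(p))
  write_volume_nifti(ph$volume, p)
  expect_equal(read_volume_nifti(p), ph$volume, ignore_attr = TRUE)
})
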