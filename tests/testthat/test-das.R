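test_that("DAS sum is count-normalized over valid channels", {
  v <- matrix(2, 10, 8)
  ap <- list(values = v, valid = matrix(TRUE, 10, 8))
  expect_equal(das_line(ap), rep(2, 10))
  # alternating +a/-a cancels
  v2 <- matrix(rep(c(1, -1), 4), 10, 8, byrow = TRUE)
  expect_equal(das_line(list(values = v2, valid = matrix(TRUE, 10, 8))),
               rep(0, 10))
  # all channels invalid at a pixel -> 0
  val <- matrix(TRUE, 10, 8); val[3, ] <- FALSE
  v3 <- matrix(1, 10, 8); v3[!val] <- 0
  out <- das_line(list(values = v3, valid = val))
  expect_equal(out[3], 0)
  expect_equal(out[-3], rep(1, 9))
})

test_that("envelope of a pure axial cosine is flat at its amplitude", {
  g <- image_grid(seq(0, 1, by = 0.1), seq(1, by = 0.05, length.out = 1024))
  n <- g$nz
  rf <- matrix(3 * cos(2 * pi * (1:n) / 16), n, g$nx)
  env <- envelope_detect(rf, g)
  mid <- env$linear_amplitude[50:(n - 50), ]
  expect_lt(max(abs(mid - 3)) / 3, 0.01)
  # zero in, zero out; and linear in gain
  expect_equal(envelope_detect(matrix(0, n, g$nx), g)$linear_amplitude,
               matrix(0, n, g$nx))
  env2 <- envelope_detect(2.5 * rf, g)
  expect_equal(env2$linear_amplitude, 2.5 * env$linear_amplitude,
               tolerance = 1e-12)
})

test_that("envelope is invariant to the RF carrier phase", {
  g <- image_grid(seq(0, 1, by = 0.1), seq(1, by = 0.05, length.out = 1024))
  n <- g$nz
  e0 <- envelope_detect(matrix(cos(2 * pi * (1:n) / 16), n, g$nx), g)
  e1 <- envelope_detect(matrix(cos(2 * pi * (1:n) / 16 + pi / 3), n, g$nx), g)
  mid <- 50:(n - 50)
  expect_lt(max(abs(e0$linear_amplitude[mid, 1] - e1$linear_amplitude[mid, 1])),
            0.01)
})

test_that("log compression normalizes, converts and clips", {
  m <- matrix(c(1, 0.5, 1e-3, 0.2), 2, 2)
  img <- image_from_matrix(m)
  db <- log_compress(img, 25)
  expect_equal(db[1, 1], 0)
  expect_equal(db[2, 1], 20 * log10(0.5), tolerance = 1e-9)  # -6.02 dB
  expect_equal(db[1, 2], -25)                                 # clipped
  expect_true(all(db <= 0 & db >= -25))
  zero <- image_from_matrix(matrix(0, 2, 2))
  expect_error(log_compress(zero), "all-zero")
})

test_that("DAS localizes a noise-free point source within half a wavelength", {
  geom <- tiny_geometry(32)
  src <- c(-0.9, 21)
  d <- simulate_point_source(src, geom, fs = 32, depth_mm = 30,
                             noise_level = 0, seed = 1)
  grid <- tiny_grid(geom, depth = c(15, 27), spacing = geom$wavelength / 4)
  img <- beamform_frame(d, grid, "das")
  pk <- brightest_pixel(img)
  expect_lt(sqrt(sum((pk - src)^2)), geom$wavelength / 2)
})

test_that("DAS -6 dB lateral width tracks the diffraction estimate", {
  geom <- tiny_geometry(64)
  src <- c(0, 20)
  d <- simulate_point_source(src, geom, fs = 32, depth_mm = 30,
                             noise_level = 0, seed = 2)
  grid <- image_grid(seq(-4, 4, by = 0.05), seq(18, 22, by = 0.05))
  img <- beamform_frame(d, grid, "das")
  iz <- which.min(abs(grid$axial - src[2]))
  prof <- img$linear_amplitude[iz, ]
  above <- grid$lateral[prof >= max(prof) / 2]
  width <- diff(range(above))
  aperture <- diff(range(geom$element_positions[, "x"]))
  pred <- geom$wavelength * src[2] / aperture
  expect_lt(abs(width - pred) / pred, 0.25)
})

test_that("scan conversion: identity for linear arrays, geometry oracle for convex", {
  img <- image_from_matrix(matrix(runif(60), 10, 6))
  expect_identical(scan_convert(img, tiny_geometry(16)), img)

  cvx <- array_geometry(48, pitch = 0.4, kerf = 0.1, center_frequency = 3.5,
                        curvature_radius = 40)
  angles <- seq(-0.2, 0.2, length.out = 41)
  ranges <- seq(5, 40, by = 0.25)
  polar <- matrix(1, length(ranges), length(angles))
  pg <- image_grid(seq(0, by = 1, length.out = length(angles)),
                   ranges)
  pimg <- bimage(polar, pg, tag = "DAS")
  cart <- scan_convert(pimg, cvx, angles = angles, ranges = ranges)
  mask <- attr(cart, "sector_mask")
  expect_equal(max(abs(cart$linear_amplitude[mask] - 1)), 0, tolerance = 1e-9)
  expect_true(all(cart$linear_amplitude[!mask] == 0))

  # single bright sample at known (angle, range) lands at the forward-mapped
  # Cartesian position within one pixel
  polar2 <- matrix(0, length(ranges), length(angles))
  ia <- 31; ir <- 61
  polar2[ir, ia] <- 1
  pimg2 <- bimage(polar2, pg, tag = "DAS")
  cart2 <- scan_convert(pimg2, cvx, angles = angles, ranges = ranges)
  pk <- brightest_pixel(cart2)
  R <- 40
  x_true <- (R + ranges[ir]) * sin(angles[ia])
  z_true <- (R + ranges[ir]) * cos(angles[ia]) - R
  expect_lt(abs(pk["x"] - x_true), cart2$grid$dx + 1e-9)
  expect_lt(abs(pk["z"] - z_true), cart2$grid$dz + 1e-9)
})
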