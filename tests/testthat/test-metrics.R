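two_roi_image <- function(vin, vout, n = 40) {
  # left half carries "out" values, right half "in" values
  m <- matrix(0, n, 2 * n)
  m[, 1:n] <- vout
  m[, (n + 1):(2 * n)] <- vin
  img <- image_from_matrix(m, dx = 0.1, dz = 0.1)
  list(img = img,
       roi_out = roi(range(img$grid$lateral[1:n]), range(img$grid$axial)),
       roi_in = roi(range(img$grid$lateral[(n + 1):(2 * n)]),
                    range(img$grid$axial)))
}

test_that("gCNR edge cases: identical -> 0, disjoint -> 1", {
  set.seed(51)
  v <- runif(1600)
  s <- two_roi_image(v, v)
  expect_equal(gcnr(s$img, s$roi_in, s$roi_out), 0)
  s2 <- two_roi_image(2, 1)
  expect_equal(gcnr(s2$img, s2$roi_in, s2$roi_out), 1)
  # degenerate range (both ROIs the same constant) -> 0 by definition
  s3 <- two_roi_image(1, 1)
  expect_equal(gcnr(s3$img, s3$roi_in, s3$roi_out), 0)
})

test_that("gCNR of half-overlapping uniforms is 0.5", {
  set.seed(52)
  n <- 317  # ~1e5 pixels per ROI
  s <- two_roi_image(runif(n * n, 0, 1), runif(n * n, 0.5, 1.5), n = n)
  expect_lt(abs(gcnr(s$img, s$roi_out, s$roi_in) - 0.5), 0.02)
})

test_that("gCNR is exactly gain-invariant and in [0, 1]", {
  set.seed(53)
  s <- two_roi_image(rexp(1600), 0.5 + rexp(1600), n = 40)
  g1 <- gcnr(s$img, s$roi_in, s$roi_out)
  scaled <- image_from_matrix(7 * s$img$linear_amplitude)
  g2 <- gcnr(scaled, s$roi_in, s$roi_out)
  expect_identical(g1, g2)
  expect_gte(g1, 0); expect_lte(g1, 1)
  # monotone transform changes gCNR only through binning
  logd <- image_from_matrix(log1p(s$img$linear_amplitude))
  expect_lt(abs(gcnr(logd, s$roi_in, s$roi_out) - g1), 0.05)
})

test_that("CNR arithmetic, degenerate cases and gain invariance", {
  s <- two_roi_image(2, 1)
  expect_error(cnr(s$img, s$roi_in, s$roi_out), "undefined")
  set.seed(54)
  # equal-mean ROIs -> 0 numerator
  v <- rnorm(1600, 5)
  s2 <- two_roi_image(v, sample(v))
  expect_lt(cnr(s2$img, s2$roi_in, s2$roi_out), 0.05)
  # closed form: means 2 and 1, sds 1/sqrt(2) each -> CNR 1
  a <- rep(c(2 - 1 / sqrt(2), 2 + 1 / sqrt(2)), 800)
  b <- rep(c(1 - 1 / sqrt(2), 1 + 1 / sqrt(2)), 800)
  s3 <- two_roi_image(a, b)
  expect_equal(cnr(s3$img, s3$roi_in, s3$roi_out), 1, tolerance = 1e-9)
  scaled <- image_from_matrix(3 * s3$img$linear_amplitude)
  expect_equal(cnr(scaled, s3$roi_in, s3$roi_out), 1, tolerance = 1e-9)
})

test_that("SNR matches Rayleigh moments and is gain invariant", {
  geom_mean_ratio <- sqrt(pi / 2) / sqrt(2 - pi / 2)  # mean/sd ~ 1.9130
  set.seed(55)
  n <- 100
  v <- sqrt(-2 * log(runif(n * n)))  # Rayleigh(1) draws
  s <- two_roi_image(v, v, n = n)
  val <- snr(s$img, s$roi_in, s$roi_in)
  expect_equal(val, geom_mean_ratio, tolerance = 0.05 * geom_mean_ratio)
  scaled <- image_from_matrix(11 * s$img$linear_amplitude)
  expect_equal(snr(scaled, s$roi_in, s$roi_in), val, tolerance = 1e-9)
  flat <- two_roi_image(1, 1)
  expect_error(snr(flat$img, flat$roi_in, flat$roi_out), "zero variance")
})

test_that("out-of-plane filter discards at the boundary", {
  out <- filter_out_of_plane(c(3.0, 3.01, 10, 0.4))
  expect_equal(out$discarded, c(1L, 4L))  # SNR = 3 is discarded
  expect_equal(out$kept, c(2L, 3L))
  expect_equal(sort(c(out$kept, out$discarded)), 1:4)
})

test_that("-6 dB area of a Gaussian spot matches the closed form", {
  dx <- 0.02
  g <- image_grid(seq(-6, 6, by = dx), seq(10, 22, by = dx))
  sigma <- 1.3
  m <- exp(-(outer(g$axial - 16, rep(1, g$nx)) ^ 2 +
             outer(rep(1, g$nz), g$lateral) ^ 2) / (2 * sigma^2))
  img <- bimage(m, g, tag = "DAS")
  area <- contour_area_6db(img, center = c(0, 16), roi_size_mm = 10)
  r6 <- sigma * sqrt(2 * log(1 / 10^(-6 / 20)))
  expect_equal(area, pi * r6^2, tolerance = 0.03 * pi * r6^2)
  # relative threshold: doubling amplitudes leaves the area unchanged
  img2 <- bimage(2 * m, g, tag = "DAS")
  expect_equal(contour_area_6db(img2, center = c(0, 16)), area)
})

test_that("-6 dB area of a single-pixel impulse is one pixel", {
  m <- matrix(0, 101, 101)
  m[51, 51] <- 1
  img <- image_from_matrix(m, dx = 0.2, dz = 0.2)
  ctr <- brightest_pixel(img)
  expect_equal(contour_area_6db(img, center = ctr, roi_size_mm = 10),
               0.2 * 0.2, tolerance = 1e-12)
  zero <- image_from_matrix(matrix(0, 101, 101), dx = 0.2, dz = 0.2)
  zero$linear_amplitude[1, 1] <- 1  # peak far outside the ROI
  expect_error(contour_area_6db(zero, center = c(10, 11), roi_size_mm = 4),
               "zero")
})

test_that("peak-to-CoM distance follows the weighted-mean oracle", {
  # two pixels: amplitude 1 at x = 0, 3 at x = 1 -> CoM at 0.75, peak at 1
  m <- matrix(c(1, 3), 1, 2)
  g <- image_grid(c(0, 1), c(5, 6))
  img <- bimage(rbind(m, 0), g, tag = "DAS")
  expect_equal(peak_to_com_distance(img), 0.25, tolerance = 1e-9)
  # symmetric Gaussian -> ~0
  dx <- 0.05
  gg <- image_grid(seq(-3, 3, by = dx), seq(10, 16, by = dx))
  spot <- exp(-(outer((gg$axial - 13)^2, rep(1, gg$nx)) +
                outer(rep(1, gg$nz), gg$lateral^2)) / 1.5)
  expect_lt(peak_to_com_distance(bimage(spot, gg, tag = "DAS")),
            sqrt(2) * dx)
  # skewed mass: direct oracle
  set.seed(56)
  m2 <- matrix(runif(25), 5, 5)
  g2 <- image_grid(seq(0, 4, by = 1), seq(0, 4, by = 1))
  img2 <- bimage(m2, g2, tag = "DAS")
  xs <- rep(g2$lateral, each = 5); zs <- rep(g2$axial, 5)
  com <- c(sum(xs * m2) / sum(m2), sum(zs * m2) / sum(m2))
  pk <- which(m2 == max(m2), arr.ind = TRUE)
  d_oracle <- sqrt((com[1] - g2$lateral[pk[2]])^2 + (com[2] - g2$axial[pk[1]])^2)
  expect_equal(peak_to_com_distance(img2), d_oracle, tolerance = 1e-9)
})

test_that("bone-contact comparison: t-test and outlier flagging", {
  same <- compare_bone_contact(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$mean_difference, 0)
  shift <- compare_bone_contact(c(11, 12, 13), c(1, 2, 3))
  expect_lt(shift$p_value, 0.01)
  expect_equal(shift$mean_difference, 10)
  # Welch statistic oracle via stats::t.test
  set.seed(57)
  a <- rnorm(10, 10, 5); b <- rnorm(10, 2, 1)
  res <- compare_bone_contact(a, b)
  ref <- t.test(a, b, var.equal = FALSE)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value)
  # 1.5 IQR rule flags the extreme point
  bs <- box_stats(c(1, 2, 3, 100))
  expect_equal(bs$outliers[[1]], 100)
  expect_equal(bs$median, 2.5)
  # broom-style accessors
  td <- tidy(res); gl <- glance(res)
  expect_s3_class(td, "tbl_df")
  expect_named(gl, c("mean_difference", "statistic", "p_value"))
})
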