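blob_image <- function(centers, sigma = 0.6, noise = 0, seed = NULL,
                       dx = 0.1, n = 80) {
  g <- image_grid(seq(0, by = dx, length.out = n),
                  seq(1, by = dx, length.out = n))
  m <- matrix(0, n, n)
  for (k in seq_len(nrow(centers))) {
    m <- m + exp(-(outer((g$axial - centers[k, 2])^2, rep(1, n)) +
                   outer(rep(1, n), (g$lateral - centers[k, 1])^2)) /
                   (2 * sigma^2))
  }
  if (noise > 0) {
    if (!is.null(seed)) set.seed(seed)
    m <- pmax(m + matrix(rnorm(n * n, sd = noise), n), 0)
  }
  bimage(m, g, tag = "DAS")
}

test_that("fractional-maximum threshold behaves per contract", {
  img <- image_from_matrix(matrix(c(0.2, 0.5, 1.0, 0.1), 2, 2))
  m <- threshold_mask(img, 0.5)
  expect_equal(as.vector(m$pixels), c(FALSE, TRUE, TRUE, FALSE))
  m3 <- threshold_mask(img, 0.3)
  expect_equal(as.vector(m3$pixels), c(FALSE, TRUE, TRUE, FALSE))
  uni <- image_from_matrix(matrix(2, 4, 4))
  expect_true(all(threshold_mask(uni, 0.9)$pixels))
  expect_error(threshold_mask(image_from_matrix(matrix(0, 2, 2)), 0.5),
               "all-zero")
})

test_that("morphological cleanup removes specks, fills holes, is idempotent", {
  g <- image_grid(seq(0, by = 0.13, length.out = 40),
                  seq(1, by = 0.13, length.out = 40))
  px <- matrix(FALSE, g$nz, g$nx)
  px[10:25, 10:25] <- TRUE
  px[17, 17] <- FALSE          # interior hole
  px[35, 35] <- TRUE           # isolated pixel
  m <- binary_mask <- structure(list(pixels = px, grid = g), class = "binary_mask")
  clean <- morphological_clean(m, open_mm = 0.38, close_mm = 0.63)
  expect_false(clean$pixels[35, 35])
  expect_true(clean$pixels[17, 17])
  expect_true(all(clean$pixels[12:23, 12:23]))
  twice <- morphological_clean(clean, 0.38, 0.63)
  expect_identical(twice$pixels, clean$pixels)
  solid <- structure(list(pixels = matrix(TRUE, 20, 20),
                          grid = image_grid(seq(0, 1.9, 0.1), seq(1, 2.9, 0.1))),
                     class = "binary_mask")
  expect_identical(morphological_clean(solid)$pixels, solid$pixels)
})

test_that("connected components are 8-connected with amplitude-weighted CoM", {
  g <- image_grid(seq(0, 0.9, by = 0.1), seq(1, 1.9, by = 0.1))
  px <- matrix(FALSE, 10, 10)
  px[2:4, 2:4] <- TRUE
  px[7:9, 6:8] <- TRUE
  amp <- matrix(1, 10, 10)
  img <- bimage(amp, g, tag = "DAS")
  m <- structure(list(pixels = px, grid = g), class = "binary_mask")
  cs <- extract_components(m, img)
  expect_equal(nrow(cs$components), 2)
  expect_equal(cs$components$com_x[1], g$lateral[3])
  expect_equal(cs$components$com_z[1], g$axial[3])
  # diagonal touch merges under 8-connectivity
  px2 <- matrix(FALSE, 10, 10); px2[3, 3] <- TRUE; px2[4, 4] <- TRUE
  cs2 <- extract_components(structure(list(pixels = px2, grid = g),
                                      class = "binary_mask"), img)
  expect_equal(nrow(cs2$components), 1)
  # bright right edge pulls the CoM right of centre
  amp3 <- matrix(1, 10, 10); amp3[2:4, 4] <- 5
  cs3 <- extract_components(m, bimage(amp3, g, tag = "DAS"))
  expect_gt(cs3$components$com_x[1], g$lateral[3])
  # CoM stays inside the bounding box
  expect_true(all(cs3$components$com_x >= cs3$components$x_min &
                  cs3$components$com_x <= cs3$components$x_max))
  # empty mask -> zero components, no error
  empty <- structure(list(pixels = matrix(FALSE, 10, 10), grid = g),
                     class = "binary_mask")
  expect_equal(nrow(extract_components(empty, img)$components), 0)
})

test_that("nearest-contour selection picks the closest blob and traces it", {
  img <- blob_image(rbind(c(2, 3), c(6, 6)), sigma = 0.4)
  mask <- threshold_mask(img, 0.5)
  sel <- select_contour_nearest(mask, reference_point = c(2.2, 3.4))
  cs <- extract_components(sel$mask, img)
  expect_equal(nrow(cs$components), 1)
  expect_lt(abs(cs$components$com_x - 2), 0.15)
  expect_gt(nrow(sel$boundary), 4)
  sel2 <- select_contour_nearest(mask, reference_point = c(6, 5.5))
  expect_lt(abs(extract_components(sel2$mask, img)$components$com_x - 6), 0.15)
  empty <- structure(list(pixels = matrix(FALSE, 4, 4),
                          grid = image_grid(0:3, 1:4)), class = "binary_mask")
  expect_error(select_contour_nearest(empty, c(0, 1)), "empty")
})

test_that("thickness profiles match direct sums and conserve area", {
  g <- image_grid(seq(0, 1.9, by = 0.1), seq(1, 2.9, by = 0.1))
  px <- matrix(FALSE, 20, 20)
  px[5:6, 3:12] <- TRUE                      # 10 px wide x 2 px tall
  m <- structure(list(pixels = px, grid = g), class = "binary_mask")
  th <- integrated_thickness(m)
  expect_equal(th$lateral[3:12], rep(0.2, 10))
  expect_equal(th$overall_lateral, 0.2, tolerance = 1e-12)
  # L-shaped mask against brute-force row/column sums
  px[7:15, 3] <- TRUE
  mL <- structure(list(pixels = px, grid = g), class = "binary_mask")
  thL <- integrated_thickness(mL)
  expect_equal(thL$lateral, colSums(px) * 0.1)
  expect_equal(thL$axial, rowSums(px) * 0.1)
  expect_equal(sum(thL$lateral) * g$dx, thL$area_mm2, tolerance = 1e-12)
  expect_equal(sum(thL$axial) * g$dz, thL$area_mm2, tolerance = 1e-12)
  # empty mask -> zero profiles
  e <- structure(list(pixels = matrix(FALSE, 20, 20), grid = g),
                 class = "binary_mask")
  expect_true(all(integrated_thickness(e)$lateral == 0))
})

test_that("thickness differences respond to a one-pixel axial dilation", {
  g <- image_grid(seq(0, 1.9, by = 0.1), seq(1, 2.9, by = 0.1))
  ref <- matrix(FALSE, 20, 20); ref[8:10, 5:14] <- TRUE
  test_px <- ref; test_px[7, 5:14] <- TRUE; test_px[11, 5:14] <- TRUE
  mt <- structure(list(pixels = test_px, grid = g), class = "binary_mask")
  mr <- structure(list(pixels = ref, grid = g), class = "binary_mask")
  d <- thickness_difference(mt, mr)
  expect_equal(d$lateral, rep(2 * g$dz, 10), tolerance = 1e-12)
  expect_identical(thickness_difference(mr, mr)$lateral, rep(0, 10))
  g2 <- image_grid(seq(0, 1.9, by = 0.1), seq(2, 3.9, by = 0.1))
  m2 <- structure(list(pixels = ref, grid = g2), class = "binary_mask")
  expect_error(thickness_difference(mt, m2), "different grids")
})

test_that("threshold-clean-components recovers three blobs across seeds", {
  centers <- rbind(c(2, 2.5), c(5.5, 3), c(4, 6))
  for (seed in 1:20) {
    img <- blob_image(centers, sigma = 0.45, noise = 0.05, seed = seed)
    mask <- morphological_clean(threshold_mask(img, 0.3), 0.38, 0.63)
    cs <- extract_components(mask, img)
    expect_equal(nrow(cs$components), 3)
  }
})
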