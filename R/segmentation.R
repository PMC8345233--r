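#' Fractional-maximum binary threshold
#'
#' Pixel is `TRUE` iff its linear amplitude reaches `fraction` of the
#' image-wide maximum. Typical fractions: 0.5 for bone-boundary extraction
#' on a linear-array scene, 0.3 for the landmark-segmentation pipeline.
#'
#' @param image a [bimage()].
#' @param fraction threshold fraction in `(0, 1)`.
#' @return Object of class `binary_mask`: list with logical `pixels`
#'   (`nz x nx`) and the `grid`.
#' @export
threshold_mask <- function(image, fraction) {
  stopifnot(inherits(image, "bimage"), fraction > 0, fraction < 1)
  mx <- max(image$linear_amplitude)
  if (mx <= 0) stop("threshold_mask: all-zero image", call. = FALSE)
  structure(list(pixels = image$linear_amplitude >= fraction * mx,
                 grid = image$grid),
            class = "binary_mask")
}

binary_mask <- function(pixels, grid) {
  structure(list(pixels = pixels, grid = grid), class = "binary_mask")
}

#' Morphological cleanup of a segmentation mask
#'
#' Opening (removes isolated pixels and thin spurs) followed by closing
#' (fills small holes), with square structuring elements whose physical
#' sizes are converted to pixels per axis as `round(size / spacing)`,
#' minimum 1 pixel.
#'
#' @param mask a `binary_mask`.
#' @param open_mm,close_mm structuring-element side lengths in mm.
#' @return A cleaned `binary_mask`.
#' @export
morphological_clean <- function(mask, open_mm = 0.38, close_mm = 0.63) {
  stopifnot(inherits(mask, "binary_mask"), open_mm > 0, close_mm > 0)
  g <- mask$grid
  se <- function(size_mm) {
    matrix(1L, max(1L, round(size_mm / g$dz)), max(1L, round(size_mm / g$dx)))
  }
  m <- EBImage::Image(mask$pixels * 1)
  m <- EBImage::opening(m, se(open_mm))
  m <- EBImage::closing(m, se(close_mm))
  binary_mask(EBImage::imageData(m) > 0.5, g)
}

# 8-connected labeling by frontier flood fill; returns an integer matrix
# (0 = background, components numbered 1..K in first-pixel order)
label_components_8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labs <- matrix(0L, nr, nc)
  lab <- 0L
  todo <- which(mask)
  off_r <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  off_c <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  for (seed in todo) {
    if (labs[seed] != 0L) next
    lab <- lab + 1L
    labs[seed] <- lab
    fr_r <- ((seed - 1L) %% nr) + 1L
    fr_c <- ((seed - 1L) %/% nr) + 1L
    while (length(fr_r)) {
      nb_r <- rep(fr_r, times = 8L) + rep(off_r, each = length(fr_r))
      nb_c <- rep(fr_c, times = 8L) + rep(off_c, each = length(fr_r))
      ok <- nb_r >= 1L & nb_r <= nr & nb_c >= 1L & nb_c <= nc
      nb_r <- nb_r[ok]; nb_c <- nb_c[ok]
      idx <- nb_r + (nb_c - 1L) * nr
      keep <- !duplicated(idx)
      idx <- idx[keep]
      hit <- mask[idx] & labs[idx] == 0L
      idx <- idx[hit]
      labs[idx] <- lab
      fr_r <- ((idx - 1L) %% nr) + 1L
      fr_c <- ((idx - 1L) %/% nr) + 1L
    }
  }
  labs
}

#' Connected components with amplitude-weighted centres of mass
#'
#' Labels the mask with 8-connectivity (so thin diagonal bone boundaries are
#' not split) and computes, per component, the pixel count, bounding box and
#' the amplitude-weighted centre of mass, where each pixel's weight is the
#' image amplitude normalized by the component's maximum amplitude.
#'
#' @param mask a `binary_mask`.
#' @param image the matching [bimage()] supplying amplitudes.
#' @return Object of class `component_set`: list with integer `labels`
#'   matrix and a tibble `components` (label, n_pixels, com_x, com_z and the
#'   bounding box in mm). An empty mask yields zero components.
#' @export
extract_components <- function(mask, image) {
  stopifnot(inherits(mask, "binary_mask"), inherits(image, "bimage"))
  g <- mask$grid
  labs <- label_components_8(mask$pixels)
  k <- max(labs)
  if (k == 0) {
    comps <- tibble::tibble(label = integer(), n_pixels = integer(),
                            com_x = numeric(), com_z = numeric(),
                            x_min = numeric(), x_max = numeric(),
                            z_min = numeric(), z_max = numeric())
    return(structure(list(labels = labs, components = comps, grid = g),
                     class = "component_set"))
  }
  amp <- image$linear_amplitude
  rows <- row(labs)[labs > 0]; cols <- col(labs)[labs > 0]
  lv <- labs[labs > 0]; av <- amp[labs > 0]
  comp_max <- vapply(split(av, lv), max, 0)
  wts <- av / comp_max[lv]
  wsum <- vapply(split(wts, lv), sum, 0)
  xs <- g$lateral[cols]; zs <- g$axial[rows]
  comps <- tibble::tibble(
    label = seq_len(k),
    n_pixels = as.integer(tabulate(lv, k)),
    com_x = unname(vapply(split(wts * xs, lv), sum, 0) / wsum),
    com_z = unname(vapply(split(wts * zs, lv), sum, 0) / wsum),
    x_min = unname(vapply(split(xs, lv), min, 0)),
    x_max = unname(vapply(split(xs, lv), max, 0)),
    z_min = unname(vapply(split(zs, lv), min, 0)),
    z_max = unname(vapply(split(zs, lv), max, 0)))
  structure(list(labels = labs, components = comps, grid = g),
            class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("<component_set> %d component(s)\n", nrow(x$components)))
  print(x$components)
  invisible(x)
}

#' Select the component nearest a reference point
#'
#' Returns the connected component whose boundary comes closest (Euclidean
#' distance in mm) to a reference point, e.g. the vertebral foramen. Ties go
#' to the lower label index (logged). The boundary is returned as an ordered
#' polyline traced along the pixel half-level contour.
#'
#' @param mask a `binary_mask` with at least one component.
#' @param reference_point `(x, z)` in mm.
#' @param image optional [bimage()] for component amplitudes (defaults to a
#'   unit image).
#' @return List with `mask` (single-component `binary_mask`), `label`,
#'   `distance_mm`, and `boundary` (data frame of ordered x, z vertices).
#' @export
select_contour_nearest <- function(mask, reference_point, image = NULL) {
  stopifnot(inherits(mask, "binary_mask"))
  g <- mask$grid
  labs <- label_components_8(mask$pixels)
  k <- max(labs)
  if (k == 0) stop("select_contour_nearest: empty mask", call. = FALSE)
  # boundary pixels: masked with at least one unmasked 4-neighbour (or edge)
  p <- mask$pixels
  pad <- rbind(FALSE, cbind(FALSE, p, FALSE), FALSE)
  core <- pad[-c(1, nrow(pad)), -c(1, ncol(pad))] &
    pad[-c(nrow(pad) - 1, nrow(pad)), -c(1, ncol(pad))] &
    pad[-c(1, 2), -c(1, ncol(pad))] &
    pad[-c(1, nrow(pad)), -c(ncol(pad) - 1, ncol(pad))] &
    pad[-c(1, nrow(pad)), -c(1, 2)]
  bnd <- p & !core
  br <- row(bnd)[bnd]; bc <- col(bnd)[bnd]; bl <- labs[bnd]
  d <- sqrt((g$lateral[bc] - reference_point[1])^2 +
            (g$axial[br] - reference_point[2])^2)
  dmin <- vapply(split(d, bl), min, 0)
  best <- as.integer(names(dmin))[dmin == min(dmin)]
  if (length(best) > 1) {
    message("select_contour_nearest: distance tie between components ",
            paste(best, collapse = ", "), "; taking the lowest label")
  }
  best <- min(best)
  sel <- labs == best
  cl <- grDevices::contourLines(x = g$axial, y = g$lateral,
                                z = sel * 1, levels = 0.5)
  boundary <- if (length(cl)) {
    data.frame(x = cl[[1]]$y, z = cl[[1]]$x)
  } else {
    data.frame(x = g$lateral[col(sel)[sel]], z = g$axial[row(sel)[sel]])
  }
  list(mask = binary_mask(sel, g), label = best,
       distance_mm = min(dmin), boundary = boundary)
}

#' Integrated segmentation thickness profiles
#'
#' The lateral profile gives, at each lateral position, the summed axial
#' extent (mm) of the mask in that column; the axial profile is the
#' analogous row sum. The overall thickness of a boundary is the mean
#' profile value over positions where the mask is present. Profiles conserve
#' mask area: `sum(lateral) * dx == sum(axial) * dz == area`.
#'
#' @param mask a `binary_mask`.
#' @return List with `lateral` (length `nx`, mm), `axial` (length `nz`, mm),
#'   `overall_lateral`, `overall_axial` (mm) and `area_mm2`.
#' @export
integrated_thickness <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  g <- mask$grid
  lat <- colSums(mask$pixels) * g$dz
  axi <- rowSums(mask$pixels) * g$dx
  list(lateral = lat, axial = axi,
       overall_lateral = if (any(lat > 0)) mean(lat[lat > 0]) else 0,
       overall_axial = if (any(axi > 0)) mean(axi[axi > 0]) else 0,
       area_mm2 = sum(mask$pixels) * g$dx * g$dz)
}

#' Thickness-profile differences between two segmentations
#'
#' Elementwise difference (test minus reference) of the integrated thickness
#' profiles at positions where either mask is present, with box-plot
#' summaries per dimension.
#'
#' @param mask_test,mask_reference `binary_mask`s on the same grid.
#' @return List with `lateral`, `axial` (numeric difference vectors at the
#'   active positions) and `summary` (tibble of [box_stats()] per dimension).
#' @export
thickness_difference <- function(mask_test, mask_reference) {
  gt <- mask_test$grid; gr <- mask_reference$grid
  if (gt$nz != gr$nz || gt$nx != gr$nx ||
      max(abs(gt$lateral - gr$lateral)) > 1e-9 ||
      max(abs(gt$axial - gr$axial)) > 1e-9) {
    stop("thickness_difference: masks are on different grids", call. = FALSE)
  }
  pt <- integrated_thickness(mask_test)
  pr <- integrated_thickness(mask_reference)
  sel_l <- pt$lateral > 0 | pr$lateral > 0
  sel_a <- pt$axial > 0 | pr$axial > 0
  dl <- (pt$lateral - pr$lateral)[sel_l]
  da <- (pt$axial - pr$axial)[sel_a]
  list(lateral = dl, axial = da,
       summary = rbind(cbind(dimension = "lateral", box_stats(dl)),
                       cbind(dimension = "axial", box_stats(da))))
}
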