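#' Rectangular region of interest
#'
#' An ROI is a lateral x axial rectangle in mm, resolved against an image
#' grid at use time.
#'
#' @param lateral,axial length-2 numeric ranges in mm.
#' @return Object of class `roi`.
#' @export
roi <- function(lateral, axial) {
  stopifnot(length(lateral) == 2, length(axial) == 2,
            lateral[1] < lateral[2], axial[1] < axial[2])
  structure(list(lateral = lateral, axial = axial), class = "roi")
}

#' Square ROI centred on a point
#'
#' @param center length-2 `(x, z)` centre in mm.
#' @param size_mm side length in mm.
#' @return A [roi()].
#' @export
roi_square <- function(center, size_mm) {
  roi(center[1] + c(-1, 1) * size_mm / 2, center[2] + c(-1, 1) * size_mm / 2)
}

# resolve an ROI to matrix indices against a grid (list: rows, cols)
resolve_roi <- function(r, grid, partial = FALSE) {
  stopifnot(inherits(r, "roi"), inherits(grid, "image_grid"))
  rows <- which(grid$axial >= r$axial[1] & grid$axial <= r$axial[2])
  cols <- which(grid$lateral >= r$lateral[1] & grid$lateral <= r$lateral[2])
  if (!length(rows) || !length(cols)) {
    stop("roi: empty after resolution against the grid", call. = FALSE)
  }
  if (!partial) {
    tol <- 1e-9
    if (r$axial[1] < grid$axial[1] - grid$dz - tol ||
        r$axial[2] > grid$axial[grid$nz] + grid$dz + tol ||
        r$lateral[1] < grid$lateral[1] - grid$dx - tol ||
        r$lateral[2] > grid$lateral[grid$nx] + grid$dx + tol) {
      stop("roi: extends outside the image", call. = FALSE)
    }
  }
  list(rows = rows, cols = cols)
}

#' Extract ROI pixel values from an image
#'
#' @param image a [bimage()] or a plain matrix (then `grid` is required).
#' @param r a [roi()].
#' @param grid grid for matrix input.
#' @return Numeric vector of linear-amplitude values.
#' @export
roi_values <- function(image, r, grid = NULL) {
  if (inherits(image, "bimage")) {
    m <- image$linear_amplitude; grid <- image$grid
  } else {
    m <- image
    if (is.null(grid)) stop("roi_values: grid required for matrix input", call. = FALSE)
  }
  ix <- resolve_roi(r, grid)
  as.vector(m[ix$rows, ix$cols])
}

#' Generalized contrast-to-noise ratio
#'
#' `gCNR = 1 - sum_k min(p_i(k), p_o(k))`, where `p_i` and `p_o` are the
#' probability mass functions of the linear amplitudes inside and outside the
#' target, estimated with 256 equal-width bins spanning the pooled range of
#' both ROIs. Bounded in `[0, 1]`; equal distributions give 0 and disjoint
#' supports give 1. A degenerate pooled range (both ROIs constant and equal)
#' is defined as gCNR 0.
#'
#' @param image a [bimage()] (or matrix with `grid`).
#' @param roi_in,roi_out target and background [roi()]s.
#' @param grid grid when `image` is a matrix.
#' @param n_bins number of shared-range histogram bins.
#' @return Value in `[0, 1]`.
#' @export
gcnr <- function(image, roi_in, roi_out, grid = NULL, n_bins = 256) {
  vi <- roi_values(image, roi_in, grid)
  vo <- roi_values(image, roi_out, grid)
  rng <- range(c(vi, vo))
  if (diff(rng) == 0) return(0)
  brk <- seq(rng[1], rng[2], length.out = n_bins + 1)
  binv <- function(v) {
    k <- pmin(pmax(findInterval(v, brk, rightmost.closed = TRUE), 1), n_bins)
    tabulate(k, n_bins) / length(v)
  }
  1 - sum(pmin(binv(vi), binv(vo)))
}

#' Contrast-to-noise ratio
#'
#' `|S_i - S_o| / sqrt(sigma_i^2 + sigma_o^2)` on linear (pre-log) amplitude.
#'
#' @inheritParams gcnr
#' @return Nonnegative value.
#' @export
cnr <- function(image, roi_in, roi_out, grid = NULL) {
  vi <- roi_values(image, roi_in, grid)
  vo <- roi_values(image, roi_out, grid)
  stopifnot(length(vi) >= 2, length(vo) >= 2)
  num <- abs(mean(vi) - mean(vo))
  den <- sqrt(stats::var(vi) * (length(vi) - 1) / length(vi) +
              stats::var(vo) * (length(vo) - 1) / length(vo))
  if (den == 0) {
    if (num == 0) return(0)
    stop("cnr: zero variance in both ROIs with unequal means is undefined",
         call. = FALSE)
  }
  num / den
}

#' Signal-to-noise ratio
#'
#' `SNR = mu_t / sigma_b`: mean of the target ROI over the standard deviation
#' of the background ROI, on linear amplitude.
#'
#' @param image a [bimage()] (or matrix with `grid`).
#' @param target_roi,background_roi [roi()]s.
#' @param grid grid when `image` is a matrix.
#' @return Nonnegative value.
#' @export
snr <- function(image, target_roi, background_roi, grid = NULL) {
  vt <- roi_values(image, target_roi, grid)
  vb <- roi_values(image, background_roi, grid)
  stopifnot(length(vb) >= 2)
  sb <- stats::sd(vb) * sqrt((length(vb) - 1) / length(vb))
  if (sb == 0) stop("snr: background ROI has zero variance", call. = FALSE)
  mean(vt) / sb
}

#' Out-of-plane frame filter
#'
#' Frames whose SNR is 3 or less (by default) are judged to contain mostly
#' out-of-plane noise and are discarded; strictly greater values are kept.
#' The partition is exhaustive and disjoint.
#'
#' @param snr_values numeric vector of per-frame SNR values.
#' @param threshold discard boundary (discard when `snr <= threshold`).
#' @return List with integer index vectors `kept` and `discarded`.
#' @export
filter_out_of_plane <- function(snr_values, threshold = 3) {
  keep <- snr_values > threshold
  list(kept = which(keep), discarded = which(!keep))
}

#' Area of the -6 dB contour around a photoacoustic target
#'
#' Centres a square ROI on the target, thresholds the ROI at
#' `10^(-6/20)` (about 0.501) of the ROI maximum, and returns the physical
#' area of the 8-connected region containing the ROI peak. The connected
#' region (rather than every suprathreshold pixel) is used so satellite
#' lobes do not inflate the area.
#'
#' @param image a [bimage()] (linear amplitude).
#' @param center target centre `(x, z)` in mm; conventionally the brightest
#'   pixel of the matching LW-SLSC image ([brightest_pixel()]). Defaults to
#'   the brightest pixel of `image` itself.
#' @param roi_size_mm side of the analysis ROI in mm.
#' @return Area in mm^2.
#' @export
contour_area_6db <- function(image, center = NULL, roi_size_mm = 10) {
  stopifnot(inherits(image, "bimage"))
  if (is.null(center)) center <- brightest_pixel(image)
  r <- roi_square(center, roi_size_mm)
  ix <- resolve_roi(r, image$grid)
  sub <- image$linear_amplitude[ix$rows, ix$cols]
  mx <- max(sub)
  if (mx <= 0) stop("contour_area_6db: ROI is identically zero", call. = FALSE)
  mask <- sub >= 10^(-6 / 20) * mx
  labs <- label_components_8(mask)
  pk <- which(sub == mx, arr.ind = TRUE)[1, ]
  npx <- sum(labs == labs[pk[1], pk[2]])
  npx * image$grid$dx * image$grid$dz
}

#' Brightest pixel of an image
#'
#' @param image a [bimage()].
#' @return `(x, z)` coordinates in mm of the global amplitude maximum; ties
#'   resolved to the first pixel in row-major scan order (a note is logged).
#' @export
brightest_pixel <- function(image) {
  m <- image$linear_amplitude
  hits <- which(m == max(m), arr.ind = TRUE)
  if (nrow(hits) > 1) {
    message("brightest_pixel: ", nrow(hits),
            " tied maxima; taking the first in row-major order")
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  }
  c(x = image$grid$lateral[hits[1, 2]], z = image$grid$axial[hits[1, 1]])
}

#' Distance between image peak and amplitude centre of mass
#'
#' A compactness measure of a photoacoustic target: the Euclidean distance
#' (mm) between the amplitude-weighted centre of mass of the ROI and its
#' brightest pixel. Small for compact, well-focused targets; large for
#' diffuse ones. With `threshold` set, the centre of mass is restricted to
#' the 8-connected suprathreshold component containing the peak — the
#' segmented target blob, matching how centres of mass are computed for
#' landmark extraction — so the measure reflects the target's shape rather
#' than the background floor.
#'
#' @param image a [bimage()].
#' @param r optional [roi()] (default: whole image).
#' @param threshold optional fraction of the ROI maximum (e.g. 0.3); the
#'   centre of mass then uses only the connected component (containing the
#'   peak) of pixels at or above it.
#' @return Distance in mm.
#' @export
peak_to_com_distance <- function(image, r = NULL, threshold = NULL) {
  g <- image$grid
  if (is.null(r)) {
    rows <- seq_len(g$nz); cols <- seq_len(g$nx)
  } else {
    ix <- resolve_roi(r, g); rows <- ix$rows; cols <- ix$cols
  }
  sub <- image$linear_amplitude[rows, cols]
  mx <- max(sub)
  if (mx <= 0) stop("peak_to_com_distance: ROI maximum is zero", call. = FALSE)
  if (!is.null(threshold)) {
    labs <- label_components_8(sub >= threshold * mx)
    pk0 <- which(sub == mx, arr.ind = TRUE)[1, ]
    sub <- sub * (labs == labs[pk0[1], pk0[2]])
  }
  hits <- which(sub == mx, arr.ind = TRUE)
  if (nrow(hits) > 1) {
    message("peak_to_com_distance: tied maxima; taking the first in row-major order")
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  }
  xk <- g$lateral[cols]; zk <- g$axial[rows]
  tot <- sum(sub)
  com <- c(sum(colSums(sub) * xk), sum(rowSums(sub) * zk)) / tot
  peak <- c(xk[hits[1, 2]], zk[hits[1, 1]])
  sqrt(sum((com - peak)^2))
}

#' Box-plot summary with the 1.5 IQR outlier rule
#'
#' @param x numeric vector.
#' @return One-row tibble: n, median, q1, q3, min, max, and a list column of
#'   outliers (values beyond 1.5 interquartile ranges from the quartiles).
#' @export
box_stats <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  out <- x[x < q[1] - 1.5 * iqr | x > q[3] + 1.5 * iqr]
  tibble::tibble(n = length(x), median = q[2], q1 = q[1], q3 = q[3],
                 min = min(x), max = max(x), outliers = list(out))
}

#' Compare -6 dB areas between bone-contact groups
#'
#' Two-sample Welch t-test (two-sided, unequal variances) on per-frame
#' contour areas from two bone-contact conditions, plus per-group box-plot
#' summaries. Welch's variant is used because the two groups typically show
#' very unequal spreads.
#'
#' @param areas_a,areas_b numeric vectors of per-frame areas (mm^2), e.g. the
#'   cancellous and cortical groups.
#' @param labels length-2 character group labels.
#' @return Object of class `bone_contact_test`: list with `mean_difference`
#'   (`mean(a) - mean(b)`), `statistic`, `p_value`, `groups` (tibble of
#'   box-plot summaries) and the raw `data` tibble.
#' @export
compare_bone_contact <- function(areas_a, areas_b,
                                 labels = c("cancellous", "cortical")) {
  stopifnot(length(areas_a) >= 2, length(areas_b) >= 2)
  tt <- stats::t.test(areas_a, areas_b, var.equal = FALSE)
  groups <- rbind(cbind(group = labels[1], box_stats(areas_a)),
                  cbind(group = labels[2], box_stats(areas_b)))
  structure(list(mean_difference = mean(areas_a) - mean(areas_b),
                 statistic = unname(tt$statistic), p_value = tt$p.value,
                 groups = tibble::as_tibble(groups),
                 data = tibble::tibble(
                   group = rep(labels, c(length(areas_a), length(areas_b))),
                   area_mm2 = c(areas_a, areas_b))),
            class = "bone_contact_test")
}

#' @export
print.bone_contact_test <- function(x, ...) {
  cat(sprintf("<bone_contact_test> mean difference %.3f mm^2, t = %.3f, p = %.3g\n",
              x$mean_difference, x$statistic, x$p_value))
  print(x$groups[, c("group", "n", "median", "q1", "q3", "min", "max")])
  invisible(x)
}

#' Tidy a bone-contact comparison
#'
#' @param x a [compare_bone_contact()] result.
#' @param ... unused.
#' @return `tidy()`: per-group summary tibble; `glance()`: one-row tibble
#'   with the test statistics.
#' @export
#' @method tidy bone_contact_test
tidy.bone_contact_test <- function(x, ...) x$groups

#' @rdname tidy.bone_contact_test
#' @export
#' @method glance bone_contact_test
glance.bone_contact_test <- function(x, ...) {
  tibble::tibble(mean_difference = x$mean_difference,
                 statistic = x$statistic, p_value = x$p_value)
}
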