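#' Beamformed image container
#'
#' Holds a nonnegative linear-amplitude image on an [image_grid()] together
#' with the beamformer tag. For coherence beamformers the raw (possibly
#' negative) pixel values remain accessible in `$raw`; `$linear_amplitude`
#' is clamped at zero so that log compression and the amplitude metrics are
#' well defined.
#'
#' @param linear_amplitude nonnegative `nz x nx` matrix.
#' @param grid an [image_grid()].
#' @param tag one of `"DAS"`, `"SLSC"`, `"LWSLSC"`.
#' @param raw optional signed pixel values before clamping.
#' @return An object of class `bimage`.
#' @export
bimage <- function(linear_amplitude, grid, tag = c("DAS", "SLSC", "LWSLSC"),
                   raw = NULL) {
  tag <- match.arg(tag)
  stopifnot(is.matrix(linear_amplitude), all(is.finite(linear_amplitude)),
            nrow(linear_amplitude) == grid$nz, ncol(linear_amplitude) == grid$nx,
            all(linear_amplitude >= 0))
  structure(list(linear_amplitude = linear_amplitude, grid = grid,
                 beamformer_tag = tag, raw = raw,
                 normalization = max(linear_amplitude)),
            class = "bimage")
}

#' @export
print.bimage <- function(x, ...) {
  cat(sprintf("<bimage> %s, %d x %d px (%.3g x %.3g mm), max %.4g\n",
              x$beamformer_tag, x$grid$nz, x$grid$nx,
              diff(range(x$grid$axial)), diff(range(x$grid$lateral)),
              x$normalization))
  invisible(x)
}

#' Delay-and-sum of one focused line
#'
#' Coherent sum of the time-aligned channels, normalized by the number of
#' valid channels per pixel so that image brightness is comparable across
#' aperture masks; pixels where no channel is valid are 0.
#'
#' @param aperture a `delayed_aperture` from [delay_channels()].
#' @return Numeric vector of signed RF pixel values (one per depth sample).
#' @export
das_line <- function(aperture) {
  n_ok <- rowSums(aperture$valid)
  out <- rowSums(aperture$values * aperture$valid) / pmax(n_ok, 1)
  out[n_ok == 0] <- 0
  out
}

#' Delay-and-sum beamforming of a focused frame
#'
#' @param focused output of [focus_frame()].
#' @return Signed RF image matrix (`nz x nx`); use [envelope_detect()] for
#'   the amplitude image.
#' @export
das_rf <- function(focused) {
  nz <- dim(focused$values)[1]; nx <- dim(focused$values)[3]
  rf <- matrix(0, nz, nx)
  for (ix in seq_len(nx)) {
    ap <- list(values = focused$values[, , ix], valid = focused$valid[, , ix])
    rf[, ix] <- das_line(ap)
  }
  rf
}

# analytic signal per column via FFT (Marple's single-sided spectrum method)
analytic_signal <- function(x) {
  n <- nrow(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::mvfft(stats::mvfft(x) * h, inverse = TRUE) / n
}

#' Envelope detection
#'
#' Magnitude of the axial analytic signal of an RF image.
#'
#' @param rf_image signed RF matrix (`nz x nx`, depth along rows).
#' @param grid an [image_grid()].
#' @param tag beamformer tag for the resulting [bimage()].
#' @return A [bimage()] with nonnegative `linear_amplitude`.
#' @export
envelope_detect <- function(rf_image, grid, tag = "DAS") {
  stopifnot(all(is.finite(rf_image)))
  env <- Mod(analytic_signal(rf_image))
  bimage(env, grid, tag = tag, raw = rf_image)
}

#' Log compression for display
#'
#' @param image a [bimage()].
#' @param dynamic_range_db display dynamic range in dB (positive).
#' @return Matrix of dB values in `[-dynamic_range_db, 0]`, normalized to the
#'   image maximum.
#' @export
log_compress <- function(image, dynamic_range_db = 25) {
  stopifnot(inherits(image, "bimage"), dynamic_range_db > 0)
  mx <- max(image$linear_amplitude)
  if (mx <= 0) stop("log_compress: all-zero image cannot be normalized", call. = FALSE)
  db <- 20 * log10(pmax(image$linear_amplitude, .Machine$double.xmin) / mx)
  pmax(db, -dynamic_range_db)
}

#' Scan conversion for convex arrays
#'
#' Maps an image sampled in beam space (range along the beam x beam angle)
#' onto a Cartesian grid by bilinear interpolation. Beams are radial lines
#' from the arc centre of curvature located at `(0, -R)`; a beam-space sample
#' at angle `theta` and range `r` (mm beyond the array face) lies at
#' `x = (R + r) sin(theta)`, `z = (R + r) cos(theta) - R`. Cartesian pixels
#' outside the imaged sector are 0 and masked. For a linear geometry the
#' input image is returned unchanged (identity pass-through).
#'
#' @param image a [bimage()]; for a convex geometry its rows index `ranges`
#'   and its columns `angles`.
#' @param geometry an [array_geometry()].
#' @param angles beam angles in radians (one per image column).
#' @param ranges ranges in mm beyond the array face (one per image row).
#' @param grid target Cartesian [image_grid()]; defaults to a grid covering
#'   the sector at half-wavelength spacing.
#' @return A [bimage()] on `grid` with attribute `sector_mask` (logical
#'   matrix, `TRUE` inside the imaged sector).
#' @export
scan_convert <- function(image, geometry, angles = NULL, ranges = NULL,
                         grid = NULL) {
  stopifnot(inherits(image, "bimage"))
  if (is.null(geometry$curvature_radius)) return(image)
  R <- geometry$curvature_radius
  img <- image$linear_amplitude
  if (is.null(ranges)) ranges <- image$grid$axial
  if (is.null(angles)) {
    stop("scan_convert: beam angles must be supplied for a convex geometry",
         call. = FALSE)
  }
  stopifnot(length(ranges) == nrow(img), length(angles) == ncol(img))
  if (is.null(grid)) {
    rmax <- max(ranges)
    xmax <- (R + rmax) * sin(max(abs(angles)))
    sp <- geometry$wavelength / 2
    grid <- image_grid(seq(-xmax, xmax, by = sp), seq(0, rmax, by = sp))
  }
  px <- rep(grid$lateral, each = grid$nz)
  pz <- rep(grid$axial, times = grid$nx)
  rr <- sqrt(px^2 + (pz + R)^2) - R
  th <- atan2(px, pz + R)
  # fractional indices into the (range, angle) sampling
  fi <- (rr - ranges[1]) / (ranges[2] - ranges[1]) + 1
  fj <- (th - angles[1]) / (angles[2] - angles[1]) + 1
  inside <- fi >= 1 & fi <= length(ranges) & fj >= 1 & fj <= length(angles)
  i0 <- pmin(pmax(floor(fi), 1), length(ranges) - 1)
  j0 <- pmin(pmax(floor(fj), 1), length(angles) - 1)
  wi <- fi - i0; wj <- fj - j0
  v <- (1 - wi) * (1 - wj) * img[cbind(i0, j0)] +
       wi * (1 - wj) * img[cbind(i0 + 1, j0)] +
       (1 - wi) * wj * img[cbind(i0, j0 + 1)] +
       wi * wj * img[cbind(i0 + 1, j0 + 1)]
  v[!inside] <- 0
  out <- bimage(matrix(v, grid$nz, grid$nx), grid, tag = image$beamformer_tag)
  attr(out, "sector_mask") <- matrix(inside, grid$nz, grid$nx)
  out
}
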