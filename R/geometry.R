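#' Transducer array geometry
#'
#' Describes a linear or convex ultrasound array: element count, pitch, kerf,
#' optional radius of curvature, and the centre frequency used to derive the
#' wavelength. Element positions are computed in the imaging plane with the
#' lateral axis `x` along the array and the axial axis `z` increasing with
#' depth away from the array face. For a convex array the elements lie on an
#' arc whose centre of curvature sits behind the probe at `z = -curvature_radius`,
#' so the central element is at `z = 0` and edge elements at `z < 0`.
#'
#' @param n_elements number of transducer elements (>= 2).
#' @param pitch element centre-to-centre spacing in mm.
#' @param kerf gap between elements in mm (`pitch > kerf >= 0`).
#' @param center_frequency transmit/receive centre frequency in MHz.
#' @param curvature_radius radius of curvature in mm, or `NULL` for a linear
#'   array.
#' @param sound_speed speed of sound in m/s used to derive the wavelength.
#'
#' @return An object of class `array_geometry`: a list with fields
#'   `n_elements`, `pitch`, `kerf`, `curvature_radius`, `center_frequency`,
#'   `wavelength` (mm) and `element_positions` (an `n_elements` x 2 matrix of
#'   (x, z) coordinates in mm).
#' @export
#' @examples
#' geom <- array_geometry(128, pitch = 0.3, kerf = 0.06, center_frequency = 4)
#' geom$wavelength  # 0.385 mm at 1540 m/s
array_geometry <- function(n_elements, pitch, kerf = 0, center_frequency,
                           curvature_radius = NULL, sound_speed = 1540) {
  stopifnot(n_elements >= 2, pitch > 0, center_frequency > 0, sound_speed > 0)
  if (!(pitch > kerf && kerf >= 0)) {
    stop("array_geometry: require pitch > kerf >= 0", call. = FALSE)
  }
  # mm = (m/s) / (MHz * 1000)
  wavelength <- sound_speed / (center_frequency * 1000)
  idx <- seq_len(n_elements) - (n_elements + 1) / 2
  if (is.null(curvature_radius)) {
    pos <- cbind(x = idx * pitch, z = rep(0, n_elements))
  } else {
    stopifnot(curvature_radius > 0)
    theta <- idx * pitch / curvature_radius  # arc-length pitch
    pos <- cbind(x = curvature_radius * sin(theta),
                 z = -curvature_radius * (1 - cos(theta)))
  }
  structure(list(n_elements = as.integer(n_elements), pitch = pitch,
                 kerf = kerf, curvature_radius = curvature_radius,
                 center_frequency = center_frequency,
                 sound_speed = sound_speed,
                 wavelength = wavelength, element_positions = pos),
            class = "array_geometry")
}

#' @export
print.array_geometry <- function(x, ...) {
  kind <- if (is.null(x$curvature_radius)) "linear" else
    sprintf("convex (R = %g mm)", x$curvature_radius)
  cat(sprintf("<array_geometry> %d-element %s array, pitch %g mm, kerf %g mm, fc %g MHz (lambda %.4g mm)\n",
              x$n_elements, kind, x$pitch, x$kerf, x$center_frequency, x$wavelength))
  invisible(x)
}

#' Cartesian image grid
#'
#' Pixel-centre coordinates for a beamformed image. Coordinates must be
#' strictly increasing and uniformly spaced; `axial` is depth from the array
#' face in mm.
#'
#' @param lateral,axial numeric vectors of pixel-centre coordinates in mm.
#' @return An object of class `image_grid` with fields `lateral`, `axial`,
#'   `dx`, `dz`, `nx`, `nz`.
#' @export
image_grid <- function(lateral, axial) {
  chk <- function(v, nm) {
    if (length(v) < 2) stop("image_grid: ", nm, " needs >= 2 coordinates", call. = FALSE)
    d <- diff(v)
    if (any(d <= 0)) stop("image_grid: ", nm, " must be strictly increasing", call. = FALSE)
    if (max(abs(d - d[1])) > 1e-9 * abs(d[1])) {
      stop("image_grid: ", nm, " must be uniformly spaced", call. = FALSE)
    }
    d[1]
  }
  dx <- chk(lateral, "lateral")
  dz <- chk(axial, "axial")
  structure(list(lateral = lateral, axial = axial, dx = dx, dz = dz,
                 nx = length(lateral), nz = length(axial)),
            class = "image_grid")
}

#' Default imaging grid for a geometry
#'
#' Builds a grid spanning the array's lateral extent down to `depth_mm`, with
#' pixel spacing `spacing_mm` (default half a wavelength).
#'
#' @param geometry an [array_geometry()].
#' @param depth_mm maximum image depth in mm.
#' @param min_depth_mm minimum image depth in mm.
#' @param spacing_mm pixel spacing in mm (both axes).
#' @return An [image_grid()].
#' @export
default_grid <- function(geometry, depth_mm, min_depth_mm = 1,
                         spacing_mm = geometry$wavelength / 2) {
  xmax <- max(abs(geometry$element_positions[, "x"]))
  image_grid(lateral = seq(-xmax, xmax, by = spacing_mm),
             axial = seq(min_depth_mm, depth_mm, by = spacing_mm))
}
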